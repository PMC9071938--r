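# Internal helpers shared across modules.

# Centered-FFT index shift for n-dimensional arrays (DC moved to grid centre).
fftshiftN <- function(x, inverse = FALSE) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    h <- if (inverse) ceiling(n / 2) else floor(n / 2)
    c(seq_len(n)[-seq_len(h)], seq_len(h))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Round-half-up to integer (printed-percent convention).
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

stopifnot_finite <- function(x, what = "input") {
  if (any(!is.finite(Re(x))) || any(!is.finite(Im(x))))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(TRUE)
}

# Derive a per-stage seed from a global seed; keeps results < 2^31.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 97 + offset * 1009) %% 2147483647)
}

# Wrap radians to [-pi, pi).
wrapPhase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out >= pi] <- -pi  # guard exact boundary
  out
}

# complex array <-> 2-channel real array (H x W x 2), channel 1 = Re.
cplxToChan <- function(z) {
  array(c(Re(z), Im(z)), dim = c(dim(z), 2L))
}
chanToCplx <- function(a) {
  d <- dim(a)
  matrix(complex(real = a[, , 1L], imaginary = a[, , 2L]), d[1L], d[2L])
}
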
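#' Construct a ComplexImage
#'
#' @param values complex (or real, promoted to complex) 2D/3D array
#' @param spacing mm per axis; recycled to the array dimensionality
#' @return a \linkS4class{ComplexImage}
#' @export
complexImage <- function(values, spacing = 1) {
  if (is.null(dim(values))) stop("values must have a dim attribute")
  stopifnot_finite(values, "image")
  if (!is.complex(values)) {
    values <- array(complex(real = values, imaginary = 0), dim(values))
  }
  spacing <- rep_len(as.numeric(spacing), length(dim(values)))
  new("ComplexImage", values = values, spacing = spacing)
}

#' Forward and inverse Fourier transforms (centered, orthonormal)
#'
#' The project-wide spectral convention: DC at the grid centre and
#' orthonormal scaling, so that Parseval's identity holds exactly and the
#' round trip is the identity to floating-point precision.
#'
#' @param img a \linkS4class{ComplexImage}
#' @return \code{forwardFFT}: a \linkS4class{KSpace}; \code{inverseFFT}: a
#'   \linkS4class{ComplexImage}
#' @examples
#' x <- complexImage(array(rnorm(64), c(8, 8)))
#' k <- forwardFFT(x)
#' max(Mod(imgValues(inverseFFT(k)) - imgValues(x)))  # ~1e-16
#' @export
forwardFFT <- function(img) {
  if (!is(img, "ComplexImage")) img <- complexImage(img)
  v <- img@values
  stopifnot_finite(v, "image")
  k <- fftshiftN(stats::fft(fftshiftN(v, inverse = TRUE))) / sqrt(length(v))
  new("KSpace", values = k, spacing = img@spacing, centered = TRUE)
}

#' @rdname forwardFFT
#' @param k a \linkS4class{KSpace}
#' @export
inverseFFT <- function(k) {
  v <- if (is(k, "KSpace")) k@values else k
  stopifnot_finite(v, "k-space")
  sp <- if (is(k, "KSpace")) k@spacing else rep(1, length(dim(v)))
  x <- fftshiftN(stats::fft(fftshiftN(v, inverse = TRUE), inverse = TRUE)) /
    sqrt(length(v))
  new("ComplexImage", values = x, spacing = sp)
}

#' Variable-density Cartesian undersampling mask
#'
#' Retains a fully sampled central band of phase-encode lines
#' (\code{centerFraction} of columns) and samples the remaining lines
#' without replacement with probability density decaying with distance from
#' the centre, so that the total kept fraction is 1/acceleration. The mask
#' is constant along the frequency-encode (row) axis.
#'
#' @param shape grid shape (2 ints)
#' @param acceleration nominal undersampling factor (>= 1)
#' @param centerFraction fraction of central lines always kept (in [0, 1))
#' @param seed RNG seed; same seed gives an identical mask
#' @return a \linkS4class{SamplingMask}
#' @export
makeSamplingMask <- function(shape, acceleration = 4, centerFraction = 0.08,
                             seed = 1L) {
  if (acceleration < 1) stop("acceleration must be >= 1")
  if (centerFraction >= 1) stop("centerFraction must be < 1")
  ny <- shape[2]
  keepLines <- rep(FALSE, ny)
  nKeep <- max(1L, round(ny / acceleration))
  nCenter <- min(nKeep, max(0L, round(ny * centerFraction)))
  mid <- (ny + 1) / 2
  ord <- order(abs(seq_len(ny) - mid))
  keepLines[ord[seq_len(nCenter)]] <- TRUE
  nRand <- nKeep - nCenter
  if (nRand > 0) {
    cand <- which(!keepLines)
    # variable density: weight ~ 1/(1 + normalized distance from centre)^2
    w <- 1 / (1 + (abs(cand - mid) / (ny / 2)))^2
    withr_seed <- deriveSeed(seed, 7L)
    old <- .Random.seed_exists()
    set.seed(withr_seed)
    pick <- sample(cand, nRand, prob = w)
    restoreSeedState(old)
    keepLines[pick] <- TRUE
  }
  keep <- matrix(rep(keepLines, each = shape[1]), shape[1], ny)
  new("SamplingMask", keep = keep, acceleration = acceleration,
      centerFraction = centerFraction)
}

# Preserve / restore the caller's RNG state around internally seeded draws.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
restoreSeedState <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Data-consistency operator
#'
#' Re-imposes measured k-space samples on a network prediction. At
#' unsampled locations the prediction passes through; at sampled locations
#' the output is \code{(k_pred + lambda * k_meas) / (1 + lambda)}. The
#' default \code{lambda = Inf} is hard replacement: measured samples are
#' restored exactly, making the operator idempotent.
#'
#' @param kPred predicted \linkS4class{KSpace}
#' @param kMeas measured \linkS4class{KSpace}
#' @param mask a \linkS4class{SamplingMask}
#' @param lambda non-negative consistency weight; Inf = hard
#' @return a \linkS4class{KSpace}
#' @export
dataConsistency <- function(kPred, kMeas, mask, lambda = Inf) {
  p <- if (is(kPred, "KSpace")) kPred@values else kPred
  m <- if (is(kMeas, "KSpace")) kMeas@values else kMeas
  keep <- maskKeep(mask)
  if (!identical(dim(p), dim(m)) || !identical(dim(p), dim(keep)))
    stop("k-space and mask shapes must agree")
  if (lambda < 0) stop("lambda must be non-negative")
  out <- p
  if (is.infinite(lambda)) {
    out[keep] <- m[keep]
  } else {
    out[keep] <- (p[keep] + lambda * m[keep]) / (1 + lambda)
  }
  sp <- if (is(kPred, "KSpace")) kPred@spacing else rep(1, length(dim(p)))
  new("KSpace", values = out, spacing = sp, centered = TRUE)
}

#' Zero-filled reconstruction
#'
#' Inverse transform of the undersampled k-space with missing samples at
#' zero; the baseline any learned reconstruction must beat.
#'
#' @param kMeas measured (already masked) \linkS4class{KSpace}
#' @param mask a \linkS4class{SamplingMask}
#' @return a \linkS4class{ComplexImage}
#' @export
zeroFilled <- function(kMeas, mask = NULL) {
  v <- if (is(kMeas, "KSpace")) kMeas@values else kMeas
  if (!is.null(mask)) v[!maskKeep(mask)] <- 0 + 0i
  sp <- if (is(kMeas, "KSpace")) kMeas@spacing else rep(1, length(dim(v)))
  inverseFFT(new("KSpace", values = v, spacing = sp, centered = TRUE))
}

#' Serialize a k-space + mask measurement pair
#'
#' The container is a NIfTI pair (real and imaginary parts), a mask NIfTI,
#' and a JSON sidecar holding acceleration, seed and spacing, written under
#' a common path prefix.
#'
#' @param k a \linkS4class{KSpace}
#' @param mask a \linkS4class{SamplingMask}
#' @param prefix output path prefix (files `<prefix>_{real,imag,mask}.nii.gz`
#'   and `<prefix>.json`)
#' @param seed seed to record
#' @return invisibly, the sidecar path
#' @export
writeKSpace <- function(k, mask, prefix, seed = NA_integer_) {
  RNifti::writeNifti(Re(k@values), paste0(prefix, "_real.nii.gz"))
  RNifti::writeNifti(Im(k@values), paste0(prefix, "_imag.nii.gz"))
  RNifti::writeNifti(array(as.numeric(maskKeep(mask)), dim(maskKeep(mask))),
                     paste0(prefix, "_mask.nii.gz"))
  side <- list(acceleration = mask@acceleration,
               centerFraction = mask@centerFraction,
               spacing = k@spacing, seed = seed, centered = k@centered)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' @rdname writeKSpace
#' @return \code{readKSpace}: list with elements \code{k} and \code{mask}
#' @export
readKSpace <- function(prefix) {
  re <- as.array(RNifti::readNifti(paste0(prefix, "_real.nii.gz")))
  im <- as.array(RNifti::readNifti(paste0(prefix, "_imag.nii.gz")))
  mk <- as.array(RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))) > 0.5
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  k <- new("KSpace", values = array(complex(real = re, imaginary = im), dim(re)),
           spacing = as.numeric(side$spacing), centered = isTRUE(side$centered))
  mask <- new("SamplingMask", keep = array(mk, dim(re)),
              acceleration = side$acceleration,
              centerFraction = side$centerFraction)
  list(k = k, mask = mask, seed = side$seed)
}
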
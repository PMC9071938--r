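#' Homodyne high-pass phase correction
#'
#' Removes slowly varying background phase: the complex image
#' \code{m * exp(i*phi)} is divided by its low-pass version, where the
#' low-pass keeps only a central k-space window (32 x 32 or 64 x 64 by
#' convention) with Hann apodization to suppress ringing. The corrected
#' phase is the argument of the quotient: background trends vanish while
#' compact phase defects (microbleeds, veins) survive.
#'
#' @param pair a \linkS4class{MagnitudePhasePair}
#' @param window central window size in k-space samples (32 or 64; other
#'   sizes allowed with a warning)
#' @param apodization "hann" (default) or "none"
#' @return corrected phase array, wrapped to [-pi, pi)
#' @export
highpassPhase <- function(pair, window = 64, apodization = c("hann", "none")) {
  apodization <- match.arg(apodization)
  d <- dim(pair@magnitude)
  if (window > min(d[1:2])) stop("filter window larger than the image grid")
  if (!window %in% c(32, 64))
    warning("window ", window, " is non-standard (32 or 64 expected)")
  win1d <- function(n, full) {
    w <- numeric(full)
    mid <- floor(full / 2) + 1
    off <- seq(-floor(n / 2), ceiling(n / 2) - 1)   # DC-centred offsets
    idx <- mid + off
    sel <- idx >= 1 & idx <= full
    # symmetric about the DC bin so the kernel stays real (zero-phase)
    w[idx[sel]] <- if (apodization == "hann")
      0.5 * (1 + cos(2 * pi * off[sel] / n)) else 1
    w
  }
  wx <- win1d(window, d[1]); wy <- win1d(window, d[2])
  win2d <- outer(wx, wy)
  nz <- if (length(d) == 3) d[3] else 1L
  corrected <- array(0, d)
  cm <- array(complex(modulus = pair@magnitude, argument = pair@phase), d)
  for (z in seq_len(nz)) {
    sl <- if (length(d) == 3) cm[, , z] else cm
    k <- fftshiftN(stats::fft(fftshiftN(sl, inverse = TRUE)))
    lp <- fftshiftN(stats::fft(fftshiftN(k * win2d, inverse = TRUE),
                               inverse = TRUE)) / length(sl)
    q <- sl * Conj(lp)   # argument of sl / lp without division blow-ups
    phi <- wrapPhase(Arg(q))
    if (length(d) == 3) corrected[, , z] <- phi else corrected <- phi
  }
  corrected
}

#' Negative-phase mask
#'
#' Maps corrected phase to voxel weights: \code{(pi + phi)/pi} for
#' negative phase, 1 otherwise, raised to the m-th power (default m = 4).
#' Paramagnetic structures with negative phase are thereby attenuated when
#' the mask multiplies the magnitude.
#'
#' @param phase corrected phase array (wrapped)
#' @param m number of mask multiplications (integer >= 0)
#' @return a \linkS4class{PhaseMask}
#' @export
negativePhaseMask <- function(phase, m = 4L) {
  w <- ifelse(phase < 0, (pi + phase) / pi, 1)
  w <- pmin(pmax(w, 0), 1)^m
  new("PhaseMask", weights = array(w, dim(phase)), m = as.numeric(m))
}

#' Compose the susceptibility-weighted image
#'
#' Voxelwise product of the magnitude image and the phase-mask weights;
#' the result never exceeds the magnitude.
#'
#' @param pair a \linkS4class{MagnitudePhasePair}
#' @param mask a \linkS4class{PhaseMask}
#' @param filterWindow provenance: the high-pass window used
#' @return a \linkS4class{SWIVolume}
#' @export
composeSWI <- function(pair, mask, filterWindow = 64) {
  if (!identical(dim(pair@magnitude), dim(mask@weights)))
    stop("magnitude and mask shapes must agree")
  new("SWIVolume", values = pair@magnitude * mask@weights,
      spacing = pair@spacing, filterWindow = filterWindow, m = mask@m)
}

#' Minimum-intensity projection
#'
#' Each output slice is the voxelwise minimum over a slab of input slices,
#' rendering dark veins and microbleeds as continuous dark structures.
#' Slabs are taken over consecutive non-overlapping groups of
#' \code{slab_thickness} slices (the last slab may be thinner).
#'
#' @param swi a \linkS4class{SWIVolume} (or 3D array)
#' @param slab_thickness slices per slab (>= 1; clamped to the volume depth
#'   with a warning when larger)
#' @return 3D array of projected slices (one per slab)
#' @export
minIntensityProjection <- function(swi, slab_thickness = 8L) {
  v <- if (is(swi, "SWIVolume")) swi@values else swi
  stopifnot(slab_thickness >= 1)
  nz <- dim(v)[3]
  if (slab_thickness > nz) {
    warning("slab thicker than the volume; clamped to ", nz, " slices")
    slab_thickness <- nz
  }
  starts <- seq(1, nz, by = slab_thickness)
  out <- array(0, c(dim(v)[1:2], length(starts)))
  for (i in seq_along(starts)) {
    idx <- starts[i]:min(starts[i] + slab_thickness - 1, nz)
    out[, , i] <- apply(v[, , idx, drop = FALSE], c(1, 2), min)
  }
  out
}

#' Full SWI chain for one subject
#'
#' Convenience wrapper: high-pass phase correction, negative-phase mask,
#' magnitude weighting and (optionally) the minimum-intensity projection.
#'
#' @param pair a \linkS4class{MagnitudePhasePair}
#' @param window high-pass window (32 or 64)
#' @param m mask multiplications
#' @param mip_slab slab thickness for the projection; NULL to skip
#' @return list: \code{swi} (\linkS4class{SWIVolume}), \code{mask},
#'   \code{correctedPhase}, \code{mip} (or NULL)
#' @export
swiPipeline <- function(pair, window = 64, m = 4L, mip_slab = 8L) {
  phi <- highpassPhase(pair, window)
  mask <- negativePhaseMask(phi, m)
  swi <- composeSWI(pair, mask, filterWindow = window)
  mip <- if (is.null(mip_slab)) NULL else minIntensityProjection(swi, mip_slab)
  list(swi = swi, mask = mask, correctedPhase = phi, mip = mip)
}
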
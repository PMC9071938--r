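#' Vertebrobasilar geometry specification
#'
#' Parameters of the synthetic vertebrobasilar tree: the two vertebral
#' artery diameters, the basilar curvature type and lateral amplitude, and
#' the confluence point where the vertebrals merge into the basilar.
#' Laterality convention: +x is the subject's left, so a C-type basilar
#' bows toward the subject's left (positive lateral deviation) and a
#' reverse-C toward the right.
#'
#' @param left_diameter,right_diameter vertebral diameters in mm, in
#'   (0.5, 6.0)
#' @param basilar_curvature_type one of "normal", "C", "reverse_C", "S"
#' @param basilar_amplitude peak lateral deviation in mm (>= 0; must be 0
#'   iff type is "normal")
#' @param confluence_point mm coordinates of the vertebrobasilar junction
#' @param basilar_length chord length of the basilar segment in mm
#' @param seed integer seed (used for reproducible point jitter, if any)
#' @return validated list of class "vesselGeometrySpec"
#' @export
vesselGeometrySpec <- function(left_diameter = 3.5, right_diameter = 3.2,
                               basilar_curvature_type = "normal",
                               basilar_amplitude = 0,
                               confluence_point = c(32, 32, 6),
                               basilar_length = 25, seed = 1L) {
  if (left_diameter <= 0.5 || left_diameter >= 6.0 ||
      right_diameter <= 0.5 || right_diameter >= 6.0)
    stop("vertebral diameters must lie in (0.5, 6.0) mm")
  basilar_curvature_type <- match.arg(basilar_curvature_type,
                                      c("normal", "C", "reverse_C", "S"))
  if (basilar_amplitude < 0) stop("amplitude must be >= 0")
  if ((basilar_curvature_type == "normal") != (basilar_amplitude == 0))
    stop("type 'normal' requires amplitude 0 and vice versa")
  structure(list(left_diameter = left_diameter,
                 right_diameter = right_diameter,
                 basilar_curvature_type = basilar_curvature_type,
                 basilar_amplitude = basilar_amplitude,
                 confluence_point = as.numeric(confluence_point),
                 basilar_length = basilar_length, seed = as.integer(seed)),
            class = "vesselGeometrySpec")
}

#' Build vertebrobasilar centerlines and the width field
#'
#' Two vertebral centerlines rise to the confluence point, continued by the
#' basilar centerline whose signed lateral (x) deviation from its chord
#' realises the requested curvature type: C is a single positive half-sine
#' lobe, reverse-C its mirror image, S a full sine period (one sign change,
#' both excursions reaching the amplitude), normal a straight segment. The
#' width field returns the local vessel diameter (mm) at an arc position;
#' vertebral widths are the specified constants, the basilar width is their
#' mean (vessels have Gaussian cross-sections of these diameters when
#' rasterised).
#'
#' @param spec a \code{\link{vesselGeometrySpec}}
#' @param n_points points per centerline
#' @return list with elements \code{left}, \code{right}, \code{basilar}
#'   (n x 3 mm matrices, ordered toward/away from the confluence) and
#'   \code{widthField}, a function \code{(s_mm, side)} returning diameter
#'   in mm for side "left", "right" or "basilar"
#' @export
makeVesselTree <- function(spec, n_points = 81L) {
  stopifnot(inherits(spec, "vesselGeometrySpec"))
  c0 <- spec$confluence_point
  t <- seq(0, 1, length.out = n_points)
  # vertebrals: gentle planar curves approaching the confluence from below
  vert <- function(side) {
    sgn <- if (side == "left") 1 else -1
    start <- c0 + c(sgn * 9, 2, -18)
    cbind(start[1] + (c0[1] - start[1]) * t - sgn * 2 * sin(pi * t),
          start[2] + (c0[2] - start[2]) * t,
          start[3] + (c0[3] - start[3]) * t)
  }
  dev <- switch(spec$basilar_curvature_type,
                normal = rep(0, n_points),
                C = spec$basilar_amplitude * sin(pi * t),
                reverse_C = -spec$basilar_amplitude * sin(pi * t),
                S = spec$basilar_amplitude * sin(2 * pi * t))
  basilar <- cbind(c0[1] + dev, rep(c0[2], n_points),
                   c0[3] + spec$basilar_length * t)
  widthField <- function(s_mm, side = c("left", "right", "basilar")) {
    side <- match.arg(side)
    rep_len(switch(side, left = spec$left_diameter,
                   right = spec$right_diameter,
                   basilar = mean(c(spec$left_diameter, spec$right_diameter))),
            length(s_mm))
  }
  list(left = vert("left"), right = vert("right"), basilar = basilar,
       widthField = widthField)
}

# cumulative arc length (mm) of an n x 3 centerline
.arcLength <- function(pts) {
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                       pts[-nrow(pts), , drop = FALSE])^2))
  if (any(d <= 0)) stop("centerline has duplicate consecutive points")
  c(0, cumsum(d))
}

#' Three-point vertebral diameter measurement
#'
#' Samples the vessel width at arc positions 0, 3 and 6 mm from the
#' vertebrobasilar confluence (the measurement starting point) and returns
#' their arithmetic mean as the side's diameter.
#'
#' @param centerline n x 3 mm matrix ordered starting at the confluence
#' @param widthField function(s_mm, side) returning local diameter in mm,
#'   or a function(s_mm) of one argument
#' @param side passed through to \code{widthField} when it accepts one
#' @return list: \code{diameter_mm} (mean) and \code{samples_mm} (the three
#'   sampled widths at 0, 3, 6 mm)
#' @export
measureDiameter <- function(centerline, widthField, side = "left") {
  arc <- .arcLength(centerline)
  pts <- c(0, 3, 6)
  if (max(arc) < 6)
    stop("centerline must extend >= 0.6 cm beyond the starting point")
  w <- if (length(formals(widthField)) >= 2) widthField(pts, side)
       else widthField(pts)
  list(diameter_mm = mean(w), samples_mm = w)
}

#' Vertebral artery dominance and asymmetry grade
#'
#' The dominant side is the larger vertebral when the diameter difference
#' is at least 0.3 mm, else none. Independently, the difference is graded:
#' Grade I for 0.04-0.70 mm, II for 0.71-1.17 mm, III for 1.18-2.67 mm
#' (half-open bands with midpoint boundaries 0.705 and 1.175 bridging the
#' printed gaps); differences outside [0.04, 2.67] are ungraded.
#'
#' @param left_diameter,right_diameter vertebral diameters in mm
#' @return list: \code{dominant_side} ("left"/"right"/"none"),
#'   \code{diff_mm}, \code{grade} ("I"/"II"/"III"/"ungraded")
#' @export
assessDominance <- function(left_diameter, right_diameter) {
  stopifnot(left_diameter > 0, right_diameter > 0)
  diff <- abs(left_diameter - right_diameter)
  side <- if (diff < 0.3) "none" else
    if (left_diameter > right_diameter) "left" else "right"
  grade <- if (diff < 0.04 || diff > 2.67) "ungraded"
    else if (diff < 0.705) "I"
    else if (diff < 1.175) "II"
    else "III"
  list(dominant_side = side, diff_mm = diff, grade = grade)
}

#' Basilar artery bending metrics and curvature typing
#'
#' BAL (basilar artery length) is the straight-line distance between the
#' centerline endpoints; BL (bending length) is the maximum perpendicular
#' distance of any centerline point to that chord. The curvature type comes
#' from the signed lateral-deviation profile along the chord: no excursion
#' beyond the threshold is "normal"; a single-signed excursion is "C"
#' (toward the subject's left, +x) or "reverse_C" (right); excursions of
#' both signs beyond the threshold are "S".
#'
#' @param centerline n x 3 mm matrix (n >= 3)
#' @param threshold_mm abnormal-deviation threshold (default 2 mm)
#' @return list: \code{bal_mm}, \code{bl_mm}, \code{curvature_type}
#' @export
basilarMetrics <- function(centerline, threshold_mm = 2) {
  stopifnot(nrow(centerline) >= 3)
  a <- centerline[1, ]; b <- centerline[nrow(centerline), ]
  chord <- b - a
  bal <- sqrt(sum(chord^2))
  if (bal < 1e-9) stop("degenerate centerline: endpoints coincide")
  u <- chord / bal
  rel <- sweep(centerline, 2, a)
  along <- rel %*% u
  perp <- rel - outer(as.vector(along), u)
  bl <- max(sqrt(rowSums(perp^2)))
  # signed lateral deviation: project the perpendicular onto the lateral
  # reference (+x = subject's left) orthogonalised against the chord
  lat <- c(1, 0, 0) - sum(u * c(1, 0, 0)) * u
  nl <- sqrt(sum(lat^2))
  signedDev <- if (nl < 1e-9) rep(0, nrow(centerline))
    else as.vector(perp %*% (lat / nl))
  posMax <- max(signedDev); negMin <- min(signedDev)
  type <- if (posMax >= threshold_mm && -negMin >= threshold_mm) "S"
    else if (posMax >= threshold_mm) "C"
    else if (-negMin >= threshold_mm) "reverse_C"
    else "normal"
  list(bal_mm = bal, bl_mm = bl, curvature_type = type)
}

#' Morphometry of one subject's vessel tree
#'
#' Runs three-point diameter measurement on both vertebrals, the dominance
#' assessment, and basilar bending metrics; returns one results row.
#'
#' @param tree output of \code{\link{makeVesselTree}}
#' @param threshold_mm curvature threshold passed to
#'   \code{\link{basilarMetrics}}
#' @return one-row data.frame: left_mm, right_mm, diff_mm, dominant_side,
#'   grade, bal_mm, bl_mm, curvature_type
#' @export
vesselMorphometry <- function(tree, threshold_mm = 2) {
  # vertebral centerlines are ordered away from the confluence for
  # measurement: reverse them so arc position 0 is the confluence
  left <- measureDiameter(tree$left[nrow(tree$left):1, ], tree$widthField,
                          "left")
  right <- measureDiameter(tree$right[nrow(tree$right):1, ], tree$widthField,
                           "right")
  dom <- assessDominance(left$diameter_mm, right$diameter_mm)
  bas <- basilarMetrics(tree$basilar, threshold_mm)
  data.frame(left_mm = left$diameter_mm, right_mm = right$diameter_mm,
             diff_mm = dom$diff_mm, dominant_side = dom$dominant_side,
             grade = dom$grade, bal_mm = bas$bal_mm, bl_mm = bas$bl_mm,
             curvature_type = bas$curvature_type,
             stringsAsFactors = FALSE)
}

#' Read/write centerlines as CSV (ordered x_mm, y_mm, z_mm)
#' @param centerline n x 3 matrix
#' @param path CSV path
#' @return \code{readCenterline}: n x 3 matrix
#' @export
writeCenterline <- function(centerline, path) {
  colnames(centerline) <- c("x_mm", "y_mm", "z_mm")
  utils::write.csv(as.data.frame(centerline), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCenterline
#' @export
readCenterline <- function(path) {
  as.matrix(utils::read.csv(path)[, c("x_mm", "y_mm", "z_mm")])
}
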
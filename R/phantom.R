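#' Phantom specification
#'
#' Describes one synthetic brain-like acquisition: grid geometry, background
#' tissue ellipsoids, and the lesions to implant. All geometry is in mm with
#' the world origin at the volume corner and axes aligned with voxel axes.
#'
#' @param grid_shape voxels per axis (3 ints)
#' @param voxel_spacing mm per axis (3 positive floats)
#' @param n_background_ellipsoids number of random tissue ellipsoids
#' @param cmb_specs list of lists: \code{center} (mm, length 3),
#'   \code{diameter} (mm, must lie in the 1.5-6.5 mm microbleed band),
#'   \code{contrast} (susceptibility contrast in (0, 1], scales the negative
#'   phase offset and magnitude drop)
#' @param vein_specs list of lists: \code{polyline} (n x 3 mm matrix),
#'   \code{radius} (mm), \code{contrast}
#' @param lacune_specs list of lists: \code{center} (mm), \code{diameter}
#'   (mm, < 15)
#' @param noise_sd additive complex Gaussian noise SD (relative to unit
#'   tissue magnitude)
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   phantom
#' @return validated list of class "phantomSpec"
#' @export
phantomSpec <- function(grid_shape = c(64L, 64L, 32L),
                        voxel_spacing = c(1, 1, 1),
                        n_background_ellipsoids = 6L,
                        cmb_specs = list(), vein_specs = list(),
                        lacune_specs = list(),
                        noise_sd = 0.02, seed = 1L) {
  if (any(voxel_spacing <= 0)) stop("voxel_spacing must be positive")
  fov <- grid_shape * voxel_spacing
  checkCenter <- function(ctr, what) {
    if (any(ctr < 0) || any(ctr > fov))
      stop(what, " center outside the field of view")
  }
  for (s in cmb_specs) {
    if (s$diameter <= 0) stop("cmb diameter must be > 0")
    if (s$diameter < 1.5 || s$diameter > 6.5)
      stop("cmb diameter ", s$diameter,
           " mm outside the 1.5-6.5 mm microbleed band")
    checkCenter(s$center, "cmb")
  }
  for (s in lacune_specs) {
    if (s$diameter <= 0) stop("lacune diameter must be > 0")
    if (s$diameter >= 15)
      stop("lacune diameter ", s$diameter, " mm must be < 15 mm")
    checkCenter(s$center, "lacune")
  }
  for (s in vein_specs) {
    if (s$radius <= 0) stop("vein radius must be > 0")
    apply(s$polyline, 1, checkCenter, what = "vein")
  }
  # reject focal lesions whose spheres overlap (small tolerance)
  foci <- c(cmb_specs, lacune_specs)
  if (length(foci) > 1) {
    for (i in seq_len(length(foci) - 1)) for (j in (i + 1):length(foci)) {
      d <- sqrt(sum((foci[[i]]$center - foci[[j]]$center)^2))
      if (d < 0.5 * (foci[[i]]$diameter + foci[[j]]$diameter) + 1)
        stop("overlapping lesion specs: lesions ", i, " and ", j,
             " are only ", signif(d, 3), " mm apart")
    }
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 n_background_ellipsoids = as.integer(n_background_ellipsoids),
                 cmb_specs = cmb_specs, vein_specs = vein_specs,
                 lacune_specs = lacune_specs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantomSpec")
}

# mm coordinate grids for a phantom spec (voxel centres at (i - 0.5)*dx).
.mmGrids <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 0.5) * spacing[1],
       y = (seq_len(shape[2]) - 0.5) * spacing[2],
       z = (seq_len(shape[3]) - 0.5) * spacing[3])
}

# logical sphere mask around a mm centre
.sphereMask <- function(g, center, radius) {
  dx2 <- (g$x - center[1])^2
  dy2 <- (g$y - center[2])^2
  dz2 <- (g$z - center[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
}

# distance field (mm) from a polyline; returns array of min distances
.polylineDist <- function(g, poly) {
  shape <- c(length(g$x), length(g$y), length(g$z))
  d2 <- array(Inf, shape)
  P <- expand.grid(x = g$x, y = g$y, z = g$z)
  pm <- as.matrix(P)
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(pm)) else
      pmin(1, pmax(0, ((pm[, 1] - a[1]) * ab[1] + (pm[, 2] - a[2]) * ab[2] +
                         (pm[, 3] - a[3]) * ab[3]) / len2))
    dd <- (pm[, 1] - (a[1] + t * ab[1]))^2 +
      (pm[, 2] - (a[2] + t * ab[2]))^2 +
      (pm[, 3] - (a[3] + t * ab[3]))^2
    d2 <- pmin(d2, array(dd, shape))
  }
  sqrt(d2)
}

#' Generate one synthetic subject from a phantom spec
#'
#' Builds a piecewise-smooth brain-like magnitude volume (a head ellipsoid
#' plus random interior tissue ellipsoids), T1-/T2-weighted analogues, and a
#' slowly varying background phase. Microbleeds and veins are implanted as
#' magnitude drops with locally negative phase offsets (constant within the
#' object) so that negative-phase SWI masking darkens them; lacunar cavities
#' are hypointense on the T1 analogue and hyperintense on the T2 analogue.
#' Additive complex Gaussian noise is applied last.
#'
#' @param spec a \code{\link{phantomSpec}}
#' @param subjectId id string
#' @param group "case" or "control"
#' @return a \linkS4class{SyntheticSubject}
#' @export
makePhantom <- function(spec, subjectId = "S1", group = "case") {
  stopifnot(inherits(spec, "phantomSpec"))
  old <- .Random.seed_exists()
  on.exit(restoreSeedState(old))
  set.seed(spec$seed)
  shape <- spec$grid_shape; sp <- spec$voxel_spacing
  g <- .mmGrids(shape, sp)
  fov <- shape * sp
  ctr <- fov / 2

  # head ellipsoid + random interior tissue ellipsoids
  semi <- fov / 2 * 0.9
  nx <- outer(outer(((g$x - ctr[1]) / semi[1])^2,
                    ((g$y - ctr[2]) / semi[2])^2, `+`),
              ((g$z - ctr[3]) / semi[3])^2, `+`)
  head <- nx <= 1
  mag <- array(0.05, shape)
  mag[head] <- 0.8
  t1 <- array(0.05, shape); t1[head] <- 0.7
  t2 <- array(0.05, shape); t2[head] <- 0.4
  for (e in seq_len(spec$n_background_ellipsoids)) {
    c0 <- ctr + (stats::runif(3) - 0.5) * fov * 0.4
    ax <- fov * stats::runif(3, 0.05, 0.2)
    q <- outer(outer(((g$x - c0[1]) / ax[1])^2,
                     ((g$y - c0[2]) / ax[2])^2, `+`),
               ((g$z - c0[3]) / ax[3])^2, `+`) <= 1
    q <- q & head
    dv <- stats::runif(1, -0.25, 0.25)
    mag[q] <- mag[q] + dv
    t1[q] <- t1[q] + dv * 0.8
    t2[q] <- t2[q] - dv * 0.6
  }
  mag <- pmin(pmax(mag, 0.02), 1.2)
  t1 <- pmin(pmax(t1, 0.02), 1.2)
  t2 <- pmin(pmax(t2, 0.02), 1.2)

  # slowly varying background phase: low-order separable polynomial field
  cx <- stats::runif(3, -0.15, 0.15)
  u <- (g$x - ctr[1]) / fov[1]; v <- (g$y - ctr[2]) / fov[2]
  w <- (g$z - ctr[3]) / fov[3]
  phase <- outer(outer(cx[1] * u + 0.1 * u^2, cx[2] * v, `+`), cx[3] * w, `+`)

  truth <- data.frame(class = character(), x_mm = numeric(), y_mm = numeric(),
                      z_mm = numeric(), diameter_mm = numeric(),
                      stringsAsFactors = FALSE)
  for (s in spec$cmb_specs) {
    m <- .sphereMask(g, s$center, s$diameter / 2)
    k <- s$contrast
    mag[m] <- mag[m] * (1 - 0.55 * k)
    t2[m] <- t2[m] * (1 - 0.4 * k)
    phase[m] <- phase[m] - 1.2 * k
    truth <- rbind(truth, data.frame(class = "cmb", x_mm = s$center[1],
                                     y_mm = s$center[2], z_mm = s$center[3],
                                     diameter_mm = s$diameter))
  }
  for (s in spec$vein_specs) {
    d <- .polylineDist(g, s$polyline)
    m <- d <= s$radius
    k <- s$contrast
    mag[m] <- mag[m] * (1 - 0.35 * k)
    phase[m] <- phase[m] - 0.8 * k
    mid <- s$polyline[ceiling(nrow(s$polyline) / 2), ]
    truth <- rbind(truth, data.frame(class = "vein", x_mm = mid[1],
                                     y_mm = mid[2], z_mm = mid[3],
                                     diameter_mm = 2 * s$radius))
  }
  for (s in spec$lacune_specs) {
    m <- .sphereMask(g, s$center, s$diameter / 2)
    t1[m] <- t1[m] * 0.35          # long T1: hypointense on T1W analogue
    t2[m] <- pmin(t2[m] + 0.6, 1.4) # long T2: hyperintense on T2W analogue
    mag[m] <- mag[m] * 0.9
    truth <- rbind(truth, data.frame(class = "lacune", x_mm = s$center[1],
                                     y_mm = s$center[2], z_mm = s$center[3],
                                     diameter_mm = s$diameter))
  }

  noise <- complex(real = stats::rnorm(length(mag), 0, spec$noise_sd),
                   imaginary = stats::rnorm(length(mag), 0, spec$noise_sd))
  cvol <- array(complex(modulus = mag, argument = phase) + noise, shape)
  t1 <- t1 + array(stats::rnorm(length(t1), 0, spec$noise_sd), shape)
  t2 <- t2 + array(stats::rnorm(length(t2), 0, spec$noise_sd), shape)
  ci <- new("ComplexImage", values = cvol, spacing = sp)
  new("SyntheticSubject", subjectId = subjectId, group = group,
      t1Like = t1, t2Like = t2, complexImage = ci, truthLesions = truth,
      vesselTruth = list(), spacing = sp)
}

#' Random non-overlapping phantom spec
#'
#' Places the requested numbers of microbleeds, veins and lacunes at random
#' non-overlapping positions inside the head and returns the corresponding
#' \code{\link{phantomSpec}}.
#'
#' @param n_cmb,n_vein,n_lacune lesion counts
#' @param cmb_diameters mm range to draw microbleed diameters from
#'   (within the 1.5-6.5 mm band)
#' @param lacune_diameters mm range for lacune diameters (< 15)
#' @param grid_shape,voxel_spacing,noise_sd,seed as in
#'   \code{\link{phantomSpec}}
#' @return a \code{\link{phantomSpec}}
#' @export
randomPhantomSpec <- function(n_cmb = 3L, n_vein = 1L, n_lacune = 1L,
                              cmb_diameters = c(3, 6),
                              lacune_diameters = c(5, 12),
                              grid_shape = c(64L, 64L, 32L),
                              voxel_spacing = c(1, 1, 1),
                              noise_sd = 0.02, seed = 1L) {
  old <- .Random.seed_exists()
  on.exit(restoreSeedState(old))
  set.seed(deriveSeed(seed, 3L))
  fov <- grid_shape * voxel_spacing
  ctr <- fov / 2
  # veins first, so focal lesions can keep clear of their course
  veins <- lapply(seq_len(n_vein), function(i) {
    x0 <- ctr[1] + stats::runif(1, -0.25, 0.25) * fov[1]
    y0 <- ctr[2] + stats::runif(1, -0.25, 0.25) * fov[2]
    zz <- seq(0.15 * fov[3], 0.85 * fov[3], length.out = 12)
    poly <- cbind(x0 + 2 * sin(zz / fov[3] * 2 * pi),
                  y0 + 2 * cos(zz / fov[3] * 2 * pi), zz)
    list(polyline = poly, radius = stats::runif(1, 0.8, 1.2),
         contrast = stats::runif(1, 0.8, 1))
  })
  segDist <- function(p, poly) {
    dmin <- Inf
    for (i in seq_len(nrow(poly) - 1)) {
      a <- poly[i, ]; b <- poly[i + 1, ]
      ab <- b - a
      t <- min(1, max(0, sum((p - a) * ab) / sum(ab^2)))
      dmin <- min(dmin, sqrt(sum((p - a - t * ab)^2)))
    }
    dmin
  }
  placed <- list()   # (center, diameter) pairs already taken
  draw <- function(diam) {
    for (try in 1:200) {
      c0 <- ctr + (stats::runif(3) - 0.5) * fov * c(0.5, 0.5, 0.45)
      ok <- TRUE
      for (p in placed) {
        if (sqrt(sum((c0 - p$center)^2)) <
            0.5 * (diam + p$diameter) + 2) { ok <- FALSE; break }
      }
      if (ok) for (vn in veins) {
        if (segDist(c0, vn$polyline) < diam / 2 + vn$radius + 2) {
          ok <- FALSE; break
        }
      }
      if (ok) return(c0)
    }
    stop("could not place lesion without overlap")
  }
  cmbs <- lapply(seq_len(n_cmb), function(i) {
    d <- stats::runif(1, cmb_diameters[1], cmb_diameters[2])
    c0 <- draw(d)
    placed[[length(placed) + 1]] <<- list(center = c0, diameter = d)
    list(center = c0, diameter = d, contrast = stats::runif(1, 0.8, 1))
  })
  lacs <- lapply(seq_len(n_lacune), function(i) {
    d <- stats::runif(1, lacune_diameters[1], lacune_diameters[2])
    c0 <- draw(d)
    placed[[length(placed) + 1]] <<- list(center = c0, diameter = d)
    list(center = c0, diameter = d)
  })
  phantomSpec(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
              cmb_specs = cmbs, vein_specs = veins, lacune_specs = lacs,
              noise_sd = noise_sd, seed = deriveSeed(seed, 11L))
}

#' Magnitude/phase pair of a subject's complex acquisition
#' @param subject a \linkS4class{SyntheticSubject}
#' @return a \linkS4class{MagnitudePhasePair}
#' @export
magnitudePhase <- function(subject) {
  v <- subject@complexImage@values
  new("MagnitudePhasePair", magnitude = array(Mod(v), dim(v)),
      phase = array(wrapPhase(Arg(v)), dim(v)), spacing = subject@spacing)
}

#' Write a subject's volumes and truth table to disk
#'
#' T1/T2 analogues and magnitude/phase as NIfTI, truth lesions as CSV.
#'
#' @param subject a \linkS4class{SyntheticSubject}
#' @param dir output directory (created if missing)
#' @return invisibly, the written file paths
#' @export
writeSubject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- subject@subjectId
  p <- function(suffix) file.path(dir, paste0(id, "_", suffix))
  mp <- magnitudePhase(subject)
  RNifti::writeNifti(subject@t1Like, p("t1.nii.gz"))
  RNifti::writeNifti(subject@t2Like, p("t2.nii.gz"))
  RNifti::writeNifti(mp@magnitude, p("mag.nii.gz"))
  RNifti::writeNifti(mp@phase, p("pha.nii.gz"))
  utils::write.csv(subject@truthLesions, p("truth.csv"), row.names = FALSE)
  invisible(c(p("t1.nii.gz"), p("t2.nii.gz"), p("mag.nii.gz"),
              p("pha.nii.gz"), p("truth.csv")))
}
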
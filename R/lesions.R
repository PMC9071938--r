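#' Detection parameters
#'
#' Size, signal and shape criteria for microbleed and lacune detection.
#' Microbleeds are compact hypointense foci with equivalent diameter in the
#' 1.5-6.5 mm band; lacunar cavities must be smaller than 15 mm; elongated
#' components (vessels traced across many contiguous slices) are excluded.
#'
#' @param cmb_diameter_band mm band for reported microbleeds
#' @param lacune_max_diameter mm upper bound (exclusive) for lacunes
#' @param hypointensity_z z-score threshold vs local background (negative)
#' @param cmb_rel_drop maximum fraction of the local background a
#'   microbleed voxel may retain (signal must drop below this fraction)
#' @param elongation_max maximum elongation (max in-plane/through-plane
#'   extent over equivalent diameter) before a component is labelled
#'   vessel_excluded
#' @param background_kernel_mm median-filter kernel for the local
#'   background estimate
#' @param lacune_t1_frac lacune voxels must fall below this fraction of
#'   the median tissue T1 signal (CSF-like long-T1 cavity)
#' @param lacune_t2_gain lacune voxels must exceed the median tissue T2
#'   signal by at least this amount (long-T2)
#' @param cmb_phase_max maximum corrected phase (radians) a microbleed
#'   voxel may carry when the corrected phase is available; paramagnetic
#'   foci have negative phase, dark tissue boundaries do not
#' @return validated list of class "detectionParams"
#' @export
detectionParams <- function(cmb_diameter_band = c(1.5, 6.5),
                            lacune_max_diameter = 15,
                            hypointensity_z = -3,
                            cmb_rel_drop = 0.65,
                            elongation_max = 3,
                            background_kernel_mm = 10,
                            lacune_t1_frac = 0.55,
                            lacune_t2_gain = 0.25,
                            cmb_phase_max = -0.2) {
  if (cmb_diameter_band[1] >= cmb_diameter_band[2])
    stop("diameter band lower bound must be below the upper bound")
  stopifnot(is.finite(hypointensity_z), is.finite(elongation_max))
  structure(list(cmb_diameter_band = cmb_diameter_band,
                 lacune_max_diameter = lacune_max_diameter,
                 hypointensity_z = hypointensity_z,
                 cmb_rel_drop = cmb_rel_drop,
                 elongation_max = elongation_max,
                 background_kernel_mm = background_kernel_mm,
                 lacune_t1_frac = lacune_t1_frac,
                 lacune_t2_gain = lacune_t2_gain,
                 cmb_phase_max = cmb_phase_max),
            class = "detectionParams")
}

# one-voxel 6-neighbourhood dilation (bridges single-voxel gaps so the
# hypointense core and its through-plane caps label as one object);
# erosion is its dual, used to keep detection clear of the brain edge
.dilate1 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}
.erode <- function(m, iter = 2L) {
  for (i in seq_len(iter)) m <- !.dilate1(!m)
  m
}

# summarise a labelled component set into a candidate table
.componentTable <- function(lab, contrastZ, spacing) {
  n <- max(lab)
  if (n == 0)
    return(data.frame(label = integer(), x_mm = numeric(), y_mm = numeric(),
                      z_mm = numeric(), diameter_mm = numeric(),
                      contrast = numeric(), elongation = numeric(),
                      n_slices_spanned = integer(),
                      stringsAsFactors = FALSE))
  d <- dim(lab)
  idx <- which(lab > 0)
  comp <- lab[idx]
  ai <- arrayInd(idx, d)
  vvol <- prod(spacing)
  out <- lapply(seq_len(n), function(ci) {
    sel <- comp == ci
    co <- ai[sel, , drop = FALSE]
    nv <- nrow(co)
    eqd <- 2 * (3 * nv * vvol / (4 * pi))^(1 / 3)
    cen <- (colMeans(co) - 0.5) * spacing
    # extent along each axis in mm (bounding box)
    ext <- (apply(co, 2, max) - apply(co, 2, min) + 1) * spacing
    data.frame(label = ci, x_mm = cen[1], y_mm = cen[2], z_mm = cen[3],
               diameter_mm = eqd,
               contrast = mean(contrastZ[idx[sel]]),
               elongation = max(ext) / eqd,
               n_slices_spanned = length(unique(co[, 3])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# local background (median filter) and z-score map inside the brain mask
.localBackground <- function(vol, spacing, kernel_mm) {
  r <- pmax(1L, as.integer(round(kernel_mm / 2 / spacing)))
  median_filter_3d(vol, as.integer(dim(vol)), r[1], r[2], r[3])
}
.zMap <- function(vol, bg, brainMask) {
  resid <- vol - bg
  sigma <- stats::mad(resid[brainMask])
  if (sigma < 1e-9) sigma <- stats::sd(resid[brainMask])
  if (!is.finite(sigma) || sigma < 1e-12) sigma <- 1e-12
  z <- resid / sigma
  z[!brainMask] <- 0
  array(z, dim(vol))
}

#' Detect cerebral microbleeds on an SWI volume
#'
#' Voxels below the hypointensity threshold relative to a median-filtered
#' local background are grouped by 26-connectivity 3D components (a
#' one-voxel dilation joins through-plane caps to their core before
#' labelling). Each component's equivalent diameter (sphere of equal voxel
#' volume) must fall in the microbleed band; elongated components (vessels
#' traced through contiguous slices) are labelled \code{vessel_excluded}
#' and not counted. When the magnitude image is supplied, lesion size is
#' re-measured on it: susceptibility blooming widens the dark halo on the
#' weighted image, while the magnitude drop stays confined to the lesion.
#'
#' @param swi a \linkS4class{SWIVolume}
#' @param params a \code{\link{detectionParams}}
#' @param magnitude optional unweighted magnitude volume for blooming-free
#'   size measurement
#' @param correctedPhase optional corrected phase volume; when supplied,
#'   candidate voxels must also carry negative phase (below
#'   \code{cmb_phase_max}), separating paramagnetic foci from dark
#'   tissue-intensity structure
#' @return data.frame of candidates: class, x_mm, y_mm, z_mm, diameter_mm,
#'   contrast, elongation, n_slices_spanned
#' @export
detectCMB <- function(swi, params = detectionParams(), magnitude = NULL,
                      correctedPhase = NULL) {
  v <- imgValues(swi)
  spacing <- voxelSpacing(swi)
  if (length(spacing) != 3) stop("voxel spacing must be known for 3 axes")
  bg <- .localBackground(v, spacing, params$background_kernel_mm)
  brain <- bg > 0.1 * max(bg)    # lesion-robust mask from the background
  z <- .zMap(v, bg, brain)
  brain <- .erode(brain)         # keep clear of edge ringing
  hypo <- (z < params$hypointensity_z) & (v < params$cmb_rel_drop * bg) &
    brain
  if (!is.null(correctedPhase))
    hypo <- hypo & (correctedPhase < params$cmb_phase_max)
  # label on the one-voxel dilation so through-plane caps join their core,
  # but measure only core voxels
  lab <- label_components_3d(.dilate1(hypo), as.integer(dim(v)))
  lab[!hypo] <- 0L
  tab <- .componentTable(lab, z, spacing)
  if (!nrow(tab)) return(cbind(class = character(0), tab))
  if (!is.null(magnitude)) {
    bgm <- .localBackground(magnitude, spacing, params$background_kernel_mm)
    magCore <- (magnitude < params$cmb_rel_drop * bgm) & brain
    if (!is.null(correctedPhase))
      magCore <- magCore & (correctedPhase < params$cmb_phase_max)
    labM <- label_components_3d(.dilate1(magCore), as.integer(dim(v)))
    labM[!magCore] <- 0L
    nM <- tabulate(labM[labM > 0])
    vvol <- prod(spacing)
    for (i in seq_len(nrow(tab))) {
      over <- labM[lab == tab$label[i]]
      over <- over[over > 0]
      if (length(over)) {
        mlab <- as.integer(names(which.max(table(over))))
        tab$diameter_mm[i] <- 2 * (3 * nM[mlab] * vvol / (4 * pi))^(1 / 3)
      }
    }
  }
  lo <- params$cmb_diameter_band[1]; hi <- params$cmb_diameter_band[2]
  cls <- ifelse(tab$elongation > params$elongation_max, "vessel_excluded",
                ifelse(tab$diameter_mm >= lo & tab$diameter_mm <= hi,
                       "cmb", "size_excluded"))
  out <- cbind(class = cls, tab)
  out[out$class != "size_excluded", , drop = FALSE]
}

#' Detect lacunar infarcts on co-registered T1/T2 analogues
#'
#' Lacunar cavities carry CSF-like long-T1 / long-T2 signal: components
#' must fall below \code{lacune_t1_frac} of the median tissue signal on the
#' T1-weighted analogue and exceed the median by \code{lacune_t2_gain} on
#' the T2-weighted analogue (a conjunction; hyperintensity on both volumes
#' is not a lacune). Components with equivalent diameter below 15 mm are
#' kept; larger cavities are excluded.
#'
#' @param t1Like,t2Like co-registered real volumes on a shared grid
#' @param spacing mm per axis
#' @param params a \code{\link{detectionParams}}
#' @return data.frame of lacune candidates (same columns as
#'   \code{\link{detectCMB}})
#' @export
detectLacune <- function(t1Like, t2Like, spacing = c(1, 1, 1),
                         params = detectionParams()) {
  if (!identical(dim(t1Like), dim(t2Like)))
    stop("t1 and t2 volumes must share a grid")
  bg1 <- .localBackground(t1Like, spacing, params$background_kernel_mm)
  brain <- bg1 > 0.1 * max(bg1)
  m1 <- stats::median(t1Like[brain])
  m2 <- stats::median(t2Like[brain])
  s1 <- max(stats::mad(t1Like[brain]), 0.05 * m1)
  brain <- .erode(brain)
  joint <- brain & (t1Like < params$lacune_t1_frac * m1) &
    (t2Like > m2 + params$lacune_t2_gain) &
    ((t1Like - m1) / s1 < params$hypointensity_z)
  lab <- label_components_3d(.dilate1(joint), as.integer(dim(t1Like)))
  lab[!joint] <- 0L
  tab <- .componentTable(lab, (t1Like - m1) / s1, spacing)
  if (!nrow(tab)) return(cbind(class = character(0), tab))
  cls <- ifelse(tab$diameter_mm < params$lacune_max_diameter, "lacune",
                "size_excluded")
  out <- cbind(class = cls, tab)
  out[out$class == "lacune", , drop = FALSE]
}

#' Count candidates of one class
#'
#' @param candidates candidate data.frame from a detector
#' @param class class to count ("cmb", "lacune", ...)
#' @return integer count
#' @export
countLesions <- function(candidates, class = "cmb") {
  if (is.null(candidates) || !nrow(candidates)) return(0L)
  sum(candidates$class == class)
}

#' Microbleed positivity of a subject
#' @param candidates candidate table
#' @return TRUE when at least one microbleed was detected
#' @export
cmbPositive <- function(candidates) countLesions(candidates, "cmb") >= 1L

#' Seeded microbleed-detection benchmark on random phantoms
#'
#' Generates phantoms with known truth, runs the SWI chain and the
#' microbleed detector, and matches candidates to truth (a candidate
#' matches when its centroid lies within the true radius + 2 mm). Reports
#' recall restricted to lesions at or above \code{min_diameter} and the
#' mean false-positive count per subject.
#'
#' @param n_phantoms phantoms to simulate
#' @param seed benchmark seed
#' @param params a \code{\link{detectionParams}}
#' @param min_diameter mm; recall is computed over truth lesions >= this
#' @param n_cmb,n_vein microbleeds and veins per phantom
#' @return list: recall, fp_per_subject, n_truth, n_matched, candidates
#'   (all reported microbleeds with match flags)
#' @export
cmbDetectionBenchmark <- function(n_phantoms = 20L, seed = 1L,
                                  params = detectionParams(),
                                  min_diameter = 3, n_cmb = 3L,
                                  n_vein = 1L) {
  nMatched <- 0L; nTruth <- 0L; nFP <- 0L
  allCands <- list()
  for (i in seq_len(n_phantoms)) {
    spec <- randomPhantomSpec(n_cmb = n_cmb, n_vein = n_vein, n_lacune = 1L,
                              seed = deriveSeed(seed, 400 + i))
    s <- makePhantom(spec, subjectId = sprintf("B%02d", i))
    mp <- magnitudePhase(s)
    sw <- swiPipeline(mp, mip_slab = NULL)
    cand <- detectCMB(sw$swi, params, magnitude = mp@magnitude,
                      correctedPhase = sw$correctedPhase)
    cand <- cand[cand$class == "cmb", , drop = FALSE]
    truth <- truthLesions(s)
    truth <- truth[truth$class == "cmb" & truth$diameter_mm >= min_diameter, ,
                   drop = FALSE]
    matched <- rep(FALSE, nrow(cand))
    for (j in seq_len(nrow(truth))) {
      d <- sqrt((cand$x_mm - truth$x_mm[j])^2 +
                  (cand$y_mm - truth$y_mm[j])^2 +
                  (cand$z_mm - truth$z_mm[j])^2)
      hit <- which(d < truth$diameter_mm[j] / 2 + 2 & !matched)
      if (length(hit)) {
        nMatched <- nMatched + 1L
        matched[hit[1]] <- TRUE
      }
    }
    nTruth <- nTruth + nrow(truth)
    nFP <- nFP + sum(!matched)
    if (nrow(cand))
      allCands[[i]] <- cbind(subject = sprintf("B%02d", i), cand,
                             matched = matched)
  }
  list(recall = if (nTruth) nMatched / nTruth else NA_real_,
       fp_per_subject = nFP / n_phantoms, n_truth = nTruth,
       n_matched = nMatched,
       candidates = do.call(rbind, allCands))
}

#' Write a candidate table as CSV
#' @param candidates candidate table
#' @param subject subject id to prepend
#' @param path CSV path
#' @export
writeCandidates <- function(candidates, subject, path) {
  utils::write.csv(cbind(subject = subject, candidates), path,
                   row.names = FALSE)
  invisible(path)
}
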
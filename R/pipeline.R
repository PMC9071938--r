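#' Pipeline run configuration
#'
#' One JSON-serializable object holding every stage's parameters and the
#' global seed. The global seed fans out to per-stage seeds through a
#' fixed splitting rule (documented in \code{\link{deriveStageSeed}}), so
#' each stage is independently reproducible. Unknown keys are rejected.
#'
#' Scan-parameter defaults documented for the emulated acquisition:
#' TR 17.0 ms, TE 25.0 ms, flip angle 15 degrees, 2 mm slices (these are
#' documentation only; the phantom is resolution-parameterised directly).
#'
#' @param out_dir output directory (required)
#' @param seed global integer seed
#' @param n_train,n_test training/held-out phantom subjects
#' @param grid_shape phantom grid
#' @param acceleration,center_fraction undersampling parameters
#' @param train training block: NULL to skip training and use the
#'   zero-filled reconstruction, else a list with epochs, learning_rate,
#'   batch_size
#' @param swi_window,swi_m,mip_slab SWI parameters
#' @param detection a \code{\link{detectionParams}}
#' @param curvature_threshold_mm morphometry threshold
#' @param cohort a \code{\link{cohortSpec}} (NULL: defaults with the global
#'   seed)
#' @param alpha significance level for the statistics block
#' @return validated list of class "runConfig"
#' @export
runConfig <- function(out_dir, seed = 1L, n_train = 4L, n_test = 2L,
                      grid_shape = c(64L, 64L, 32L), acceleration = 4,
                      center_fraction = 0.08,
                      train = list(epochs = 6L, learning_rate = 1e-3,
                                   batch_size = 4L),
                      swi_window = 64, swi_m = 4L, mip_slab = 8L,
                      detection = detectionParams(),
                      curvature_threshold_mm = 2,
                      cohort = NULL, alpha = 0.05) {
  if (missing(out_dir) || is.null(out_dir) || !nzchar(out_dir))
    stop("config requires an output directory")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 grid_shape = as.integer(grid_shape),
                 acceleration = acceleration,
                 center_fraction = center_fraction, train = train,
                 swi_window = swi_window, swi_m = swi_m, mip_slab = mip_slab,
                 detection = detection,
                 curvature_threshold_mm = curvature_threshold_mm,
                 cohort = if (is.null(cohort)) cohortSpec(seed = seed)
                   else cohort,
                 alpha = alpha),
            class = "runConfig")
}

#' Per-stage seed derivation
#'
#' Stage k of a run with global seed s uses
#' \code{(97 s + 1009 k) mod (2^31 - 1)}; stages are numbered simulate = 1,
#' mask = 2, train = 3, swi = 4, detect = 5, morph = 6, stats = 7.
#'
#' @param seed global seed
#' @param stage stage number
#' @return derived integer seed
#' @export
deriveStageSeed <- function(seed, stage) deriveSeed(seed, stage)

#' Read/write a run configuration as JSON
#' @param config a \code{\link{runConfig}}
#' @param path JSON path
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(runConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  raw$detection <- if (is.null(raw$detection)) detectionParams()
    else do.call(detectionParams, raw$detection[names(raw$detection) %in%
                                  names(formals(detectionParams))])
  if (!is.null(raw$cohort))
    raw$cohort <- do.call(cohortSpec, raw$cohort[names(raw$cohort) %in%
                                  names(formals(cohortSpec))])
  do.call(runConfig, raw)
}

#' Run the end-to-end pipeline
#'
#' phantom simulation -> undersampling -> reconstruction (trained cascade
#' or zero-filled) -> SWI -> lesion detection -> vessel morphometry ->
#' cohort statistics. Every stage logs its timing; artifacts are written
#' under the configured output directory and checksummed into the run
#' manifest. A stage failure aborts with the failing stage named; earlier
#' artifacts are preserved.
#'
#' @param config a \code{\link{runConfig}}
#' @param verbose print per-stage progress?
#' @return the run manifest (list): config hash, per-file md5 checksums,
#'   package version, timings
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- list()
  artifacts <- character(0)
  runStage <- function(name, f) {
    t0 <- Sys.time()
    out <- tryCatch(f(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    say("stage %-8s done in %.1fs", name, timings[[name]])
    out
  }

  # 1. simulate phantoms
  subjects <- runStage("simulate", function() {
    lapply(seq_len(config$n_train + config$n_test), function(i) {
      ps <- randomPhantomSpec(grid_shape = config$grid_shape,
                              seed = deriveStageSeed(config$seed, 1) + i)
      makePhantom(ps, subjectId = sprintf("S%02d", i),
                  group = if (i <= config$n_train) "case" else "control")
    })
  })
  for (s in subjects) artifacts <- c(artifacts, writeSubject(
    s, file.path(config$out_dir, "phantoms")))

  # 2. undersample central slices of each subject into 2D samples
  sliceData <- runStage("mask", function() {
    lapply(seq_along(subjects), function(i) {
      v <- subjects[[i]]@complexImage@values
      zmid <- dim(v)[3] %/% 2
      lapply((zmid - 1):(zmid + 2), function(z) {
        sl <- v[, , z]
        mask <- makeSamplingMask(dim(sl), config$acceleration,
                                 config$center_fraction,
                                 seed = deriveStageSeed(config$seed, 2) +
                                   i * 100 + z)
        kf <- .fwd(sl)
        km <- kf
        km[!maskKeep(mask)] <- 0 + 0i
        list(kMeas = km, mask = mask, target = sl, subject = i)
      })
    })
  })
  flat <- unlist(sliceData, recursive = FALSE)
  trainSet <- flat[vapply(flat, function(s) s$subject <= config$n_train,
                          logical(1))]
  testSet <- flat[vapply(flat, function(s) s$subject > config$n_train,
                         logical(1))]

  # 3. reconstruction
  evalTab <- runStage("recon", function() {
    model <- buildCascadeModel(seed = deriveStageSeed(config$seed, 3))
    if (!is.null(config$train)) {
      tc <- trainConfig(epochs = config$train$epochs,
                        learning_rate = config$train$learning_rate,
                        batch_size = config$train$batch_size,
                        seed = deriveStageSeed(config$seed, 3))
      model <- trainCascade(model, trainSet, tc)$model
    }
    evaluateRecon(model, testSet)
  })
  reconPath <- file.path(config$out_dir, "recon_eval.csv")
  utils::write.csv(evalTab, reconPath, row.names = FALSE)
  artifacts <- c(artifacts, reconPath)

  # 4-5. SWI + detection per subject
  detTab <- runStage("detect", function() {
    do.call(rbind, lapply(subjects, function(s) {
      sw <- swiPipeline(magnitudePhase(s), config$swi_window, config$swi_m,
                        config$mip_slab)
      cands <- detectCMB(sw$swi, config$detection)
      lacs <- detectLacune(s@t1Like, s@t2Like, s@spacing, config$detection)
      both <- rbind(cands, lacs)
      if (nrow(both)) cbind(subject = s@subjectId, both)
      else NULL
    }))
  })
  detPath <- file.path(config$out_dir, "lesions.csv")
  utils::write.csv(detTab, detPath, row.names = FALSE)
  artifacts <- c(artifacts, detPath)

  # 6. morphometry on cohort vessel geometry + 7. statistics
  coh <- runStage("morph", function() {
    cohRes <- makeCohort(config$cohort)
    morph <- do.call(rbind, lapply(cohRes$subjects, function(s) {
      tree <- makeVesselTree(do.call(vesselGeometrySpec, s@vesselTruth))
      cbind(subject = s@subjectId, vesselMorphometry(
        tree, config$curvature_threshold_mm))
    }))
    list(table = cohRes$table, morph = morph)
  })
  cohPath <- file.path(config$out_dir, "cohort.csv")
  morphPath <- file.path(config$out_dir, "morphometry.csv")
  utils::write.csv(coh$table, cohPath, row.names = FALSE)
  utils::write.csv(coh$morph, morphPath, row.names = FALSE)
  artifacts <- c(artifacts, cohPath, morphPath)

  report <- runStage("stats", function() cohortReport(coh$table,
                                                      config$alpha))
  artifacts <- c(artifacts, writeCohortReport(
    report, file.path(config$out_dir, "stats")))

  # manifest
  cfgPath <- file.path(config$out_dir, "config.json")
  writeRunConfig(config, cfgPath)
  # hash the config without its output location, so identical runs in
  # different directories share a hash
  norm <- unclass(config)
  norm$out_dir <- NULL
  normPath <- tempfile(fileext = ".json")
  jsonlite::write_json(norm, normPath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(
    config_hash = unname(tools::md5sum(normPath)),
    version = as.character(utils::packageVersion("SWIcascade")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    timings = timings,
    checksums = as.list(tools::md5sum(artifacts)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
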
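#' Cohort specification
#'
#' Two-group (case/control) cohort design: per-group lacunar-infarct count
#' distributions, microbleed positivity and count-given-positive
#' distributions, vertebral dominance and abnormal-curvature probabilities.
#' Lacune counts are Poisson when the supplied SD matches equidispersion
#' and negative binomial when sd^2 > mean (the SD is exposed as a free
#' parameter); microbleed counts given positivity are zero-truncated
#' Poisson.
#'
#' @param n_per_group subjects per group (>= 2)
#' @param lacune_count_means (case, control) mean lacune counts
#' @param lacune_count_sds (case, control) lacune-count SDs; NULL for
#'   Poisson
#' @param cmb_positive_prob (case, control) probability of being
#'   microbleed-positive
#' @param cmb_count_lambda (case, control) zero-truncated-Poisson rate of
#'   microbleed counts among positives
#' @param dominance_prob (case, control) probability of vertebral dominance
#' @param abnormal_curvature_prob (case, control) probability of an
#'   abnormal (C / reverse-C / S) basilar curvature
#' @param seed integer seed
#' @return validated list of class "cohortSpec"
#' @export
cohortSpec <- function(n_per_group = 30L,
                       lacune_count_means = c(2.400, 0.672),
                       lacune_count_sds = c(3.358, 1.252),
                       cmb_positive_prob = c(14 / 30, 4 / 30),
                       cmb_count_lambda = c(3.3, 2.7),
                       dominance_prob = c(19 / 30, 8 / 30),
                       abnormal_curvature_prob = c(10 / 30, 4 / 30),
                       seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  probs <- c(cmb_positive_prob, dominance_prob, abnormal_curvature_prob)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must be in [0,1]")
  if (any(lacune_count_means < 0)) stop("count means must be >= 0")
  structure(list(n_per_group = as.integer(n_per_group),
                 lacune_count_means = lacune_count_means,
                 lacune_count_sds = lacune_count_sds,
                 cmb_positive_prob = cmb_positive_prob,
                 cmb_count_lambda = cmb_count_lambda,
                 dominance_prob = dominance_prob,
                 abnormal_curvature_prob = abnormal_curvature_prob,
                 seed = as.integer(seed)),
            class = "cohortSpec")
}

# draw n counts with the given mean/SD: negative binomial when
# overdispersed, Poisson otherwise
.drawCounts <- function(n, mean, sd = NULL) {
  if (mean == 0) return(integer(n))
  if (!is.null(sd) && sd^2 > mean * 1.0001) {
    size <- mean^2 / (sd^2 - mean)
    stats::rnbinom(n, size = size, mu = mean)
  } else {
    stats::rpois(n, mean)
  }
}

# zero-truncated Poisson via the inverse-CDF restricted above 0
.drawZTPois <- function(n, lambda) {
  if (n == 0) return(integer(0))
  u <- stats::runif(n, stats::ppois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Generate a two-group cohort
#'
#' Draws per-subject lesion counts, microbleed positivity, vertebral
#' dominance and basilar curvature from the distributions in the spec and
#' returns the cohort table plus lightweight subject records. With
#' \code{volumes = TRUE} each subject additionally gets phantom volumes
#' with the drawn numbers of lesions implanted (slow; intended for small
#' cohorts).
#'
#' @param spec a \code{\link{cohortSpec}}
#' @param volumes generate phantom volumes per subject?
#' @return list: \code{table} (data.frame with columns subject_id, group,
#'   lacune_count, cmb_count, cmb_positive, dominant_side, diameter_diff_mm,
#'   curvature_type) and \code{subjects} (list of
#'   \linkS4class{SyntheticSubject})
#' @export
makeCohort <- function(spec, volumes = FALSE) {
  stopifnot(inherits(spec, "cohortSpec"))
  old <- .Random.seed_exists()
  on.exit(restoreSeedState(old))
  set.seed(spec$seed)
  n <- spec$n_per_group
  rows <- list(); subjects <- list()
  for (gi in 1:2) {
    group <- c("case", "control")[gi]
    lac <- .drawCounts(n, spec$lacune_count_means[gi],
                       if (is.null(spec$lacune_count_sds)) NULL
                       else spec$lacune_count_sds[gi])
    pos <- stats::runif(n) < spec$cmb_positive_prob[gi]
    cmb <- integer(n)
    cmb[pos] <- .drawZTPois(sum(pos), spec$cmb_count_lambda[gi])
    dom <- stats::runif(n) < spec$dominance_prob[gi]
    diff <- ifelse(dom, stats::runif(n, 0.3, 2.0), stats::runif(n, 0, 0.29))
    side <- ifelse(dom, ifelse(stats::runif(n) < 0.5, "left", "right"),
                   "none")
    abn <- stats::runif(n) < spec$abnormal_curvature_prob[gi]
    ctype <- ifelse(abn, sample(c("C", "reverse_C", "S"), n, replace = TRUE),
                    "normal")
    ids <- sprintf("%s%02d", if (gi == 1) "P" else "C", seq_len(n))
    rows[[gi]] <- data.frame(subject_id = ids, group = group,
                             lacune_count = lac, cmb_count = cmb,
                             cmb_positive = pos, dominant_side = side,
                             diameter_diff_mm = diff, curvature_type = ctype,
                             stringsAsFactors = FALSE)
    for (si in seq_len(n)) {
      base <- 3.2
      ld <- if (side[si] == "left") base + diff[si] else base
      rd <- if (side[si] == "right") base + diff[si] else base
      vspec <- vesselGeometrySpec(
        left_diameter = ld, right_diameter = rd,
        basilar_curvature_type = ctype[si],
        basilar_amplitude = if (ctype[si] == "normal") 0
          else stats::runif(1, 2.5, 4.5),
        seed = deriveSeed(spec$seed, gi * 1000 + si))
      if (volumes) {
        ps <- randomPhantomSpec(n_cmb = cmb[si], n_vein = 1L,
                                n_lacune = min(lac[si], 4L),
                                seed = deriveSeed(spec$seed, gi * 5000 + si))
        subj <- makePhantom(ps, subjectId = ids[si], group = group)
        subj@vesselTruth <- unclass(vspec)
      } else {
        subj <- new("SyntheticSubject", subjectId = ids[si], group = group,
                    t1Like = array(numeric(0)), t2Like = array(numeric(0)),
                    complexImage = NULL,
                    truthLesions = data.frame(class = character(),
                                              x_mm = numeric(),
                                              y_mm = numeric(),
                                              z_mm = numeric(),
                                              diameter_mm = numeric()),
                    vesselTruth = unclass(vspec), spacing = c(1, 1, 1))
      }
      subjects[[length(subjects) + 1]] <- subj
    }
  }
  list(table = do.call(rbind, rows), subjects = subjects)
}
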
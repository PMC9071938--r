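#' @useDynLib SWIcascade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' ComplexImage: a complex-valued image grid with physical spacing
#'
#' The spatial-domain operand of the reconstruction pipeline: a 2D slice or
#' 3D volume of complex values (magnitude + phase) together with the voxel
#' spacing in millimetres.
#'
#' @slot values complex array (2D or 3D), all finite
#' @slot spacing numeric vector of mm per axis, one entry per array dimension
#' @export
setClass("ComplexImage",
  representation(values = "ANY", spacing = "numeric"),
  validity = function(object) {
    v <- object@values
    if (!is.array(v) && !is.matrix(v)) return("values must be an array")
    if (!is.complex(v) && !is.numeric(v)) return("values must be complex or numeric")
    if (any(!is.finite(Re(v))) || any(!is.finite(Im(v))))
      return("values must be finite")
    if (length(dim(v)) != length(object@spacing))
      return("spacing length must match array dimensionality")
    if (any(object@spacing <= 0)) return("spacing must be positive")
    TRUE
  })

#' KSpace: the spatial-frequency counterpart of a ComplexImage
#'
#' Complex spectrum on the same grid as its image counterpart. When
#' `centered` is TRUE the DC component sits at the grid centre (the
#' project-wide convention; all transforms here are centred and orthonormal).
#'
#' @slot values complex array, same shape as the image it transforms
#' @slot spacing numeric, mm per axis of the originating image
#' @slot centered logical, DC at grid centre
#' @export
setClass("KSpace",
  representation(values = "ANY", spacing = "numeric", centered = "logical"),
  validity = function(object) {
    v <- object@values
    if (!is.array(v) && !is.matrix(v)) return("values must be an array")
    if (any(!is.finite(Re(v))) || any(!is.finite(Im(v))))
      return("values must be finite")
    if (length(object@centered) != 1) return("centered must be a single flag")
    TRUE
  })

#' SamplingMask: Cartesian undersampling pattern for k-space
#'
#' Boolean keep/discard grid with a fully sampled central band of
#' phase-encode lines and the nominal acceleration factor it realises.
#' Undersampling acts along one phase-encode axis only (columns).
#'
#' @slot keep logical matrix/array of retained k-space locations
#' @slot acceleration nominal undersampling factor (>= 1)
#' @slot centerFraction fraction of fully sampled central lines
#' @export
setClass("SamplingMask",
  representation(keep = "ANY", acceleration = "numeric",
                 centerFraction = "numeric"),
  validity = function(object) {
    if (!is.logical(object@keep)) return("keep must be logical")
    if (object@acceleration < 1) return("acceleration must be >= 1")
    if (object@centerFraction < 0 || object@centerFraction >= 1)
      return("centerFraction must be in [0, 1)")
    TRUE
  })

#' MagnitudePhasePair: the two outputs of a gradient-echo acquisition
#'
#' @slot magnitude non-negative real volume (MI)
#' @slot phase real volume in [-pi, pi) radians (PI)
#' @slot spacing mm per axis
#' @export
setClass("MagnitudePhasePair",
  representation(magnitude = "ANY", phase = "ANY", spacing = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@magnitude), dim(object@phase)))
      return("magnitude and phase must share a grid")
    if (any(object@magnitude < 0)) return("magnitude must be non-negative")
    if (any(object@phase < -pi - 1e-9) || any(object@phase >= pi + 1e-9))
      return("phase must be wrapped to [-pi, pi)")
    TRUE
  })

#' PhaseMask: negative-phase weighting map for SWI
#'
#' Voxelwise weights in [0, 1] derived from the corrected phase: negative
#' phase is mapped linearly to (pi + phi)/pi, non-negative phase to 1, and
#' the map is raised to the m-th power before multiplying the magnitude.
#'
#' @slot weights real volume in [0, 1]
#' @slot m number of mask multiplications applied (integer >= 0)
#' @export
setClass("PhaseMask",
  representation(weights = "ANY", m = "numeric"),
  validity = function(object) {
    w <- object@weights
    if (any(w < -1e-12) || any(w > 1 + 1e-12))
      return("weights must lie in [0, 1]")
    if (object@m < 0 || object@m != round(object@m))
      return("m must be a non-negative integer")
    TRUE
  })

#' SWIVolume: the susceptibility-weighted image
#'
#' Magnitude image multiplied voxelwise by a phase mask; never exceeds the
#' magnitude it was derived from. Provenance records the high-pass filter
#' window and the number of mask multiplications.
#'
#' @slot values non-negative real volume
#' @slot spacing mm per axis
#' @slot filterWindow high-pass filter window size used for the phase
#' @slot m mask multiplications used
#' @export
setClass("SWIVolume",
  representation(values = "ANY", spacing = "numeric",
                 filterWindow = "numeric", m = "numeric"),
  validity = function(object) {
    if (any(object@values < -1e-12)) return("values must be non-negative")
    if (length(dim(object@values)) < 2) return("values must be a volume")
    TRUE
  })

#' SyntheticSubject: one phantom subject
#'
#' Multi-contrast volumes, the complex acquisition, the ground-truth lesion
#' table and the vessel geometry used to generate the subject. Cohort-level
#' generation may leave the volume slots empty (length-0 arrays) when only
#' the tabulated measurements are needed.
#'
#' @slot subjectId character id
#' @slot group "case" or "control"
#' @slot t1Like,t2Like real volumes (T1-/T2-weighted analogues)
#' @slot complexImage the complex acquisition (\linkS4class{ComplexImage}) or NULL
#' @slot truthLesions data.frame: class, x_mm, y_mm, z_mm, diameter_mm
#' @slot vesselTruth list: the vessel geometry spec used
#' @slot spacing mm per axis
#' @export
setClass("SyntheticSubject",
  representation(subjectId = "character", group = "character",
                 t1Like = "ANY", t2Like = "ANY", complexImage = "ANY",
                 truthLesions = "data.frame", vesselTruth = "list",
                 spacing = "numeric"),
  validity = function(object) {
    if (!object@group %in% c("case", "control"))
      return("group must be 'case' or 'control'")
    if (nrow(object@truthLesions) &&
        !all(object@truthLesions$class %in% c("cmb", "lacune", "vein")))
      return("truth lesion classes must be cmb/lacune/vein")
    if (length(object@t1Like) && length(object@t2Like) &&
        !identical(dim(object@t1Like), dim(object@t2Like)))
      return("volumes must share grid_shape")
    TRUE
  })

#' CascadeModel: the five-stage dual-domain reconstruction network
#'
#' Five concatenated stages, each holding independent (unshared) parameters
#' for an image-domain feature extractor, a k-space-domain feature
#' extractor, and the two cross-fusion maps. Stages 1-4 are structurally
#' identical; stage 5 additionally carries the output head producing the
#' final reconstructed image.
#'
#' @slot stages list of 5 per-stage parameter sets
#' @slot config the \code{stageConfig} all stages share structurally
#' @slot fusion "conv" (1x1 fusion convolution) or "identity"
#' @slot dcLambda data-consistency weight; Inf = hard replacement (default)
#' @export
setClass("CascadeModel",
  representation(stages = "list", config = "list", fusion = "character",
                 dcLambda = "numeric"),
  validity = function(object) {
    if (length(object@stages) != 5) return("a cascade has exactly 5 stages")
    if (!object@fusion %in% c("conv", "identity"))
      return("fusion must be 'conv' or 'identity'")
    if (object@dcLambda < 0) return("dcLambda must be non-negative")
    TRUE
  })
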
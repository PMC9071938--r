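#' Extract the value grid of an image-like object
#' @param x a ComplexImage, KSpace, SWIVolume or PhaseMask
#' @return the underlying array
#' @export
setGeneric("imgValues", function(x) standardGeneric("imgValues"))

#' Extract the voxel spacing (mm per axis)
#' @param x an image-like object
#' @return numeric vector of mm per axis
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname imgValues
#' @export
setMethod("imgValues", "ComplexImage", function(x) x@values)
#' @rdname imgValues
#' @export
setMethod("imgValues", "KSpace", function(x) x@values)
#' @rdname imgValues
#' @export
setMethod("imgValues", "SWIVolume", function(x) x@values)
#' @rdname imgValues
#' @export
setMethod("imgValues", "PhaseMask", function(x) x@weights)

#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "ComplexImage", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "KSpace", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "SWIVolume", function(x) x@spacing)
#' @rdname voxelSpacing
#' @export
setMethod("voxelSpacing", "SyntheticSubject", function(x) x@spacing)

#' Logical keep-grid of a sampling mask
#' @param x a SamplingMask
#' @return logical matrix of retained k-space locations
#' @export
setGeneric("maskKeep", function(x) standardGeneric("maskKeep"))
#' @rdname maskKeep
#' @export
setMethod("maskKeep", "SamplingMask", function(x) x@keep)

#' Ground-truth lesion table of a synthetic subject
#' @param x a SyntheticSubject
#' @return data.frame with columns class, x_mm, y_mm, z_mm, diameter_mm
#' @export
setGeneric("truthLesions", function(x) standardGeneric("truthLesions"))
#' @rdname truthLesions
#' @export
setMethod("truthLesions", "SyntheticSubject", function(x) x@truthLesions)

setMethod("show", "ComplexImage", function(object) {
  cat("ComplexImage:", paste(dim(object@values), collapse = " x "),
      "voxels @", paste(signif(object@spacing, 3), collapse = " x "), "mm\n")
})
setMethod("show", "KSpace", function(object) {
  cat("KSpace:", paste(dim(object@values), collapse = " x "),
      if (object@centered) "(centered)\n" else "(uncentered)\n")
})
setMethod("show", "SamplingMask", function(object) {
  cat(sprintf("SamplingMask: %s, nominal %gx, kept fraction %.3f\n",
              paste(dim(object@keep), collapse = " x "),
              object@acceleration, mean(object@keep)))
})
setMethod("show", "SWIVolume", function(object) {
  cat(sprintf("SWIVolume: %s voxels (high-pass window %d, m = %d)\n",
              paste(dim(object@values), collapse = " x "),
              as.integer(object@filterWindow), as.integer(object@m)))
})
setMethod("show", "SyntheticSubject", function(object) {
  cat(sprintf("SyntheticSubject %s [%s]: %d truth lesions\n",
              object@subjectId, object@group, nrow(object@truthLesions)))
})
setMethod("show", "CascadeModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "CascadeModel: 5 stages, %d conv layers x %d channels per domain, %s fusion, %s data consistency\n",
    cfg$n_conv_layers, cfg$n_channels, object@fusion,
    if (is.infinite(object@dcLambda)) "hard" else sprintf("soft (lambda=%g)", object@dcLambda)))
})
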
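#' Accessors for image-grid objects
#'
#' `imageData()` returns the raw 3-D array, `spacing()` the voxel size in
#' mm, `affine()` the 4x4 voxel-to-world transform, `voxelVolume()` the
#' volume of one voxel in mm^3, and `vocabulary()` the class-name-to-id
#' map of a [LabelMap-class].
#'
#' @param x A [Volume-class] or [LabelMap-class].
#' @return See each accessor's description.
#' @name grid-accessors
#' @aliases imageData spacing affine voxelVolume vocabulary modality
#' @examples
#' v <- Volume(array(0, c(4, 4, 4)), spacing = 2)
#' voxelVolume(v)  # 8 mm^3
NULL

#' @rdname grid-accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))
#' @rdname grid-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname grid-accessors
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))
#' @rdname grid-accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname grid-accessors
#' @export
setGeneric("vocabulary", function(x) standardGeneric("vocabulary"))
#' @rdname grid-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

for (cls in c("Volume", "LabelMap")) {
  setMethod("imageData", cls, function(x) x@data)
  setMethod("spacing", cls, function(x) x@spacing)
  setMethod("affine", cls, function(x) x@affine)
  setMethod("voxelVolume", cls, function(x) prod(x@spacing))
  setMethod("dim", cls, function(x) dim(x@data))
}

setMethod("vocabulary", "LabelMap", function(x) x@vocabulary)
setMethod("modality", "Volume", function(x) x@modality)

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume [%s]: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              object@modality, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelMap: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  voc <- object@vocabulary
  cat(sprintf("  %d classes: %s\n", length(voc),
              paste(utils::head(names(voc), 8), collapse = ", ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec: %dx%dx%d @ %.3g mm, tumor %.3g cm^3 ",
                     "(%s), noise %.3g, bias %.3g, seed %d\n"),
              object@gridShape[1], object@gridShape[2], object@gridShape[3],
              object@spacing[1], object@tumorVolume, object@tumorSide,
              object@noiseSD, object@biasAmplitude, object@seed))
})

setMethod("show", "PhantomCase", function(object) {
  cat("PhantomCase (ct, t1, t2fs, truth)\n")
  show(object@spec)
})

setMethod("show", "PreprocessVariant", function(object) {
  cat(sprintf("PreprocessVariant \"%s\" (clip [%g, %g], percentile %g)\n",
              object@name, object@clipLo, object@clipHi,
              object@backgroundPercentile))
})

#' Case accessors for PhantomCase
#'
#' @param x A [PhantomCase-class].
#' @return The requested component.
#' @name phantom-accessors
NULL

#' @rdname phantom-accessors
#' @export
setGeneric("ctVolume", function(x) standardGeneric("ctVolume"))
#' @rdname phantom-accessors
#' @export
setGeneric("t1Volume", function(x) standardGeneric("t1Volume"))
#' @rdname phantom-accessors
#' @export
setGeneric("t2fsVolume", function(x) standardGeneric("t2fsVolume"))
#' @rdname phantom-accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname phantom-accessors
#' @export
setGeneric("phantomSpec", function(x) standardGeneric("phantomSpec"))

setMethod("ctVolume", "PhantomCase", function(x) x@ct)
setMethod("t1Volume", "PhantomCase", function(x) x@t1)
setMethod("t2fsVolume", "PhantomCase", function(x) x@t2fs)
setMethod("truthLabels", "PhantomCase", function(x) x@truth)
setMethod("phantomSpec", "PhantomCase", function(x) x@spec)
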
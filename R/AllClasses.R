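#' @import methods
NULL

#' Volume: a 3-D scalar intensity grid with voxel geometry
#'
#' A `Volume` holds a 3-D array of scalar intensities (arbitrary units;
#' Hounsfield-like for CT volumes) together with its voxel spacing in
#' millimetres, a 4x4 voxel-to-world affine, and a modality tag.
#'
#' @slot data 3-D numeric array of intensities.
#' @slot spacing Numeric vector of length 3: voxel edge lengths in mm.
#' @slot affine 4x4 voxel-to-world transform (0-based voxel indices).
#' @slot modality One of `"CT"`, `"T1w"`, `"T2wfs"`, `"other"`.
#'
#' @seealso [Volume()], [LabelMap-class], [readVolume()]
#' @exportClass Volume
setClass("Volume",
  representation(
    data = "array",
    spacing = "numeric",
    affine = "matrix",
    modality = "character"
  ),
  prototype(
    data = array(0, c(1L, 1L, 1L)),
    spacing = c(1, 1, 1),
    affine = diag(4),
    modality = "other"
  )
)

.validGrid <- function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "'data' must have exactly 3 dimensions")
  if (any(dim(object@data) < 1L))
    msg <- c(msg, "every dimension of 'data' must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive finite values")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "'affine' must be a 4x4 matrix")
  else if (!is.finite(det(object@affine)) || abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "'affine' must be invertible")
  msg
}

setValidity("Volume", function(object) {
  msg <- .validGrid(object)
  if (length(object@modality) != 1L ||
      !object@modality %in% c("CT", "T1w", "T2wfs", "other"))
    msg <- c(msg, "'modality' must be one of CT, T1w, T2wfs, other")
  if (length(msg)) msg else TRUE
})

#' LabelMap: a 3-D integer class-id grid with a vocabulary
#'
#' A `LabelMap` is an integer-valued grid aligned to a [Volume-class],
#' mapping each voxel to a class id. Id 0 is reserved for background and
#' never appears in the vocabulary.
#'
#' @slot data 3-D array of non-negative integer class ids.
#' @slot spacing,affine As for [Volume-class].
#' @slot vocabulary Named integer vector: names are class names, values ids.
#'
#' @seealso [LabelMap()], [vocabulary()]
#' @exportClass LabelMap
setClass("LabelMap",
  representation(
    data = "array",
    spacing = "numeric",
    affine = "matrix",
    vocabulary = "integer"
  ),
  prototype(
    data = array(0L, c(1L, 1L, 1L)),
    spacing = c(1, 1, 1),
    affine = diag(4),
    vocabulary = integer()
  )
)

setValidity("LabelMap", function(object) {
  msg <- .validGrid(object)
  ids <- unique(as.vector(object@data))
  if (any(ids < 0) || any(ids != as.integer(ids)))
    msg <- c(msg, "'data' must contain non-negative integer ids")
  voc <- object@vocabulary
  if (length(voc)) {
    if (is.null(names(voc)) || any(!nzchar(names(voc))))
      msg <- c(msg, "'vocabulary' must be a named integer vector")
    if (anyDuplicated(voc) || anyDuplicated(names(voc)))
      msg <- c(msg, "'vocabulary' ids and names must be unique")
    if (any(voc == 0L))
      msg <- c(msg, "id 0 is reserved for background")
  }
  unknown <- setdiff(ids, c(0L, unname(voc)))
  if (length(unknown))
    msg <- c(msg, sprintf("ids present in data but not in vocabulary: %s",
                          paste(unknown, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Volume
#'
#' @param data 3-D numeric array.
#' @param spacing Voxel spacing in mm (length 3, recycled from length 1).
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing`.
#' @param modality Modality tag (`"CT"`, `"T1w"`, `"T2wfs"`, `"other"`).
#' @return A [Volume-class] object.
#' @examples
#' v <- Volume(array(rnorm(8), c(2, 2, 2)), spacing = 2)
#' spacing(v)
#' @export
Volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                   modality = "other") {
  data <- .as3d(data)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  new("Volume", data = data, spacing = spacing,
      affine = affine, modality = modality)
}

#' Construct a LabelMap
#'
#' @param data 3-D array of non-negative integer ids.
#' @param spacing,affine As in [Volume()].
#' @param vocabulary Named integer vector mapping class names to ids, or a
#'   character vector of class names (assigned ids `1:n`).
#' @return A [LabelMap-class] object.
#' @examples
#' lm <- LabelMap(array(c(0L, 1L), c(2, 1, 1)), vocabulary = c(kidney = 1L))
#' vocabulary(lm)
#' @export
LabelMap <- function(data, spacing = c(1, 1, 1), affine = NULL,
                     vocabulary = integer()) {
  data <- .as3d(data)
  storage.mode(data) <- "integer"
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  if (is.character(vocabulary))
    vocabulary <- stats::setNames(seq_along(vocabulary), vocabulary)
  vocabulary <- stats::setNames(as.integer(vocabulary), names(vocabulary))
  new("LabelMap", data = data, spacing = spacing, affine = affine,
      vocabulary = vocabulary)
}

.as3d <- function(data) {
  if (is.null(dim(data))) dim(data) <- c(length(data), 1L, 1L)
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  data
}

#' PhantomSpec: parameters of one synthetic abdominal subject
#'
#' Describes a single phantom case: grid geometry, lesion size and side,
#' noise and bias-field levels, and the random seed. Defaults give a
#' 96^3 grid at 2 mm isotropic spacing (a scaled-down abdomen of
#' 192 mm extent) with a 29 cm^3 renal lesion.
#'
#' @slot gridShape Integer vector of length 3 (voxels per axis).
#' @slot spacing Numeric length 3, voxel size in mm before resampling.
#' @slot tumorVolume Lesion volume in cm^3.
#' @slot tumorSide `"left"` or `"right"`.
#' @slot noiseSD Additive Gaussian noise standard deviation, intensity units.
#' @slot biasAmplitude Relative amplitude of the smooth multiplicative
#'   bias field, in `[0, 1)`.
#' @slot seed Integer seed; the same spec always generates bit-identical
#'   output.
#'
#' @seealso [PhantomSpec()], [generatePhantom()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    gridShape = "integer",
    spacing = "numeric",
    tumorVolume = "numeric",
    tumorSide = "character",
    noiseSD = "numeric",
    biasAmplitude = "numeric",
    seed = "integer"
  ),
  prototype(
    gridShape = c(96L, 96L, 96L),
    spacing = c(2, 2, 2),
    tumorVolume = 29,
    tumorSide = "left",
    noiseSD = 1,
    biasAmplitude = 0.01,
    seed = 1L
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 16L))
    msg <- c(msg, "'gridShape' must be 3 integers >= 16")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive values")
  if (length(object@tumorVolume) != 1L || object@tumorVolume <= 0)
    msg <- c(msg, "'tumorVolume' must be a positive scalar (cm^3)")
  if (!object@tumorSide %in% c("left", "right"))
    msg <- c(msg, "'tumorSide' must be \"left\" or \"right\"")
  if (object@noiseSD < 0)
    msg <- c(msg, "'noiseSD' must be non-negative")
  if (object@biasAmplitude < 0 || object@biasAmplitude >= 1)
    msg <- c(msg, "'biasAmplitude' must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param gridShape Grid dimensions in voxels (length 3 or scalar).
#' @param spacing Voxel spacing in mm (length 3 or scalar).
#' @param tumorVolume Lesion volume in cm^3 (default 29, a typical
#'   mid-sized renal lesion).
#' @param tumorSide `"left"` or `"right"` kidney.
#' @param noiseSD Additive Gaussian noise SD, as a fraction of each
#'   modality's intensity scale (default 0.009).
#' @param biasAmplitude Relative bias-field amplitude (default 0.01).
#' @param seed Integer seed.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- PhantomSpec(tumorVolume = 50, tumorSide = "right", seed = 7)
#' @export
PhantomSpec <- function(gridShape = c(96L, 96L, 96L), spacing = c(2, 2, 2),
                        tumorVolume = 29, tumorSide = "left",
                        noiseSD = 0.009, biasAmplitude = 0.01, seed = 1L) {
  new("PhantomSpec",
      gridShape = as.integer(rep_len(gridShape, 3L)),
      spacing = rep_len(as.numeric(spacing), 3L),
      tumorVolume = as.numeric(tumorVolume),
      tumorSide = tumorSide,
      noiseSD = as.numeric(noiseSD),
      biasAmplitude = as.numeric(biasAmplitude),
      seed = as.integer(seed))
}

#' PhantomCase: one synthetic subject's co-registered volumes and truth
#'
#' @slot ct,t1,t2fs [Volume-class] objects on a shared grid.
#' @slot truth Ground-truth [LabelMap-class] on the same grid.
#' @slot spec The generating [PhantomSpec-class].
#'
#' @seealso [generatePhantom()]
#' @exportClass PhantomCase
setClass("PhantomCase",
  representation(
    ct = "Volume",
    t1 = "Volume",
    t2fs = "Volume",
    truth = "LabelMap",
    spec = "PhantomSpec"
  )
)

setValidity("PhantomCase", function(object) {
  msg <- character()
  dims <- list(dim(object@ct@data), dim(object@t1@data),
               dim(object@t2fs@data), dim(object@truth@data))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    msg <- c(msg, "all four grids must share the same shape")
  if (length(msg)) msg else TRUE
})

#' PreprocessVariant: a named preprocessing recipe
#'
#' Bundles one of the three preprocessing variants with its parameters:
#' `"unprocessed"` (image untouched), `"inverted"` (clip then plain
#' intensity negative), and `"inverted_black"` (clip, negative, and
#' first-percentile background zeroing).
#'
#' @slot name Variant name.
#' @slot clipLo,clipHi Clipping bounds applied before inversion
#'   (defaults 0 and 3000).
#' @slot backgroundPercentile Percentile (in (0, 100)) at or below which
#'   original intensities are mapped to 0 in `"inverted_black"` (default 1).
#'
#' @seealso [preprocessVolume()], [variantNames()]
#' @exportClass PreprocessVariant
setClass("PreprocessVariant",
  representation(
    name = "character",
    clipLo = "numeric",
    clipHi = "numeric",
    backgroundPercentile = "numeric"
  ),
  prototype(name = "inverted_black", clipLo = 0, clipHi = 3000,
            backgroundPercentile = 1)
)

setValidity("PreprocessVariant", function(object) {
  msg <- character()
  if (!object@name %in% variantNames())
    msg <- c(msg, sprintf("'name' must be one of: %s",
                          paste(variantNames(), collapse = ", ")))
  if (object@clipLo >= object@clipHi)
    msg <- c(msg, "'clipLo' must be < 'clipHi'")
  if (object@backgroundPercentile <= 0 || object@backgroundPercentile >= 100)
    msg <- c(msg, "'backgroundPercentile' must be in (0, 100)")
  if (length(msg)) msg else TRUE
})

#' Allowed preprocessing variant names
#'
#' @return Character vector of the three variant names.
#' @export
variantNames <- function() c("unprocessed", "inverted", "inverted_black")

#' Construct a PreprocessVariant
#'
#' @param name One of [variantNames()].
#' @param clipLo,clipHi Clip bounds (defaults 0 and 3000).
#' @param backgroundPercentile Background percentile (default 1).
#' @return A [PreprocessVariant-class] object.
#' @examples
#' PreprocessVariant("inverted_black")
#' @export
PreprocessVariant <- function(name, clipLo = 0, clipHi = 3000,
                              backgroundPercentile = 1) {
  new("PreprocessVariant", name = name, clipLo = as.numeric(clipLo),
      clipHi = as.numeric(clipHi),
      backgroundPercentile = as.numeric(backgroundPercentile))
}
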
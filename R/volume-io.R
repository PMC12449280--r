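#' Read a 3-D NIfTI volume
#'
#' Reads a `.nii` or `.nii.gz` file into a [Volume-class]. Images carrying a
#' qform/sform are reoriented to the closest-to-RAS axis order on load, so
#' that left/right organ logic is well defined; spacing and affine are taken
#' from the header and intensities are left unmodified.
#'
#' @param path Path to a 3-D NIfTI file.
#' @param modality Modality tag to attach (`"CT"`, `"T1w"`, `"T2wfs"`,
#'   `"other"`).
#' @return A [Volume-class].
#' @seealso [writeVolume()], [readLabelMap()]
#' @export
readVolume <- function(path, modality = "other") {
  nii <- .readNifti3d(path)
  Volume(nii$data, spacing = nii$spacing, affine = nii$affine,
         modality = modality)
}

#' Read a NIfTI label map
#'
#' As [readVolume()], but coerces voxel values to integer class ids and
#' attaches a vocabulary. If `vocabulary` is `NULL`, a JSON sidecar named
#' `<image>.labels.json` (a name-to-id object) is read when present;
#' otherwise ids are named `class_<id>`.
#'
#' @param path Path to a 3-D integer-valued NIfTI file.
#' @param vocabulary Named integer vector mapping class names to ids, or
#'   `NULL` to auto-discover.
#' @return A [LabelMap-class].
#' @export
readLabelMap <- function(path, vocabulary = NULL) {
  nii <- .readNifti3d(path)
  dat <- nii$data
  if (max(abs(dat - round(dat))) > 1e-6)
    stopf("'%s' contains non-integer values; not a label map", path)
  dat <- round(dat)
  if (is.null(vocabulary)) {
    sidecar <- .sidecarPath(path)
    if (file.exists(sidecar)) {
      voc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      vocabulary <- stats::setNames(as.integer(voc), names(voc))
    } else {
      ids <- setdiff(sort(unique(as.vector(dat))), 0)
      vocabulary <- stats::setNames(as.integer(ids),
                                    sprintf("class_%d", as.integer(ids)))
    }
  }
  LabelMap(dat, spacing = nii$spacing, affine = nii$affine,
           vocabulary = vocabulary)
}

.sidecarPath <- function(path) {
  sub("\\.nii(\\.gz)?$", ".labels.json", path)
}

.readNifti3d <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stopf("'%s' is %d-D; only 3-D images are supported",
          path, length(dim(img)))
  hasForm <- attr(RNifti::xform(img), "code") > 0
  if (hasForm) {
    # canonical axis order so sided (left/right) logic is well defined
    RNifti::orientation(img) <- "RAS"
    aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
    sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  } else {
    sp <- RNifti::pixdim(img)
    aff <- diag(c(sp, 1))
  }
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))
  list(data = dat, spacing = as.numeric(sp), affine = unclass(aff))
}

#' Write a volume or label map to NIfTI
#'
#' Volumes are written as 32-bit float; label maps with an integer on-disk
#' type (and, when a vocabulary is present, a `<image>.labels.json` sidecar
#' with the name-to-id mapping). Both `.nii` and `.nii.gz` paths are
#' accepted; `.nii.gz` is the conventional choice.
#'
#' @param v A [Volume-class] or [LabelMap-class].
#' @param path Output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @param sidecar Write the vocabulary sidecar for label maps (default TRUE).
#' @return `path`, invisibly.
#' @seealso [readVolume()]
#' @export
writeVolume <- function(v, path, sidecar = TRUE) {
  if (!dir.exists(dirname(path)))
    stopf("parent directory does not exist: %s", dirname(path))
  isLabel <- is(v, "LabelMap")
  dat <- v@data
  if (isLabel) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  RNifti::sform(img) <- structure(v@affine, code = 2L)
  dtype <- if (isLabel) {
    if (max(dat) > 32767L) "int32" else "int16"
  } else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  if (isLabel && sidecar && length(v@vocabulary)) {
    jsonlite::write_json(as.list(v@vocabulary), .sidecarPath(path),
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' Resample to an isotropic voxel size
#'
#' Resamples a volume or label map to `target_mm` isotropic spacing
#' (default 1 mm, the working resolution of the pipeline). Intensity
#' volumes are interpolated trilinearly; label maps by nearest neighbor,
#' so no fractional class ids can arise and no new ids are introduced.
#' Voxel (0,0,0) centers are kept aligned and the physical extent is
#' preserved to within one voxel per axis.
#'
#' @param v A [Volume-class] or [LabelMap-class].
#' @param target_mm Positive scalar target voxel edge length in mm.
#' @return An object of the same class as `v` on the new grid.
#' @examples
#' v <- Volume(array(rnorm(1000), c(10, 10, 10)), spacing = 2)
#' dim(resampleIsotropic(v, 1))  # about 20 x 20 x 20
#' @export
resampleIsotropic <- function(v, target_mm = 1.0) {
  if (!is.numeric(target_mm) || length(target_mm) != 1L ||
      !is.finite(target_mm) || target_mm <= 0)
    stopf("'target_mm' must be a positive scalar")
  isLabel <- is(v, "LabelMap")
  sp <- v@spacing
  dIn <- dim(v@data)
  dOut <- pmax(1L, as.integer(round(dIn * sp / target_mm)))
  if (identical(sp, rep(target_mm, 3)) && identical(dOut, dIn)) return(v)
  dat <- if (isLabel) {
    out <- resample_nearest_cpp(as.integer(v@data), dIn, dOut,
                                target_mm / sp)
    array(out, dOut)
  } else {
    out <- resample_trilinear_cpp(as.double(v@data), dIn, dOut,
                                  target_mm / sp)
    array(out, dOut)
  }
  newAff <- v@affine %*% diag(c(target_mm / sp, 1))
  if (isLabel)
    LabelMap(dat, spacing = rep(target_mm, 3), affine = newAff,
             vocabulary = v@vocabulary)
  else
    Volume(dat, spacing = rep(target_mm, 3), affine = newAff,
           modality = v@modality)
}
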
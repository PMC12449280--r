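# Segmentation backends.
#
# The backend contract: a segmenter takes a Volume and returns a LabelMap on
# the same grid, emitting only ids from its declared vocabulary (plus 0).
# Two backends are provided: a deterministic rule-based intensity-window
# segmenter encoding CT intensity priors (the desk-scale stand-in for a
# CT-trained model: it succeeds on CT-like intensity distributions and fails
# on un-inverted T1w-like ones), and an adapter that shells out to an
# external segmentation command.

#' Window table for the rule-based segmenter
#'
#' A window table is a data.frame with one row per class:
#' `class_name`, `lo`, `hi` (intensity bounds, `lo < hi`),
#' `min_component_mm3` (connected components smaller than this are
#' discarded), `side_constraint` (`"none"`, `"left_of_midline"`,
#' `"right_of_midline"`; the midline is the middle sagittal plane of the
#' grid), and `priority` (integer; higher-priority classes claim voxels
#' first, ties broken by row order).
#'
#' `defaultWindows()` loads the table shipped with the package, which is
#' expressed on the robustly rescaled intensity scale (`scale = "relative"`:
#' volume intensities mapped linearly so min is 0 and max is 1, mirroring
#' the input normalization of CT-trained networks) and matched to the
#' phantom's CT intensity model. `readWindows()` loads a table from a JSON
#' file of the same layout.
#'
#' @param path Path to a JSON window table.
#' @return A data.frame window table with attribute `"scale"` set to
#'   `"raw"` or `"relative"`.
#' @seealso [windowSegment()]
#' @export
defaultWindows <- function() {
  readWindows(system.file("extdata", "windows_default.json",
                          package = "invertseg", mustWork = TRUE))
}

#' @rdname defaultWindows
#' @export
readWindows <- function(path) {
  if (!file.exists(path)) stopf("window table not found: %s", path)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- as.data.frame(spec$windows, stringsAsFactors = FALSE)
  .checkWindows(tab)
  attr(tab, "scale") <- if (is.null(spec$scale)) "raw" else spec$scale
  tab
}

.checkWindows <- function(tab) {
  need <- c("class_name", "lo", "hi", "min_component_mm3",
            "side_constraint", "priority")
  if (!is.data.frame(tab) || nrow(tab) == 0L)
    stopf("window table must be a non-empty data.frame")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stopf("window table lacks columns: %s", paste(missing, collapse = ", "))
  if (any(tab$lo >= tab$hi)) stopf("every window needs lo < hi")
  if (any(tab$min_component_mm3 < 0))
    stopf("'min_component_mm3' must be non-negative")
  bad <- setdiff(tab$side_constraint,
                 c("none", "left_of_midline", "right_of_midline"))
  if (length(bad))
    stopf("unknown side_constraint: %s", paste(bad, collapse = ", "))
  if (anyDuplicated(tab$class_name))
    stopf("duplicate class names in window table")
  invisible(tab)
}

#' Rule-based intensity-window segmentation
#'
#' Segments a volume by per-class intensity windows: for each window in
#' descending priority, voxels inside `[lo, hi]` and satisfying the side
#' constraint form a candidate mask; 26-connectivity components smaller
#' than `min_component_mm3` are discarded; surviving voxels not yet claimed
#' by a higher-priority class receive the class id. The result is
#' deterministic for identical input.
#'
#' With `scale = "relative"` (the default table's scale) the window bounds
#' refer to the volume's intensities rescaled linearly to `[0, 1]` by its
#' minimum and maximum — the normalization a CT-trained network applies to
#' its input. With `scale = "raw"` the bounds are literal intensities.
#'
#' @param v A [Volume-class].
#' @param windows A window table (see [defaultWindows()]).
#' @param scale `"raw"` or `"relative"`; defaults to the table's own
#'   `"scale"` attribute, or `"raw"` if it has none.
#' @return A [LabelMap-class] on the same grid; class ids are assigned
#'   `1:nrow(windows)` in table order.
#' @examples
#' w <- data.frame(class_name = "blob", lo = 20, hi = 60,
#'                 min_component_mm3 = 0, side_constraint = "none",
#'                 priority = 1)
#' v <- Volume(array(c(rep(-1000, 500), rep(40, 12)), c(8, 8, 8)))
#' table(imageData(windowSegment(v, w, scale = "raw")))
#' @export
windowSegment <- function(v, windows, scale = NULL) {
  stopifnot(is(v, "Volume"))
  .checkWindows(windows)
  if (is.null(scale))
    scale <- attr(windows, "scale") %||% "raw"
  if (!scale %in% c("raw", "relative"))
    stopf("'scale' must be \"raw\" or \"relative\"")
  x <- v@data
  if (scale == "relative") {
    rng <- range(x)
    if (rng[2] > rng[1]) x <- (x - rng[1]) / (rng[2] - rng[1])
    else x <- array(0, dim(x))
  }
  shape <- dim(x)
  vox <- voxelVolume(v)
  # windows in descending priority; the midline (middle sagittal plane,
  # left = low x in canonical RAS order) and component filtering are
  # handled in the compiled kernel
  ord <- order(-windows$priority, seq_len(nrow(windows)))
  sideCode <- match(windows$side_constraint[ord],
                    c("none", "left_of_midline", "right_of_midline")) - 1L
  out <- window_assign_cpp(as.double(x), shape,
                           windows$lo[ord], windows$hi[ord],
                           sideCode, windows$min_component_mm3[ord] / vox,
                           as.integer(ord))
  out <- array(out, shape)
  LabelMap(out, spacing = v@spacing, affine = v@affine,
           vocabulary = stats::setNames(seq_len(nrow(windows)),
                                        windows$class_name))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an external segmentation command
#'
#' Adapter for CT segmentation models reachable as shell commands (e.g.
#' TotalSegmentator-style tools). The volume is written to NIfTI in
#' `workdir`, `{input}` and `{output}` placeholders in `commandTemplate`
#' are substituted, and the command is executed. If `{output}` names a
#' single NIfTI file it is read as the result label map; if it names a
#' directory, every `*.nii`/`*.nii.gz` inside is treated as a binary mask
#' named by its file stem and merged using `classMapping` (a named integer
#' vector or path to a JSON name-to-id object; later entries never
#' overwrite earlier ones). Nothing is resampled or renamed silently.
#'
#' @param commandTemplate Shell command containing `{input}` and `{output}`.
#' @param v A [Volume-class].
#' @param workdir Working directory for the exchange files (default: a
#'   fresh temporary directory).
#' @param classMapping Named integer vector (name -> id), or path to a JSON
#'   file with that mapping; required for multi-file outputs, optional for
#'   single-file outputs (used then to attach a vocabulary).
#' @return A [LabelMap-class] on the input grid.
#' @export
externalSegment <- function(commandTemplate, v, workdir = tempfile("extseg"),
                            classMapping = NULL) {
  stopifnot(is(v, "Volume"))
  if (!grepl("{input}", commandTemplate, fixed = TRUE) ||
      !grepl("{output}", commandTemplate, fixed = TRUE))
    stopf("'commandTemplate' must contain {input} and {output} placeholders")
  if (is.character(classMapping) && length(classMapping) == 1L &&
      file.exists(classMapping)) {
    mp <- jsonlite::read_json(classMapping, simplifyVector = TRUE)
    classMapping <- stats::setNames(as.integer(mp), names(mp))
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  input <- file.path(workdir, "input.nii.gz")
  output <- file.path(workdir, "output")
  writeVolume(v, input)
  cmd <- gsub("{output}", output,
              gsub("{input}", input, commandTemplate, fixed = TRUE),
              fixed = TRUE)
  status <- system(cmd, intern = FALSE)
  if (status != 0L) {
    unlink(workdir, recursive = TRUE)
    stopf("backend command failed with exit status %d: %s", status, cmd)
  }
  lm <- .collectExternalOutput(output, v, classMapping)
  checkSameGrid(lm@data, v@data, "backend output and input")
  lm
}

.collectExternalOutput <- function(output, v, classMapping) {
  single <- c(output, paste0(output, ".nii.gz"), paste0(output, ".nii"))
  isFile <- vapply(single, function(p) file.exists(p) && !dir.exists(p),
                   logical(1))
  if (any(isFile)) {
    return(readLabelMap(single[which(isFile)[1]], vocabulary = classMapping))
  }
  if (!dir.exists(output))
    stopf("backend produced no output at %s", output)
  files <- list.files(output, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (!length(files))
    stopf("backend output directory %s contains no NIfTI files", output)
  if (is.null(classMapping))
    stopf("multi-file backend output requires a class mapping")
  out <- NULL
  for (f in files) {
    stem <- sub("\\.nii(\\.gz)?$", "", basename(f))
    if (!stem %in% names(classMapping)) next
    mask <- .readNifti3d(f)
    if (is.null(out))
      out <- list(data = array(0L, dim(mask$data)),
                  spacing = mask$spacing, affine = mask$affine)
    sel <- mask$data > 0 & out$data == 0L
    out$data[sel] <- classMapping[[stem]]
  }
  if (is.null(out))
    stopf("no backend output file matched the class mapping")
  LabelMap(out$data, spacing = out$spacing, affine = out$affine,
           vocabulary = classMapping)
}
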
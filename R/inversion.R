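#' Clip intensities to a fixed range
#'
#' Maps every voxel to `min(hi, max(lo, x))`. The default range of 0 to
#' 3000 covers typical MRI scanner units while removing extreme outliers
#' before inversion.
#'
#' @param v A [Volume-class].
#' @param lo,hi Clip bounds, `lo < hi`.
#' @return A [Volume-class] with identical geometry.
#' @seealso [invertPlain()], [invertBlack()], [preprocessVolume()]
#' @export
clipIntensities <- function(v, lo = 0, hi = 3000) {
  stopifnot(is(v, "Volume"))
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stopf("'lo' must be < 'hi' (got %s, %s)", lo, hi)
  out <- v
  out@data <- pmin(pmax(v@data, lo), hi)  # array first: keeps dim
  out
}

#' Plain intensity inversion (image negative)
#'
#' Maps each voxel `x` to `max(X) - x + min(X)`, where `X` is the set of
#' all voxel values of the volume: the image negative within its original
#' intensity range. The operation is an involution and preserves the
#' minimum and maximum exactly.
#'
#' @param v A [Volume-class].
#' @return The inverted [Volume-class].
#' @examples
#' v <- Volume(array(c(0, 10, 30, 30), c(4, 1, 1)))
#' imageData(invertPlain(v))[, 1, 1]  # 30 20 0 0
#' @export
invertPlain <- function(v) {
  stopifnot(is(v, "Volume"))
  if (length(v@data) == 0) stopf("empty volume")
  M <- max(v@data)
  m <- min(v@data)
  out <- v
  out@data <- (M - v@data) + m
  out
}

#' Inversion with background zeroing
#'
#' The image negative with the area around the patient forced to black:
#' let `t` be the `p`-th percentile of all voxel values (linear
#' interpolation); voxels with `x <= t` map to 0 and all others to
#' `max(X) - x + min(X)`. With `p = 1` this blacks out background air,
#' which in exported MRI is a large tie mass at the image minimum, while
#' leaving the body's intensity ordering inverted.
#'
#' @param v A [Volume-class].
#' @param p Background percentile in (0, 100); default 1.
#' @return The inverted [Volume-class] with zeroed background.
#' @seealso [preprocessVolume()]
#' @export
invertBlack <- function(v, p = 1) {
  stopifnot(is(v, "Volume"))
  if (length(v@data) == 0) stopf("empty volume")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 100)
    stopf("'p' must be a percentile in (0, 100)")
  x <- v@data
  t <- stats::quantile(x, p / 100, names = FALSE, type = 7)
  M <- max(x)
  m <- min(x)
  out <- v
  inv <- (M - x) + m
  inv[x <= t] <- 0
  out@data <- inv
  out
}

#' Apply a named preprocessing variant
#'
#' Dispatches to the three preprocessing recipes used when running a
#' CT-trained model on MRI: `"unprocessed"` returns the input untouched;
#' `"inverted"` clips then takes the plain negative; `"inverted_black"`
#' clips, then inverts with the background percentile computed on the
#' clipped, pre-inversion intensities.
#'
#' @param v A [Volume-class].
#' @param variant A [PreprocessVariant-class] or one of [variantNames()].
#' @return The preprocessed [Volume-class]; spacing, affine and grid shape
#'   are never changed.
#' @examples
#' v <- Volume(array(runif(64, 0, 500), c(4, 4, 4)))
#' preprocessVolume(v, "inverted_black")
#' @export
preprocessVolume <- function(v, variant = "inverted_black") {
  if (is.character(variant)) {
    if (length(variant) != 1L || !variant %in% variantNames())
      stopf("unknown variant '%s'; expected one of: %s",
            paste(variant, collapse = ","),
            paste(variantNames(), collapse = ", "))
    variant <- PreprocessVariant(variant)
  }
  stopifnot(is(variant, "PreprocessVariant"))
  switch(variant@name,
    unprocessed = v,
    inverted = invertPlain(clipIntensities(v, variant@clipLo,
                                           variant@clipHi)),
    inverted_black = invertBlack(clipIntensities(v, variant@clipLo,
                                                 variant@clipHi),
                                 variant@backgroundPercentile)
  )
}
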
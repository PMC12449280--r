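# Class-wise Dice evaluation, bootstrap summaries, tumor localization and
# volume stratification. EvalTable is a plain data.frame with one row per
# (case, sequence, variant, class): columns case_id, sequence, variant,
# class_name, dsc, ref_volume_cm3, pred_volume_cm3. dsc is NA only when
# both masks are empty (undefined overlap).

#' Dice similarity coefficient of two binary masks
#'
#' `2 * |A intersect B| / (|A| + |B|)` for voxel masks of equal shape:
#' 1 for identical non-empty masks, 0 for disjoint ones. When both masks
#' are empty the overlap is undefined and `NA` is returned.
#'
#' @param pred,ref Logical (or 0/1) arrays of equal shape.
#' @return A scalar in `[0, 1]`, or `NA` if both masks are empty.
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
#' b <- array(c(TRUE, FALSE, TRUE, FALSE), c(4, 1, 1))
#' dice(a, b)  # 2*1/(2+2) = 0.5
#' @export
dice <- function(pred, ref) {
  checkSameGrid(pred, ref, "masks")
  p <- sum(pred != 0)
  r <- sum(ref != 0)
  if (p + r == 0L) return(NA_real_)
  2 * sum(pred != 0 & ref != 0) / (p + r)
}

#' Class mapping between backend and reference vocabularies
#'
#' A named character vector `c(predictionClass = referenceClass, ...)`.
#' Several prediction classes may map onto one reference class (their masks
#' are unioned); unmapped prediction classes are ignored.
#'
#' `identityMapping()` maps every reference class to itself.
#'
#' @param ref A [LabelMap-class] whose vocabulary defines the classes.
#' @return Named character vector.
#' @export
identityMapping <- function(ref) {
  nm <- names(vocabulary(ref))
  stats::setNames(nm, nm)
}

#' Evaluate one prediction against a reference
#'
#' Computes one evaluation record per reference class in `mapping`: the
#' prediction mask is the union of all prediction classes mapped to that
#' reference class, the reference mask is the class's voxels in `ref`, and
#' volumes are voxel count times voxel volume. Prediction and reference
#' must live on the same grid (resample caller-side otherwise).
#'
#' @param pred,ref [LabelMap-class] objects on the same grid.
#' @param mapping Named character vector (prediction class -> reference
#'   class); default maps identical names.
#' @param case_id,sequence,variant Metadata copied into every record.
#' @return A data.frame (EvalTable rows): `case_id`, `sequence`, `variant`,
#'   `class_name`, `dsc`, `ref_volume_cm3`, `pred_volume_cm3`.
#' @seealso [dice()], [summarizeDice()]
#' @export
evaluateCase <- function(pred, ref, mapping = identityMapping(ref),
                         case_id = "case", sequence = "T1w",
                         variant = "unprocessed") {
  checkSameGrid(pred@data, ref@data, "prediction and reference")
  refClasses <- unique(unname(mapping))
  refClasses <- refClasses[refClasses %in% names(vocabulary(ref))]
  predVoc <- vocabulary(pred)
  refVoc <- vocabulary(ref)
  voxCm3 <- voxelVolume(ref) / 1000
  # joint (pred id, ref id) contingency counts in one pass; since label
  # maps are disjoint by construction, unions over prediction classes are
  # sums of counts
  P <- max(1L, predVoc, 0L)
  R <- max(1L, refVoc, 0L)
  code <- as.vector(pred@data) + (P + 1L) * as.vector(ref@data)
  counts <- matrix(tabulate(code + 1L, nbins = (P + 1L) * (R + 1L)),
                   nrow = P + 1L)
  predSizes <- rowSums(counts)
  refSizes <- colSums(counts)
  rows <- lapply(refClasses, function(rc) {
    predNames <- names(mapping)[mapping == rc]
    predIds <- unname(predVoc[names(predVoc) %in% predNames])
    rid <- refVoc[[rc]]
    inter <- sum(counts[predIds + 1L, rid + 1L])
    p <- sum(predSizes[predIds + 1L])
    r <- refSizes[rid + 1L]
    data.frame(case_id = case_id, sequence = sequence, variant = variant,
               class_name = rc,
               dsc = if (p + r == 0) NA_real_ else 2 * inter / (p + r),
               ref_volume_cm3 = r * voxCm3,
               pred_volume_cm3 = p * voxCm3,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize Dice scores with bootstrap confidence intervals
#'
#' Groups evaluation records and reports the pooled mean DSC per group with
#' a 95% case-level nonparametric bootstrap confidence interval (percentile
#' method): case ids are resampled with replacement and the pooled mean of
#' the selected cases' records recomputed `B` times. Undefined DSCs (both
#' masks empty) are excluded from means and counted in `n_undefined`.
#' Groups with no defined records are flagged (`empty = TRUE`), never
#' silently dropped.
#'
#' @param table EvalTable data.frame (see [evaluateCase()]).
#' @param groupBy Character vector of grouping columns
#'   (default `c("sequence", "variant")`).
#' @param B Bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap (default 1).
#' @return A data.frame with the group columns plus `mean_dsc`, `ci_lo`,
#'   `ci_hi`, `n_records`, `n_cases`, `n_undefined`, `empty`.
#' @export
summarizeDice <- function(table, groupBy = c("sequence", "variant"),
                          B = 2000, level = 0.95, seed = 1L) {
  stopifnot(is.data.frame(table), all(groupBy %in% names(table)))
  if (!nrow(table)) stopf("empty evaluation table")
  key <- interaction(table[groupBy], drop = TRUE, lex.order = TRUE)
  alpha <- (1 - level) / 2
  out <- lapply(levels(key), function(k) {
    sub <- table[key == k, , drop = FALSE]
    grp <- sub[1, groupBy, drop = FALSE]
    def <- sub[!is.na(sub$dsc), , drop = FALSE]
    n_undef <- sum(is.na(sub$dsc))
    if (!nrow(def)) {
      return(cbind(grp, data.frame(mean_dsc = NA_real_, ci_lo = NA_real_,
                                   ci_hi = NA_real_, n_records = 0L,
                                   n_cases = 0L, n_undefined = n_undef,
                                   empty = TRUE)))
    }
    cases <- unique(def$case_id)
    perCase <- split(def$dsc, def$case_id)
    boot <- withSeed(seed, vapply(seq_len(B), function(b) {
      pick <- sample(cases, length(cases), replace = TRUE)
      mean(unlist(perCase[pick], use.names = FALSE))
    }, numeric(1)))
    ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
    cbind(grp, data.frame(mean_dsc = mean(def$dsc), ci_lo = ci[1],
                          ci_hi = ci[2], n_records = nrow(def),
                          n_cases = length(cases), n_undefined = n_undef,
                          empty = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify tumor localization
#'
#' Per-case categorization of a tumor prediction against a non-empty
#' reference: `"not_detected"` if the prediction is empty, `"correct"` if
#' at least `minOverlap` of the reference voxels are covered (default: any
#' overlapping voxel), `"incorrect"` otherwise. Every (pred, ref) pair
#' falls in exactly one category.
#'
#' @param pred,ref Logical (or 0/1) arrays of equal shape; `ref` must be
#'   non-empty.
#' @param minOverlap Minimum fraction of reference voxels that must be
#'   covered to count as correct (default 0: any overlap).
#' @return One of `"correct"`, `"incorrect"`, `"not_detected"`.
#' @export
classifyLocalization <- function(pred, ref, minOverlap = 0) {
  checkSameGrid(pred, ref, "masks")
  nref <- sum(ref != 0)
  if (nref == 0L) stopf("reference tumor mask is empty: task undefined")
  if (sum(pred != 0) == 0L) return("not_detected")
  frac <- sum(pred != 0 & ref != 0) / nref
  if (frac > 0 && frac >= minOverlap) "correct" else "incorrect"
}

#' Stratify tumor DSC by lesion volume
#'
#' Splits tumor records at the median reference volume (records exactly at
#' the median go to the upper stratum) and reports the mean DSC per
#' stratum — the volume-dependence summary of lesion segmentation quality.
#'
#' @param records EvalTable rows for the tumor class with defined
#'   `ref_volume_cm3`; at least 2 required.
#' @return A list: `median_volume_cm3`, `mean_dsc_below`, `mean_dsc_above`,
#'   `n_below`, `n_above`, and `flag` (non-`NA` when a stratum is empty).
#' @export
stratifyByVolume <- function(records) {
  stopifnot(is.data.frame(records))
  records <- records[!is.na(records$ref_volume_cm3), , drop = FALSE]
  if (nrow(records) < 2L)
    stopf("need at least 2 records with defined volumes")
  med <- stats::median(records$ref_volume_cm3)
  below <- records[records$ref_volume_cm3 < med, , drop = FALSE]
  above <- records[records$ref_volume_cm3 >= med, , drop = FALSE]
  flag <- if (!nrow(below)) "below stratum empty (all volumes equal)"
          else NA_character_
  list(median_volume_cm3 = med,
       mean_dsc_below = if (nrow(below)) mean(below$dsc, na.rm = TRUE)
                        else NA_real_,
       mean_dsc_above = if (nrow(above)) mean(above$dsc, na.rm = TRUE)
                        else NA_real_,
       n_below = nrow(below), n_above = nrow(above), flag = flag)
}
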
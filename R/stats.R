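# Paired nonparametric statistics: Shapiro-Wilk normality (descriptive),
# Wilcoxon signed-rank comparisons between preprocessing variants,
# Spearman volume-DSC correlation, and Benjamini-Hochberg correction.
#
# The signed-rank test is implemented in-package because its contract is
# pinned down precisely: zero differences dropped before ranking, midranks
# for tied absolute differences, an exact null distribution for n <= 25
# (computed by dynamic programming over rank sums, valid with ties), and a
# normal approximation with tie and continuity corrections above.

#' Shapiro-Wilk normality p-value
#'
#' Thin validated wrapper around [stats::shapiro.test()], reported
#' descriptively alongside the nonparametric comparisons (the pipeline
#' always uses Wilcoxon tests regardless of the outcome). A constant
#' sample has no defined statistic and is reported as non-normal (p = 0)
#' with a flag.
#'
#' @param x Numeric sample, `3 <= length(x) <= 5000`.
#' @return A list with `p`, `statistic`, and `degenerate`.
#' @export
shapiroWilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L)
    stopf("Shapiro-Wilk requires 3 <= n <= 5000 (got %d)", length(x))
  if (stats::sd(x) == 0)
    return(list(p = 0, statistic = NA_real_, degenerate = TRUE))
  ht <- stats::shapiro.test(x)
  list(p = unname(ht$p.value), statistic = unname(ht$statistic),
       degenerate = FALSE)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on the differences `a - b`. Zero differences are dropped
#' before ranking; tied absolute differences receive midranks. For n <= 25
#' non-zero pairs the exact two-sided p-value is computed from the exact
#' null distribution of the positive-rank sum (enumerated by dynamic
#' programming over all sign assignments, which remains exact under
#' midranks); for larger n a normal approximation with tie correction and
#' continuity correction is used. If every difference is zero the
#' comparison is degenerate and reported as p = 1.
#'
#' @param a,b Paired numeric vectors of equal length >= 1.
#' @param exactMax Largest n for which the exact distribution is used
#'   (default 25).
#' @return A list: `statistic` (positive-rank sum V), `p`, `n` (non-zero
#'   pairs), `method` (`"exact"` or `"normal"`), `degenerate`.
#' @examples
#' wilcoxonSignedRank(c(5, 6, 7, 8, 9, 10), c(1, 2, 3, 4, 5, 6))$p  # 0.03125
#' @export
wilcoxonSignedRank <- function(a, b, exactMax = 25L) {
  if (length(a) != length(b)) stopf("'a' and 'b' must have equal length")
  if (!length(a)) stopf("need at least one pair")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p = 1, n = 0L, method = "degenerate",
                degenerate = TRUE))
  r <- rank(abs(d))          # midranks for ties
  V <- sum(r[d > 0])
  if (n <= exactMax) {
    p <- .exactSignedRankP(V, r)
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4      # midrank variance (absorbs tie correction)
    z <- (abs(V - mu) - 0.5) / sqrt(sig2)
    z <- max(z, 0)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(p, 1)
    method <- "normal"
  }
  list(statistic = V, p = p, n = n, method = method, degenerate = FALSE)
}

# Exact two-sided p-value for the positive-rank sum V given the midranks r:
# P(|V' - mu| >= |V - mu|) under random independent signs. Ranks are doubled
# to make midranks integral; the distribution of the doubled rank sum is
# built by convolution over the sign assignments.
.exactSignedRankP <- function(V, r) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  dist <- .rankSumDistribution(r2)
  mu2 <- total / 2
  dev <- abs(2 * V - mu2)    # deviation of doubled V from its mean
  support <- seq(0L, total)
  prob <- dist / sum(dist)
  sum(prob[abs(support - mu2) >= dev - 1e-9])
}

# dist[s + 1] = number of sign assignments with doubled positive-rank sum s.
.rankSumDistribution <- function(r2) {
  total <- sum(r2)
  dist <- numeric(total + 1L)
  dist[1L] <- 1
  upper <- 0L
  for (ri in r2) {
    newUpper <- upper + ri
    nxt <- numeric(total + 1L)
    idx <- seq_len(upper + 1L)
    nxt[idx] <- dist[idx]
    nxt[idx + ri] <- nxt[idx + ri] + dist[idx]
    dist <- nxt
    upper <- newUpper
  }
  dist
}

#' Spearman rank correlation
#'
#' Product-moment correlation of midranks (average ranks for ties), with a
#' two-sided p-value from the t approximation on `n - 2` degrees of
#' freedom. A constant input has no defined correlation and is flagged.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list: `rho`, `p`, `n`, `degenerate`.
#' @examples
#' spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho  # 0.8
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stopf("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stopf("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values,
#' delegated to [stats::p.adjust()] after validation; adjusted values are
#' elementwise >= the raw values, follow their p-values under permutation,
#' and are capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("all p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pairwise variant comparisons over an evaluation table
#'
#' For each requested pair of preprocessing variants and each sequence,
#' forms the per-case comparison unit — the mean DSC across classes
#' (`level = "mean"`) or the tumor-class DSC (`level = "tumor"`) — and runs
#' the paired Wilcoxon signed-rank test. All comparisons emitted together
#' form one Benjamini-Hochberg family. Shapiro-Wilk p-values of the paired
#' differences are reported descriptively.
#'
#' @param table EvalTable data.frame (see [evaluateCase()]).
#' @param pairs List of length-2 character vectors of variant names;
#'   default: all three pairwise comparisons.
#' @param level `"mean"` or `"tumor"`.
#' @param tumorClass Reference class name used when `level = "tumor"`.
#' @return A data.frame with one row per (sequence, pair): `sequence`,
#'   `comparison`, `n_pairs`, `statistic`, `p_raw`, `p_adjusted`,
#'   `p_normality`, `degenerate`.
#' @export
compareVariants <- function(table,
                            pairs = list(c("unprocessed", "inverted"),
                                         c("unprocessed", "inverted_black"),
                                         c("inverted", "inverted_black")),
                            level = c("mean", "tumor"),
                            tumorClass = "tumor") {
  level <- match.arg(level)
  stopifnot(is.data.frame(table))
  unit <- if (level == "tumor")
    table[table$class_name == tumorClass, , drop = FALSE]
  else table
  agg <- stats::aggregate(dsc ~ case_id + sequence + variant, data = unit,
                          FUN = mean, na.action = stats::na.omit)
  rows <- list()
  for (sq in sort(unique(agg$sequence))) {
    for (pr in pairs) {
      a <- agg[agg$sequence == sq & agg$variant == pr[1], ]
      b <- agg[agg$sequence == sq & agg$variant == pr[2], ]
      common <- intersect(a$case_id, b$case_id)
      missing <- setdiff(union(a$case_id, b$case_id), common)
      if (length(missing))
        stopf("unmatched cases for %s vs %s (%s): %s", pr[1], pr[2], sq,
              paste(missing, collapse = ", "))
      if (!length(common)) next
      av <- a$dsc[match(common, a$case_id)]
      bv <- b$dsc[match(common, b$case_id)]
      wt <- wilcoxonSignedRank(av, bv)
      sw <- if (length(common) >= 3) shapiroWilk(av - bv)$p else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = sq, comparison = sprintf("%s vs %s", pr[1], pr[2]),
        n_pairs = length(common), statistic = wt$statistic, p_raw = wt$p,
        p_normality = sw, degenerate = wt$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stopf("no comparable variant pairs in table")
  res <- do.call(rbind, rows)
  res$p_adjusted <- bhAdjust(res$p_raw)
  res[, c("sequence", "comparison", "n_pairs", "statistic", "p_raw",
          "p_adjusted", "p_normality", "degenerate")]
}
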
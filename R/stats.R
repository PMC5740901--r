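# Statistical layer: one-sample Wilcoxon signed-rank test against no
# change, 2x2 chi-square association test, Benjamini-Hochberg adjustment.

# Exact two-sided signed-rank p-value by dynamic programming over the
# null distribution of W+ under independent sign flips. `ranks2` holds
# doubled ranks (average ties make ranks half-integers, so doubling gives
# integers); `w2` is the doubled observed statistic.
.signrank_exact_p <- function(w2, ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (d in ranks2) {
    g <- f
    g[(d + 1):(total + 1)] <- g[(d + 1):(total + 1)] + f[1:(total + 1 - d)]
    f <- g
  }
  f <- f / sum(f)
  p_le <- sum(f[1:(w2 + 1)])
  p_ge <- sum(f[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test against no change
#'
#' Two-sided one-sample test of median zero on a set of log2 fold
#' changes, as used to ask whether a peak-fate group's genes change
#' expression. Exact zeros are discarded (their count is reported). For
#' `n <= exact_max` the null is enumerated exactly over all sign
#' assignments (ties handled by average ranks); otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param lfcs Numeric vector of log2 fold changes.
#' @param exact_max Largest n for which the exact null is used
#'   (default 20).
#' @return List of class `test_result`: `statistic` (W+, `NA` if all
#'   values were zero), `pvalue`, `n` (after zero removal), `n_zero`,
#'   `method`.
#' @export
wilcoxon_no_change <- function(lfcs, exact_max = 20) {
  x <- lfcs[!is.na(lfcs)]
  n_zero <- sum(x == 0)
  x <- x[x != 0]
  n <- length(x)
  if (n == 0)
    return(structure(list(statistic = NA_real_, pvalue = 1, n = 0L,
                          n_zero = n_zero,
                          method = "wilcoxon signed-rank (degenerate: all zero)"),
                     class = "test_result"))
  r <- rank(abs(x))
  W <- sum(r[x > 0])
  if (n <= exact_max) {
    p <- .signrank_exact_p(as.integer(round(2 * W)),
                           as.integer(round(2 * r)))
    method <- "wilcoxon signed-rank (exact sign enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "wilcoxon signed-rank (normal approximation, tie/continuity corrected)"
  }
  structure(list(statistic = W, pvalue = p, n = n, n_zero = n_zero,
                 method = method),
            class = "test_result")
}

#' Two-sample Wilcoxon rank-sum test (sensitivity mode)
#'
#' Compares a group's fold changes against a reference set of fold
#' changes (e.g. genes not associated with an altered peak); provided as
#' a sensitivity companion to [wilcoxon_no_change()].
#'
#' @param lfcs Group fold changes.
#' @param reference Reference fold changes.
#' @return A `test_result` list.
#' @export
wilcoxon_vs_reference <- function(lfcs, reference) {
  ht <- suppressWarnings(stats::wilcox.test(lfcs, reference))
  structure(list(statistic = unname(ht$statistic), pvalue = ht$p.value,
                 n = c(length(lfcs), length(reference)), n_zero = 0L,
                 method = "wilcoxon rank-sum (two-sample)"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %s, p = %.4g, n = %s\n", x$method,
              format(x$statistic), x$pvalue,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Chi-square test of group membership versus expression change
#'
#' Pearson chi-square on the 2x2 table (in-group vs out-group) x
#' (changed vs unchanged), df = 1, no continuity correction by default.
#' Used to ask whether genes associated with an altered peak are more
#' likely to be differentially expressed than genes that are not.
#'
#' @param in_changed,in_unchanged Counts for genes in the group.
#' @param out_changed,out_unchanged Counts for genes outside the group.
#' @param correct Apply Yates continuity correction? Default `FALSE`.
#' @return A `test_result` list, additionally carrying `fraction_in` and
#'   `fraction_out` (changed fractions).
#' @export
chi_square_membership <- function(in_changed, in_unchanged,
                                  out_changed, out_unchanged,
                                  correct = FALSE) {
  counts <- c(in_changed, in_unchanged, out_changed, out_unchanged)
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be nonnegative")
  m <- matrix(counts, nrow = 2, byrow = TRUE,
              dimnames = list(c("in_group", "out_group"),
                              c("changed", "unchanged")))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square test undefined: a table margin is zero")
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  structure(list(statistic = unname(ht$statistic),
                 pvalue = ht$p.value,
                 n = sum(m),
                 fraction_in = in_changed / (in_changed + in_unchanged),
                 fraction_out = out_changed / (out_changed + out_unchanged),
                 method = sprintf("pearson chi-square on 2x2 (%s continuity correction)",
                                  if (correct) "with" else "no")),
            class = "test_result")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted q-values, monotone in the p-value ranking, clipped
#' at 1. Errors on p-values outside \[0, 1\]; `NA`s propagate.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
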
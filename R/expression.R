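# Differential-expression handling: DE tables, a simple count-based DE
# routine, direct-target filtering, quadrant categorization of doubly
# regulated genes, and double-knockdown rescue quantification.
#
# Naming: the two sibling subunits are "A" and "B" throughout (in the
# study regime A is BRG1, B is BRM); quadrant categories are `both_up`,
# `both_down`, `a_up_b_down`, `a_down_b_up`.

#' Analysis configuration
#'
#' Tunable thresholds shared across the pipeline.
#'
#' @param fdr Significance threshold on BH-adjusted q-values
#'   (default 0.05; no fold-change cutoff is applied anywhere).
#' @param merge_gap Recursive peak-merge gap in bp (default 500).
#' @param profile_window Metaprofile half-window in bp (default 2000).
#' @param profile_binsize Metaprofile bin size in bp (default 10).
#' @param fragment_extension Fragment extension in bp used when coverage
#'   tracks are generated (default 150); a property of track generation,
#'   not re-applied at read time.
#' @param seed Integer seed for any randomized step.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(fdr = 0.05, merge_gap = 500,
                            profile_window = 2000, profile_binsize = 10,
                            fragment_extension = 150, seed = 1L) {
  if (!(fdr > 0 && fdr < 1)) stop("fdr must lie in (0, 1)")
  for (v in c(merge_gap = merge_gap, profile_window = profile_window,
              profile_binsize = profile_binsize,
              fragment_extension = fragment_extension))
    if (v < 0) stop("bp parameters must be nonnegative")
  structure(list(fdr = fdr, merge_gap = merge_gap,
                 profile_window = profile_window,
                 profile_binsize = profile_binsize,
                 fragment_extension = fragment_extension,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

.de_required_cols <- c("gene_id", "mean_expr", "log2fc", "pvalue", "qvalue")

#' Read a differential-expression table
#'
#' TSV with header columns `gene_id`, `mean_expr`, `log2fc`, `pvalue`,
#' `qvalue`. Rows with missing `log2fc` or `qvalue` are retained but
#' flagged untestable. p/q outside \[0, 1\] is a validation error.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with the required columns plus `testable`.
#' @export
read_de_table <- function(path) {
  de <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(.de_required_cols, names(de))
  if (length(missing) > 0)
    stop("missing required column: ", missing[1])
  validate_de_table(de[.de_required_cols])
}

#' Validate (and flag) a DE table
#'
#' @param de `data.frame` with the required DE columns.
#' @return The table with a `testable` logical column appended.
#' @export
validate_de_table <- function(de) {
  for (col in c("pvalue", "qvalue")) {
    v <- de[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop(col, " outside [0, 1]")
  }
  if (anyDuplicated(de$gene_id))
    stop("duplicated gene_id: ", de$gene_id[duplicated(de$gene_id)][1])
  de$testable <- !is.na(de$log2fc) & !is.na(de$qvalue)
  de
}

#' Write a DE table
#'
#' @param de A DE `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  write.table(de[.de_required_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Simple count-based differential expression
#'
#' A deliberately plain two-group DE routine for synthetic end-to-end
#' runs: median-of-ratios size factors (geometric-mean reference over
#' genes with all-positive counts), log2 fold change of normalized group
#' means with pseudocount 0.5, per-gene pooled-variance two-sample t
#' statistic on log2 normalized counts (pseudocount 0.5), and BH-adjusted
#' q-values. Genes with zero counts in every sample are excluded.
#' Numerical agreement with shrinkage-based DE tools is not a goal; the
#' downstream logic consumes only (log2fc, q).
#'
#' @param counts Nonnegative integer matrix, genes x samples, with
#'   rownames as gene ids.
#' @param group Factor (or coercible) of length `ncol(counts)` with
#'   exactly two levels, reference level first; each level needs at
#'   least 2 samples.
#' @return DE `data.frame` (`gene_id`, `mean_expr`, `log2fc`, `pvalue`,
#'   `qvalue`, `testable`); `log2fc` is knockdown (second level) over
#'   reference.
#' @export
simple_de <- function(counts, group) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  group <- factor(group)
  if (nlevels(group) != 2)
    stop("group must have exactly two levels")
  if (any(table(group) < 2))
    stop("each group needs at least 2 samples")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%d", seq_len(nrow(counts)))
  keep <- rowSums(counts) > 0
  cnt <- counts[keep, , drop = FALSE]
  loggeo <- rowMeans(log(cnt))
  ref <- is.finite(loggeo)
  if (!any(ref))
    stop("no gene has positive counts in every sample; cannot estimate size factors")
  sf <- apply(cnt, 2, function(cj) exp(median(log(cj[ref]) - loggeo[ref])))
  norm <- sweep(cnt, 2, sf, "/")
  g1 <- group == levels(group)[1]
  g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, g2, drop = FALSE])
  lfc <- log2((m2 + 0.5) / (m1 + 0.5))
  l <- log2(norm + 0.5)
  lm1 <- rowMeans(l[, g1, drop = FALSE])
  lm2 <- rowMeans(l[, g2, drop = FALSE])
  v1 <- rowSums((l[, g1, drop = FALSE] - lm1)^2) / (n1 - 1)
  v2 <- rowSums((l[, g2, drop = FALSE] - lm2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- lm2 - lm1
  tstat <- diff / se
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  p[se == 0 & diff == 0] <- 1
  p[se == 0 & diff != 0] <- 0
  out <- data.frame(gene_id = rownames(cnt),
                    mean_expr = rowMeans(norm),
                    log2fc = lfc, pvalue = p, qvalue = bh_adjust(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  validate_de_table(out)
}

#' Restrict a DE table to direct target genes
#'
#' A direct target is a gene that is the nearest gene of at least one
#' peak in the relevant peak universe. Each gene appears once regardless
#' of how many peaks it absorbs.
#'
#' @param de A DE `data.frame`.
#' @param assignments A [nearest_gene()] table.
#' @return The subset of `de` whose genes are targets.
#' @export
direct_targets <- function(de, assignments) {
  targets <- unique(assignments$gene_id[!is.na(assignments$gene_id)])
  de[de$gene_id %in% targets, , drop = FALSE]
}

#' Quadrant categorization of doubly regulated genes
#'
#' Genes significant (q <= fdr) in *both* single-knockdown contrasts are
#' assigned by the sign pair of their fold changes: (+,+) `both_up`,
#' (-,-) `both_down`, (+,-) `a_up_b_down`, (-,+) `a_down_b_up`. Genes
#' with a fold change of exactly 0, or significant in at most one
#' contrast, are uncategorized and absent from the result.
#'
#' @param de_a,de_b DE tables for the two single knockdowns.
#' @param config An [analysis_config()].
#' @return `data.frame` with `gene_id`, `lfc_a`, `lfc_b`, `category`.
#' @export
quadrant_categorize <- function(de_a, de_b, config = analysis_config()) {
  m <- merge(de_a[, c("gene_id", "log2fc", "qvalue")],
             de_b[, c("gene_id", "log2fc", "qvalue")],
             by = "gene_id", suffixes = c("_a", "_b"))
  sig <- !is.na(m$qvalue_a) & !is.na(m$qvalue_b) &
    !is.na(m$log2fc_a) & !is.na(m$log2fc_b) &
    m$qvalue_a <= config$fdr & m$qvalue_b <= config$fdr &
    m$log2fc_a != 0 & m$log2fc_b != 0
  m <- m[sig, , drop = FALSE]
  up_a <- m$log2fc_a > 0
  up_b <- m$log2fc_b > 0
  category <- ifelse(up_a & up_b, "both_up",
                     ifelse(!up_a & !up_b, "both_down",
                            ifelse(up_a, "a_up_b_down", "a_down_b_up")))
  out <- data.frame(gene_id = m$gene_id, lfc_a = m$log2fc_a,
                    lfc_b = m$log2fc_b, category = category,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Double-knockdown rescue analysis
#'
#' For each categorized gene, the rescue index
#' `1 - |lfc_double| / mean(|lfc_a|, |lfc_b|)` quantifies how far the
#' double knockdown returns expression toward baseline: 1 means full
#' rescue (`lfc_double = 0`), values near 0 mean no rescue, negative
#' values mean the double knockdown exaggerates the change. The index is
#' symmetric in the two subunits.
#'
#' @param de_a,de_b,de_double DE tables for the single and double
#'   knockdowns.
#' @param categories A [quadrant_categorize()] table.
#' @param config An [analysis_config()] (unused thresholds kept for a
#'   uniform signature).
#' @return List with `records` (per gene: `gene_id`, `category`,
#'   `lfc_a`, `lfc_b`, `lfc_double`, `rescue_index`) and `summary`
#'   (per category: `n`, `median_abs_single`, `median_abs_double`,
#'   `median_rescue_index`, and for concordant categories
#'   `median_exaggeration` = median of `|lfc_double| - mean single
#'   magnitude` and `same_sign_fraction` of the double versus the
#'   singles).
#' @export
rescue_analysis <- function(de_a, de_b, de_double, categories,
                            config = analysis_config()) {
  dd <- de_double[, c("gene_id", "log2fc")]
  names(dd)[2] <- "lfc_double"
  rec <- merge(categories, dd, by = "gene_id")
  n_drop <- nrow(categories) - nrow(rec)
  if (n_drop > 0)
    warning(n_drop, " categorized gene(s) missing from the double-knockdown table; dropped")
  mean_single <- (abs(rec$lfc_a) + abs(rec$lfc_b)) / 2
  rec$rescue_index <- 1 - abs(rec$lfc_double) / mean_single
  rec <- rec[order(rec$gene_id), , drop = FALSE]
  rownames(rec) <- NULL
  cats <- sort(unique(rec$category))
  summ <- do.call(rbind, lapply(cats, function(cc) {
    r <- rec[rec$category == cc, , drop = FALSE]
    ms <- (abs(r$lfc_a) + abs(r$lfc_b)) / 2
    concordant <- cc %in% c("both_up", "both_down")
    data.frame(category = cc, n = nrow(r),
               median_abs_single = median(ms),
               median_abs_double = median(abs(r$lfc_double)),
               median_rescue_index = median(r$rescue_index),
               median_exaggeration = if (concordant)
                 median(abs(r$lfc_double) - ms) else NA_real_,
               same_sign_fraction = if (concordant)
                 mean(sign(r$lfc_double) == sign(r$lfc_a)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(summ))
    summ <- data.frame(category = character(), n = integer(),
                       median_abs_single = numeric(),
                       median_abs_double = numeric(),
                       median_rescue_index = numeric(),
                       median_exaggeration = numeric(),
                       same_sign_fraction = numeric())
  rownames(summ) <- NULL
  list(records = rec, summary = summ)
}

#' Genes regulated only in the double knockdown (redundant class)
#'
#' Genes significant in the double-knockdown contrast but in neither
#' single knockdown; these mark redundancy between the two subunits.
#'
#' @param de_a,de_b,de_double DE tables.
#' @param config An [analysis_config()].
#' @return Character vector of gene ids.
#' @export
double_only_genes <- function(de_a, de_b, de_double,
                              config = analysis_config()) {
  sig <- function(de) de$gene_id[!is.na(de$qvalue) & de$qvalue <= config$fdr]
  setdiff(sig(de_double), union(sig(de_a), sig(de_b)))
}
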
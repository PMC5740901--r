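# End-to-end orchestration: read -> blacklist -> merge -> fates ->
# groups -> nearest gene -> DE integration -> categories -> rescue ->
# stats -> profiles, with a machine-readable report.

.stage_msg <- function(...) message(sprintf("[peakfates] %s", sprintf(...)))

#' Run the full occupancy/expression pipeline
#'
#' Executes every stage on either user-supplied files or a synthetic
#' dataset generated on the fly, writes all tables plus a JSON report to
#' `outdir`, and returns the report. Deterministic given the config.
#'
#' The config is a nested list (or a YAML file with the same structure):
#' \preformatted{
#' outdir: out/
#' analysis: {fdr: 0.05, merge_gap: 500,
#'            profile_window: 2000, profile_binsize: 10}
#' synthetic: {seed: 1, n_peaks: 2000, n_genes: 1000,
#'             de_mode: direct, tracks: true}   # or instead:
#' inputs:
#'   peaks: {a_shNS: ..., a_shA: ..., a_shB: ...,
#'           b_shNS: ..., b_shA: ..., b_shB: ...}
#'   blacklist: ...        # optional; stage skipped when absent
#'   segmentation: ...     # optional
#'   tss: ...
#'   de: {shA: ..., shB: ..., double: ...}
#'   tracks: {a_shNS: ..., ..., cofactor: ...}  # optional
#' }
#'
#' @param config A list as above, or the path to a YAML file.
#' @param outdir Output directory; overrides `config$outdir`.
#' @return The run report (list of class `run_report`), invisibly
#'   written to `report.json`.
#' @export
run_full <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("config must name an outdir")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  acfg <- do.call(analysis_config, c(config$analysis))
  report <- list(config = config, seed = acfg$seed,
                 version = as.character(packageVersion("peakfates")),
                 stages = list())

  truth <- NULL
  if (!is.null(config$synthetic)) {
    .stage_msg("stage simulate: generating synthetic data")
    syn <- config$synthetic
    de_mode <- if (is.null(syn$de_mode)) "direct" else syn$de_mode
    emit_tracks <- !identical(syn$tracks, FALSE)
    gcfg <- do.call(generator_config,
                    syn[setdiff(names(syn), c("de_mode", "tracks"))])
    truth <- generate_truth(gcfg)
    manifest <- emit_datasets(truth, file.path(outdir, "data"),
                              de_mode = de_mode, tracks = emit_tracks)
    inputs <- list(
      peaks = list(a_shNS = manifest$peaks_a_shNS,
                   a_shA = manifest$peaks_a_shA,
                   a_shB = manifest$peaks_a_shB,
                   b_shNS = manifest$peaks_b_shNS,
                   b_shA = manifest$peaks_b_shA,
                   b_shB = manifest$peaks_b_shB),
      blacklist = manifest$blacklist,
      segmentation = manifest$segmentation,
      tss = manifest$tss,
      de = list(shA = manifest$de_shA, shB = manifest$de_shB,
                double = manifest$de_double))
    if (emit_tracks)
      inputs$tracks <- list(a_shNS = manifest$coverage_a_shNS,
                            b_shNS = manifest$coverage_b_shNS,
                            cofactor = manifest$cofactor)
    report$manifest <- manifest
  } else {
    inputs <- config$inputs
    if (is.null(inputs)) stop("config needs either 'synthetic' or 'inputs'")
  }

  # -- peaks: read, blacklist, merge -----------------------------------
  .stage_msg("stage peaks: read, blacklist filter, recursive merge")
  raw <- lapply(inputs$peaks, read_peaks)
  report$stages$peaks_in <- lapply(raw, length)
  if (!is.null(inputs$blacklist)) {
    blacklist <- read_peaks(inputs$blacklist, format = "bed")
    raw <- lapply(raw, filter_blacklist, blacklist = blacklist)
    report$stages$blacklist <- list(n_regions = length(blacklist),
                                    peaks_surviving = lapply(raw, length))
  } else {
    report$stages$blacklist <- "skipped"
  }
  peaks <- lapply(raw, recursive_merge, merge_gap = acfg$merge_gap)
  report$stages$peaks_merged <- lapply(peaks, length)
  for (nm in names(peaks))
    write_peaks(peaks[[nm]], file.path(outdir, sprintf("peaks_%s_merged.bed", nm)))

  # -- fates and groups ------------------------------------------------
  .stage_msg("stage fates: lost vs retained/gained; sibling groups")
  fate_a <- classify_fate(peaks$a_shNS, peaks$a_shA,
                          subunit = "A", kd_condition = "shA")
  fate_b <- classify_fate(peaks$b_shNS, peaks$b_shB,
                          subunit = "B", kd_condition = "shB")
  groups_a <- cross_classify(regions_of(fate_a[fate_a$fate == "lost", ]),
                             peaks$b_shNS, peaks$b_shA, subunit = "A")
  groups_b <- cross_classify(regions_of(fate_b[fate_b$fate == "lost", ]),
                             peaks$a_shNS, peaks$a_shB, subunit = "B")
  report$stages$fates <- list(a = summary(fate_a), b = summary(fate_b))
  report$stages$groups <- list(a = as.list(table(groups_a$status)),
                               b = as.list(table(groups_b$status)))
  for (nm in c("fate_a", "fate_b", "groups_a", "groups_b"))
    write.table(get(nm), file.path(outdir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

  # -- chromatin states (optional) -------------------------------------
  if (!is.null(inputs$segmentation)) {
    seg <- read_peaks(inputs$segmentation, format = "bed")
    report$stages$chromatin_states <-
      list(a = annotate_chromatin_state(peaks$a_shNS, seg),
           b = annotate_chromatin_state(peaks$b_shNS, seg))
  }

  # -- nearest genes ---------------------------------------------------
  .stage_msg("stage targets: nearest-gene assignment")
  tss <- load_tss(inputs$tss)
  union_control <- recursive_merge(
    peak_set(c(as.character(GenomeInfoDb::seqnames(peaks$a_shNS)),
               as.character(GenomeInfoDb::seqnames(peaks$b_shNS))),
             c(bed_start(peaks$a_shNS), bed_start(peaks$b_shNS)),
             c(bed_end(peaks$a_shNS), bed_end(peaks$b_shNS))),
    merge_gap = acfg$merge_gap)
  assignments <- nearest_gene(union_control, tss)
  write.table(assignments, file.path(outdir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$stages$targets <- list(n_peaks = nrow(assignments),
                                n_target_genes =
                                  length(unique(assignments$gene_id)))

  # -- DE integration --------------------------------------------------
  .stage_msg("stage expression: categories, redundant class, rescue")
  de <- lapply(inputs$de, read_de_table)
  de_t <- lapply(de, direct_targets, assignments = assignments)
  categories <- quadrant_categorize(de_t$shA, de_t$shB, acfg)
  rescue <- rescue_analysis(de_t$shA, de_t$shB, de_t$double, categories, acfg)
  redundant <- double_only_genes(de_t$shA, de_t$shB, de_t$double, acfg)
  sig_a <- de_t$shA$gene_id[!is.na(de_t$shA$qvalue) & de_t$shA$qvalue <= acfg$fdr]
  sig_b <- de_t$shB$gene_id[!is.na(de_t$shB$qvalue) & de_t$shB$qvalue <= acfg$fdr]
  either <- union(sig_a, sig_b)
  both <- intersect(sig_a, sig_b)
  affected <- union(either, redundant)
  report$stages$expression <- list(
    category_counts = as.list(table(categories$category)),
    n_categorized = nrow(categories),
    n_single_either = length(either),
    n_single_both = length(both),
    n_double_only = length(redundant),
    n_affected_total = length(affected),
    n_genes_measured = length(unique(de$shA$gene_id)),
    rescue_summary = rescue$summary)
  write.table(categories, file.path(outdir, "categories.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rescue$records, file.path(outdir, "rescue.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # -- statistical layer ----------------------------------------------
  .stage_msg("stage stats: group-level tests")
  group_regions <- rbind(groups_a[, c("chrom", "start", "end", "group")],
                         groups_b[, c("chrom", "start", "end", "group")])
  group_regions <- group_regions[!is.na(group_regions$group), , drop = FALSE]
  group_genes <- lapply(split(group_regions, group_regions$group),
                        function(df) {
                          a <- nearest_gene(regions_of(df), tss)
                          unique(a$gene_id[!is.na(a$gene_id)])
                        })
  wilcox <- lapply(group_genes, function(genes) {
    lapply(list(shA = de$shA, shB = de$shB), function(d) {
      l <- d$log2fc[d$gene_id %in% genes & d$testable]
      w <- wilcoxon_no_change(l)
      list(n = w$n, statistic = w$statistic, pvalue = w$pvalue,
           median_lfc = if (w$n > 0) median(l[l != 0]) else NA_real_)
    })
  })
  assoc_genes <- unique(unlist(group_genes))
  measured <- unique(de$shA$gene_id)
  changed <- union(sig_a, sig_b)
  chisq <- lapply(group_genes, function(genes) {
    inn <- intersect(genes, measured)
    out <- setdiff(setdiff(measured, assoc_genes), genes)
    ct <- chi_square_membership(length(intersect(inn, changed)),
                                length(setdiff(inn, changed)),
                                length(intersect(out, changed)),
                                length(setdiff(out, changed)))
    list(statistic = ct$statistic, pvalue = ct$pvalue,
         fraction_in = ct$fraction_in, fraction_out = ct$fraction_out)
  })
  report$stages$tests <- list(wilcoxon = wilcox, chi_square = chisq)

  # -- profiles --------------------------------------------------------
  if (!is.null(inputs$tracks)) {
    .stage_msg("stage profiles: TSS and midpoint metaprofiles")
    tr <- inputs$tracks
    if (!is.null(tr$a_shNS)) {
      track_a <- read_bedgraph(tr$a_shNS)
      expr <- setNames(de$shA$mean_expr, de$shA$gene_id)
      tert <- tss_profiles_by_expression(track_a, tss, expr,
                                         acfg$profile_window,
                                         acfg$profile_binsize)
      for (nm in names(tert))
        write_profile(tert[[nm]], file.path(outdir,
                                            sprintf("profile_tss_%s.tsv", nm)))
      report$stages$profiles$tss_by_expression <-
        lapply(tert, function(p) list(n = p$n_anchors,
                                      peak_mean = max(p$mean)))
    }
    if (!is.null(tr$cofactor)) {
      cof <- read_bedgraph(tr$cofactor)
      g3 <- groups_b[groups_b$status == "sibling_lost", , drop = FALSE]
      g4 <- groups_b[groups_b$status == "sibling_retained_gained", , drop = FALSE]
      if (nrow(g3) > 0 && nrow(g4) > 0) {
        cmp <- compare_groups_signal(cof,
                                     g3$chrom, midpoint(regions_of(g3)),
                                     g4$chrom, midpoint(regions_of(g4)),
                                     acfg$profile_window, acfg$profile_binsize)
        write_profile(cmp$profile_x, file.path(outdir, "profile_cofactor_sibling_lost.tsv"))
        write_profile(cmp$profile_y, file.path(outdir, "profile_cofactor_sibling_retained.tsv"))
        report$stages$profiles$cofactor_central_ratio <- cmp$central_ratio
      }
    }
  }

  # -- recovery scoring (synthetic runs) -------------------------------
  if (!is.null(truth)) {
    .stage_msg("stage recovery: scoring against planted truth")
    rec <- score_recovery(truth, list(fate_a = fate_a, fate_b = fate_b,
                                      groups_a = groups_a,
                                      groups_b = groups_b,
                                      categories = categories,
                                      rescue = rescue$records))
    report$recovery <- rec[!vapply(rec, is.table, logical(1))]
  }

  class(report) <- "run_report"
  jsonlite::write_json(.report_jsonable(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

# Strip non-serializable bits for the JSON report.
.report_jsonable <- function(report) {
  r <- unclass(report)
  r$manifest <- NULL
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat("peakfates run report (version ", x$version, ")\n", sep = "")
  f <- x$stages$fates
  if (!is.null(f))
    cat(sprintf("  fates: A lost %d/%d (%.2f), B lost %d/%d (%.2f)\n",
                f$a$n_lost, f$a$n, f$a$lost_fraction,
                f$b$n_lost, f$b$n, f$b$lost_fraction))
  e <- x$stages$expression
  if (!is.null(e)) {
    cat("  categories:",
        paste(sprintf("%s=%d", names(e$category_counts),
                      unlist(e$category_counts)), collapse = ", "), "\n")
    cat(sprintf("  regulated in both singles: %d; double-only: %d; affected total: %d of %d measured\n",
                e$n_single_both, e$n_double_only, e$n_affected_total,
                e$n_genes_measured))
  }
  if (!is.null(x$recovery)) {
    v <- unlist(x$recovery)
    cat("  recovery:",
        paste(sprintf("%s=%.3f", names(v), v), collapse = ", "), "\n")
  }
  invisible(x)
}
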
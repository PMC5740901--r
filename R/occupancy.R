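# Peak-fate classification between control and knockdown, Groups 1-4
# cross-classification against the sibling subunit, and per-region signal
# quantification.

#' Classify control-peak fates after knockdown
#'
#' Every control-condition peak is `"lost"` if it overlaps no peak of the
#' same subunit in the knockdown, `"retained_gained"` otherwise
#' (any-overlap, >= 1 shared base). Gained and retained are deliberately
#' not distinguished: a peak call appearing only after knockdown cannot be
#' told apart from a quantitative change crossing the calling threshold.
#'
#' @param control_peaks,kd_peaks Post-blacklist, post-merge `GRanges` peak
#'   sets of the same subunit in control and knockdown.
#' @param subunit,kd_condition Optional labels carried into the output.
#' @return `data.frame` of class `fate_table` with columns `peak_id`,
#'   `chrom`, `start`, `end`, `subunit`, `kd_condition`, `fate`.
#' @export
classify_fate <- function(control_peaks, kd_peaks, subunit = NA_character_,
                          kd_condition = NA_character_) {
  ov <- overlaps_any(control_peaks, kd_peaks)
  ids <- S4Vectors::mcols(control_peaks)$name
  if (is.null(ids)) ids <- sprintf("peak_%d", seq_along(control_peaks))
  out <- data.frame(peak_id = ids,
                    chrom = as.character(GenomeInfoDb::seqnames(control_peaks)),
                    start = bed_start(control_peaks),
                    end = bed_end(control_peaks),
                    subunit = subunit, kd_condition = kd_condition,
                    fate = ifelse(ov, "retained_gained", "lost"),
                    stringsAsFactors = FALSE)
  class(out) <- c("fate_table", "data.frame")
  out
}

#' Summarize a fate table
#'
#' @param object A [classify_fate()] result.
#' @param ... Unused.
#' @return Named list with `n`, `n_lost`, `n_retained_gained`,
#'   `lost_fraction`.
#' @method summary fate_table
#' @export
summary.fate_table <- function(object, ...) {
  n <- nrow(object)
  n_lost <- sum(object$fate == "lost")
  list(n = n, n_lost = n_lost, n_retained_gained = n - n_lost,
       lost_fraction = if (n > 0) n_lost / n else NA_real_)
}

#' Rebuild a `GRanges` from a fate/group table (or any table with
#' `chrom`/`start`/`end` BED columns).
#'
#' @param df A `data.frame` with `chrom`, `start`, `end` and optionally
#'   `peak_id` columns.
#' @return A `GRanges`.
#' @export
regions_of <- function(df) {
  peak_set(df$chrom, df$start, df$end,
           name = if ("peak_id" %in% names(df)) df$peak_id else NULL)
}

#' Cross-classify lost regions by the sibling subunit's fate
#'
#' For each region that lost a subunit-A peak in the A knockdown, the
#' sibling subunit B is examined in the *same* knockdown: if a B peak
#' overlaps the region in the A knockdown (whether or not present in
#' control) the sibling is retained/gained; otherwise, if a B peak
#' overlapped in control, the sibling is lost; regions where the sibling
#' never had a peak are reported as `"sibling_absent"` and excluded from
#' the numbered groups (absence is not loss). Numbering follows the
#' convention Group 1/2 for lost A regions (sibling lost / retained) and
#' Group 3/4 for lost B regions.
#'
#' @param lost_regions `GRanges` of regions that lost subunit A's peak in
#'   the A knockdown (e.g. the lost subset of a [classify_fate()] table
#'   via [regions_of()]).
#' @param sibling_control Sibling subunit's peaks in the control.
#' @param sibling_in_kd Sibling subunit's peaks in the same knockdown.
#' @param subunit `"A"` (groups 1/2) or `"B"` (groups 3/4): which subunit
#'   the lost regions belong to.
#' @return `data.frame` of class `group_table` with columns `peak_id`,
#'   `chrom`, `start`, `end`, `sibling_in_control`, `sibling_in_kd`,
#'   `status`, `group` (`NA` for sibling-absent regions).
#' @export
cross_classify <- function(lost_regions, sibling_control, sibling_in_kd,
                           subunit = c("A", "B")) {
  subunit <- match.arg(subunit)
  in_ns <- overlaps_any(lost_regions, sibling_control)
  in_kd <- overlaps_any(lost_regions, sibling_in_kd)
  status <- ifelse(in_kd, "sibling_retained_gained",
                   ifelse(in_ns, "sibling_lost", "sibling_absent"))
  base <- if (subunit == "A") 0L else 2L
  group <- ifelse(status == "sibling_lost", base + 1L,
                  ifelse(status == "sibling_retained_gained", base + 2L,
                         NA_integer_))
  ids <- S4Vectors::mcols(lost_regions)$name
  if (is.null(ids)) ids <- sprintf("region_%d", seq_along(lost_regions))
  out <- data.frame(peak_id = ids,
                    chrom = as.character(GenomeInfoDb::seqnames(lost_regions)),
                    start = bed_start(lost_regions),
                    end = bed_end(lost_regions),
                    sibling_in_control = in_ns, sibling_in_kd = in_kd,
                    status = status, group = as.integer(group),
                    stringsAsFactors = FALSE)
  class(out) <- c("group_table", "data.frame")
  out
}

#' Mean coverage per region for a set of tracks
#'
#' Computes the mean per-base signal of each coverage track over each
#' region (uncovered bases count as 0), plus the Pearson correlation
#' matrix between tracks over the region set.
#'
#' @param regions A `GRanges` region set (e.g. the union of two subunits'
#'   control peaks).
#' @param tracks Named list of coverage tracks (see [coverage_track()]).
#' @return List of class `signal_matrix` with elements `signal` (regions
#'   by tracks `data.frame` of means) and `correlation` (Pearson matrix,
#'   `NULL` for a single track).
#' @export
quantify_signal <- function(regions, tracks) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    names(tracks) <- sprintf("track_%d", seq_along(tracks))
  mat <- vapply(tracks, function(tr) region_means(tr, regions),
                numeric(length(regions)))
  mat <- matrix(mat, nrow = length(regions),
                dimnames = list(NULL, names(tracks)))
  ids <- S4Vectors::mcols(regions)$name
  if (is.null(ids)) ids <- sprintf("region_%d", seq_along(regions))
  sig <- data.frame(region_id = ids, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  corr <- if (length(tracks) >= 2) stats::cor(mat) else NULL
  structure(list(signal = sig, correlation = corr),
            class = "signal_matrix")
}
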
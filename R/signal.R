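# Coverage tracks (piecewise-constant signal over half-open intervals)
# and binned metaprofiles anchored at peak midpoints or TSS.

#' Construct a coverage track
#'
#' A piecewise-constant, nonnegative signal over 0-based half-open
#' intervals. Intervals must not overlap; uncovered bases read as 0.
#'
#' @param chrom,start,end Interval coordinates (BED convention).
#' @param value Nonnegative signal values.
#' @param label Optional track label.
#' @return A sorted `GRanges` with a `score` column.
#' @export
coverage_track <- function(chrom, start, end, value, label = NULL) {
  value <- as.numeric(value)
  if (length(value) != length(start))
    stop("value must have one entry per interval")
  if (length(value) > 0 && any(value < 0))
    stop("coverage values must be >= 0")
  gr <- peak_set(chrom, start, end, score = value, label = label)
  if (!IRanges::isDisjoint(gr))
    stop("coverage intervals overlap")
  gr
}

#' Read a bedGraph coverage track
#'
#' Four tab-separated columns (chrom, start, end, value); intervals must
#' be sorted and non-overlapping within each chromosome. Violations are
#' reported with their line numbers.
#'
#' @param path Path to the bedGraph file.
#' @param label Optional track label.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(coverage_track(character(), numeric(), numeric(), numeric(),
                          label = label))
  fields <- .split_fields(lines, 4L, path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- .num_field(fields, 2L, path, "start")
  end <- .num_field(fields, 3L, path, "end")
  value <- .num_field(fields, 4L, path, "value")
  bad <- which(end <= start)
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: end <= start", path, lineno[bad[1]]))
  for (c in unique(chrom)) {
    i <- which(chrom == c)
    if (is.unsorted(start[i]))
      stop(sprintf("%s: intervals on %s are not sorted (line %d)",
                   path, c, lineno[i[which(diff(start[i]) < 0)[1] + 1]]))
    ov <- which(start[i][-1] < end[i][-length(i)])
    if (length(ov) > 0)
      stop(sprintf("%s: overlapping intervals on %s (lines %d and %d)",
                   path, c, lineno[i[ov[1]]], lineno[i[ov[1] + 1]]))
  }
  coverage_track(chrom, start, end, value, label = label)
}

#' Write a coverage track as bedGraph
#'
#' @param track A [coverage_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(as.character(GenomeInfoDb::seqnames(track)),
                   bed_start(track), bed_end(track),
                   S4Vectors::mcols(track)$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Run-length encoding of a track: RleList of per-base values per
# chromosome (0 where uncovered).
coverage_rle <- function(track) {
  GenomicRanges::coverage(track, weight = S4Vectors::mcols(track)$score)
}

#' Mean per-base coverage over regions
#'
#' @param track A [coverage_track()].
#' @param regions A `GRanges` region set.
#' @return Numeric vector of per-region means (uncovered bases read 0).
#' @export
region_means <- function(track, regions) {
  cov <- coverage_rle(track)
  out <- numeric(length(regions))
  chr <- as.character(GenomeInfoDb::seqnames(regions))
  for (c in unique(chr)) {
    sel <- which(chr == c)
    if (!(c %in% names(cov))) next
    r <- cov[[c]]
    L <- length(r)
    s <- GenomicRanges::start(regions)[sel]
    e <- GenomicRanges::end(regions)[sel]
    cs <- pmax(s, 1L)
    ce <- pmin(e, L)
    ok <- cs <= ce
    sums <- numeric(length(sel))
    if (any(ok)) {
      v <- IRanges::Views(r, cs[ok], ce[ok])
      sums[ok] <- IRanges::viewSums(v)
    }
    out[sel] <- sums / (e - s + 1)
  }
  out
}

# Per-anchor x per-bin matrix of bin means around 0-based anchor points.
# Windows reaching past the track extent are zero-padded.
.profile_matrix <- function(track, chrom, pos, window, binsize) {
  if (length(pos) == 0) stop("empty anchor list")
  if (window %% binsize != 0)
    stop("window must be divisible by binsize")
  nb <- as.integer(2 * window / binsize)
  cov <- coverage_rle(track)
  M <- matrix(0, nrow = length(pos), ncol = nb)
  n_edge <- 0L
  for (c in unique(chrom)) {
    sel <- which(chrom == c)
    r <- if (c %in% names(cov)) cov[[c]] else S4Vectors::Rle(numeric(0))
    L <- length(r)
    for (k in sel) {
      s <- pos[k] - window + 1   # 1-based window [s, e]
      e <- pos[k] + window
      v <- numeric(2 * window)
      cs <- max(s, 1L)
      ce <- min(e, L)
      if (cs <= ce)
        v[(cs - s + 1):(ce - s + 1)] <- as.numeric(S4Vectors::window(r, cs, ce))
      if (s < 1 || e > L) n_edge <- n_edge + 1L
      M[k, ] <- colMeans(matrix(v, nrow = binsize))
    }
  }
  attr(M, "n_edge") <- n_edge
  M
}

.profile_from_matrix <- function(M, window, binsize, anchor = "points") {
  structure(list(anchor = anchor,
                 offset = seq(-window + binsize / 2, window - binsize / 2,
                              by = binsize),
                 mean = colMeans(M),
                 n_anchors = nrow(M),
                 window = window, binsize = binsize,
                 n_edge = attr(M, "n_edge")),
            class = "signal_profile")
}

#' Binned signal profile around anchor points
#'
#' For each anchor the mean per-base signal in each bin of
#' `[pos - window, pos + window)` is computed, then averaged across
#' anchors. Anchors nearer than `window` to a contig edge are zero-padded
#' (their count is reported as `n_edge`).
#'
#' @param track A [coverage_track()].
#' @param chrom,pos Anchor chromosomes and 0-based positions (midpoints,
#'   TSS, ...).
#' @param window Half-window in bp (default 2000).
#' @param binsize Bin size in bp (default 10); must divide `window`.
#' @param keep_matrix Keep the per-anchor matrix in the result?
#' @return A `signal_profile`: list with `offset` (bin centers relative
#'   to the anchor), `mean`, `n_anchors`, `window`, `binsize`, `n_edge`,
#'   and optionally `matrix`.
#' @export
profile_at_points <- function(track, chrom, pos, window = 2000,
                              binsize = 10, keep_matrix = FALSE) {
  M <- .profile_matrix(track, as.character(chrom), as.numeric(pos),
                       window, binsize)
  p <- .profile_from_matrix(M, window, binsize)
  if (keep_matrix) {
    attr(M, "n_edge") <- NULL
    p$matrix <- M
  }
  p
}

#' @export
print.signal_profile <- function(x, ...) {
  cat(sprintf("signal_profile: %d anchors, +/-%d bp in %d-bp bins (%d at an edge)\n",
              x$n_anchors, x$window, x$binsize, x$n_edge))
  cat(sprintf("  mean signal: min %.4g, max %.4g\n",
              min(x$mean), max(x$mean)))
  invisible(x)
}

#' TSS metaprofiles stratified by expression tertile
#'
#' Genes are ranked by mean expression (ties broken by gene id) and split
#' into low/medium/high tertiles by rank. One profile per tertile is
#' computed at the TSS, strand-oriented: the bin vector of a minus-strand
#' gene is reversed before averaging.
#'
#' @param track A [coverage_track()].
#' @param tss A [tss_set()].
#' @param expression Named numeric vector of mean expression, names are
#'   gene ids; at least 3 genes present in `tss` required.
#' @param window,binsize See [profile_at_points()].
#' @return Named list `low`/`medium`/`high` of `signal_profile`s.
#' @export
tss_profiles_by_expression <- function(track, tss, expression,
                                       window = 2000, binsize = 10) {
  genes <- intersect(tss$gene_id, names(expression))
  if (length(genes) < 3)
    stop("expression values available for fewer than 3 annotated genes")
  t <- tss[match(genes, tss$gene_id), , drop = FALSE]
  ord <- order(expression[genes], genes)
  n <- length(genes)
  cuts <- floor(seq(0, n, length.out = 4))
  tiers <- list(low = ord[seq_len(cuts[2])],
                medium = ord[(cuts[2] + 1):cuts[3]],
                high = ord[(cuts[3] + 1):cuts[4]])
  lapply(tiers, function(idx) {
    M <- .profile_matrix(track, t$chrom[idx], t$pos[idx], window, binsize)
    neg <- t$strand[idx] == "-"
    if (any(neg)) M[neg, ] <- M[neg, ncol(M):1, drop = FALSE]
    .profile_from_matrix(M, window, binsize, anchor = "TSS")
  })
}

#' Compare signal between two anchor groups
#'
#' Profiles both groups on an identical grid and reports the per-bin
#' difference plus the ratio of mean signal in the central region
#' (default +/-500 bp), e.g. cofactor occupancy at regions losing both
#' sibling subunits versus regions retaining one.
#'
#' @param track A [coverage_track()].
#' @param chrom_x,pos_x Anchors of group X.
#' @param chrom_y,pos_y Anchors of group Y.
#' @param window,binsize See [profile_at_points()].
#' @param center Half-width in bp of the central band for the ratio.
#' @return List with `profile_x`, `profile_y`, `difference` (X - Y per
#'   bin) and `central_ratio` (mean X / mean Y over the central band).
#' @export
compare_groups_signal <- function(track, chrom_x, pos_x, chrom_y, pos_y,
                                  window = 2000, binsize = 10,
                                  center = 500) {
  px <- profile_at_points(track, chrom_x, pos_x, window, binsize)
  py <- profile_at_points(track, chrom_y, pos_y, window, binsize)
  cb <- abs(px$offset) <= center
  denom <- mean(py$mean[cb])
  ratio <- if (denom > 0) mean(px$mean[cb]) / denom else NA_real_
  list(profile_x = px, profile_y = py,
       difference = px$mean - py$mean,
       central_ratio = ratio)
}

#' Write a profile as TSV
#'
#' @param profile A `signal_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(bin_center_offset = profile$offset,
                   mean_signal = profile$mean,
                   n = profile$n_anchors)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
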
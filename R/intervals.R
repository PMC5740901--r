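# Genomic interval model: peak sets as GRanges, BED/narrowPeak readers and
# writers, blacklist filtering, recursive merging and overlap queries.
#
# Coordinates at the package boundary are BED-style (0-based, half-open);
# GRanges internals are 1-based closed. `peak_set()` / `bed_start()` /
# `bed_end()` do the conversion so no other code thinks about it.

#' Construct a peak set
#'
#' Builds a sorted [GenomicRanges::GRanges] from BED-style (0-based,
#' half-open) coordinates. Chromosomes are ordered lexicographically and
#' intervals by start position, so any constructor output is deterministic.
#'
#' @param chrom Chromosome names (character).
#' @param start,end 0-based half-open interval bounds; `start < end`,
#'   `start >= 0`.
#' @param name Optional per-interval identifiers.
#' @param score Optional numeric scores.
#' @param summit Optional summit offsets (narrowPeak column 10).
#' @param signal,pvalue,qvalue Optional narrowPeak enrichment columns.
#' @param label Condition/antibody tag stored in `metadata()`.
#' @param provenance Source file path stored in `metadata()`.
#' @return A sorted `GRanges`.
#' @examples
#' peak_set(c("chr1", "chr1"), c(0, 600), c(100, 700))
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NULL,
                     summit = NULL, signal = NULL, pvalue = NULL,
                     qvalue = NULL, label = NULL,
                     provenance = NA_character_) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start and end must have equal length")
  if (length(start) > 0) {
    if (any(is.na(chrom) | is.na(start) | is.na(end)))
      stop("missing values in interval coordinates")
    if (any(start < 0)) stop("interval start must be >= 0")
    if (any(end <= start)) stop("interval end must be greater than start")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- as.character(name)
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- as.numeric(score)
  if (!is.null(signal)) S4Vectors::mcols(gr)$signal <- as.numeric(signal)
  if (!is.null(pvalue)) S4Vectors::mcols(gr)$pvalue <- as.numeric(pvalue)
  if (!is.null(qvalue)) S4Vectors::mcols(gr)$qvalue <- as.numeric(qvalue)
  if (!is.null(summit)) S4Vectors::mcols(gr)$summit <- as.integer(summit)
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$label <- label
  S4Vectors::metadata(gr)$provenance <- provenance
  gr
}

#' BED-style coordinates of a peak set
#'
#' @param x A `GRanges`.
#' @return Integer vector of 0-based starts / half-open ends.
#' @export
bed_start <- function(x) GenomicRanges::start(x) - 1L

#' @rdname bed_start
#' @export
bed_end <- function(x) GenomicRanges::end(x)

# Split tab-separated lines, enforcing a minimum field count with the
# offending line number in the error.
.split_fields <- function(lines, min_fields, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < min_fields)
  if (length(bad) > 0)
    stop(sprintf("%s: line %d has %d field(s); at least %d required",
                 path, bad[1], nf[bad[1]], min_fields))
  fields
}

.num_field <- function(fields, k, path, what) {
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", k)))
  bad <- which(is.na(v))
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: %s is not numeric", path, bad[1], what))
  v
}

#' Read peak calls from BED or narrowPeak
#'
#' Reads a tab-separated peak file with no header. With `format = "auto"`
#' a file whose lines all have exactly 10 fields is treated as ENCODE
#' narrowPeak (name, score, strand, signalValue, pValue, qValue, summit
#' preserved); otherwise as BED3+ (name and score kept when present).
#'
#' @param path Path to the peak file.
#' @param format `"auto"`, `"narrowPeak"` or `"bed"`.
#' @param label Optional condition/antibody tag stored with the set.
#' @return A sorted `GRanges` (see [peak_set()]).
#' @export
read_peaks <- function(path, format = c("auto", "narrowPeak", "bed"),
                       label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0)
    return(peak_set(character(), numeric(), numeric(), label = label,
                    provenance = path))
  fields <- .split_fields(lines, 3L, path)
  nf <- lengths(fields)
  if (format == "auto")
    format <- if (all(nf == 10L)) "narrowPeak" else "bed"
  if (format == "narrowPeak" && any(nf < 10L))
    stop(sprintf("%s: line %d has %d fields; narrowPeak requires 10",
                 path, which(nf < 10L)[1], nf[which(nf < 10L)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- .num_field(fields, 2L, path, "start")
  end <- .num_field(fields, 3L, path, "end")
  bad <- which(end <= start)
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: end (%g) <= start (%g)",
                 path, bad[1], end[bad[1]], start[bad[1]]))
  name <- if (all(nf >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  score <- if (all(nf >= 5L)) .num_field(fields, 5L, path, "score") else NULL
  if (format == "narrowPeak") {
    peak_set(chrom, start, end, name = name, score = score,
             signal = .num_field(fields, 7L, path, "signalValue"),
             pvalue = .num_field(fields, 8L, path, "pValue"),
             qvalue = .num_field(fields, 9L, path, "qValue"),
             summit = .num_field(fields, 10L, path, "summit"),
             label = label, provenance = path)
  } else {
    peak_set(chrom, start, end, name = name, score = score,
             label = label, provenance = path)
  }
}

#' Write a peak set to BED or narrowPeak
#'
#' @param x A `GRanges` peak set.
#' @param path Output path.
#' @param format `"auto"` writes narrowPeak when a `summit` column is
#'   present, BED otherwise.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path, format = c("auto", "narrowPeak", "bed")) {
  format <- match.arg(format)
  mc <- S4Vectors::mcols(x)
  if (format == "auto")
    format <- if ("summit" %in% names(mc)) "narrowPeak" else "bed"
  n <- length(x)
  get_or <- function(col, default) {
    if (col %in% names(mc)) mc[[col]] else rep(default, n)
  }
  name <- get_or("name", NA_character_)
  if (anyNA(name)) name <- ifelse(is.na(name), sprintf("peak_%d", seq_len(n)), name)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(x)),
                   start = bed_start(x), end = bed_end(x),
                   stringsAsFactors = FALSE)
  if (format == "narrowPeak") {
    df$name <- name
    df$score <- get_or("score", 0)
    df$strand <- "."
    df$signal <- get_or("signal", 0)
    df$pvalue <- get_or("pvalue", -1)
    df$qvalue <- get_or("qvalue", -1)
    df$summit <- get_or("summit", as.integer(floor((bed_end(x) - bed_start(x)) / 2)))
  } else if ("name" %in% names(mc) || "score" %in% names(mc)) {
    df$name <- name
    df$score <- get_or("score", 0)
    df$strand <- "."
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove peaks overlapping a blacklist
#'
#' Drops every peak sharing at least one base with any blacklist region
#' (standard any-overlap blacklist practice; no reciprocal-fraction rule).
#' An empty blacklist is the identity. Order of survivors is preserved.
#'
#' @param peaks,blacklist `GRanges` peak sets.
#' @return The surviving peaks.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (length(blacklist) == 0) return(peaks)
  peaks[!IRanges::overlapsAny(peaks, blacklist, ignore.strand = TRUE)]
}

#' Recursively merge nearby peaks
#'
#' Replaces any two same-chromosome intervals whose gap
#' (`next.start - prev.end`, BED coordinates) is `<= merge_gap` by their
#' span, repeated to the fixpoint (the transitive closure). Touching or
#' overlapping intervals always merge. Idempotent.
#'
#' @param peaks A `GRanges` peak set.
#' @param merge_gap Maximum gap in bp to close (default 500).
#' @return Merged `GRanges`; merged regions are named `region_<i>`.
#' @export
recursive_merge <- function(peaks, merge_gap = 500) {
  if (merge_gap < 0) stop("merge_gap must be >= 0")
  out <- GenomicRanges::reduce(peaks, min.gapwidth = merge_gap + 1,
                               ignore.strand = TRUE)
  if (length(out) > 0)
    S4Vectors::mcols(out)$name <- sprintf("region_%d", seq_along(out))
  S4Vectors::metadata(out) <- S4Vectors::metadata(peaks)
  out
}

#' Flag query intervals overlapping any subject interval
#'
#' One logical per query interval: `TRUE` iff it shares at least one base
#' with some subject interval (half-open convention, so abutting intervals
#' do not overlap).
#'
#' @param query,subject `GRanges` peak sets.
#' @return Logical vector along `query`.
#' @export
overlaps_any <- function(query, subject) {
  IRanges::overlapsAny(query, subject, ignore.strand = TRUE)
}

#' Interval midpoints
#'
#' `floor((start + end) / 2)` in BED (0-based) coordinates.
#'
#' @param x A `GRanges`.
#' @return Integer vector of 0-based midpoint positions.
#' @export
midpoint <- function(x) {
  as.integer(floor((bed_start(x) + bed_end(x)) / 2))
}

#' Annotate peaks with chromatin states
#'
#' Assigns each peak the segmentation state containing its midpoint.
#' Peaks whose midpoint falls outside the segmentation are counted in an
#' `"unannotated"` class; state fractions are computed over annotated
#' peaks and sum to 1.
#'
#' @param peaks A `GRanges` peak set.
#' @param segmentation A `GRanges` with a `name` metadata column holding
#'   state labels; intervals must be non-overlapping.
#' @return `data.frame` with columns `state`, `n`, `fraction`
#'   (`fraction` is `NA` for the `"unannotated"` row).
#' @export
annotate_chromatin_state <- function(peaks, segmentation) {
  states <- S4Vectors::mcols(segmentation)$name
  if (is.null(states))
    stop("segmentation must carry state labels in a 'name' column")
  if (!IRanges::isDisjoint(segmentation))
    stop("segmentation intervals overlap; states must be disjoint")
  if (length(peaks) == 0)
    return(data.frame(state = character(), n = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  mid <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                                IRanges::IRanges(midpoint(peaks) + 1, width = 1))
  hit <- GenomicRanges::findOverlaps(mid, segmentation, select = "first",
                                     ignore.strand = TRUE)
  assigned <- ifelse(is.na(hit), NA_character_, states[hit])
  n_un <- sum(is.na(assigned))
  tab <- table(assigned[!is.na(assigned)])
  out <- data.frame(state = names(tab), n = as.integer(tab),
                    fraction = as.numeric(tab) / max(sum(tab), 1L),
                    stringsAsFactors = FALSE)
  out <- out[order(out$state), , drop = FALSE]
  if (n_un > 0)
    out <- rbind(out, data.frame(state = "unannotated", n = n_un,
                                 fraction = NA_real_))
  rownames(out) <- NULL
  out
}
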
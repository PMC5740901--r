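# TSS annotation and nearest-gene ("direct target") assignment.

#' Construct a TSS set
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom Chromosome names.
#' @param pos 0-based TSS positions.
#' @param strand `"+"` or `"-"` per gene.
#' @return A `data.frame` of class `tss_set`, sorted by (chrom, pos),
#'   with columns `gene_id`, `chrom`, `pos`, `strand`.
#' @export
tss_set <- function(gene_id, chrom, pos, strand = "+") {
  gene_id <- as.character(gene_id)
  chrom <- rep_len(as.character(chrom), length(gene_id))
  pos <- as.numeric(pos)
  strand <- rep_len(as.character(strand), length(gene_id))
  if (length(gene_id) != length(chrom) || length(chrom) != length(pos))
    stop("gene_id, chrom and pos must have equal length")
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup) > 0)
    stop("duplicated gene_id: ", dup[1])
  if (length(pos) > 0 && any(pos < 0)) stop("TSS position must be >= 0")
  if (length(strand) > 0 && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- data.frame(gene_id = gene_id, chrom = chrom, pos = pos,
                   strand = strand, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("tss_set", "data.frame")
  df
}

#' Load a TSS annotation
#'
#' Reads a BED-like table (chrom, pos, pos+1, gene_id\[, score, strand\]).
#' A duplicated gene id is an error naming the gene.
#'
#' @param path Path to the TSS file.
#' @return A [tss_set()].
#' @export
load_tss <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(tss_set(character(), character(), numeric()))
  fields <- .split_fields(lines, 4L, path)
  nf <- lengths(fields)
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- .num_field(fields, 2L, path, "position")
  gene_id <- vapply(fields, `[[`, "", 4L)
  strand <- if (all(nf >= 6L)) vapply(fields, `[[`, "", 6L) else "+"
  tss_set(gene_id, chrom, pos, strand)
}

#' Write a TSS set
#'
#' @param x A [tss_set()].
#' @param path Output path (BED6 dialect).
#' @return `path`, invisibly.
#' @export
write_tss <- function(x, path) {
  df <- data.frame(x$chrom, x$pos, x$pos + 1, x$gene_id, 0, x$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assign each peak its nearest gene
#'
#' The direct target of a peak is the gene whose TSS minimizes the
#' distance to the peak midpoint, strand ignored. Exact ties are broken
#' by the lexicographically smallest `gene_id`; peaks on chromosomes with
#' no TSS are reported unassigned (`NA`).
#'
#' @param peaks A `GRanges` peak set.
#' @param tss A [tss_set()].
#' @return `data.frame` with columns `peak_id`, `chrom`, `midpoint`,
#'   `gene_id`, `distance` (signed, midpoint minus TSS).
#' @export
nearest_gene <- function(peaks, tss) {
  n <- length(peaks)
  ids <- S4Vectors::mcols(peaks)$name
  if (is.null(ids)) ids <- sprintf("peak_%d", seq_len(n))
  out <- data.frame(peak_id = ids,
                    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
                    midpoint = midpoint(peaks),
                    gene_id = NA_character_,
                    distance = NA_real_,
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  if (nrow(tss) == 0) {
    warning("empty TSS set; all peaks unassigned")
    return(out)
  }
  for (c in unique(out$chrom)) {
    t <- tss[tss$chrom == c, , drop = FALSE]
    if (nrow(t) == 0) next
    sel <- which(out$chrom == c)
    pos <- t$pos          # sorted by tss_set constructor
    gid <- t$gene_id
    m <- out$midpoint[sel]
    j <- findInterval(m, pos)
    dl <- ifelse(j >= 1, m - pos[pmax(j, 1)], Inf)
    dr <- ifelse(j < length(pos), pos[pmin(j + 1, length(pos))] - m, Inf)
    d <- pmin(dl, dr)
    for (k in seq_along(sel)) {
      cand <- which(pos == m[k] - d[k] | pos == m[k] + d[k])
      g <- cand[order(gid[cand])][1]
      out$gene_id[sel[k]] <- gid[g]
      out$distance[sel[k]] <- m[k] - pos[g]
    }
  }
  if (anyNA(out$gene_id))
    warning(sum(is.na(out$gene_id)),
            " peak(s) on chromosomes without any TSS left unassigned")
  out
}
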
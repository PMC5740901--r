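# Independent brute-force oracles used to check the package's interval,
# signal and statistics routines. All oracles work on plain data.frames
# of 0-based half-open intervals and deliberately share no code with the
# implementation.

# Transitive-closure merge oracle: repeated pairwise merging until no
# pair within `gap` remains.
oracle_merge <- function(df, gap) {
  repeat {
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    changed <- FALSE
    i <- 1
    while (i < nrow(df)) {
      if (df$chrom[i] == df$chrom[i + 1] &&
          df$start[i + 1] - df$end[i] <= gap) {
        df$end[i] <- max(df$end[i], df$end[i + 1])
        df <- df[-(i + 1), , drop = FALSE]
        changed <- TRUE
      } else i <- i + 1
    }
    if (!changed) return(df)
  }
}

# Quadratic any-overlap oracle (half-open intervals).
oracle_overlaps <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

# Base-level blacklist oracle: keep a peak iff none of its bases falls
# in any blacklist interval. Only usable on small coordinates.
oracle_blacklist_keep <- function(peaks, blacklist) {
  vapply(seq_len(nrow(peaks)), function(i) {
    bases <- seq(peaks$start[i], peaks$end[i] - 1)
    for (j in seq_len(nrow(blacklist))) {
      if (blacklist$chrom[j] != peaks$chrom[i]) next
      if (any(bases >= blacklist$start[j] & bases < blacklist$end[j]))
        return(FALSE)
    }
    TRUE
  }, logical(1))
}

# Expand a track data.frame (chrom,start,end,value; 0-based half-open)
# into a per-base vector for one chromosome, of length `len`.
oracle_track_vector <- function(track_df, chrom, len) {
  v <- numeric(len)
  t <- track_df[track_df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(t))) {
    s <- t$start[i] + 1
    e <- min(t$end[i], len)
    if (s <= e) v[s:e] <- t$value[i]
  }
  v
}

# Naive per-base mean over a 0-based half-open region.
oracle_region_mean <- function(track_df, chrom, start, end) {
  len <- max(track_df$end[track_df$chrom == chrom], end)
  v <- oracle_track_vector(track_df, chrom, len)
  mean(v[(start + 1):end])
}

# Naive binned profile around a 0-based anchor (zero-padded at edges).
oracle_profile <- function(track_df, chrom, pos, window, binsize) {
  len <- max(track_df$end, pos + window)
  v <- oracle_track_vector(track_df, chrom, len)
  s <- pos - window + 1
  idx <- s:(pos + window)
  w <- ifelse(idx >= 1 & idx <= len, v[pmax(idx, 1)], 0)
  colMeans(matrix(w, nrow = binsize))
}

# Exhaustive sign-flip oracle for the one-sample Wilcoxon signed-rank
# two-sided p-value (zeros must already be removed).
oracle_signrank_p <- function(x) {
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Closed-form 2x2 Pearson chi-square from the ad-bc formula.
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Expected-counts chi-square oracle for any table.
oracle_chisq_expected <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Hand step-up Benjamini-Hochberg.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Exhaustive nearest-TSS oracle with lexicographic tie-break.
oracle_nearest <- function(mid, chrom, tss) {
  t <- tss[tss$chrom == chrom, , drop = FALSE]
  if (nrow(t) == 0) return(NA_character_)
  d <- abs(t$pos - mid)
  cand <- t$gene_id[d == min(d)]
  sort(cand)[1]
}

# Random interval set on small coordinates, as a data.frame.
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                             max_len = 120) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

df_to_peaks <- function(df) peak_set(df$chrom, df$start, df$end)

# Same ordering as the peak_set constructor (chrom, start, end).
sort_df <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

peaks_to_df <- function(p) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(p)),
             start = bed_start(p), end = bed_end(p),
             stringsAsFactors = FALSE)
}
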
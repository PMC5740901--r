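test_that("peak sets are sorted and validated on construction", {
  p <- peak_set(c("chr2", "chr1", "chr1"), c(50, 500, 0), c(80, 600, 100))
  expect_equal(as.character(GenomeInfoDb::seqnames(p)),
               c("chr1", "chr1", "chr2"))
  expect_equal(bed_start(p), c(0, 500, 50))
  expect_equal(bed_end(p), c(100, 600, 80))
  expect_error(peak_set("chr1", 100, 100), "end")
  expect_error(peak_set("chr1", -5, 10), ">= 0")
  expect_length(peak_set(character(), numeric(), numeric()), 0)
})

test_that("BED and narrowPeak round-trip through read/write", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t500\t600\tb", "chr1\t0\t100\ta", "chr2\t10\t20\tc"), f)
  p <- read_peaks(f)
  expect_equal(bed_start(p), c(0, 500, 10))        # sorted
  expect_equal(S4Vectors::mcols(p)$name, c("a", "b", "c"))

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  set.seed(42)
  orig <- peak_set(rep("chr1", 10), seq(0, 9000, by = 1000),
                   seq(0, 9000, by = 1000) + 300,
                   name = sprintf("p%d", 1:10), score = 1:10 * 10,
                   signal = round(runif(10, 1, 20), 3),
                   pvalue = round(runif(10, 1, 20), 3),
                   qvalue = round(runif(10, 1, 20), 3),
                   summit = rep(150L, 10))
  write_peaks(orig, np, format = "narrowPeak")
  back <- read_peaks(np)
  expect_equal(bed_start(back), bed_start(orig))
  expect_equal(bed_end(back), bed_end(orig))
  for (col in c("name", "score", "signal", "pvalue", "qvalue", "summit"))
    expect_equal(S4Vectors::mcols(back)[[col]], S4Vectors::mcols(orig)[[col]],
                 info = col)
})

test_that("malformed peak files fail with the offending line", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100", "chr1\t5"), f)
  expect_error(read_peaks(f), "line 2")
  writeLines(c("chr1\t0\t100", "chr1\t200\t150"), f)
  expect_error(read_peaks(f), "line 2")
  writeLines(character(), f)
  expect_length(read_peaks(f), 0)
})

test_that("blacklist filtering removes any-overlap peaks, half-open", {
  peaks <- peak_set("chr1", 100, 200)
  expect_length(filter_blacklist(peaks, peak_set("chr1", 150, 160)), 0)
  expect_length(filter_blacklist(peaks, peak_set("chr1", 200, 300)), 1)
  expect_identical(filter_blacklist(peaks, peak_set(character(), numeric(), numeric())),
                   peaks)
})

test_that("blacklist filtering matches a base-level brute-force scan", {
  set.seed(101)
  for (rep in 1:30) {
    peaks <- random_intervals(15)
    bl <- random_intervals(4)
    kept <- filter_blacklist(df_to_peaks(peaks), df_to_peaks(bl))
    want <- oracle_blacklist_keep(sort_df(peaks),
                                  bl)
    expect_equal(length(kept), sum(want))
    expect_false(any(overlaps_any(kept, df_to_peaks(bl))))
  }
})

test_that("recursive merge closes gaps <= merge_gap transitively", {
  m <- recursive_merge(peak_set(c("chr1", "chr1"), c(0, 600), c(100, 700)), 500)
  expect_equal(cbind(bed_start(m), bed_end(m)), cbind(0, 700))
  m <- recursive_merge(peak_set(c("chr1", "chr1"), c(0, 601), c(100, 701)), 500)
  expect_length(m, 2)
  # second merge enabled by the first: recursion to fixpoint
  m <- recursive_merge(peak_set(rep("chr1", 3), c(0, 550, 1100),
                                c(100, 650, 1200)), 500)
  expect_equal(cbind(bed_start(m), bed_end(m)), cbind(0, 1200))
  expect_length(recursive_merge(peak_set(character(), numeric(), numeric())), 0)
})

test_that("recursive merge agrees with the pairwise-closure oracle and is idempotent", {
  set.seed(7)
  for (rep in 1:40) {
    df <- random_intervals(20)
    gap <- sample(c(0, 5, 50, 500), 1)
    m <- recursive_merge(df_to_peaks(df), gap)
    want <- oracle_merge(df, gap)
    expect_equal(peaks_to_df(m), data.frame(want, row.names = NULL))
    m2 <- recursive_merge(m, gap)
    expect_equal(peaks_to_df(m2), peaks_to_df(m))
    # coverage never decreases
    expect_gte(sum(bed_end(m) - bed_start(m)),
               sum(IRanges::width(GenomicRanges::reduce(df_to_peaks(df)))))
  }
})

test_that("overlaps_any matches the quadratic oracle and the half-open rule", {
  expect_true(overlaps_any(peak_set("chr1", 0, 100), peak_set("chr1", 50, 150)))
  expect_false(overlaps_any(peak_set("chr1", 0, 100), peak_set("chr1", 100, 200)))
  set.seed(13)
  for (rep in 1:30) {
    q <- random_intervals(20)
    s <- random_intervals(10)
    got <- overlaps_any(df_to_peaks(q), df_to_peaks(s))
    want <- oracle_overlaps(sort_df(q), s)
    expect_equal(got, want)
  }
})

test_that("midpoint floors the coordinate average", {
  expect_equal(midpoint(peak_set("chr1", 100, 200)), 150L)
  expect_equal(midpoint(peak_set("chr1", 0, 1)), 0L)
  expect_equal(midpoint(peak_set("chr1", 3, 8)), 5L)
})

test_that("chromatin-state annotation assigns by midpoint and flags uncovered peaks", {
  seg <- peak_set(rep("chr1", 3), c(0, 100, 200), c(100, 200, 300),
                  name = c("Promoter", "Strong_Enhancer", "Quiescent"))
  peaks <- peak_set(rep("chr1", 10), seq(100, 190, by = 10),
                    seq(100, 190, by = 10) + 8)
  tab <- annotate_chromatin_state(peaks, seg)
  expect_equal(tab$state, "Strong_Enhancer")
  expect_equal(tab$fraction, 1.0)
  expect_equal(nrow(annotate_chromatin_state(df_to_peaks(random_intervals(0)), seg)), 0)
  overlapping <- peak_set(c("chr1", "chr1"), c(0, 50), c(100, 150),
                          name = c("a", "b"))
  expect_error(annotate_chromatin_state(peaks, overlapping), "overlap")
})

test_that("chromatin-state fractions match a per-peak linear scan", {
  set.seed(33)
  seg_df <- data.frame(chrom = "chr1",
                       start = c(0, 300, 700),
                       end = c(300, 700, 1200),
                       state = c("s1", "s2", "s3"))
  seg <- peak_set(seg_df$chrom, seg_df$start, seg_df$end, name = seg_df$state)
  peaks <- random_intervals(50, chroms = "chr1")
  tab <- annotate_chromatin_state(df_to_peaks(peaks), seg)
  mids <- floor((peaks$start + peaks$end) / 2)
  want <- vapply(mids, function(m) {
    hit <- which(seg_df$start <= m & m < seg_df$end)
    if (length(hit) == 0) "unannotated" else seg_df$state[hit]
  }, character(1))
  for (s in unique(want)) {
    expect_equal(tab$n[tab$state == s], sum(want == s), info = s)
  }
  assigned <- tab[tab$state != "unannotated", ]
  expect_equal(sum(assigned$fraction), 1.0)
})
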
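test_that("bedGraph reader validates sorting and overlap, round-trips values", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t100\t1.5", "chr1\t100\t250\t0.25",
               "chr2\t50\t60\t4"), f)
  tr <- read_bedgraph(f)
  expect_equal(S4Vectors::mcols(tr)$score, c(1.5, 0.25, 4))
  expect_equal(region_means(tr, peak_set("chr1", 300, 400)), 0)  # uncovered
  writeLines(c("chr1\t100\t200\t1", "chr1\t0\t50\t1"), f)
  expect_error(read_bedgraph(f), "not sorted")
  writeLines(c("chr1\t0\t100\t1", "chr1\t50\t150\t1"), f)
  expect_error(read_bedgraph(f), "overlap")
  expect_error(coverage_track("chr1", 0, 10, -1), ">= 0")
})

test_that("profiles reproduce constant tracks and the per-base oracle", {
  const <- coverage_track("chr1", 0, 10000, 2.5)
  p <- profile_at_points(const, "chr1", 5000, window = 500, binsize = 10)
  expect_equal(p$mean, rep(2.5, 100))
  # value 1 only on [0,100), anchor 50, window 50: all bins 1
  tr <- coverage_track("chr1", 0, 100, 1)
  p <- profile_at_points(tr, "chr1", 50, window = 50, binsize = 10)
  expect_equal(p$mean, rep(1, 10))
  expect_error(profile_at_points(tr, character(), numeric()), "empty")
  expect_error(profile_at_points(tr, "chr1", 50, window = 55, binsize = 10),
               "divisible")
  # random step track vs naive per-base averaging
  set.seed(61)
  steps <- data.frame(chrom = "chr1", start = seq(0, 1900, 100),
                      end = seq(100, 2000, 100),
                      value = round(runif(20, 0, 3), 2))
  trs <- coverage_track(steps$chrom, steps$start, steps$end, steps$value)
  anchors <- sample.int(1900, 20)
  p <- profile_at_points(trs, rep("chr1", 20), anchors,
                         window = 200, binsize = 20, keep_matrix = TRUE)
  want <- t(vapply(anchors, function(a)
    oracle_profile(steps, "chr1", a, 200, 20), numeric(20)))
  expect_equal(unname(p$matrix), unname(want), tolerance = 1e-9)
  expect_equal(p$mean, colMeans(want), tolerance = 1e-9)
  # conservation: grand mean of bins equals per-base mean over windows
  expect_equal(mean(p$mean), mean(want), tolerance = 1e-9)
})

test_that("profiles are linear in the track", {
  set.seed(62)
  steps <- data.frame(chrom = "chr1", start = seq(0, 900, 100),
                      end = seq(100, 1000, 100), value = runif(10, 0, 2))
  t1 <- coverage_track(steps$chrom, steps$start, steps$end, steps$value)
  t3 <- coverage_track(steps$chrom, steps$start, steps$end, 3 * steps$value)
  p1 <- profile_at_points(t1, rep("chr1", 5), c(100, 300, 500, 700, 900),
                          window = 100, binsize = 10)
  p3 <- profile_at_points(t3, rep("chr1", 5), c(100, 300, 500, 700, 900),
                          window = 100, binsize = 10)
  expect_equal(p3$mean, 3 * p1$mean, tolerance = 1e-12)
})

test_that("TSS tertiles split by rank and orient by strand", {
  tss9 <- tss_set(sprintf("g%d", 1:9), "chr1", seq(1000, 9000, 1000))
  expr <- setNames(as.numeric(1:9), tss9$gene_id)
  tr <- coverage_track("chr1", 0, 10000, 1)
  out <- tss_profiles_by_expression(tr, tss9, expr, window = 100, binsize = 10)
  expect_equal(vapply(out, function(p) p$n_anchors, integer(1)),
               c(low = 3L, medium = 3L, high = 3L))
  # ties broken deterministically by gene id
  out2 <- tss_profiles_by_expression(tr, tss9, setNames(rep(1, 9), tss9$gene_id),
                                     window = 100, binsize = 10)
  expect_equal(vapply(out2, function(p) p$n_anchors, integer(1)),
               c(low = 3L, medium = 3L, high = 3L))
  # planted high-expression signal dominates the high tertile
  tr2 <- coverage_track(rep("chr1", 7),
                        c(0, 6950, 7050, 7950, 8050, 8950, 9050),
                        c(6950, 7050, 7950, 8050, 8950, 9050, 10000),
                        c(0.2, 5, 0.2, 5, 0.2, 5, 0.2))
  out3 <- tss_profiles_by_expression(tr2, tss9, expr, window = 200, binsize = 10)
  expect_gt(max(out3$high$mean), max(out3$low$mean))
})

test_that("strand reversal mirrors each tertile profile", {
  set.seed(63)
  steps <- data.frame(chrom = "chr1", start = seq(0, 19900, 100),
                      end = seq(100, 20000, 100), value = runif(200, 0, 2))
  tr <- coverage_track(steps$chrom, steps$start, steps$end, steps$value)
  pos <- seq(2000, 18000, length.out = 9)
  expr <- setNames(as.numeric(1:9), sprintf("g%d", 1:9))
  fwd <- tss_set(sprintf("g%d", 1:9), "chr1", pos, "+")
  rev <- tss_set(sprintf("g%d", 1:9), "chr1", pos, "-")
  pf <- tss_profiles_by_expression(tr, fwd, expr, window = 200, binsize = 10)
  pr <- tss_profiles_by_expression(tr, rev, expr, window = 200, binsize = 10)
  for (tier in names(pf))
    expect_equal(pr[[tier]]$mean, base::rev(pf[[tier]]$mean), tolerance = 1e-12)
})

test_that("group comparison reports per-bin differences and central ratio", {
  tr <- coverage_track("chr1", 0, 10000, 1)
  anchors <- c(2000, 5000, 8000)
  cmp <- compare_groups_signal(tr, rep("chr1", 3), anchors,
                               rep("chr1", 3), anchors,
                               window = 500, binsize = 10)
  expect_equal(cmp$difference, rep(0, 100))
  expect_equal(cmp$central_ratio, 1)
  # group X on 2x signal
  tr2 <- coverage_track(c("chr1", "chr1"), c(0, 5000), c(5000, 10000),
                        c(2, 1))
  cmp2 <- compare_groups_signal(tr2, "chr1", 2000, "chr1", 8000,
                                window = 500, binsize = 10)
  expect_equal(cmp2$central_ratio, 2, tolerance = 1e-9)
})
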
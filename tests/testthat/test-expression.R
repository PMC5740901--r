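make_de <- function(gene_id, lfc, q, mean_expr = 100) {
  validate_de_table(data.frame(gene_id = gene_id, mean_expr = mean_expr,
                               log2fc = lfc, pvalue = q, qvalue = q,
                               stringsAsFactors = FALSE))
}

test_that("DE tables validate columns, bounds and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  de <- make_de(sprintf("g%d", 1:5), c(-1, 0, 1, 2, NA),
                c(0.01, 0.5, 0.04, 0.2, 0.9))
  write_de_table(de, f)
  back <- read_de_table(f)
  expect_equal(back$log2fc, de$log2fc)
  expect_equal(back$qvalue, de$qvalue)
  expect_equal(back$testable, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  writeLines("gene_id\tmean_expr\tlog2fc\tpvalue", f)
  expect_error(read_de_table(f), "qvalue")
  expect_error(make_de("g1", 1, 1.3), "\\[0, 1\\]")
})

test_that("simple_de normalizes library size away and recovers fold changes", {
  set.seed(9)
  base <- round(runif(200, 50, 2000))
  # sample2 is a straight 2x scaling of sample1 in both groups: after
  # size-factor correction every gene has log2fc 0
  counts <- cbind(a1 = base, a2 = 2 * base, b1 = base, b2 = 2 * base)
  de <- simple_de(counts, c("ctrl", "ctrl", "kd", "kd"))
  expect_equal(de$log2fc, rep(0, 200))
  # one gene at 4x after normalization has log2fc ~ 2 at high counts
  kd <- base
  kd[1] <- base[1] * 4
  counts <- cbind(a1 = base, a2 = base, b1 = kd, b2 = kd)
  de <- simple_de(counts, c("ctrl", "ctrl", "kd", "kd"))
  expect_equal(de$log2fc[1], 2, tolerance = 0.05)
  # all-zero genes are excluded
  counts[2, ] <- 0
  de <- simple_de(counts, c("ctrl", "ctrl", "kd", "kd"))
  expect_false("gene_2" %in% de$gene_id)
  expect_equal(nrow(de), 199)
})

test_that("simple_de is invariant to within-group relabeling and sample scaling", {
  set.seed(19)
  counts <- matrix(rnbinom(100 * 6, mu = 300, size = 50), 100,
                   dimnames = list(sprintf("g%d", 1:100), NULL))
  grp <- rep(c("ctrl", "kd"), each = 3)
  de1 <- simple_de(counts, grp)
  de2 <- simple_de(counts[, c(2, 1, 3, 6, 5, 4)], grp)
  expect_equal(de2, de1)
  scaled <- counts
  scaled[, 4] <- round(scaled[, 4] * 3)
  de3 <- simple_de(scaled, grp)
  expect_equal(de3$log2fc, de1$log2fc, tolerance = 0.02)
  expect_error(simple_de(counts[, 1:3], c("ctrl", "ctrl", "kd")),
               "at least 2")
})

test_that("direct-target filtering keeps each target gene once", {
  de <- make_de(c("g1", "g2", "g3"), c(1, 1, 1), c(0.01, 0.01, 0.01))
  asg <- data.frame(peak_id = c("p1", "p2", "p3"),
                    gene_id = c("g1", "g1", "g3"))
  out <- direct_targets(de, asg)
  expect_equal(out$gene_id, c("g1", "g3"))
})

test_that("quadrant categorization requires significance in both contrasts", {
  cfg <- analysis_config(fdr = 0.05)
  de_a <- make_de(c("g1", "g2", "g3", "g4"), c(1, 1, -2, 0.5),
                  c(0.01, 0.01, 0.02, 0.04))
  de_b <- make_de(c("g1", "g2", "g3", "g4"), c(2, -1, -1, 0.5),
                  c(0.01, 0.2, 0.01, 0.04))
  cats <- quadrant_categorize(de_a, de_b, cfg)
  expect_equal(cats$gene_id, c("g1", "g3", "g4"))  # g2 not significant in B
  expect_equal(cats$category, c("both_up", "both_down", "both_up"))
  # a zero fold change is uncategorized even when significant
  de_a0 <- make_de("g9", 0, 0.001)
  de_b0 <- make_de("g9", 1, 0.001)
  expect_equal(nrow(quadrant_categorize(de_a0, de_b0, cfg)), 0)
  # discordant quadrants
  de_a2 <- make_de(c("u", "v"), c(1.5, -1.5), 0.01)
  de_b2 <- make_de(c("u", "v"), c(-0.5, 0.5), 0.01)
  cats2 <- quadrant_categorize(de_a2, de_b2, cfg)
  expect_equal(setNames(cats2$category, cats2$gene_id),
               c(u = "a_up_b_down", v = "a_down_b_up"))
})

test_that("rescue index follows the stated arithmetic and is symmetric", {
  cats <- data.frame(gene_id = c("g1", "g2"), lfc_a = c(2, 1.5),
                     lfc_b = c(-2, -0.5),
                     category = c("a_up_b_down", "a_up_b_down"))
  de_a <- make_de(c("g1", "g2"), c(2, 1.5), 0.01)
  de_b <- make_de(c("g1", "g2"), c(-2, -0.5), 0.01)
  de_d <- make_de(c("g1", "g2"), c(0, 0.5), 0.5)
  res <- rescue_analysis(de_a, de_b, de_d, cats)
  expect_equal(res$records$rescue_index, c(1, 0.5))
  # swapping the A and B labels leaves the index unchanged
  cats_sw <- data.frame(gene_id = cats$gene_id, lfc_a = cats$lfc_b,
                        lfc_b = cats$lfc_a, category = "a_down_b_up")
  res_sw <- rescue_analysis(de_b, de_a, de_d, cats_sw)
  expect_equal(res_sw$records$rescue_index, res$records$rescue_index)
  # genes missing from the double table are dropped with a warning
  expect_warning(r2 <- rescue_analysis(de_a, de_b, make_de("g1", 0, 0.5), cats),
                 "dropped")
  expect_equal(r2$records$gene_id, "g1")
})

test_that("near-zero double-knockdown fold changes yield rescue indices near 1", {
  set.seed(23)
  n <- 200
  lfc_d <- rnorm(n, 0, 0.1)
  cats <- data.frame(gene_id = sprintf("g%03d", 1:n), lfc_a = 1.5,
                     lfc_b = -1.5, category = "a_up_b_down")
  res <- rescue_analysis(make_de(cats$gene_id, 1.5, 0.01),
                         make_de(cats$gene_id, -1.5, 0.01),
                         make_de(cats$gene_id, lfc_d, 0.5), cats)
  expect_gte(res$summary$median_rescue_index, 0.9)
})

test_that("double-only genes define the redundant class", {
  de_a <- make_de(c("g1", "g2"), c(1, 0), c(0.01, 0.9))
  de_b <- make_de(c("g1", "g2"), c(1, 0), c(0.01, 0.9))
  de_d <- make_de(c("g1", "g2"), c(1, 2), c(0.01, 0.01))
  expect_equal(double_only_genes(de_a, de_b, de_d), "g2")
})
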
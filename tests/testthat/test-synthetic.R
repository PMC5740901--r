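# A small generator configuration shared across tests: 200 loci, 100
# genes, class sizes scaled down proportionally from the defaults.
small_config <- function(seed = 1, ...) {
  generator_config(n_peaks = 200, n_genes = 100,
                   quadrant_counts = c(both_up = 8, both_down = 10,
                                       a_up_b_down = 11, a_down_b_up = 12),
                   n_redundant = 10, seed = seed, ...)
}

test_that("planting is exact: realized counts equal configured counts", {
  truth <- generate_truth(small_config())
  expect_equal(sum(truth$loci$fate_a == "lost", na.rm = TRUE),
               round(0.4 * sum(!is.na(truth$loci$fate_a))))
  expect_equal(sum(truth$loci$fate_b == "lost", na.rm = TRUE),
               round(0.7 * sum(!is.na(truth$loci$fate_b))))
  cls <- table(truth$genes$class)
  expect_equal(unname(cls[c("both_up", "both_down", "a_up_b_down",
                            "a_down_b_up", "redundant")]),
               as.integer(c(8, 10, 11, 12, 10)), ignore_attr = TRUE)
  # 1000 subunit-A peaks at loss fraction 0.40 with no sibling-absent
  # margin: exactly 400 planted lost
  t2 <- generate_truth(generator_config(n_peaks = 1000, n_genes = 100,
                                        quadrant_counts = c(both_up = 5,
                                                            both_down = 5,
                                                            a_up_b_down = 5,
                                                            a_down_b_up = 5),
                                        n_redundant = 5,
                                        sibling_absent_frac = 0, seed = 2))
  expect_equal(sum(t2$loci$fate_a == "lost", na.rm = TRUE), 400)
})

test_that("truth and emitted files are deterministic given the seed", {
  t1 <- generate_truth(small_config(seed = 42))
  t2 <- generate_truth(small_config(seed = 42))
  expect_equal(t1$loci, t2$loci)
  expect_equal(t1$genes, t2$genes)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_datasets(t1, d1, tracks = FALSE, counts = FALSE)
  emit_datasets(t2, d2, tracks = FALSE, counts = FALSE)
  for (f in setdiff(list.files(d1), "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("planted truth constraints hold: fates follow presence, targets exist", {
  truth <- generate_truth(small_config(seed = 3))
  l <- truth$loci
  expect_true(all((l$fate_a == "lost") ==
                    (l$present_a_shNS & !l$present_a_shA), na.rm = TRUE))
  expect_true(all((l$fate_b == "lost") ==
                    (l$present_b_shNS & !l$present_b_shB), na.rm = TRUE))
  # every class gene is linked to a locus so it can be a direct target
  cls_genes <- truth$genes[truth$genes$class != "null", ]
  expect_false(anyNA(cls_genes$locus_id))
  asg <- nearest_gene(synth_peak_set(truth, "a", "shNS", decoys = FALSE),
                      synth_tss(truth))
  expect_true(all(cls_genes$gene_id[cls_genes$locus_id %in%
                                      l$locus_id[l$present_a_shNS]] %in%
                    asg$gene_id))
})

test_that("emitted files parse back through their readers", {
  truth <- generate_truth(small_config(seed = 4))
  outdir <- withr::local_tempdir()
  manifest <- emit_datasets(truth, outdir, de_mode = "direct")
  p <- read_peaks(manifest$peaks_a_shNS)
  expect_equal(length(p),
               sum(truth$loci$present_a_shNS) + nrow(truth$decoys))
  expect_s4_class(read_peaks(manifest$blacklist), "GRanges")
  seg <- read_peaks(manifest$segmentation, format = "bed")
  expect_true(IRanges::isDisjoint(seg))
  expect_setequal(unique(S4Vectors::mcols(seg)$name),
                  c("Strong_Enhancer", "Promoter", "Quiescent"))
  tss <- load_tss(manifest$tss)
  expect_equal(nrow(tss), nrow(truth$genes))
  tr <- read_bedgraph(manifest$coverage_a_shNS)
  expect_s4_class(tr, "GRanges")
  de <- read_de_table(manifest$de_shA)
  expect_equal(nrow(de), nrow(truth$genes))
  cc <- read.table(manifest$counts_shA, header = TRUE, sep = "\t")
  expect_equal(dim(cc), c(nrow(truth$genes), 1 + 2 * truth$config$replicates))
})

test_that("coverage tracks are consistent with peak presence", {
  truth <- generate_truth(small_config(seed = 6))
  tr <- synth_coverage_track(truth, "a", "shA")
  present <- truth$loci[truth$loci$present_a_shA, ][1:20, ]
  absent <- truth$loci[!is.na(truth$loci$fate_a) &
                         truth$loci$fate_a == "lost", ][1:20, ]
  mp <- region_means(tr, peak_set(present$chrom, present$start, present$end))
  ma <- region_means(tr, peak_set(absent$chrom, absent$start, absent$end))
  expect_true(all(mp > 5))           # plateaus near peak_height = 8
  expect_true(all(ma < 2))           # background near 0.5
})

test_that("noiseless emission recovers planted fates exactly; jitter degrades gracefully", {
  truth <- generate_truth(small_config(seed = 8))
  bl <- peak_set(truth$blacklist$chrom, truth$blacklist$start,
                 truth$blacklist$end)
  run_fates <- function(truth, jitter) {
    m <- function(su, cond)
      recursive_merge(filter_blacklist(
        synth_peak_set(truth, su, cond, jitter = jitter, decoys = FALSE), bl))
    list(fate_a = classify_fate(m("a", "shNS"), m("a", "shA")),
         fate_b = classify_fate(m("b", "shNS"), m("b", "shB")))
  }
  rec0 <- score_recovery(truth, run_fates(truth, jitter = 0))
  expect_equal(rec0$fate_accuracy_a, 1.0)
  expect_equal(rec0$fate_accuracy_b, 1.0)
  # accuracy is monotone (non-increasing) over a noise ladder
  accs <- vapply(c(0, 150, 350), function(j)
    score_recovery(truth, run_fates(truth, jitter = j))$fate_accuracy_a,
    numeric(1))
  expect_true(all(diff(accs) <= 1e-12))
})

test_that("recovery scoring flags planted-vs-recovered disagreements", {
  truth <- generate_truth(small_config(seed = 10))
  ns <- synth_peak_set(truth, "a", "shNS", decoys = FALSE)
  kd <- synth_peak_set(truth, "a", "shA", decoys = FALSE)
  ft <- classify_fate(ns, kd)
  flipped <- ft
  flipped$fate[1:10] <- ifelse(flipped$fate[1:10] == "lost",
                               "retained_gained", "lost")
  rec <- score_recovery(truth, list(fate_a = flipped))
  expect_equal(rec$fate_accuracy_a, 1 - 10 / nrow(ft))
})

test_that("direct DE emission realizes the planted significance structure", {
  truth <- generate_truth(small_config(seed = 12))
  de_a <- synth_de_table(truth, "shA")
  de_b <- synth_de_table(truth, "shB")
  de_d <- synth_de_table(truth, "double")
  cats <- quadrant_categorize(de_a, de_b)
  planted <- truth$genes$class[match(cats$gene_id, truth$genes$gene_id)]
  expect_equal(unname(cats$category), unname(planted))
  expect_setequal(double_only_genes(de_a, de_b, de_d),
                  truth$genes$gene_id[truth$genes$class == "redundant"])
})
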
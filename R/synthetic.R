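# Synthetic-data generator with exactly planted ground truth: peak sets
# per subunit and condition with planted lost/retained fractions and
# group labels, coverage tracks consistent with peak presence, TSS and
# chromatin-state annotations, counts and DE tables with planted gene
# classes, plus recovery scoring against the planted truth.
#
# Planting is by exact-count assignment (shuffle, then assign), never by
# independent coin flips, so realized class counts equal configured
# counts always.

#' Generator configuration
#'
#' Defaults mirror the study regime at desk scale: loss fractions 0.40
#' (subunit A, BRG1-like) and 0.70 (subunit B, BRM-like); quadrant
#' category sizes 89/111/115/116; significance at FDR 0.05 with no
#' fold-change cutoff; coverage emitted with 150-bp fragment extension.
#'
#' @param n_peaks Number of shared peak loci (default 2000).
#' @param n_genes Number of genes (default 1000).
#' @param replicates RNA-seq replicates per condition (default 3).
#' @param quadrant_counts Named counts for `both_up`, `both_down`,
#'   `a_up_b_down`, `a_down_b_up` (defaults 89/111/115/116).
#' @param n_redundant Genes significant only in the double knockdown
#'   (default 100).
#' @param loss_frac_a,loss_frac_b Fractions of each subunit's control
#'   peaks lost in its own knockdown (defaults 0.40 / 0.70).
#' @param sibling_loss_frac Fraction of lost regions where the sibling is
#'   also lost (default 0.6).
#' @param sibling_absent_frac Fraction of lost regions where the sibling
#'   never had a peak (default 0.05).
#' @param effect_size_mean,effect_size_sd,effect_size_min Log2
#'   fold-change magnitudes of affected genes: `|lfc| ~ N(mean, sd)`
#'   floored at `effect_size_min` (defaults 1.5 / 0.3 / 0.5).
#' @param double_residual_sd Residual |lfc| scatter of antagonistic genes
#'   in the double knockdown (default 0.1).
#' @param concordant_exaggeration Multiplier on the mean single-knockdown
#'   magnitude for concordant genes in the double knockdown
#'   (default 1.15, a slight exaggeration).
#' @param nb_dispersion Negative-binomial dispersion of simulated counts
#'   (default 0.01, a low-variability cell-line regime).
#' @param base_mean_log,base_mean_sdlog Log-normal parameters of baseline
#'   gene means (defaults log(500), 0.8).
#' @param jitter_bp Peak-boundary jitter: each emitted boundary is
#'   shifted by a uniform integer in `[-jitter_bp, jitter_bp]`
#'   (default 0 = noiseless).
#' @param peak_width,locus_spacing Peak width and distance between locus
#'   starts in bp (defaults 400 / 3000; spacing is large enough that
#'   jittered peaks never merge across loci at the default merge gap).
#' @param n_chrom Number of chromosomes to spread loci over (default 2).
#' @param background_level,coverage_noise_sd,coverage_bin Background
#'   coverage level, its noise sd, and background bin width in bp.
#' @param peak_height Plateau coverage at a present peak (default 8).
#' @param cofactor_multiplier_lost,cofactor_multiplier_retained Cofactor
#'   track plateau multipliers at regions whose sibling is lost versus
#'   retained (defaults 2 / 1).
#' @param n_blacklist Number of blacklist decoy regions (default 4).
#' @param seed Master seed; all emitted data are deterministic given the
#'   config.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_peaks = 2000, n_genes = 1000,
                             replicates = 3,
                             quadrant_counts = c(both_up = 89,
                                                 both_down = 111,
                                                 a_up_b_down = 115,
                                                 a_down_b_up = 116),
                             n_redundant = 100,
                             loss_frac_a = 0.40, loss_frac_b = 0.70,
                             sibling_loss_frac = 0.60,
                             sibling_absent_frac = 0.05,
                             effect_size_mean = 1.5,
                             effect_size_sd = 0.3,
                             effect_size_min = 0.5,
                             double_residual_sd = 0.1,
                             concordant_exaggeration = 1.15,
                             nb_dispersion = 0.01,
                             base_mean_log = log(500),
                             base_mean_sdlog = 0.8,
                             jitter_bp = 0,
                             peak_width = 400, locus_spacing = 3000,
                             n_chrom = 2,
                             background_level = 0.5,
                             coverage_noise_sd = 0.1,
                             coverage_bin = 500,
                             peak_height = 8,
                             cofactor_multiplier_lost = 2,
                             cofactor_multiplier_retained = 1,
                             n_blacklist = 4,
                             seed = 1L) {
  quadrant_counts <- unlist(quadrant_counts)  # lists arrive from YAML configs
  cfg <- list(n_peaks = as.integer(n_peaks), n_genes = as.integer(n_genes),
              replicates = as.integer(replicates),
              quadrant_counts = quadrant_counts,
              n_redundant = as.integer(n_redundant),
              loss_frac_a = loss_frac_a, loss_frac_b = loss_frac_b,
              sibling_loss_frac = sibling_loss_frac,
              sibling_absent_frac = sibling_absent_frac,
              effect_size_mean = effect_size_mean,
              effect_size_sd = effect_size_sd,
              effect_size_min = effect_size_min,
              double_residual_sd = double_residual_sd,
              concordant_exaggeration = concordant_exaggeration,
              nb_dispersion = nb_dispersion,
              base_mean_log = base_mean_log,
              base_mean_sdlog = base_mean_sdlog,
              jitter_bp = as.integer(jitter_bp),
              peak_width = as.integer(peak_width),
              locus_spacing = as.integer(locus_spacing),
              n_chrom = as.integer(n_chrom),
              background_level = background_level,
              coverage_noise_sd = coverage_noise_sd,
              coverage_bin = as.integer(coverage_bin),
              peak_height = peak_height,
              cofactor_multiplier_lost = cofactor_multiplier_lost,
              cofactor_multiplier_retained = cofactor_multiplier_retained,
              n_blacklist = as.integer(n_blacklist),
              seed = as.integer(seed))
  if (cfg$n_peaks <= 0 || cfg$n_genes <= 0 || cfg$replicates <= 0)
    stop("counts must be positive")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  stopifnot(identical(sort(names(cfg$quadrant_counts)),
                      sort(c("both_up", "both_down",
                             "a_up_b_down", "a_down_b_up"))))
  if (cfg$jitter_bp < 0) stop("jitter_bp must be >= 0")
  class(cfg) <- "generator_config"
  cfg
}

# Exact-count sample without replacement; stable for size 0 and
# length-1 pools (no 1:n surprise).
.take <- function(pool, k) {
  if (k <= 0) return(integer(0))
  pool[sample.int(length(pool), k)]
}

#' Generate planted ground truth
#'
#' Builds a genome of evenly spaced peak loci shared by the two sibling
#' subunits, plants per-condition presence flags realizing the configured
#' loss fractions and group proportions *exactly*, places one TSS next to
#' each class gene's locus so that every affected gene is a direct
#' target, and assigns planted log2 fold changes per contrast per gene
#' class (concordant genes slightly exaggerated in the double knockdown;
#' antagonistic genes rescued; redundant genes affected only in the
#' double).
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_truth` with elements `config`,
#'   `genome`, `loci`, `genes`, `blacklist`, `decoys` and realized
#'   summaries.
#' @export
generate_truth <- function(config = generator_config()) {
  cfg <- config
  with_seed(derive_seed(cfg$seed, 1), {
    N <- cfg$n_peaks
    per_chr <- rep(ceiling(N / cfg$n_chrom), cfg$n_chrom)
    per_chr[cfg$n_chrom] <- N - sum(per_chr[-cfg$n_chrom])
    chrom <- rep(sprintf("chr%d", seq_len(cfg$n_chrom)), per_chr)
    idx_in_chr <- unlist(lapply(per_chr, seq_len))
    start <- 1000 + (idx_in_chr - 1) * cfg$locus_spacing
    end <- start + cfg$peak_width
    genome <- data.frame(chrom = sprintf("chr%d", seq_len(cfg$n_chrom)),
                         length = vapply(seq_len(cfg$n_chrom), function(i) {
                           e <- end[chrom == sprintf("chr%d", i)]
                           if (length(e) == 0) 10000 else max(e) + 5000
                         }, numeric(1)))

    # -- plant presence flags ------------------------------------------
    n_sa <- round(cfg$sibling_absent_frac * cfg$loss_frac_a * N)
    n_sb <- round(cfg$sibling_absent_frac * cfg$loss_frac_b * N)
    SA <- .take(seq_len(N), n_sa)              # B never present here
    SB <- .take(setdiff(seq_len(N), SA), n_sb) # A never present here
    a_universe <- setdiff(seq_len(N), SB)
    b_universe <- setdiff(seq_len(N), SA)
    nA_lost <- round(cfg$loss_frac_a * length(a_universe))
    nB_lost <- round(cfg$loss_frac_b * length(b_universe))
    if (nA_lost < n_sa || nB_lost < n_sb)
      stop("sibling_absent_frac too large for the configured loss fractions")
    L_A <- c(SA, .take(setdiff(a_universe, SA), nA_lost - n_sa))
    L_B <- c(SB, .take(setdiff(b_universe, SB), nB_lost - n_sb))
    GA_pool <- setdiff(L_A, SA)
    GB_pool <- setdiff(L_B, SB)
    G1 <- .take(GA_pool, round(cfg$sibling_loss_frac * length(GA_pool)))
    G2 <- setdiff(GA_pool, G1)
    G3 <- .take(GB_pool, round(cfg$sibling_loss_frac * length(GB_pool)))
    G4 <- setdiff(GB_pool, G3)

    loci <- data.frame(locus_id = sprintf("locus_%04d", seq_len(N)),
                       chrom = chrom, start = start, end = end,
                       mid = floor((start + end) / 2),
                       stringsAsFactors = FALSE)
    loci$present_a_shNS <- seq_len(N) %in% a_universe
    loci$present_a_shA <- loci$present_a_shNS & !(seq_len(N) %in% L_A)
    loci$present_a_shB <- loci$present_a_shNS & !(seq_len(N) %in% G3)
    loci$present_b_shNS <- seq_len(N) %in% b_universe
    loci$present_b_shB <- loci$present_b_shNS & !(seq_len(N) %in% L_B)
    loci$present_b_shA <- loci$present_b_shNS & !(seq_len(N) %in% G1)
    loci$fate_a <- ifelse(!loci$present_a_shNS, NA_character_,
                          ifelse(seq_len(N) %in% L_A, "lost", "retained_gained"))
    loci$fate_b <- ifelse(!loci$present_b_shNS, NA_character_,
                          ifelse(seq_len(N) %in% L_B, "lost", "retained_gained"))
    loci$status_a <- NA_character_
    loci$status_a[G1] <- "sibling_lost"
    loci$status_a[G2] <- "sibling_retained_gained"
    loci$status_a[SA] <- "sibling_absent"
    loci$status_b <- NA_character_
    loci$status_b[G3] <- "sibling_lost"
    loci$status_b[G4] <- "sibling_retained_gained"
    loci$status_b[SB] <- "sibling_absent"
    loci$group <- NA_integer_
    loci$group[G1] <- 1L; loci$group[G2] <- 2L
    loci$group[G3] <- 3L; loci$group[G4] <- 4L

    # -- plant gene classes --------------------------------------------
    qc <- cfg$quadrant_counts
    n_classes <- sum(qc) + cfg$n_redundant
    if (n_classes > cfg$n_genes)
      stop("more planted class genes than genes")
    # class -> locus pool; directions follow the group-4 figure logic:
    # lost-A regions where the sibling is also lost behave antagonist-
    # ically with A activating (a_down_b_up), etc.
    retained_both <- setdiff(intersect(a_universe, b_universe),
                             union(L_A, L_B))
    pools <- list(a_down_b_up = G1, a_up_b_down = G2,
                  both_down = G3, both_up = G4,
                  redundant = retained_both)
    sizes <- c(a_down_b_up = unname(qc[["a_down_b_up"]]),
               a_up_b_down = unname(qc[["a_up_b_down"]]),
               both_down = unname(qc[["both_down"]]),
               both_up = unname(qc[["both_up"]]),
               redundant = cfg$n_redundant)
    for (cl in names(pools))
      if (sizes[[cl]] > length(pools[[cl]]))
        stop("more planted ", cl, " genes than available loci")
    used <- integer(0)
    gene_locus <- integer(0)
    gene_class <- character(0)
    for (cl in names(pools)) {
      loc <- .take(setdiff(pools[[cl]], used), sizes[[cl]])
      used <- c(used, loc)
      gene_locus <- c(gene_locus, loc)
      gene_class <- c(gene_class, rep(cl, length(loc)))
    }
    n_null <- cfg$n_genes - n_classes
    n_null_locus <- n_null %/% 2
    free <- setdiff(seq_len(N), used)
    n_null_locus <- min(n_null_locus, length(free))
    null_loc <- .take(free, n_null_locus)
    gene_locus <- c(gene_locus, null_loc)
    gene_class <- c(gene_class, rep("null", n_null_locus))
    # remaining null genes live in inter-locus deserts, far from any peak
    n_desert <- n_null - n_null_locus
    desert_host <- .take(seq_len(N), n_desert)
    genes <- data.frame(
      gene_id = sprintf("gene_%04d", seq_len(cfg$n_genes)),
      class = c(gene_class, rep("null", n_desert)),
      locus_id = c(loci$locus_id[gene_locus], rep(NA_character_, n_desert)),
      chrom = c(loci$chrom[gene_locus], loci$chrom[desert_host]),
      pos = c(loci$mid[gene_locus] + 100,
              loci$start[desert_host] + 1900),
      stringsAsFactors = FALSE)
    genes$strand <- ifelse(seq_len(nrow(genes)) %% 2 == 0, "-", "+")
    genes$base_mean <- rlnorm(nrow(genes), cfg$base_mean_log,
                              cfg$base_mean_sdlog)

    e_a <- pmax(cfg$effect_size_min,
                rnorm(nrow(genes), cfg$effect_size_mean, cfg$effect_size_sd))
    e_b <- pmax(cfg$effect_size_min,
                rnorm(nrow(genes), cfg$effect_size_mean, cfg$effect_size_sd))
    genes$lfc_a <- 0; genes$lfc_b <- 0; genes$lfc_double <- 0
    cl <- genes$class
    genes$lfc_a[cl == "both_up"] <- e_a[cl == "both_up"]
    genes$lfc_b[cl == "both_up"] <- e_b[cl == "both_up"]
    genes$lfc_a[cl == "both_down"] <- -e_a[cl == "both_down"]
    genes$lfc_b[cl == "both_down"] <- -e_b[cl == "both_down"]
    genes$lfc_a[cl == "a_up_b_down"] <- e_a[cl == "a_up_b_down"]
    genes$lfc_b[cl == "a_up_b_down"] <- -e_b[cl == "a_up_b_down"]
    genes$lfc_a[cl == "a_down_b_up"] <- -e_a[cl == "a_down_b_up"]
    genes$lfc_b[cl == "a_down_b_up"] <- e_b[cl == "a_down_b_up"]
    conc <- cl %in% c("both_up", "both_down")
    genes$lfc_double[conc] <- sign(genes$lfc_a[conc]) *
      cfg$concordant_exaggeration *
      (abs(genes$lfc_a[conc]) + abs(genes$lfc_b[conc])) / 2
    antag <- cl %in% c("a_up_b_down", "a_down_b_up")
    genes$lfc_double[antag] <- rnorm(sum(antag), 0, cfg$double_residual_sd)
    red <- cl == "redundant"
    genes$lfc_double[red] <- sample(c(-1, 1), sum(red), replace = TRUE) *
      e_a[red]

    # -- blacklist decoys ----------------------------------------------
    host <- unique(round(seq(2, min(per_chr[1], N) - 1,
                             length.out = cfg$n_blacklist)))
    bl_start <- loci$start[host] + 2000
    blacklist <- data.frame(chrom = loci$chrom[host],
                            start = bl_start, end = bl_start + 600,
                            stringsAsFactors = FALSE)
    # decoys sit > merge_gap from both neighboring loci so an unfiltered
    # run keeps them as separate regions
    decoys <- data.frame(chrom = loci$chrom[host],
                         start = bl_start + 50, end = bl_start + 450,
                         stringsAsFactors = FALSE)

    structure(list(config = cfg, genome = genome, loci = loci,
                   genes = genes, blacklist = blacklist, decoys = decoys,
                   realized = list(
                     loss_frac_a = nA_lost / length(a_universe),
                     loss_frac_b = nB_lost / length(b_universe),
                     n_group = c(`1` = length(G1), `2` = length(G2),
                                 `3` = length(G3), `4` = length(G4)),
                     class_counts = table(genes$class))),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d loci on %d chromosome(s), %d genes (seed %d)\n",
              nrow(x$loci), nrow(x$genome), nrow(x$genes), x$config$seed))
  cat(sprintf("  planted loss fractions: A %.3f, B %.3f\n",
              x$realized$loss_frac_a, x$realized$loss_frac_b))
  cat("  group sizes:", paste(sprintf("G%s=%d", names(x$realized$n_group),
                                      x$realized$n_group), collapse = ", "), "\n")
  invisible(x)
}

# Stream ids for derived seeds, one per emitted artifact.
.streams <- local({
  subunits <- c(a = 0L, b = 1L)
  conditions <- c(shNS = 0L, shA = 1L, shB = 2L)
  function(kind, subunit = "a", condition = "shNS") {
    base <- switch(kind, peaks = 100L, coverage = 200L, cofactor = 300L,
                   counts = 400L, de = 500L)
    base + subunits[[subunit]] * 10L + conditions[[condition]]
  }
})

#' Synthetic peak set for one subunit and condition
#'
#' Emits the peaks planted as present for the given subunit/condition,
#' with boundaries jittered by a uniform integer in
#' `[-jitter_bp, jitter_bp]` per side, plus blacklist decoy peaks (so the
#' blacklist-filtering stage has something to remove). Subunit B peaks
#' sit at a small fixed offset from subunit A peaks so the two siblings
#' overlap without being identical. Deterministic given the config.
#'
#' @param truth A [generate_truth()] result.
#' @param subunit `"a"` or `"b"`.
#' @param condition `"shNS"`, `"shA"` or `"shB"`.
#' @param jitter Override of `config$jitter_bp`.
#' @param decoys Include blacklist decoy peaks? Default `TRUE`.
#' @return A `GRanges` peak set named by locus id.
#' @export
synth_peak_set <- function(truth, subunit = c("a", "b"),
                           condition = c("shNS", "shA", "shB"),
                           jitter = NULL, decoys = TRUE) {
  subunit <- match.arg(subunit)
  condition <- match.arg(condition)
  cfg <- truth$config
  if (is.null(jitter)) jitter <- cfg$jitter_bp
  sel <- truth$loci[[paste0("present_", subunit, "_", condition)]]
  loci <- truth$loci[sel, , drop = FALSE]
  off <- if (subunit == "b") 60L else 0L
  chrom <- loci$chrom
  start <- loci$start + off
  end <- loci$end + off
  name <- loci$locus_id
  if (decoys && nrow(truth$decoys) > 0) {
    chrom <- c(chrom, truth$decoys$chrom)
    start <- c(start, truth$decoys$start)
    end <- c(end, truth$decoys$end)
    name <- c(name, sprintf("decoy_%d", seq_len(nrow(truth$decoys))))
  }
  with_seed(derive_seed(cfg$seed, .streams("peaks", subunit, condition)), {
    if (jitter > 0) {
      ds <- sample(seq(-jitter, jitter), length(start), replace = TRUE)
      de <- sample(seq(-jitter, jitter), length(end), replace = TRUE)
      start <- pmax(0, start + ds)
      end <- pmax(start + 1, end + de)
    }
    peak_set(chrom, start, end, name = name,
             score = rep(1000, length(start)),
             summit = as.integer(floor((end - start) / 2)),
             signal = runif(length(start), 5, 15),
             pvalue = rep(10, length(start)),
             qvalue = rep(5, length(start)),
             label = sprintf("subunit %s, %s", toupper(subunit), condition))
  })
}

#' Synthetic coverage track for one subunit and condition
#'
#' Piecewise-constant background noise in `coverage_bin`-bp bins, with
#' plateaus of height `peak_height` over each present peak, widened by
#' the 150-bp fragment extension on both sides.
#'
#' @inheritParams synth_peak_set
#' @param extension Fragment extension in bp (default 150).
#' @return A [coverage_track()].
#' @export
synth_coverage_track <- function(truth, subunit = c("a", "b"),
                                 condition = c("shNS", "shA", "shB"),
                                 extension = 150) {
  subunit <- match.arg(subunit)
  condition <- match.arg(condition)
  cfg <- truth$config
  sel <- truth$loci[[paste0("present_", subunit, "_", condition)]]
  loci <- truth$loci[sel, , drop = FALSE]
  off <- if (subunit == "b") 60L else 0L
  with_seed(derive_seed(cfg$seed, .streams("coverage", subunit, condition)), {
    .piecewise_track(truth$genome,
                     plateau = data.frame(chrom = loci$chrom,
                                          start = pmax(0, loci$start + off - extension),
                                          end = loci$end + off + extension,
                                          height = cfg$peak_height *
                                            runif(nrow(loci), 0.9, 1.1)),
                     bin = cfg$coverage_bin,
                     background = cfg$background_level,
                     noise_sd = cfg$coverage_noise_sd,
                     label = sprintf("coverage %s %s", subunit, condition))
  })
}

#' Synthetic cofactor coverage track
#'
#' A cofactor (e.g. a repressive-complex subunit) whose plateau height at
#' each region that lost subunit B is scaled by the group multiplier:
#' `cofactor_multiplier_lost` where the sibling A is also lost (Group 3)
#' and `cofactor_multiplier_retained` where A is retained (Group 4).
#'
#' @param truth A [generate_truth()] result.
#' @return A [coverage_track()].
#' @export
synth_cofactor_track <- function(truth) {
  cfg <- truth$config
  sel <- !is.na(truth$loci$group) & truth$loci$group %in% c(3L, 4L)
  loci <- truth$loci[sel, , drop = FALSE]
  mult <- ifelse(loci$group == 3L, cfg$cofactor_multiplier_lost,
                 cfg$cofactor_multiplier_retained)
  with_seed(derive_seed(cfg$seed, .streams("cofactor")), {
    .piecewise_track(truth$genome,
                     plateau = data.frame(chrom = loci$chrom,
                                          start = pmax(0, loci$start - 150),
                                          end = loci$end + 150,
                                          height = cfg$peak_height * mult),
                     bin = cfg$coverage_bin,
                     background = cfg$background_level,
                     noise_sd = cfg$coverage_noise_sd,
                     label = "cofactor")
  })
}

# Build a piecewise-constant track: per-bin background noise overridden
# by plateaus. Plateaus must not overlap each other (guaranteed by locus
# spacing).
.piecewise_track <- function(genome, plateau, bin, background, noise_sd,
                             label = NULL) {
  chroms <- character(0); starts <- numeric(0); ends <- numeric(0)
  values <- numeric(0)
  for (i in seq_len(nrow(genome))) {
    c <- genome$chrom[i]
    L <- genome$length[i]
    p <- plateau[plateau$chrom == c, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    edges <- sort(unique(c(seq(0, L, by = bin), L, p$start, p$end)))
    edges <- edges[edges <= L]
    if (edges[length(edges)] < L) edges <- c(edges, L)
    s <- edges[-length(edges)]
    e <- edges[-1]
    nb <- ceiling(L / bin)
    bg <- pmax(0, rnorm(nb, background, noise_sd))
    val <- bg[pmin(nb, floor(s / bin) + 1)]
    if (nrow(p) > 0) {
      j <- findInterval(s, p$start)
      inside <- j >= 1 & j <= nrow(p) & s < p$end[pmax(j, 1)]
      val[inside] <- p$height[j[inside]]
    }
    chroms <- c(chroms, rep(c, length(s)))
    starts <- c(starts, s)
    ends <- c(ends, e)
    values <- c(values, val)
  }
  coverage_track(chroms, starts, ends, values, label = label)
}

#' Synthetic chromatin-state segmentation
#'
#' Three-state segmentation covering each chromosome contiguously:
#' `Strong_Enhancer` around each peak locus midpoint, `Promoter` around
#' desert gene TSS, `Quiescent` elsewhere.
#'
#' @param truth A [generate_truth()] result.
#' @return A `GRanges` with state labels in `name`.
#' @export
synth_segmentation <- function(truth) {
  chroms <- character(0); starts <- numeric(0); ends <- numeric(0)
  states <- character(0)
  deserts <- truth$genes[is.na(truth$genes$locus_id), , drop = FALSE]
  for (i in seq_len(nrow(truth$genome))) {
    c <- truth$genome$chrom[i]
    L <- truth$genome$length[i]
    feat <- rbind(
      data.frame(start = pmax(0, truth$loci$mid[truth$loci$chrom == c] - 500),
                 end = truth$loci$mid[truth$loci$chrom == c] + 500,
                 state = "Strong_Enhancer", stringsAsFactors = FALSE),
      data.frame(start = pmax(0, deserts$pos[deserts$chrom == c] - 200),
                 end = deserts$pos[deserts$chrom == c] + 200,
                 state = "Promoter", stringsAsFactors = FALSE))
    feat <- feat[order(feat$start), , drop = FALSE]
    # clip any accidental overlap in favor of the earlier feature
    if (nrow(feat) > 1)
      feat$start[-1] <- pmax(feat$start[-1], feat$end[-nrow(feat)])
    feat <- feat[feat$start < feat$end, , drop = FALSE]
    cur <- 0
    for (k in seq_len(nrow(feat))) {
      if (feat$start[k] > cur) {
        chroms <- c(chroms, c); starts <- c(starts, cur)
        ends <- c(ends, feat$start[k]); states <- c(states, "Quiescent")
      }
      chroms <- c(chroms, c); starts <- c(starts, feat$start[k])
      ends <- c(ends, feat$end[k]); states <- c(states, feat$state[k])
      cur <- feat$end[k]
    }
    if (cur < L) {
      chroms <- c(chroms, c); starts <- c(starts, cur)
      ends <- c(ends, L); states <- c(states, "Quiescent")
    }
  }
  peak_set(chroms, starts, ends, name = states, label = "segmentation")
}

#' Synthetic TSS annotation
#'
#' @param truth A [generate_truth()] result.
#' @return A [tss_set()] of all planted genes.
#' @export
synth_tss <- function(truth) {
  tss_set(truth$genes$gene_id, truth$genes$chrom, truth$genes$pos,
          truth$genes$strand)
}

#' Synthetic RNA-seq counts for one contrast
#'
#' Negative-binomial counts around planted means: control replicates at
#' the baseline mean, knockdown replicates at `baseline * 2^lfc` for the
#' contrast's planted fold change, with per-sample depth factors drawn
#' uniformly from 0.7-1.3 (so size-factor normalization has work to do).
#'
#' @param truth A [generate_truth()] result.
#' @param contrast `"shA"`, `"shB"` or `"double"`.
#' @return List with `counts` (genes x samples integer matrix) and
#'   `group` (factor, control level first).
#' @export
synth_counts <- function(truth, contrast = c("shA", "shB", "double")) {
  contrast <- match.arg(contrast)
  cfg <- truth$config
  lfc <- switch(contrast, shA = truth$genes$lfc_a,
                shB = truth$genes$lfc_b, double = truth$genes$lfc_double)
  reps <- cfg$replicates
  stream <- .streams("counts", "a",
                     c(shA = "shNS", shB = "shA", double = "shB")[[contrast]])
  with_seed(derive_seed(cfg$seed, stream), {
    mu <- cbind(matrix(truth$genes$base_mean, nrow(truth$genes), reps),
                matrix(truth$genes$base_mean * 2^lfc, nrow(truth$genes), reps))
    depth <- runif(2 * reps, 0.7, 1.3)
    mu <- sweep(mu, 2, depth, "*")
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / cfg$nb_dispersion),
                     nrow = nrow(mu),
                     dimnames = list(truth$genes$gene_id,
                                     c(sprintf("ctrl_%d", seq_len(reps)),
                                       sprintf("kd_%d", seq_len(reps)))))
    list(counts = counts,
         group = factor(rep(c("ctrl", "kd"), each = reps),
                        levels = c("ctrl", "kd")))
  })
}

#' Synthetic DE table for one contrast
#'
#' Two emission modes: `"direct"` writes the planted fold changes with
#' p-values marking a gene significant exactly when its planted |lfc|
#' reaches `effect_size_min` (isolating downstream stages from the DE
#' fit), and `"counts"` simulates counts via [synth_counts()] and runs
#' them through [simple_de()].
#'
#' @param truth A [generate_truth()] result.
#' @param contrast `"shA"`, `"shB"` or `"double"`.
#' @param mode `"direct"` or `"counts"`.
#' @return A validated DE `data.frame`.
#' @export
synth_de_table <- function(truth, contrast = c("shA", "shB", "double"),
                           mode = c("direct", "counts")) {
  contrast <- match.arg(contrast)
  mode <- match.arg(mode)
  cfg <- truth$config
  if (mode == "counts") {
    cc <- synth_counts(truth, contrast)
    return(simple_de(cc$counts, cc$group))
  }
  lfc <- switch(contrast, shA = truth$genes$lfc_a,
                shB = truth$genes$lfc_b, double = truth$genes$lfc_double)
  stream <- .streams("de", "b",
                     c(shA = "shNS", shB = "shA", double = "shB")[[contrast]])
  with_seed(derive_seed(cfg$seed, stream), {
    affected <- abs(lfc) >= cfg$effect_size_min
    p <- ifelse(affected, 1e-8, runif(length(lfc), 0.25, 1))
    validate_de_table(data.frame(gene_id = truth$genes$gene_id,
                                 mean_expr = truth$genes$base_mean,
                                 log2fc = lfc, pvalue = p,
                                 qvalue = bh_adjust(p),
                                 stringsAsFactors = FALSE))
  })
}

#' Emit all synthetic datasets to disk
#'
#' Writes narrowPeak files per subunit and condition, bedGraph coverage
#' per subunit and condition plus the cofactor track, the blacklist,
#' segmentation and TSS BEDs, counts and DE TSVs per contrast, and a
#' truth JSON. Byte-identical across runs for a given config.
#'
#' @param truth A [generate_truth()] result.
#' @param outdir Output directory (created if needed).
#' @param de_mode DE emission mode, see [synth_de_table()].
#' @param tracks Emit coverage bedGraphs? Default `TRUE`.
#' @param counts Emit counts TSVs? Default `TRUE`.
#' @return Named list of file paths (the manifest), invisibly; also
#'   written as `manifest.json`.
#' @export
emit_datasets <- function(truth, outdir, de_mode = c("direct", "counts"),
                          tracks = TRUE, counts = TRUE) {
  de_mode <- match.arg(de_mode)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  p <- function(f) file.path(outdir, f)
  for (su in c("a", "b")) for (cond in c("shNS", "shA", "shB")) {
    f <- p(sprintf("peaks_%s_%s.narrowPeak", su, cond))
    write_peaks(synth_peak_set(truth, su, cond), f, format = "narrowPeak")
    manifest[[sprintf("peaks_%s_%s", su, cond)]] <- f
  }
  bl <- truth$blacklist
  writeLines(sprintf("%s\t%d\t%d", bl$chrom, bl$start, bl$end),
             p("blacklist.bed"))
  manifest$blacklist <- p("blacklist.bed")
  seg <- synth_segmentation(truth)
  write.table(data.frame(as.character(GenomeInfoDb::seqnames(seg)),
                         bed_start(seg), bed_end(seg),
                         S4Vectors::mcols(seg)$name),
              p("segmentation.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  manifest$segmentation <- p("segmentation.bed")
  write_tss(synth_tss(truth), p("tss.bed"))
  manifest$tss <- p("tss.bed")
  if (tracks) {
    for (su in c("a", "b")) for (cond in c("shNS", "shA", "shB")) {
      f <- p(sprintf("coverage_%s_%s.bedGraph", su, cond))
      write_bedgraph(synth_coverage_track(truth, su, cond), f)
      manifest[[sprintf("coverage_%s_%s", su, cond)]] <- f
    }
    write_bedgraph(synth_cofactor_track(truth), p("cofactor.bedGraph"))
    manifest$cofactor <- p("cofactor.bedGraph")
  }
  for (contrast in c("shA", "shB", "double")) {
    if (counts) {
      cc <- synth_counts(truth, contrast)
      f <- p(sprintf("counts_%s.tsv", contrast))
      write.table(data.frame(gene_id = rownames(cc$counts), cc$counts,
                             check.names = FALSE),
                  f, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest[[sprintf("counts_%s", contrast)]] <- f
    }
    f <- p(sprintf("de_%s.tsv", contrast))
    write_de_table(synth_de_table(truth, contrast, mode = de_mode), f)
    manifest[[sprintf("de_%s", contrast)]] <- f
  }
  jsonlite::write_json(list(config = unclass(truth$config),
                            genome = truth$genome, loci = truth$loci,
                            genes = truth$genes,
                            blacklist = truth$blacklist),
                       p("truth.json"), auto_unbox = TRUE, digits = NA)
  manifest$truth <- p("truth.json")
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Score pipeline outputs against the planted truth
#'
#' Matches recovered regions to planted loci by overlap and recovered
#' gene categories to planted classes by gene id, and reports per-stage
#' recovery metrics.
#'
#' @param truth A [generate_truth()] result.
#' @param results Named list with any of: `fate_a`, `fate_b`
#'   ([classify_fate()] tables on the merged control peaks), `groups_a`,
#'   `groups_b` ([cross_classify()] tables), `categories`
#'   ([quadrant_categorize()] table), `rescue` ([rescue_analysis()]
#'   records).
#' @return List of class `recovery_report`: per-stage accuracies, the
#'   category confusion matrix, rescue medians per planted class, and
#'   signed loss-fraction errors.
#' @export
score_recovery <- function(truth, results) {
  loci_gr <- peak_set(truth$loci$chrom, truth$loci$start, truth$loci$end,
                      name = truth$loci$locus_id)
  match_loci <- function(df) {
    gr <- regions_of(df)
    # small gap tolerance: emitted sibling peaks sit at a fixed offset
    # and jitter can shrink a region past its locus boundary
    hit <- GenomicRanges::findOverlaps(gr, loci_gr, select = "first",
                                       maxgap = 200, ignore.strand = TRUE)
    if (anyNA(hit)) stop("recovered region matches no planted locus")
    hit
  }
  rep <- list()
  for (su in c("a", "b")) {
    ft <- results[[paste0("fate_", su)]]
    if (!is.null(ft)) {
      hit <- match_loci(ft)
      planted <- truth$loci[[paste0("fate_", su)]][hit]
      rep[[paste0("fate_accuracy_", su)]] <- mean(ft$fate == planted)
      rec_frac <- mean(ft$fate == "lost")
      rep[[paste0("lost_fraction_", su)]] <- rec_frac
      rep[[paste0("lost_fraction_error_", su)]] <-
        rec_frac - truth$realized[[paste0("loss_frac_", su)]]
    }
    gt <- results[[paste0("groups_", su)]]
    if (!is.null(gt)) {
      hit <- match_loci(gt)
      planted <- truth$loci[[paste0("status_", su)]][hit]
      rep[[paste0("group_accuracy_", su)]] <- mean(gt$status == planted)
    }
  }
  if (!is.null(results$categories)) {
    cat_map <- c(both_up = "both_up", both_down = "both_down",
                 a_up_b_down = "a_up_b_down", a_down_b_up = "a_down_b_up")
    planted <- truth$genes$class
    names(planted) <- truth$genes$gene_id
    recovered <- setNames(results$categories$category,
                          results$categories$gene_id)
    quadrant_genes <- truth$genes$gene_id[planted %in% names(cat_map)]
    all_genes <- union(quadrant_genes, names(recovered))
    confusion <- table(planted = planted[all_genes],
                       recovered = ifelse(all_genes %in% names(recovered),
                                          recovered[all_genes],
                                          "uncategorized"))
    correct <- sum(recovered[quadrant_genes] ==
                     planted[quadrant_genes], na.rm = TRUE)
    rep$category_accuracy <- correct / length(quadrant_genes)
    rep$category_false_positives <-
      sum(!(names(recovered) %in% quadrant_genes))
    rep$category_confusion <- confusion
    rep$category_counts <- table(results$categories$category)
  }
  if (!is.null(results$rescue)) {
    planted <- truth$genes$class[match(results$rescue$gene_id,
                                       truth$genes$gene_id)]
    rep$rescue_median_by_class <-
      tapply(results$rescue$rescue_index, planted, median)
  }
  structure(rep, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.table(v)) {
      cat(nm, ":\n", sep = ""); print(v)
    } else {
      cat(sprintf("%s: %s\n", nm,
                  paste(format(v, digits = 4), collapse = ", ")))
    }
  }
  invisible(x)
}
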
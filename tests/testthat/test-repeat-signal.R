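sizes <- c(chr1 = 100000L)

frag <- function(starts, width, id = "s1", lib = NULL, spike = 0) {
  gr <- with_chrom_sizes(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(starts, width = width)), sizes)
  fragment_set(id, gr, library_size = lib %||% length(gr),
               spikein_size = spike)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

reps3 <- local({
  gr <- with_chrom_sizes(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 1400, 5000, 9000), width = 300)), sizes)
  S4Vectors::mcols(gr)$repeat_name <- c("IAPEz", "IAPEz", "IAPEz", "L1Md")
  S4Vectors::mcols(gr)$repeat_family <- c("ERVK", "ERVK", "ERVK", "L1")
  S4Vectors::mcols(gr)$repeat_class <- c("LTR", "LTR", "LTR", "LINE")
  repeat_annotation(gr)
})

test_that("per-repeat summation deduplicates within a label", {
  # one fragment inside one instance
  cm1 <- sum_reads_per_repeat(frag(1100, 100), reps3, "repeat_name")
  expect_equal(cm1$counts["IAPEz", "s1"], 1L)
  # a fragment bridging two adjacent same-name instances counts once
  cm2 <- sum_reads_per_repeat(frag(1250, 300), reps3, "repeat_name")
  expect_equal(cm2$counts["IAPEz", "s1"], 1L)
  expect_error(sum_reads_per_repeat(frag(1, 10), reps3[0], "repeat_name"),
               "empty")
})

test_that("per-group counts equal the brute-force oracle", {
  set.seed(51)
  f <- frag(sample(99000L, 5000, replace = TRUE), 200)
  for (key in c("repeat_name", "repeat_family")) {
    cm <- sum_reads_per_repeat(f, reps3, key)
    oracle <- oracle_label_hits(f$fragments, reps3,
                                S4Vectors::mcols(reps3)[[key]])
    expect_identical(cm$counts[names(oracle), "s1"], oracle)
  }
})

test_that("cpm normalization matches its definition and is scale-invariant", {
  cm <- count_matrix(matrix(c(10, 20), 1, 2,
                            dimnames = list("f", c("a", "b"))),
                     library_size = c(a = 2e6, b = 2e6),
                     spikein_size = c(a = 1e5, b = 2e5))
  expect_equal(normalize_counts(cm, "library_size", prior_count = 0),
               matrix(c(5, 10), 1, 2, dimnames = list("f", c("a", "b"))))
  # joint doubling of counts and denominators changes nothing; the prior
  # is an absolute pseudocount on the mean-depth scale, so exact
  # invariance is the prior-free property
  cm2 <- count_matrix(2 * cm$counts, 2 * cm$library_size,
                      2 * cm$spikein_size)
  expect_equal(unname(normalize_counts(cm, "library_size", 0)),
               unname(normalize_counts(cm2, "library_size", 0)))
  expect_equal(unname(normalize_counts(cm, "spikein", 0)),
               unname(normalize_counts(cm2, "spikein", 0)))
  # equal counts at equal depth give equal values regardless of prior
  cm3 <- count_matrix(matrix(c(7, 7), 1, 2), c(1e6, 1e6), c(5e4, 5e4))
  v <- normalize_counts(cm3, "spikein", 3)
  expect_equal(v[1, 1], v[1, 2])
  cm4 <- count_matrix(matrix(1, 1, 1), 1e6, c(s = 0))
  expect_error(normalize_counts(cm4, "spikein"), "denominator")
})

test_that("spike-in mode exposes a global efficiency loss that library-size
           mode cancels", {
  sg <- toy_genome(23)
  cfg <- chip_sim_config(5, n_replicates = 1, fragments_per_replicate = 1e5,
                         enrichment = c(ERVK = 6), spikein_fraction = 0.05)
  sc <- simulate_chip_fragments(sg, cfg)
  a <- sc$chip[[1]]
  # 2x efficiency loss: thin mouse fragments to half, spike-ins unchanged
  set.seed(61)
  keep <- sample(length(a$fragments), length(a$fragments) / 2)
  b <- fragment_set("lost", a$fragments[sort(keep)],
                    library_size = a$library_size / 2,
                    spikein_size = a$spikein_size)
  cm <- sum_reads_per_repeat(list(a, b), sg$repeats, "repeat_family")
  lib <- normalize_counts(cm, "library_size", prior_count = 0)
  spk <- normalize_counts(cm, "spikein", prior_count = 0)
  ratio_lib <- lib[, "lost"] / lib[, "chip_rep1"]
  ratio_spk <- spk[, "lost"] / spk[, "chip_rep1"]
  expect_true(all(abs(ratio_lib - 1) < 0.1))
  expect_true(all(abs(ratio_spk - 0.5) < 0.05))
})

test_that("signal matrix places counts in the right bins", {
  anchors <- with_chrom_sizes(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(5000, 5000)), sizes)
  S4Vectors::mcols(anchors)$summit <- 5000L
  # single fragment exactly covering the central-right bin [5000, 5049]
  f <- frag(5000, 50, lib = 1e6)
  bs <- signal_matrix(f, anchors, flank = 200L, bin_width = 50L)
  m <- bs$matrices$s1
  expect_equal(dim(m), c(1, 8))
  nz <- which(m[1, ] > 0)
  expect_equal(nz, 5L)  # bins: -200..-151,...,-50..-1,[0..49] is 5th
  expect_equal(m[1, 5], 1)
  # window exceeding the chromosome: missing bins are NA, not zero
  a2 <- with_chrom_sizes(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(60, 60)), sizes)
  S4Vectors::mcols(a2)$summit <- 60L
  bs2 <- signal_matrix(f, a2, flank = 200L, bin_width = 50L)
  expect_true(any(is.na(bs2$matrices$s1)))
  expect_false(any(is.na(bs2$matrices$s1[, 6:8])))
  expect_error(signal_matrix(f, anchors, flank = 170L, bin_width = 50L),
               "multiple")
})

test_that("planted local enrichment is recovered in the central bins", {
  set.seed(71)
  hot <- seq(10000, 90000, by = 4000)
  cold <- hot + 2000
  # 5x more fragments at hot anchors over a sparse uniform background
  starts <- c(rep(hot, each = 50) + sample(-50:50, 50 * length(hot), TRUE),
              rep(cold, each = 10) + sample(-50:50, 10 * length(cold), TRUE),
              sample(99500L, 500, replace = TRUE))
  f <- frag(pmax(1L, starts), 100)
  anchors <- with_chrom_sizes(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(hot, cold), width = 1)), sizes)
  S4Vectors::mcols(anchors)$summit <- c(hot, cold)
  bs <- signal_matrix(f, anchors, flank = 500L, bin_width = 100L)
  # undo waterfall ordering to address hot vs cold rows
  m <- bs$matrices$s1[order(bs$order), , drop = FALSE]
  central <- 5:6
  hot_mean <- mean(m[seq_along(hot), central])
  cold_mean <- mean(m[length(hot) + seq_along(cold), central])
  expect_gt(hot_mean / cold_mean, 4)
  expect_lt(hot_mean / cold_mean, 6.5)
  # waterfall rows are ordered by descending mean
  rm <- rowMeans(bs$matrices$s1, na.rm = TRUE)
  expect_true(all(diff(rm) <= 1e-12))
})

test_that("genome bins tile chromosomes and conserve fragment mass", {
  f <- frag(c(500, 1500, 999), 100)   # third fragment spans a bin boundary
  gb <- genome_binned_signal(list(f), bin_width = 1000L)
  expect_equal(nrow(gb), 100)
  raw <- gb$s1 * f$library_size / 1e6
  expect_equal(sum(raw), 4)  # 3 fragments, one counted in two bins
  f2 <- frag(c(500, 1500), 100)
  gb2 <- genome_binned_signal(list(f2), bin_width = 1000L)
  expect_equal(sum(gb2$s1 * f2$library_size / 1e6), 2)
})

test_that("shared enrichment loci induce cross-sample bin correlation", {
  set.seed(81)
  loci <- sample(90000L, 30)
  draw <- function(id) {
    starts <- c(rep(loci, each = 20) + sample(-300:300, 600, TRUE),
                sample(99000L, 2000, TRUE))
    frag(pmax(1L, starts), 150, id = id)
  }
  r_shared <- r_indep <- numeric(10)
  for (k in 1:10) {
    a <- draw("a"); b <- draw("b")
    ga <- genome_binned_signal(list(a, b), 1000L)
    r_shared[k] <- cor(ga$a, ga$b)
    u1 <- frag(sample(99000L, 2600, TRUE), 150, id = "a")
    u2 <- frag(sample(99000L, 2600, TRUE), 150, id = "b")
    gu <- genome_binned_signal(list(u1, u2), 1000L)
    r_indep[k] <- cor(gu$a, gu$b)
  }
  expect_gt(mean(r_shared), mean(r_indep))
})
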
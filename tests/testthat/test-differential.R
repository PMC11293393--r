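test_that("TMM factors: identity, constructed scaling, trimming robustness", {
  set.seed(131)
  mu <- exp(runif(500, log(20), log(2000)))
  a <- rnbinom(500, mu = mu, size = 10)
  cm_id <- count_matrix(cbind(s1 = a, s2 = a), c(s1 = sum(a), s2 = sum(a)))
  f_id <- trimmed_mean_factors(cm_id)
  expect_equal(f_id$compositional, c(1, 1), tolerance = 1e-12)

  # B = 2x A count-wise at equal library size -> effective ratio ~ 2
  b <- 2L * a
  cm2 <- count_matrix(cbind(s1 = a, s2 = b), c(s1 = 1e6, s2 = 1e6))
  f2 <- trimmed_mean_factors(cm2)
  expect_equal(f2$effective[2] / f2$effective[1], 2, tolerance = 0.01)

  # 10% of features shifted 8x: majority compositional factor ~ 1
  d <- a
  idx <- sample(500, 50)
  d[idx] <- 8L * d[idx]
  cmc <- count_matrix(cbind(s1 = a, s2 = d), c(s1 = 1e6, s2 = 1e6))
  fc <- trimmed_mean_factors(cmc)
  # ratio of compositional factors, majority-anchored: sample 2 carries
  # 8x contamination, the unchanged majority should keep the ratio near 1
  expect_lt(abs(fc$compositional[2] / fc$compositional[1] - 1), 0.05)
  # geometric mean of compositional factors is 1
  expect_lt(abs(mean(log(fc$compositional))), 1e-6)
})

test_that("TMM factors track the edgeR reference on well-behaved data", {
  skip_if_not_installed("edgeR")
  set.seed(132)
  mu <- exp(runif(400, log(50), log(5000)))
  y <- sapply(c(1, 1.5, 0.7, 1.2), function(f)
    rnbinom(400, mu = f * mu, size = 5))
  colnames(y) <- paste0("s", 1:4)
  cm <- count_matrix(y, setNames(colSums(y), colnames(y)))
  mine <- trimmed_mean_factors(cm, ref_sample = 1)
  ref <- edgeR::calcNormFactors(y, refColumn = 1, method = "TMM")
  ref <- unname(ref / exp(mean(log(ref))))
  expect_equal(mine$compositional, ref, tolerance = 0.05)
})

test_that("NB test keeps type-I error near nominal under the null", {
  fp <- 0
  for (s in 1:20) {
    sim <- simulate_count_matrix(count_sim_config(400 + s, 200, c(3, 3),
                                                  200, 0.1))
    res <- nb_differential(sim$counts, sim$groups)
    fp <- fp + sum(res$pvalue < 0.05)
  }
  expect_gt(fp / (20 * 200), 0.02)
  expect_lt(fp / (20 * 200), 0.09)
})

test_that("prior count keeps log2FC finite and zero rows are null", {
  y <- rbind(c(0L, 0L, 0L, 50L, 60L, 55L),
             c(0L, 0L, 0L, 0L, 0L, 0L),
             c(30L, 35L, 25L, 30L, 35L, 25L))
  rownames(y) <- c("up", "zero", "flat")
  groups <- rep(c("a", "b"), each = 3)
  res <- nb_differential(y, groups)
  expect_true(all(is.finite(res$log2FC)))
  expect_gt(res$log2FC[1], 2)
  expect_equal(res$pvalue[2], 1)
  expect_equal(res$log2FC[2], 0)
  expect_error(nb_differential(y, c("a", "a", "a", "a", "a", "b")), "2 samples")
})

test_that("BH adjustment is rank-monotone and order-invariant", {
  set.seed(141)
  sim <- simulate_count_matrix(count_sim_config(9, 100, c(3, 3), 150, 0.1,
                                                1:5, 2))
  res <- nb_differential(sim$counts, sim$groups)
  o <- order(res$pvalue)
  expect_true(all(diff(res$FDR[o]) >= -1e-12))
  perm <- sample(nrow(sim$counts))
  res_p <- nb_differential(sim$counts[perm, ], sim$groups)
  expect_equal(res_p$FDR, res$FDR[perm], tolerance = 1e-12)
})

test_that("spike-in normalized differential recovers a global binding loss", {
  # mutant with 4x reduced binding at 20 families, fixed spike-ins:
  # counts scaled 1/4 in the mutant, spike-in denominators equal
  set.seed(151)
  n_fam <- 25
  mu <- exp(runif(n_fam, log(300), log(3000)))
  wt <- sapply(1:2, function(i) rnbinom(n_fam, mu = mu, size = 20))
  mut_mu <- mu
  mut_mu[1:20] <- mu[1:20] / 4
  mut <- sapply(1:2, function(i) rnbinom(n_fam, mu = mut_mu, size = 20))
  y <- cbind(wt, mut)
  colnames(y) <- c("wt1", "wt2", "mut1", "mut2")
  rownames(y) <- paste0("fam", 1:n_fam)
  cm <- count_matrix(y, library_size = setNames(rep(1e6, 4), colnames(y)),
                     spikein_size = setNames(rep(5e4, 4), colnames(y)))
  fac <- data.frame(sample = colnames(y), denominator = 5e4,
                    compositional = 1, effective = 5e4)
  class(fac) <- c("norm_factors", "data.frame")
  res <- nb_differential(cm, factor(c("wt", "wt", "mut", "mut"),
                                    levels = c("wt", "mut")), factors = fac)
  hit <- res$sig[1:20] & res$log2FC[1:20] < 0
  expect_gte(sum(hit), 18)
})

test_that("EM assignment: degenerate, fixed-point and conservation cases", {
  # all unique reads: EM equals direct counting exactly
  A <- Matrix::sparseMatrix(i = 1:30, j = rep(1:3, each = 10), x = 1,
                            dims = c(30, 3))
  colnames(A) <- c("f1", "f2", "f3")
  em <- em_assign_multireads(A)
  expect_equal(unname(em$counts), c(10, 10, 10), tolerance = 1e-9)
  expect_lte(em$iterations, 2L)  # converges immediately

  # two features, unique support 9 and 1, 10 ambiguous reads
  A2 <- Matrix::sparseMatrix(
    i = c(1:9, 10, rep(11:20, 2)),
    j = c(rep(1, 9), 2, rep(1, 10), rep(2, 10)), x = 1, dims = c(20, 2))
  em2 <- em_assign_multireads(A2, tol = 1e-10)
  oracle <- oracle_two_feature_em(9, 1, 10)
  expect_equal(unname(em2$counts), unname(oracle), tolerance = 1e-4)
  expect_equal(sum(em2$counts), 20, tolerance = 1e-9)
  # log-likelihood is non-decreasing
  expect_true(all(diff(em2$loglik) >= -1e-10))

  # mass conservation on a random sparse fixture
  set.seed(161)
  n_reads <- 500; n_feat <- 40
  j <- lapply(1:n_reads, function(i) sample(n_feat, sample(1:4, 1)))
  A3 <- Matrix::sparseMatrix(
    i = rep(seq_len(n_reads), lengths(j)), j = unlist(j), x = 1,
    dims = c(n_reads, n_feat))
  em3 <- em_assign_multireads(A3)
  expect_equal(sum(em3$counts), n_reads, tolerance = 1e-9)
  expect_true(all(diff(em3$loglik) >= -1e-8))
  expect_error(em_assign_multireads(A3[0, , drop = FALSE]), "empty")
})

test_that("compat matrix + instance EM + family roll-up pipeline runs", {
  sg <- toy_genome(31)
  sc <- simulate_chip_fragments(sg, chip_sim_config(
    1, n_replicates = 1, fragments_per_replicate = 3000))
  # reduce fragments to midpoints: with non-overlapping instances every
  # read is then structurally unique, making EM equal direct counting
  fr <- sc$chip[[1]]$fragments
  mid <- floor((GenomicRanges::start(fr) + GenomicRanges::end(fr)) / 2)
  ms <- fragment_set("mid", with_chrom_sizes(
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(fr),
                           IRanges::IRanges(mid, mid)), sg$chrom_sizes))
  cmpt <- compat_matrix(ms, sg$repeats,
                        feature_names = paste0("inst", seq_along(sg$repeats)))
  expect_true(all(Matrix::rowSums(cmpt) == 1))
  em <- em_assign_multireads(cmpt)
  fam_counts <- rollup_counts(em$counts,
                              S4Vectors::mcols(sg$repeats)$repeat_family)
  expect_equal(sum(fam_counts), sum(em$counts), tolerance = 1e-6)
  direct <- sum_reads_per_repeat(ms, sg$repeats, "repeat_family")
  expect_equal(fam_counts[rownames(direct$counts)],
               setNames(as.numeric(direct$counts[, 1]),
                        rownames(direct$counts)),
               tolerance = 1e-6)
})
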
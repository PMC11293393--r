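test_that("stitched model is LTR + internal + LTR with exact junctions", {
  set.seed(91)
  ltr <- teseq:::random_dna(50)
  internal <- teseq:::random_dna(200)
  m <- stitch_consensus(internal, ltr, "toy")
  expect_equal(nchar(m$sequence), 300L)
  expect_equal(m$segments$start, c(1L, 51L, 251L))
  expect_equal(m$segments$end, c(50L, 250L, 300L))
  expect_identical(m$sequence, paste0(ltr, internal, ltr))
  expect_identical(model_segment(m, "LTR_3p"), ltr)
  expect_identical(model_segment(m, "internal"), internal)
  expect_error(stitch_consensus("", ltr), "empty")
  expect_error(stitch_consensus("ACGU", ltr), "invalid")
})

test_that("repeat-overlapping fragments are extracted exactly, with sequence", {
  sg <- toy_genome(29)
  sc <- simulate_chip_fragments(sg, chip_sim_config(
    1, n_replicates = 1, fragments_per_replicate = 5000))
  f <- sc$chip[[1]]
  ex <- extract_repeat_fragments(f, sg$repeats, "IAPEz-int", sg$genome)
  targets <- sg$repeats[S4Vectors::mcols(sg$repeats)$repeat_name == "IAPEz-int"]
  keep_oracle <- oracle_query_hits(f$fragments, targets) > 0
  expect_equal(length(ex$fragments), sum(keep_oracle))
  expect_identical(GenomicRanges::start(ex$fragments),
                   GenomicRanges::start(f$fragments[keep_oracle]))
  # attached sequences match the genome at those coordinates
  g1 <- ex$fragments[1]
  expect_identical(
    S4Vectors::mcols(ex$fragments)$sequence[1],
    substr(as.character(sg$genome[[as.character(GenomeInfoDb::seqnames(g1))]]),
           GenomicRanges::start(g1), GenomicRanges::end(g1)))
  expect_error(extract_repeat_fragments(f, sg$repeats, "NoSuchRepeat"),
               "NoSuchRepeat")
})

test_that("boundary fragments one base outside all instances are dropped", {
  sizes <- c(chr1 = 10000L)
  reps <- repeat_annotation(with_chrom_sizes(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1000, 1299), repeat_name = "R",
    repeat_family = "F", repeat_class = "C"), sizes))
  mk <- function(s, e) fragment_set("x", with_chrom_sizes(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e)), sizes))
  expect_length(extract_repeat_fragments(mk(900, 999), reps, "R")$fragments, 0)
  expect_length(extract_repeat_fragments(mk(900, 1000), reps, "R")$fragments, 1)
  expect_length(extract_repeat_fragments(mk(1299, 1400), reps, "R")$fragments, 1)
  expect_length(extract_repeat_fragments(mk(1300, 1400), reps, "R")$fragments, 0)
})

test_that("seeded aligner agrees with the exhaustive-offset oracle", {
  set.seed(101)
  ltr <- teseq:::random_dna(80)
  internal <- teseq:::random_dna(440)
  m <- stitch_consensus(internal, ltr, "toy")
  # exact substring: unambiguous placement inside the internal segment
  read <- substr(m$sequence, 101, 150)
  al <- align_to_consensus(read, m)
  expect_true(al$aligned)
  expect_equal(al$start, 101L)
  expect_equal(al$end, 150L)
  expect_equal(al$mismatches, 0L)

  # reads with <= 2 substitutions (guaranteed exact seed among 3 seeds)
  n <- 300
  pos <- sample(nchar(m$sequence) - 49L, n, replace = TRUE)
  reads <- vapply(seq_len(n), function(i) {
    r <- substr(m$sequence, pos[i], pos[i] + 49L)
    substitute_bases(r, sample(0:2, 1))
  }, character(1))
  rc <- sample(c(TRUE, FALSE), n, replace = TRUE)
  reads[rc] <- teseq:::revcomp(reads[rc])
  al <- align_to_consensus(reads, m, seed_length = 15, max_mismatch_rate = 0.1)
  for (i in seq_len(n)) {
    o <- oracle_align(reads[i], m$sequence, 0.1)
    expect_equal(al$aligned[i], !is.null(o))
    if (!is.null(o)) {
      expect_equal(al$start[i], o$start)
      expect_equal(al$end[i], o$end)
      expect_equal(al$strand[i], o$strand)
      expect_equal(al$mismatches[i], o$mismatches)
    }
  }
  # a read from inside the LTR maps leftmost (LTR_5p), deterministically
  ltr_read <- substr(ltr, 11, 60)
  al_ltr <- align_to_consensus(ltr_read, m)
  expect_equal(al_ltr$start, 11L)

  # random read with no seed hit stays unaligned
  junk <- paste(rep("A", 50), collapse = "")
  expect_false(align_to_consensus(junk, m)$aligned)
  expect_error(align_to_consensus("ACGTACGT", m, seed_length = 20), "seed")
})

test_that("coverage accumulates alignment spans and conserves mass", {
  m <- stitch_consensus(paste(rep("C", 200), collapse = ""),
                        paste(rep("A", 50), collapse = ""))
  a <- data.frame(read_id = 1:2, start = c(100L, 120L), end = c(149L, 169L),
                  strand = "+", mismatches = 0L, score = 50L, aligned = TRUE)
  tr <- consensus_coverage(list(r1 = a, r2 = a), m,
                           c(r1 = 1e6, r2 = 1e6))
  expect_equal(unname(tr$cpm[105, "r1"]), 1)
  expect_equal(unname(tr$cpm[130, "r1"]), 2)
  expect_equal(unname(tr$cpm[99, "r1"]), 0)
  # identical replicates: SD identically zero
  expect_true(all(tr$sd == 0))
  # mass conservation: sum of raw depth equals sum of aligned lengths
  expect_equal(sum(tr$cpm[, "r1"]) * 1e6 / 1e6, 100)
  bad <- a; bad$end[1] <- 9999L
  expect_error(consensus_coverage(list(r1 = bad), m, c(r1 = 1e6)), "bounds")
})

test_that("uniform sampling yields a flat replicate-mean trace", {
  set.seed(111)
  m <- stitch_consensus(teseq:::random_dna(1400), teseq:::random_dna(300))
  L <- nchar(m$sequence)
  n_reads <- round(20 * L / 50)   # 20x depth, 50 bp reads
  mk_rep <- function(id) {
    pos <- sample(L - 49L, n_reads, replace = TRUE)
    data.frame(read_id = seq_len(n_reads), start = pos, end = pos + 49L,
               strand = "+", mismatches = 0L, score = 50L, aligned = TRUE)
  }
  reps <- lapply(1:8, mk_rep)
  names(reps) <- paste0("r", 1:8)
  tr <- consensus_coverage(reps, m, setNames(rep(1e6, 8), names(reps)))
  central <- seq(ceiling(0.05 * L), floor(0.95 * L))
  g <- mean(tr$mean[central])
  expect_true(all(abs(tr$mean[central] - g) / g < 0.25))
})

test_that("LTR-planted fragments give LTR-dominant traces", {
  set.seed(121)
  ltr <- teseq:::random_dna(300)
  m <- stitch_consensus(teseq:::random_dna(1400), ltr)
  # reads only from the LTR sequence
  pos <- sample(251L, 400, replace = TRUE)
  reads <- substring(ltr, pos, pos + 49L)
  al <- align_to_consensus(reads, m)
  expect_true(all(al$aligned))
  tr <- consensus_coverage(list(r1 = al), m, c(r1 = 1e6))
  sm <- segment_means(tr)
  ltr_mean <- mean(sm$mean_cpm[sm$segment != "internal"])
  int_mean <- sm$mean_cpm[sm$segment == "internal"]
  expect_gt(ltr_mean / max(int_mean, 1e-9), 5)
})
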
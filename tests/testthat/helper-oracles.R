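# Independent brute-force oracles and small fixture builders.  Every oracle
# here deliberately avoids the package's fast paths (findOverlaps, k-mer
# seeding, vectorized EM) so that tests compare two independent routes.

# O(n*m) pairwise overlap: same chromosome, >=1 shared base, strand ignored
oracle_overlap <- function(query, subject) {
  qc <- as.character(GenomeInfoDb::seqnames(query))
  sc <- as.character(GenomeInfoDb::seqnames(subject))
  qs <- GenomicRanges::start(query); qe <- GenomicRanges::end(query)
  ss <- GenomicRanges::start(subject); se <- GenomicRanges::end(subject)
  hits <- matrix(FALSE, length(query), length(subject))
  for (i in seq_along(query))
    for (j in seq_along(subject))
      hits[i, j] <- qc[i] == sc[j] && qs[i] <= se[j] && qe[i] >= ss[j]
  hits
}

oracle_query_hits <- function(query, subject) {
  as.integer(rowSums(oracle_overlap(query, subject)))
}

# per-label presence tally: number of queries hitting >=1 subject of a label
oracle_label_hits <- function(query, subject, label) {
  hits <- oracle_overlap(query, subject)
  labels <- sort(unique(label))
  out <- integer(length(labels))
  names(out) <- labels
  for (k in seq_along(labels))
    out[k] <- sum(apply(hits[, label == labels[k], drop = FALSE], 1, any))
  out
}

# random intervals governed by a size table
random_intervals <- function(n, chrom_sizes, max_width = 500L) {
  ci <- sample(length(chrom_sizes), n, replace = TRUE)
  w <- sample(max_width, n, replace = TRUE)
  w <- pmin(w, chrom_sizes[ci])
  start <- vapply(seq_len(n), function(i)
    sample(chrom_sizes[ci[i]] - w[i] + 1L, 1), integer(1))
  with_chrom_sizes(
    GenomicRanges::GRanges(names(chrom_sizes)[ci],
                           IRanges::IRanges(start, width = w)),
    chrom_sizes)
}

# exhaustive all-offsets ungapped alignment oracle, both strands,
# full-read placements only; tie-break: score desc, start asc, "+" first.
# No seeding anywhere: every placement is scored.
oracle_align <- function(read, cons, max_mismatch_rate = 0.1) {
  best <- NULL
  clen <- nchar(cons)
  craw <- charToRaw(cons)
  for (strand in c("+", "-")) {
    seq <- if (strand == "+") read else
      paste(rev(strsplit(chartr("ACGTN", "TGCAN", read), "")[[1]]),
            collapse = "")
    rl <- nchar(seq)
    rraw <- charToRaw(seq)
    mm <- vapply(seq_len(clen - rl + 1L), function(s)
      sum(craw[s:(s + rl - 1L)] != rraw), integer(1))
    score <- (rl - mm) - mm
    s <- which.max(score)   # ties: smallest offset
    if (is.null(best) || score[s] > best$score ||
        (score[s] == best$score && s < best$start))
      best <- list(start = s, end = s + rl - 1L, strand = strand,
                   mismatches = mm[s], score = score[s], rl = rl)
  }
  if (best$mismatches / best$rl > max_mismatch_rate) return(NULL)
  best
}

# closed-form two-feature EM fixed point: with abundances a + b = 1 the
# stationarity equation a*N = u_a + m*a (ambiguous reads split a : b)
# gives a = u_a / (N - m)
oracle_two_feature_em <- function(unique_a, unique_b, ambiguous) {
  N <- unique_a + unique_b + ambiguous
  a <- unique_a / (N - ambiguous)
  c(a = a * N, b = (1 - a) * N)
}

# substitute exactly k bases of a sequence at distinct positions
substitute_bases <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# analytic probability that a random w-base region (start uniform among
# all fitting placements on one chromosome of length L) overlaps >=1 of
# the given instance intervals: exact integration over placements
analytic_hit_prob <- function(inst_start, inst_end, L, w) {
  lo <- pmax(1L, inst_start - w + 1L)
  hi <- pmin(L - w + 1L, inst_end)
  ir <- IRanges::reduce(IRanges::IRanges(lo, hi))
  sum(IRanges::width(ir)) / (L - w + 1L)
}

toy_catalog <- function() {
  data.frame(
    repeat_name = c("IAPEz-int", "IAPLTR1a", "L1Md_A", "B1_Mus"),
    repeat_family = c("ERVK", "ERVK", "L1", "Alu"),
    repeat_class = c("LTR", "LTR", "LINE", "SINE"),
    consensus_length = c(1200L, 300L, 1500L, 150L),
    genome_fraction = c(0.06, 0.02, 0.08, 0.03),
    divergence = c(0.05, 0.05, 0.08, 0.05))
}

toy_genome <- function(seed = 42L, chrom_lengths = c(chrA = 3e5, chrB = 2e5)) {
  simulate_genome(genome_config(seed, chrom_lengths, toy_catalog()))
}
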
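#' Configuration for a toy genome with implanted repeat instances
#'
#' The simulated genome is a uniform-random background into which copies
#' of repeat consensus sequences are implanted, mutated by per-base
#' substitutions at the stated divergence, non-overlapping, on random
#' strands.  Each catalog entry requests either an instance count or a
#' target genome fraction.
#'
#' @param seed Integer seed; the generator is a pure function of its
#'   config, so a fixed seed reproduces the genome byte for byte.
#' @param chrom_lengths Named (or unnamed, auto-named `chr1..`) vector of
#'   chromosome lengths in bases.
#' @param repeat_catalog `data.frame` with columns `repeat_name`,
#'   `repeat_family`, `repeat_class`, and either `consensus` (sequence
#'   string) or `consensus_length`; plus `n_instances` or
#'   `genome_fraction`; and `divergence` (substitutions/base, default
#'   0.05).
#' @return An object of class `genome_config`.
#' @export
genome_config <- function(seed, chrom_lengths, repeat_catalog) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  chrom_lengths <- validate_chrom_sizes(chrom_lengths)
  rc <- as.data.frame(repeat_catalog)
  need <- c("repeat_name", "repeat_family", "repeat_class")
  if (!all(need %in% colnames(rc)))
    stop("repeat_catalog needs columns ", paste(need, collapse = ", "))
  if (is.null(rc$divergence)) rc$divergence <- 0.05
  if (any(rc$divergence < 0 | rc$divergence >= 1))
    stop("divergence must be in [0, 1)")
  if (is.null(rc[["consensus"]]) && is.null(rc$consensus_length))
    stop("repeat_catalog needs 'consensus' or 'consensus_length'")
  if (is.null(rc[["n_instances"]]) && is.null(rc$genome_fraction))
    stop("repeat_catalog needs 'n_instances' or 'genome_fraction'")
  if (!is.null(rc$genome_fraction)) {
    fr <- rc$genome_fraction[!is.na(rc$genome_fraction)]
    if (any(fr < 0 | fr > 1)) stop("genome_fraction must be in [0, 1]")
    if (sum(fr) >= 1) stop("total requested repeat fraction must be < 1")
  }
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 repeat_catalog = rc),
            class = "genome_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

revcomp <- function(seq) {
  vapply(seq, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Simulate a toy genome with implanted, diverged repeat instances
#'
#' @param config A [genome_config()].
#' @return A list of class `sim_genome`: `genome` (`DNAStringSet`),
#'   `repeats` (a [repeat_annotation()] `GRanges`), `chrom_sizes`,
#'   `consensus` (`DNAStringSet` of the catalog consensi), and the config.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "genome_config"))
  sizes <- config$chrom_lengths
  rc <- config$repeat_catalog

  set.seed(te_seed(config$seed, "genome_consensus"))
  cons <- character(nrow(rc))
  for (i in seq_len(nrow(rc))) {
    cons[i] <- if (!is.null(rc[["consensus"]]) && !is.na(rc[["consensus"]][i] %||% NA))
      toupper(rc[["consensus"]][i]) else random_dna(rc$consensus_length[i])
    if (grepl("[^ACGTN]", cons[i])) stop("consensus has invalid characters")
  }
  names(cons) <- rc$repeat_name
  cons_len <- nchar(cons)

  total <- sum(as.numeric(sizes))
  n_inst <- integer(nrow(rc))
  for (i in seq_len(nrow(rc))) {
    n_inst[i] <- if (!is.null(rc[["n_instances"]]) && !is.na(rc[["n_instances"]][i] %||% NA))
      rc[["n_instances"]][i] else round(rc$genome_fraction[i] * total / cons_len[i])
  }
  if (sum(n_inst * cons_len) >= total)
    stop("requested repeats do not fit the genome")

  # place instances non-overlapping by rejection sampling, longest first
  set.seed(te_seed(config$seed, "genome_place"))
  fam_order <- order(-cons_len)
  occupied <- lapply(sizes, function(L) IRanges::IRanges())
  inst <- list()
  for (i in fam_order) {
    L <- cons_len[i]
    placed <- 0L
    tries <- 0L
    max_tries <- 200L * max(1L, n_inst[i])
    while (placed < n_inst[i]) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("requested repeats do not fit the genome (placement failed for ",
             rc$repeat_name[i], ")")
      fit <- sizes - L
      if (all(fit < 0)) stop("consensus longer than every chromosome")
      ci <- sample.int(length(sizes), 1, prob = pmax(fit, 0))
      start <- sample.int(sizes[ci] - L + 1L, 1)
      cand <- IRanges::IRanges(start, width = L)
      if (length(IRanges::findOverlaps(cand, occupied[[ci]])) == 0L) {
        occupied[[ci]] <- c(occupied[[ci]], cand)
        placed <- placed + 1L
        inst[[length(inst) + 1L]] <- list(chrom = names(sizes)[ci],
                                          start = start, fam = i)
      }
    }
  }

  set.seed(te_seed(config$seed, "genome_mutate"))
  chrom_chars <- lapply(sizes, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  n <- length(inst)
  df <- data.frame(chrom = character(n), start = integer(n), end = integer(n),
                   strand = character(n), fam = integer(n),
                   stringsAsFactors = FALSE)
  for (j in seq_along(inst)) {
    e <- inst[[j]]
    L <- cons_len[e$fam]
    mut <- mutate_dna(cons[e$fam], rc$divergence[e$fam])
    strand <- sample(c("+", "-"), 1)
    genomic <- if (strand == "-") revcomp(mut) else mut
    chrom_chars[[e$chrom]][e$start:(e$start + L - 1L)] <-
      strsplit(genomic, "")[[1]]
    df[j, ] <- list(e$chrom, e$start, e$start + L - 1L, strand, e$fam)
  }
  ord <- order(match(df$chrom, names(sizes)), df$start)
  df <- df[ord, , drop = FALSE]

  genome <- Biostrings::DNAStringSet(
    vapply(chrom_chars, paste, character(1), collapse = ""))
  names(genome) <- names(sizes)
  repeats <- with_chrom_sizes(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
    repeat_name = rc$repeat_name[df$fam],
    repeat_family = rc$repeat_family[df$fam],
    repeat_class = rc$repeat_class[df$fam]), sizes)
  structure(list(genome = genome, repeats = repeat_annotation(repeats),
                 chrom_sizes = sizes,
                 consensus = Biostrings::DNAStringSet(cons),
                 config = config),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d chromosome(s), %.0f bases, %d repeat instances (%d families)\n",
              length(x$chrom_sizes), sum(as.numeric(x$chrom_sizes)),
              length(x$repeats),
              length(unique(S4Vectors::mcols(x$repeats)$repeat_family))))
  invisible(x)
}

#' Write simulated genome outputs as plain-text files
#'
#' Emits `genome.fa`, `repeats.out` (RepeatMasker-style),
#' `chrom.sizes`, and `consensus.fa` into a directory.
#'
#' @param sim A `sim_genome`.
#' @param dir Output directory (created if absent).
#' @export
write_genome_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_rmout(sim$repeats, file.path(dir, "repeats.out"))
  write_chromsizes(sim$chrom_sizes, file.path(dir, "chrom.sizes"))
  write_fasta(sim$consensus, file.path(dir, "consensus.fa"))
  invisible(dir)
}

#' Configuration for simulated ChIP/input fragment sets
#'
#' ChIP fragments are placed with midpoint density proportional to the
#' per-family enrichment factor over repeat instances and 1 elsewhere;
#' input fragments are uniform over the genome.  Spike-in fragments are
#' represented by their per-sample totals only, drawn binomially from the
#' configured fraction.
#'
#' @param seed Integer seed.
#' @param n_replicates Replicates per condition (default 3).
#' @param fragments_per_replicate Fragments per replicate (default 1e5).
#' @param fragment_length_mean,fragment_length_sd Truncated-normal
#'   fragment length model (defaults 200 and 50; minimum length 50).
#' @param enrichment Named numeric vector of fold-enrichment over
#'   background per `repeat_family`; families absent default to 1.
#' @param spikein_fraction Expected spike-in read fraction per sample, in
#'   `[0, 1)` (default 0.05).
#' @return Object of class `chip_sim_config`.
#' @export
chip_sim_config <- function(seed, n_replicates = 3L,
                            fragments_per_replicate = 1e5,
                            fragment_length_mean = 200,
                            fragment_length_sd = 50,
                            enrichment = numeric(0),
                            spikein_fraction = 0.05) {
  if (fragments_per_replicate < 1) stop("zero fragments requested")
  if (any(enrichment < 0)) stop("enrichment factors must be >= 0")
  if (spikein_fraction < 0 || spikein_fraction >= 1)
    stop("spikein_fraction must be in [0, 1)")
  structure(list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
                 fragments_per_replicate = as.integer(fragments_per_replicate),
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 enrichment = enrichment,
                 spikein_fraction = spikein_fraction),
            class = "chip_sim_config")
}

frag_lengths <- function(n, mean, sd) {
  pmax(50L, as.integer(round(rnorm(n, mean, sd))))
}

midpoints_to_granges <- function(chrom, mid, len, sizes) {
  start <- mid - floor(len / 2)
  end <- start + len - 1L
  L <- sizes[chrom]
  shift <- pmax(0L, 1L - start); start <- start + shift; end <- end + shift
  shift <- pmax(0L, end - L); start <- pmax(1L, start - shift)
  end <- pmin(L, end - shift)
  with_chrom_sizes(GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end)),
                   sizes)
}

# Draw n fragment midpoints with density proportional to `enrichment_f`
# over instances of family f and 1 over the non-repeat background.
draw_midpoints <- function(sim, n, enrichment) {
  sizes <- sim$chrom_sizes
  fam <- S4Vectors::mcols(sim$repeats)$repeat_family
  fams <- sort(unique(fam))
  enr <- setNames(rep(1, length(fams)), fams)
  enr[names(enrichment)[names(enrichment) %in% fams]] <-
    enrichment[names(enrichment) %in% fams]
  covered <- vapply(fams, function(f)
    sum(as.numeric(GenomicRanges::width(sim$repeats[fam == f]))), numeric(1))
  total <- sum(as.numeric(sizes))
  bg_bases <- total - sum(covered)
  w <- c(bg_bases, covered * enr[fams])
  comp <- sample.int(length(w), n, replace = TRUE, prob = w)
  chrom <- character(n); mid <- integer(n)
  # background: uniform over the genome complement of repeats
  bg_idx <- which(comp == 1L)
  if (length(bg_idx)) {
    gaps <- GenomicRanges::gaps(GenomicRanges::reduce(sim$repeats,
                                                      ignore.strand = TRUE))
    gaps <- gaps[GenomicRanges::strand(gaps) == "*"]
    gw <- as.numeric(GenomicRanges::width(gaps))
    gi <- sample.int(length(gaps), length(bg_idx), replace = TRUE, prob = gw)
    off <- floor(runif(length(bg_idx)) * gw[gi])
    chrom[bg_idx] <- as.character(GenomeInfoDb::seqnames(gaps))[gi]
    mid[bg_idx] <- GenomicRanges::start(gaps)[gi] + as.integer(off)
  }
  for (k in seq_along(fams)) {
    idx <- which(comp == k + 1L)
    if (!length(idx)) next
    ins <- sim$repeats[fam == fams[k]]
    iw <- as.numeric(GenomicRanges::width(ins))
    ii <- sample.int(length(ins), length(idx), replace = TRUE, prob = iw)
    off <- floor(runif(length(idx)) * iw[ii])
    chrom[idx] <- as.character(GenomeInfoDb::seqnames(ins))[ii]
    mid[idx] <- GenomicRanges::start(ins)[ii] + as.integer(off)
  }
  list(chrom = chrom, mid = mid)
}

#' Simulate multi-replicate ChIP and input fragment sets with spike-ins
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param config A [chip_sim_config()].
#' @return A list of class `sim_chip`: `chip` and `input` (lists of
#'   [fragment_set()]), and `truth` (per-family enrichment, covered bases
#'   and expected ChIP midpoint fraction).
#' @export
simulate_chip_fragments <- function(sim, config) {
  stopifnot(inherits(sim, "sim_genome"), inherits(config, "chip_sim_config"))
  sizes <- sim$chrom_sizes
  N <- config$fragments_per_replicate
  chip <- list(); input <- list()
  for (r in seq_len(config$n_replicates)) {
    set.seed(te_seed(config$seed, paste0("chip_rep", r)))
    mp <- draw_midpoints(sim, N, config$enrichment)
    len <- frag_lengths(N, config$fragment_length_mean, config$fragment_length_sd)
    gr <- midpoints_to_granges(mp$chrom, mp$mid, len, sizes)
    spike <- rbinom(1, N, config$spikein_fraction)
    chip[[r]] <- fragment_set(paste0("chip_rep", r), gr,
                              library_size = N, spikein_size = spike)

    set.seed(te_seed(config$seed, paste0("input_rep", r)))
    mp <- draw_midpoints(sim, N, setNames(numeric(0), character(0)))
    len <- frag_lengths(N, config$fragment_length_mean, config$fragment_length_sd)
    gr <- midpoints_to_granges(mp$chrom, mp$mid, len, sizes)
    spike <- rbinom(1, N, config$spikein_fraction)
    input[[r]] <- fragment_set(paste0("input_rep", r), gr,
                               library_size = N, spikein_size = spike)
  }
  names(chip) <- sample_ids(chip); names(input) <- sample_ids(input)
  fam <- S4Vectors::mcols(sim$repeats)$repeat_family
  fams <- sort(unique(fam))
  enr <- setNames(rep(1, length(fams)), fams)
  enr[names(config$enrichment)[names(config$enrichment) %in% fams]] <-
    config$enrichment[names(config$enrichment) %in% fams]
  covered <- vapply(fams, function(f)
    sum(as.numeric(GenomicRanges::width(sim$repeats[fam == f]))), numeric(1))
  total <- sum(as.numeric(sizes))
  w <- covered * enr
  truth <- data.frame(repeat_family = fams, covered_bases = covered,
                      enrichment = unname(enr),
                      expected_chip_fraction =
                        unname(w / (total - sum(covered) + sum(w))))
  structure(list(chip = chip, input = input, truth = truth),
            class = "sim_chip")
}

#' Configuration for a negative-binomial count matrix with implanted
#' fold changes
#'
#' @param seed Integer seed.
#' @param n_features Number of features (rows).
#' @param n_per_group Samples per group, length-2 integer (default
#'   `c(3, 3)`).
#' @param baseline_mean Baseline mean; a scalar, a length-2 range for a
#'   log-uniform draw per feature, or a length-`n_features` vector.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2),
#'   > 0.
#' @param lfc_features Integer indices of features carrying an implanted
#'   log2 fold change in group 2.
#' @param lfc Implanted log2 fold change (scalar or per implanted
#'   feature).
#' @return Object of class `count_sim_config`.
#' @export
count_sim_config <- function(seed, n_features, n_per_group = c(3L, 3L),
                             baseline_mean = 200, dispersion = 0.1,
                             lfc_features = integer(0), lfc = 0) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (length(lfc_features) && (min(lfc_features) < 1 ||
                               max(lfc_features) > n_features))
    stop("lfc_features must index features")
  structure(list(seed = as.integer(seed), n_features = as.integer(n_features),
                 n_per_group = as.integer(n_per_group),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 lfc_features = as.integer(lfc_features), lfc = lfc),
            class = "count_sim_config")
}

#' Simulate an NB count matrix with known differential features
#'
#' @param config A [count_sim_config()].
#' @return A list of class `sim_counts`: `counts` (features x samples
#'   integer matrix), `groups` (factor), `truth` (`data.frame` with the
#'   per-feature true log2FC), `baseline_mean` per feature.
#' @export
simulate_count_matrix <- function(config) {
  stopifnot(inherits(config, "count_sim_config"))
  set.seed(te_seed(config$seed, "counts"))
  G <- config$n_features
  n1 <- config$n_per_group[1]; n2 <- config$n_per_group[2]
  mu0 <- if (length(config$baseline_mean) == 1) rep(config$baseline_mean, G)
  else if (length(config$baseline_mean) == 2)
    exp(runif(G, log(config$baseline_mean[1]), log(config$baseline_mean[2])))
  else config$baseline_mean
  lfc <- numeric(G)
  lfc[config$lfc_features] <- config$lfc
  mu2 <- mu0 * 2^lfc
  size <- 1 / config$dispersion
  counts <- cbind(
    matrix(rnbinom(G * n1, mu = rep(mu0, n1), size = size), nrow = G),
    matrix(rnbinom(G * n2, mu = rep(mu2, n2), size = size), nrow = G))
  rownames(counts) <- paste0("feature_", seq_len(G))
  colnames(counts) <- c(paste0("g1_s", seq_len(n1)), paste0("g2_s", seq_len(n2)))
  groups <- factor(rep(c("g1", "g2"), c(n1, n2)))
  structure(list(counts = counts, groups = groups,
                 truth = data.frame(feature = rownames(counts),
                                    baseline_mean = mu0, true_lfc = lfc),
                 baseline_mean = mu0),
            class = "sim_counts")
}
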
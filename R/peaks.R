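#' Build a peak table with per-replicate ChIP and input fragment counts
#'
#' Counts, for every peak, the fragments from each ChIP and each input
#' replicate overlapping it by at least one base.  The result feeds
#' [filter_enriched_peaks()].
#'
#' @param peaks `GRanges` of peaks (with a `summit` column, e.g. from
#'   [read_annotation()] with dialect `narrowpeak`, possibly passed
#'   through [resize_around_summit()]).
#' @param chip,input Lists of [fragment_set()] replicates.
#' @return Object of class `peak_table`: the peaks plus `chip_counts` and
#'   `input_counts` matrices (peaks x replicates) and the per-replicate
#'   library sizes.
#' @export
count_peak_fragments <- function(peaks, chip, input) {
  stopifnot(is(peaks, "GRanges"), length(chip) >= 1, length(input) >= 1)
  cnt <- function(fs) vapply(fs, function(f) {
    check_same_genome(peaks, f$fragments)
    GenomicRanges::countOverlaps(peaks, f$fragments, ignore.strand = TRUE)
  }, integer(length(peaks)))
  chip_counts <- matrix(cnt(chip), nrow = length(peaks),
                        dimnames = list(NULL, sample_ids(chip)))
  input_counts <- matrix(cnt(input), nrow = length(peaks),
                         dimnames = list(NULL, sample_ids(input)))
  structure(list(peaks = peaks, chip_counts = chip_counts,
                 input_counts = input_counts,
                 chip_lib = lib_sizes(chip), input_lib = lib_sizes(input)),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table: %d peaks, %d ChIP / %d input replicates\n",
              length(x$peaks), ncol(x$chip_counts), ncol(x$input_counts)))
  invisible(x)
}

#' Replicate-thresholded enrichment filter for candidate peaks
#'
#' A peak is kept iff its depth-normalized ChIP/input ratio exceeds
#' `min_fold` (strictly) in at least `min_reps` replicate pairs.  The
#' ratio for replicate r is
#' `((chip_r + 1) / chip_lib_r) / ((input_r + 1) / input_lib_r)`
#' — a pseudocount of one fragment on both counts keeps ratios finite at
#' empty peaks.  ChIP replicate r is paired with input replicate r (or
#' with a single shared input when only one is supplied).
#'
#' @param peak_table A [count_peak_fragments()] result.
#' @param min_fold Fold threshold (default 1.2).
#' @param min_reps Minimum number of passing replicates (default 3).
#' @return A `peak_table` restricted to the surviving peaks, with a
#'   `passes_filter` logical on the full input stored as attribute
#'   `"passes_filter"`.
#' @export
filter_enriched_peaks <- function(peak_table, min_fold = 1.2, min_reps = 3L) {
  stopifnot(inherits(peak_table, "peak_table"))
  nrep <- ncol(peak_table$chip_counts)
  nin <- ncol(peak_table$input_counts)
  if (nrep < min_reps)
    stop("fewer ChIP replicates (", nrep, ") than min_reps (", min_reps, ")")
  if (nin != nrep && nin != 1L)
    stop("need one input per ChIP replicate, or a single shared input")
  if (any(peak_table$chip_lib <= 0) || any(peak_table$input_lib <= 0))
    stop("zero library size")
  in_idx <- if (nin == 1L) rep(1L, nrep) else seq_len(nrep)
  chip_rate <- sweep(peak_table$chip_counts + 1, 2, peak_table$chip_lib, "/")
  input_rate <- sweep(peak_table$input_counts + 1, 2, peak_table$input_lib, "/")
  ratio <- chip_rate / input_rate[, in_idx, drop = FALSE]
  pass <- rowSums(ratio > min_fold) >= min_reps
  out <- structure(list(peaks = peak_table$peaks[pass],
                        chip_counts = peak_table$chip_counts[pass, , drop = FALSE],
                        input_counts = peak_table$input_counts[pass, , drop = FALSE],
                        chip_lib = peak_table$chip_lib,
                        input_lib = peak_table$input_lib),
                   class = "peak_table")
  attr(out, "passes_filter") <- pass
  attr(out, "ratios") <- ratio
  out
}

#' Assign peaks to genomic feature categories (Upset semantics)
#'
#' Membership is computed independently per category — TSS window
#' (strand-aware, `tss_width` bases upstream of the TSS, excluding the
#' TSS itself), exon, intron, repeat — so a peak can belong to several
#' categories; peaks in none are intergenic.
#'
#' @param peaks `GRanges` of peaks.
#' @param genes A [gene_annotation()].
#' @param repeats A [repeat_annotation()] `GRanges`.
#' @param tss_width Promoter window width (default 300).
#' @return A logical matrix (peaks x categories `TSS`, `exon`, `intron`,
#'   `repeat`, `intergenic`).
#' @export
categorize_peaks <- function(peaks, genes, repeats, tss_width = 300L) {
  stopifnot(is(peaks, "GRanges"), inherits(genes, "gene_annotation"))
  tss <- tss_windows(genes, tss_width)
  m <- cbind(
    TSS = GenomicRanges::countOverlaps(peaks, tss, ignore.strand = TRUE) > 0,
    exon = GenomicRanges::countOverlaps(peaks, genes$exons,
                                        ignore.strand = TRUE) > 0,
    intron = GenomicRanges::countOverlaps(peaks, genes$introns,
                                          ignore.strand = TRUE) > 0,
    `repeat` = GenomicRanges::countOverlaps(peaks, repeats,
                                            ignore.strand = TRUE) > 0)
  cbind(m, intergenic = rowSums(m) == 0)
}

#' Tabulate category combinations for an Upset-style display
#'
#' @param category_matrix Output of [categorize_peaks()].
#' @return `data.frame` of distinct category combinations and their peak
#'   counts, sorted by count.
#' @export
category_combinations <- function(category_matrix) {
  key <- apply(category_matrix, 1, function(r)
    paste(colnames(category_matrix)[r], collapse = "+"))
  tab <- sort(table(key), decreasing = TRUE)
  data.frame(combination = names(tab), n_peaks = as.integer(tab),
             row.names = NULL)
}

# Draw one randomized region set matching the peaks in number and length
# multiset: chromosome chosen with probability proportional to its
# length, start uniform such that the region fits.
random_region_set <- function(widths, chrom_sizes) {
  if (any(widths > max(chrom_sizes)))
    stop("peak longer than every chromosome")
  n <- length(widths)
  ci <- sample.int(length(chrom_sizes), n, replace = TRUE,
                   prob = as.numeric(chrom_sizes))
  # redraw any chromosome too short for its region
  for (k in which(chrom_sizes[ci] < widths)) {
    ok <- which(chrom_sizes >= widths[k])
    ci[k] <- ok[sample.int(length(ok), 1,
                           prob = as.numeric(chrom_sizes[ok]))]
  }
  start <- 1L + as.integer(floor(runif(n) * (chrom_sizes[ci] - widths + 1L)))
  GenomicRanges::GRanges(names(chrom_sizes)[ci],
                         IRanges::IRanges(start, width = widths),
                         seqlengths = chrom_sizes)
}

#' Bootstrap randomized-region null for repeat enrichment of a peak set
#'
#' Generates `n_boot` sets of randomly placed regions matching the peak
#' set in number and in its multiset of region lengths, tallies overlaps
#' with the repeat annotation per label (presence counting: a peak
#' overlapping any number of instances of one label contributes 1 to that
#' label), and reports the observed tally together with the null mean and
#' SD across bootstrap sets, the empirical z-score and the fold over the
#' null mean.
#'
#' @param peaks `GRanges` of peaks with seqlengths set.
#' @param repeats A [repeat_annotation()] `GRanges`.
#' @param n_boot Number of randomized sets (default 100).
#' @param seed Integer seed for the randomized placements.
#' @param group_key `"repeat_name"` or `"repeat_family"`.
#' @param return_boot Keep the per-bootstrap tally matrix as attribute
#'   `"boot"` (default `FALSE`).
#' @return `data.frame` of class `enrichment_result`: `label`,
#'   `observed`, `null_mean`, `null_sd`, `n_boot`, `z`, `fold` (`fold` is
#'   `NA` where `null_mean` is 0).
#' @export
bootstrap_repeat_enrichment <- function(peaks, repeats, n_boot = 100L, seed = 1L,
                                        group_key = c("repeat_name",
                                                      "repeat_family"),
                                        return_boot = FALSE) {
  group_key <- match.arg(group_key)
  stopifnot(length(peaks) > 0, n_boot >= 1)
  check_same_genome(peaks, repeats)
  sizes <- GenomeInfoDb::seqlengths(repeats)
  label <- S4Vectors::mcols(repeats)[[group_key]]
  labels <- sort(unique(label))
  observed <- overlap_count(peaks, repeats, label = label)$label_hits
  widths <- GenomicRanges::width(peaks)
  set.seed(te_seed(seed, "bootstrap_regions"))
  boot <- matrix(0L, nrow = n_boot, ncol = length(labels),
                 dimnames = list(NULL, labels))
  for (b in seq_len(n_boot)) {
    rnd <- random_region_set(widths, sizes)
    boot[b, ] <- overlap_count(rnd, repeats, label = label)$label_hits
  }
  null_mean <- colMeans(boot)
  null_sd <- apply(boot, 2, sd)
  if (n_boot == 1L) null_sd[] <- 0
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  fold <- ifelse(null_mean > 0, observed / null_mean, NA_real_)
  res <- data.frame(label = labels, observed = as.integer(observed),
                    null_mean = null_mean, null_sd = null_sd,
                    n_boot = as.integer(n_boot), z = z, fold = fold,
                    row.names = NULL)
  class(res) <- c("enrichment_result", "data.frame")
  if (return_boot) attr(res, "boot") <- boot
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Randomized-region repeat enrichment (", x$n_boot[1], " bootstrap sets)\n",
      sep = "")
  df <- as.data.frame(x)
  df$null_mean <- round(df$null_mean, 2)
  df$null_sd <- round(df$null_sd, 2)
  df$z <- round(df$z, 2); df$fold <- round(df$fold, 2)
  print(df[order(-abs(ifelse(is.na(df$z), 0, df$z))), ], row.names = FALSE)
  invisible(x)
}
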
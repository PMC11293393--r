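#' Feature-by-sample count matrix container
#'
#' @param counts Integer matrix, features x samples.
#' @param library_size,spikein_size Per-sample totals (named numeric,
#'   matching `colnames(counts)`).
#' @param group_key What one row is: `"repeat_name"`, `"repeat_family"`,
#'   `"peak"`, `"bin"`, or `"feature"`.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(counts, library_size, spikein_size = NULL,
                         group_key = "feature") {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (length(library_size) != ncol(counts))
    stop("one library_size per sample required")
  structure(list(counts = counts, library_size = library_size,
                 spikein_size = spikein_size, group_key = group_key),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d %s(s) x %d sample(s)\n", nrow(x$counts),
              x$group_key, ncol(x$counts)))
  invisible(x)
}

#' Sum fragments over repeat annotations by repeat label
#'
#' For each sample, a fragment increments a label's count once if it
#' overlaps at least one instance carrying that label — once per label
#' even when it spans two same-label instances (no double counting at
#' fragmented annotations); a fragment spanning instances of two
#' different labels increments both.
#'
#' @param fragment_sets List of [fragment_set()] objects (samples).
#' @param repeats A [repeat_annotation()] `GRanges`.
#' @param group_key `"repeat_name"`, `"repeat_family"` or
#'   `"repeat_class"`.
#' @return A [count_matrix()] with one row per label, carrying the
#'   per-sample library and spike-in sizes.
#' @export
sum_reads_per_repeat <- function(fragment_sets, repeats,
                                 group_key = c("repeat_name", "repeat_family",
                                               "repeat_class")) {
  group_key <- match.arg(group_key)
  if (length(repeats) == 0) stop("empty repeat annotation")
  if (inherits(fragment_sets, "fragment_set"))
    fragment_sets <- list(fragment_sets)
  label <- S4Vectors::mcols(repeats)[[group_key]]
  labels <- sort(unique(label))
  counts <- vapply(fragment_sets, function(f) {
    overlap_count(f$fragments, repeats, label = label)$label_hits
  }, integer(length(labels)))
  counts <- matrix(counts, nrow = length(labels),
                   dimnames = list(labels, sample_ids(fragment_sets)))
  count_matrix(counts, lib_sizes(fragment_sets, "library_size"),
               lib_sizes(fragment_sets, "spikein"), group_key = group_key)
}

#' Normalize a count matrix to cpm with a depth-scaled prior count
#'
#' Computes `(count + prior_count * s_j / mean(s)) / s_j * 1e6`, where
#' `s_j` is the sample's total library size (mode `"library_size"`) or
#' its spike-in total (mode `"spikein"`).  The prior is scaled per sample
#' by relative depth so that equal counts at equal depth map to equal
#' normalized values, and zero counts stay finite and comparable.
#' Spike-in mode makes *global* binding changes visible: a genome-wide
#' efficiency shift cancels in library-size mode but not against a fixed
#' exogenous denominator.
#'
#' @param x A [count_matrix()].
#' @param mode `"library_size"` or `"spikein"`.
#' @param prior_count Pseudocount on the mean-depth scale (default 3).
#' @return Numeric matrix of normalized values (cpm scale).
#' @export
normalize_counts <- function(x, mode = c("library_size", "spikein"),
                             prior_count = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "count_matrix"))
  s <- if (mode == "spikein") x$spikein_size else x$library_size
  if (is.null(s)) stop("no ", mode, " totals on this count_matrix")
  if (any(s <= 0)) {
    bad <- colnames(x$counts)[s <= 0]
    stop("zero ", mode, " denominator for sample(s): ",
         paste(bad, collapse = ", "))
  }
  prior <- prior_count * s / mean(s)
  t((t(x$counts) + prior) / s) * 1e6
}

#' Binned fragment signal around anchor points
#'
#' Tiles a window of `±flank` bases around each anchor (its summit for
#' width->1 anchors, otherwise its midpoint) into `2*flank/bin_width`
#' bins, counts overlapping fragments per bin, and normalizes to cpm.
#' Rows (anchors) are ordered by descending row mean of the first
#' sample's matrix — the waterfall ordering; column means and SDs across
#' anchors give the metaplot.  Windows running past a chromosome end are
#' truncated: out-of-range bins are `NA`, not zero.
#'
#' @param fragment_sets List of [fragment_set()] (samples).
#' @param anchors `GRanges` of anchor points (e.g. resized peaks with
#'   summits, or any intervals — midpoints are used).
#' @param flank Half-window in bases (default 3000); must be a multiple
#'   of `bin_width`.
#' @param bin_width Bin width in bases (default 50).
#' @return Object of class `binned_signal`: `matrices` (named list per
#'   sample, anchors x bins, waterfall-ordered), `bin_mid` (bin center
#'   offsets), `order` (anchor ordering used), `metaplot` (`data.frame`
#'   with per-sample mean and sd per bin).
#' @export
signal_matrix <- function(fragment_sets, anchors, flank = 3000L,
                          bin_width = 50L) {
  if (inherits(fragment_sets, "fragment_set"))
    fragment_sets <- list(fragment_sets)
  if (flank %% bin_width != 0) stop("flank must be a multiple of bin_width")
  n_bins <- as.integer(2 * flank / bin_width)
  center <- S4Vectors::mcols(anchors)$summit
  if (is.null(center))
    center <- floor((GenomicRanges::start(anchors) +
                       GenomicRanges::end(anchors)) / 2)
  chrom <- as.character(GenomeInfoDb::seqnames(anchors))
  sizes <- GenomeInfoDb::seqlengths(anchors)
  if (any(is.na(sizes))) stop("anchors must carry seqlengths")
  off <- seq(-flank, flank - bin_width, by = bin_width)
  bin_start <- rep(center, each = n_bins) + rep(off, length(anchors))
  bin_end <- bin_start + bin_width - 1L
  bchrom <- rep(chrom, each = n_bins)
  L <- sizes[bchrom]
  valid <- bin_start >= 1L & bin_end <= L
  vgr <- GenomicRanges::GRanges(bchrom[valid],
                                IRanges::IRanges(bin_start[valid],
                                                 bin_end[valid]),
                                seqlengths = sizes)
  mats <- lapply(fragment_sets, function(f) {
    v <- rep(NA_real_, length(bin_start))
    v[valid] <- GenomicRanges::countOverlaps(vgr, f$fragments,
                                             ignore.strand = TRUE)
    matrix(v / f$library_size * 1e6, ncol = n_bins, byrow = TRUE)
  })
  names(mats) <- sample_ids(fragment_sets)
  ord <- order(-rowMeans(mats[[1]], na.rm = TRUE))
  mats <- lapply(mats, function(m) m[ord, , drop = FALSE])
  bin_mid <- off + bin_width / 2
  meta <- do.call(rbind, lapply(names(mats), function(s) {
    data.frame(sample = s, bin_mid = bin_mid,
               mean = colMeans(mats[[s]], na.rm = TRUE),
               sd = apply(mats[[s]], 2, sd, na.rm = TRUE))
  }))
  structure(list(matrices = mats, bin_mid = bin_mid, order = ord,
                 metaplot = meta, flank = flank, bin_width = bin_width),
            class = "binned_signal")
}

#' @export
print.binned_signal <- function(x, ...) {
  cat(sprintf("binned_signal: %d anchors x %d bins (flank %d, bin %d), %d sample(s)\n",
              nrow(x$matrices[[1]]), length(x$bin_mid), x$flank, x$bin_width,
              length(x$matrices)))
  invisible(x)
}

#' Genome-wide binned cpm per sample
#'
#' Tiles every chromosome into fixed non-overlapping bins (last bin
#' truncated), assigns each fragment to every bin it overlaps, and
#' normalizes to cpm.  Suitable for cross-sample scatter and correlation
#' of binned signal.
#'
#' @param fragment_sets List of [fragment_set()].
#' @param bin_width Bin width in bases (default 1000).
#' @return `data.frame`: `chrom`, `start`, `end` (1-based closed) and one
#'   cpm column per sample.
#' @export
genome_binned_signal <- function(fragment_sets, bin_width = 1000L) {
  if (inherits(fragment_sets, "fragment_set"))
    fragment_sets <- list(fragment_sets)
  stopifnot(bin_width > 0)
  sizes <- GenomeInfoDb::seqlengths(fragment_sets[[1]]$fragments)
  bins <- GenomicRanges::tileGenome(sizes, tilewidth = bin_width,
                                    cut.last.tile.in.chrom = TRUE)
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(bins)),
                    start = GenomicRanges::start(bins),
                    end = GenomicRanges::end(bins))
  for (f in fragment_sets)
    out[[f$sample_id]] <- GenomicRanges::countOverlaps(
      bins, f$fragments, ignore.strand = TRUE) / f$library_size * 1e6
  out
}

#' Write per-sample binned signal as bedGraph-style TSV files
#'
#' @param binned Output of [genome_binned_signal()].
#' @param dir Output directory; one `<sample>.bedgraph` per sample
#'   (0-based half-open coordinates).
#' @export
write_bedgraph <- function(binned, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- setdiff(colnames(binned), c("chrom", "start", "end"))
  for (s in samples) {
    df <- data.frame(binned$chrom, binned$start - 1L, binned$end,
                     signif(binned[[s]], 6))
    write.table(df, file.path(dir, paste0(s, ".bedgraph")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
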
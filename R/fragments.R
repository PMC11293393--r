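#' A set of aligned fragments for one sample
#'
#' The counting unit throughout the package is the sequenced *fragment*
#' (both mates of a pair collapsed to one interval); a fragment
#' overlapping a feature by at least one base counts once.
#' `library_size` is the total number of genome fragments for the sample
#' (used as the cpm denominator in library-size mode) and `spikein_size`
#' the total number of fragments mapped to the exogenous spike-in genome
#' (the denominator in spike-in mode).  Spike-in fragments are carried
#' only as a total, which is all normalization needs.
#'
#' @param sample_id Sample name.
#' @param fragments `GRanges` of fragment intervals with seqlengths set.
#' @param library_size Total genome fragments; defaults to
#'   `length(fragments)`.
#' @param spikein_size Total spike-in fragments (default 0).
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(sample_id, fragments, library_size = length(fragments),
                         spikein_size = 0L) {
  stopifnot(is(fragments, "GRanges"))
  if (any(is.na(GenomeInfoDb::seqlengths(fragments))))
    stop("fragments must carry seqlengths (see with_chrom_sizes)")
  if (library_size < length(fragments))
    stop("library_size smaller than the number of fragments")
  if (spikein_size < 0) stop("spikein_size must be >= 0")
  structure(list(sample_id = as.character(sample_id), fragments = fragments,
                 library_size = as.numeric(library_size),
                 spikein_size = as.numeric(spikein_size)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set '%s': %d fragments, library_size %g, spikein_size %g\n",
              x$sample_id, length(x$fragments), x$library_size, x$spikein_size))
  invisible(x)
}

sample_ids <- function(fragment_sets) {
  vapply(fragment_sets, function(f) f$sample_id, character(1))
}

lib_sizes <- function(fragment_sets, mode = c("library_size", "spikein")) {
  mode <- match.arg(mode)
  v <- vapply(fragment_sets,
              function(f) if (mode == "spikein") f$spikein_size else f$library_size,
              numeric(1))
  setNames(v, sample_ids(fragment_sets))
}

#' Read or write the internal fragment TSV
#'
#' Plain-text exchange format for fragments: tab-separated columns
#' `chrom`, `start`, `end` (0-based half-open, BED-style) and `sample`.
#' `read_fragments_tsv` returns one [fragment_set()] per sample;
#' library and spike-in sizes, which the TSV does not carry, default to
#' the per-sample fragment count and 0 and can be overridden.
#'
#' @param path File path.
#' @param chrom_sizes Named chromosome length vector.
#' @param library_sizes,spikein_sizes Optional named vectors overriding
#'   the per-sample totals.
#' @return A named list of `fragment_set` objects.
#' @export
read_fragments_tsv <- function(path, chrom_sizes, library_sizes = NULL,
                               spikein_sizes = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "integer", "character"))
  if (!identical(colnames(df), c("chrom", "start", "end", "sample")))
    stop("fragment TSV must have columns chrom, start, end, sample")
  out <- list()
  for (s in unique(df$sample)) {
    d <- df[df$sample == s, ]
    gr <- with_chrom_sizes(
      GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end)),
      chrom_sizes)
    out[[s]] <- fragment_set(s, gr,
                             library_size = library_sizes[[s]] %||% nrow(d),
                             spikein_size = spikein_sizes[[s]] %||% 0L)
  }
  out
}

#' @rdname read_fragments_tsv
#' @param fragment_sets List of `fragment_set` objects to write.
#' @export
write_fragments_tsv <- function(fragment_sets, path) {
  dfs <- lapply(fragment_sets, function(f) {
    gr <- f$fragments
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               sample = f$sample_id)
  })
  write.table(do.call(rbind, dfs), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Import paired-end fragments from a BAM file
#'
#' Thin adapter collapsing properly paired alignments to fragment
#' intervals; everything downstream consumes the resulting
#' [fragment_set()].  Requires the Rsamtools package.
#'
#' @param path BAM file path.
#' @param sample_id Sample name.
#' @param chrom_sizes Named chromosome length vector.
#' @inheritParams fragment_set
#' @export
read_fragments_bam <- function(path, sample_id, chrom_sizes,
                               library_size = NULL, spikein_size = 0L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("read_fragments_bam requires the Rsamtools package")
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "isize"),
    flag = Rsamtools::scanBamFlag(isProperPair = TRUE, isFirstMateRead = TRUE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$isize) & b$isize > 0
  gr <- with_chrom_sizes(
    GenomicRanges::GRanges(as.character(b$rname)[keep],
                           IRanges::IRanges(b$pos[keep],
                                            width = b$isize[keep])),
    chrom_sizes)
  fragment_set(sample_id, gr, library_size = library_size %||% length(gr),
               spikein_size = spikein_size)
}
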
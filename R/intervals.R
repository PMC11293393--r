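#' Attach and validate a chromosome-size table on a set of intervals
#'
#' Sets `seqlengths` on a `GRanges` from a named vector of chromosome
#' lengths and checks every interval against it.  All interval-consuming
#' functions in the package require intervals governed by a size table, so
#' that out-of-bounds coordinates are caught at construction rather than
#' deep inside an overlap computation.
#'
#' @param gr A [GenomicRanges::GRanges].
#' @param chrom_sizes Named integer vector of chromosome lengths (bases).
#' @return The same `GRanges` with `seqlengths` set.
#' @export
with_chrom_sizes <- function(gr, chrom_sizes) {
  stopifnot(is(gr, "GRanges"))
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  bad <- setdiff(as.character(GenomeInfoDb::seqnames(gr)), names(chrom_sizes))
  if (length(bad))
    stop("chromosome(s) not in the size table: ", paste(unique(bad), collapse = ", "))
  len <- chrom_sizes[as.character(GenomeInfoDb::seqnames(gr))]
  if (any(GenomicRanges::start(gr) < 1L) || any(GenomicRanges::end(gr) > len))
    stop("interval outside chromosome bounds")
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  gr
}

validate_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector of lengths")
  if (any(chrom_sizes < 1)) stop("chromosome lengths must be positive")
  storage.mode(chrom_sizes) <- "integer"
  chrom_sizes
}

check_same_genome <- function(query, subject) {
  qs <- GenomeInfoDb::seqlengths(query)
  ss <- GenomeInfoDb::seqlengths(subject)
  if (any(is.na(qs)) || any(is.na(ss)))
    stop("both interval sets must carry a chromosome-size table (see with_chrom_sizes)")
  shared <- intersect(names(qs), names(ss))
  if (!identical(qs[shared], ss[shared]))
    stop("interval sets are governed by different chromosome-size tables")
  bad <- setdiff(
    as.character(GenomeInfoDb::seqnames(query)),
    names(GenomeInfoDb::seqlengths(subject))
  )
  if (length(bad))
    stop("unknown chromosome in query: ", paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' Count overlaps between two interval sets
#'
#' Two intervals overlap iff they share at least one base on the same
#' chromosome; strand is ignored.  Besides the per-query tally, a per-label
#' tally can be requested: for each label carried by the subject, the
#' number of *query* intervals overlapping at least one subject of that
#' label (presence counting, once per query per label).
#'
#' @param query,subject `GRanges` sharing one chromosome-size table.
#' @param label Optional character vector, one label per subject interval
#'   (e.g. `repeat_name`), for the per-label tally.
#' @return A list with `query_hits` (integer, per query interval) and,
#'   when `label` is given, `label_hits` (named integer, per label).
#' @examples
#' sizes <- c(chr1 = 10000L)
#' q <- with_chrom_sizes(GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 20)), sizes)
#' s <- with_chrom_sizes(GenomicRanges::GRanges("chr1", IRanges::IRanges(16, 30)), sizes)
#' overlap_count(q, s)$query_hits  # 1
#' @export
overlap_count <- function(query, subject, label = NULL) {
  check_same_genome(query, subject)
  hits <- GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE)
  out <- list(query_hits = GenomicRanges::countOverlaps(query, subject,
                                                        ignore.strand = TRUE))
  if (!is.null(label)) {
    stopifnot(length(label) == length(subject))
    lab <- label[S4Vectors::subjectHits(hits)]
    qh <- S4Vectors::queryHits(hits)
    pairs <- unique(paste0(qh, "\r", lab))
    lab_of_pair <- sub("^[0-9]+\r", "", pairs)
    tally <- table(factor(lab_of_pair, levels = sort(unique(label))))
    out$label_hits <- setNames(as.integer(tally), names(tally))
  }
  out
}

#' Resize peaks to a fixed width centered on their summits
#'
#' Re-centers each peak on its summit: with `w = width`, the output spans
#' `floor(w/2)` bases left of the summit and `ceil(w/2)` bases to the
#' right (half-open arithmetic), giving length exactly `w`.  Windows
#' running off a chromosome end are shifted back inside, preserving the
#' length; a chromosome shorter than `width` is an error.
#'
#' @param peaks `GRanges` with an integer metadata column `summit`
#'   (1-based genomic position, inside the peak) and seqlengths set.
#' @param width Target width in bases (default 300, the usual
#'   summit-centered window for narrow marks).
#' @return `GRanges` of constant width with the `summit` column retained.
#' @export
resize_around_summit <- function(peaks, width = 300L) {
  stopifnot(is(peaks, "GRanges"), width > 0)
  summit <- S4Vectors::mcols(peaks)$summit
  if (is.null(summit)) stop("peaks must carry a 'summit' metadata column")
  if (any(summit < GenomicRanges::start(peaks)) ||
      any(summit > GenomicRanges::end(peaks)))
    stop("summit outside its peak")
  len <- GenomeInfoDb::seqlengths(peaks)[as.character(GenomeInfoDb::seqnames(peaks))]
  if (any(is.na(len))) stop("peaks must carry seqlengths (see with_chrom_sizes)")
  if (any(len < width)) stop("chromosome shorter than the requested width")
  start <- summit - floor(width / 2)
  end <- summit - 1L + ceiling(width / 2)
  shift_r <- pmax(0L, 1L - start)
  start <- start + shift_r; end <- end + shift_r
  shift_l <- pmax(0L, end - len)
  start <- start - shift_l; end <- end - shift_l
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                                IRanges::IRanges(start, end),
                                strand = GenomicRanges::strand(peaks))
  S4Vectors::mcols(out) <- S4Vectors::mcols(peaks)
  GenomeInfoDb::seqinfo(out) <- GenomeInfoDb::seqinfo(peaks)
  out
}

#' Construct a repeat annotation
#'
#' Validates that every repeat instance carries the three RepeatMasker
#' taxonomy labels (`repeat_name`, `repeat_family`, `repeat_class`) as
#' non-empty strings.
#'
#' @param gr `GRanges` with metadata columns `repeat_name`,
#'   `repeat_family`, `repeat_class`.
#' @return The validated `GRanges`.
#' @export
repeat_annotation <- function(gr) {
  stopifnot(is(gr, "GRanges"))
  need <- c("repeat_name", "repeat_family", "repeat_class")
  mc <- S4Vectors::mcols(gr)
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    stop("repeat annotation lacks label column(s): ", paste(miss, collapse = ", "))
  for (col in need) {
    v <- mc[[col]]
    if (any(is.na(v)) || any(!nzchar(v)))
      stop("empty or missing values in ", col)
  }
  gr
}

#' Construct a gene annotation with TSSs, exons and introns
#'
#' Introns are computed per transcript as the transcript span minus its
#' exons.  Every transcript must be stranded (`+` or `-`); the TSS is the
#' 5' end on the annotated strand.
#'
#' @param transcripts `GRanges` of transcript spans with a
#'   `transcript_id` metadata column and explicit strand.
#' @param exons `GRanges` of exons with a `transcript_id` column.
#' @return A list of class `gene_annotation` with elements `transcripts`,
#'   `exons`, `introns` (all `GRanges`).
#' @export
gene_annotation <- function(transcripts, exons) {
  stopifnot(is(transcripts, "GRanges"), is(exons, "GRanges"))
  if (any(as.character(GenomicRanges::strand(transcripts)) == "*"))
    stop("transcript without strand: TSS is undefined")
  tid <- S4Vectors::mcols(transcripts)$transcript_id
  eid <- S4Vectors::mcols(exons)$transcript_id
  if (is.null(tid) || is.null(eid)) stop("transcript_id column required")
  ex_by_tx <- S4Vectors::split(GenomicRanges::ranges(exons), eid)
  intron_list <- list()
  for (i in seq_along(transcripts)) {
    id <- tid[i]
    span <- GenomicRanges::ranges(transcripts)[i]
    ex <- ex_by_tx[[id]]
    gaps <- if (is.null(ex)) span else
      IRanges::setdiff(span, IRanges::reduce(ex))
    if (length(gaps))
      intron_list[[length(intron_list) + 1L]] <- GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(transcripts)[i], gaps,
        strand = GenomicRanges::strand(transcripts)[i],
        transcript_id = id)
  }
  introns <- if (length(intron_list))
    suppressWarnings(do.call(c, intron_list))
  else GenomicRanges::GRanges()
  GenomeInfoDb::seqinfo(introns) <- GenomeInfoDb::seqinfo(transcripts)
  structure(list(transcripts = transcripts, exons = exons, introns = introns),
            class = "gene_annotation")
}

#' Strand-aware promoter (TSS) windows
#'
#' The promoter window runs from `width` bases upstream of the annotated
#' TSS up to (but not including) the TSS, reflected for minus-strand
#' transcripts.
#'
#' @param genes A [gene_annotation()] object.
#' @param width Window width in bases (default 300).
#' @return `GRanges` of promoter windows, clipped to chromosome bounds.
#' @export
tss_windows <- function(genes, width = 300L) {
  tx <- genes$transcripts
  win <- GenomicRanges::flank(tx, width = width, start = TRUE)
  GenomicRanges::trim(win)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", length(x$transcripts), "transcripts,",
      length(x$exons), "exons,", length(x$introns), "introns\n")
  invisible(x)
}
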
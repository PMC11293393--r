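#' Read an annotation or sequence file into the package's containers
#'
#' One entry point for the plain-text formats the pipeline touches.
#' Coordinates are converted to the internal `GRanges` convention at this
#' boundary: BED and narrowPeak are 0-based half-open on disk, GTF and
#' RepeatMasker `.out` are 1-based inclusive; labels are preserved
#' verbatim.  Malformed lines are reported with their line number and
#' dialect.
#'
#' @param path File path.
#' @param dialect One of `"bed"`, `"narrowpeak"`, `"gtf"`,
#'   `"repeatmasker_out"`, `"chromsizes"`, `"fasta"`.
#' @param chrom_sizes Named chromosome length vector; required for the
#'   interval dialects so coordinates can be validated on read.
#' @return `chromsizes` gives a named integer vector; `fasta` a
#'   [Biostrings::DNAStringSet]; `repeatmasker_out` a [repeat_annotation()]
#'   `GRanges`; the others a `GRanges` with dialect-specific metadata
#'   columns (`summit` for narrowPeak; parsed attributes for GTF).
#' @export
read_annotation <- function(path, dialect = c("bed", "narrowpeak", "gtf",
                                              "repeatmasker_out", "chromsizes",
                                              "fasta"),
                            chrom_sizes = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
    chromsizes = read_chromsizes(path),
    fasta = Biostrings::readDNAStringSet(path),
    bed = read_bed(path, chrom_sizes),
    narrowpeak = read_narrowpeak(path, chrom_sizes),
    gtf = read_gtf(path, chrom_sizes),
    repeatmasker_out = read_rmout(path, chrom_sizes))
}

bad_line <- function(dialect, i, why) {
  stop(sprintf("%s: malformed line %d (%s)", dialect, i, why), call. = FALSE)
}

split_lines <- function(path) {
  readLines(path, warn = FALSE)
}

read_chromsizes <- function(path) {
  lines <- split_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t| +")
  for (i in seq_along(parts))
    if (length(parts[[i]]) < 2 || is.na(suppressWarnings(as.integer(parts[[i]][2]))))
      bad_line("chromsizes", i, "expected <chrom>\\t<length>")
  validate_chrom_sizes(setNames(
    as.integer(vapply(parts, `[`, character(1), 2)),
    vapply(parts, `[`, character(1), 1)))
}

#' @rdname read_annotation
#' @export
write_chromsizes <- function(chrom_sizes, path) {
  writeLines(paste(names(chrom_sizes), chrom_sizes, sep = "\t"), path)
  invisible(path)
}

parse_tab <- function(path, dialect, min_fields) {
  lines <- split_lines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  parts <- strsplit(lines[keep], "\t")
  lineno <- which(keep)
  for (i in seq_along(parts))
    if (length(parts[[i]]) < min_fields)
      bad_line(dialect, lineno[i],
               sprintf("expected >=%d tab-separated fields", min_fields))
  list(parts = parts, lineno = lineno)
}

num_field <- function(parts, lineno, k, dialect) {
  v <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), k)))
  if (any(is.na(v))) bad_line(dialect, lineno[which(is.na(v))[1]],
                              sprintf("field %d is not numeric", k))
  v
}

read_bed <- function(path, chrom_sizes) {
  p <- parse_tab(path, "bed", 3L)
  if (!length(p$parts)) return(GenomicRanges::GRanges())
  chrom <- vapply(p$parts, `[`, character(1), 1)
  start0 <- num_field(p$parts, p$lineno, 2, "bed")
  end0 <- num_field(p$parts, p$lineno, 3, "bed")
  if (any(start0 < 0 | end0 <= start0))
    bad_line("bed", p$lineno[which(start0 < 0 | end0 <= start0)[1]],
             "need 0 <= start < end")
  n <- vapply(p$parts, length, integer(1))
  name <- ifelse(n >= 4, vapply(p$parts, function(x) x[4], character(1)), NA)
  strand <- ifelse(n >= 6, vapply(p$parts, function(x) x[6], character(1)), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                               strand = strand)
  if (!all(is.na(name))) S4Vectors::mcols(gr)$name <- name
  if (!is.null(chrom_sizes)) gr <- with_chrom_sizes(gr, chrom_sizes)
  gr
}

#' Write intervals as BED (0-based half-open)
#' @param gr `GRanges` to write.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  nm <- S4Vectors::mcols(gr)$name
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = if (is.null(nm)) "." else nm,
                   score = 0L,
                   strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

read_narrowpeak <- function(path, chrom_sizes) {
  p <- parse_tab(path, "narrowpeak", 10L)
  chrom <- vapply(p$parts, `[`, character(1), 1)
  start0 <- num_field(p$parts, p$lineno, 2, "narrowpeak")
  end0 <- num_field(p$parts, p$lineno, 3, "narrowpeak")
  offset <- num_field(p$parts, p$lineno, 10, "narrowpeak")
  if (any(offset >= end0 - start0))
    bad_line("narrowpeak", p$lineno[which(offset >= end0 - start0)[1]],
             "summit offset outside peak")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
  S4Vectors::mcols(gr)$name <- vapply(p$parts, `[`, character(1), 4)
  S4Vectors::mcols(gr)$signal <- num_field(p$parts, p$lineno, 7, "narrowpeak")
  # narrowPeak column 10 is the summit offset from the 0-based start; with
  # offset -1 (no summit) fall back to the peak midpoint
  summit <- ifelse(offset >= 0, start0 + offset + 1L,
                   floor((start0 + end0) / 2) + 1L)
  S4Vectors::mcols(gr)$summit <- as.integer(summit)
  if (!is.null(chrom_sizes)) gr <- with_chrom_sizes(gr, chrom_sizes)
  gr
}

#' @rdname write_bed
#' @export
write_narrowpeak <- function(gr, path) {
  summit <- S4Vectors::mcols(gr)$summit
  if (is.null(summit)) stop("narrowPeak output requires a 'summit' column")
  nm <- S4Vectors::mcols(gr)$name %||% paste0("peak_", seq_along(gr))
  sig <- S4Vectors::mcols(gr)$signal %||% 0
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm, score = 0L, strand = ".",
                   signal = sig, p = -1, q = -1,
                   peak = summit - GenomicRanges::start(gr))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

read_gtf <- function(path, chrom_sizes) {
  p <- parse_tab(path, "gtf", 9L)
  chrom <- vapply(p$parts, `[`, character(1), 1)
  type <- vapply(p$parts, `[`, character(1), 3)
  start1 <- num_field(p$parts, p$lineno, 4, "gtf")
  end1 <- num_field(p$parts, p$lineno, 5, "gtf")
  if (any(start1 < 1 | end1 < start1))
    bad_line("gtf", p$lineno[which(start1 < 1 | end1 < start1)[1]],
             "need 1 <= start <= end")
  strand <- vapply(p$parts, `[`, character(1), 7)
  strand[!strand %in% c("+", "-")] <- "*"
  attrs <- vapply(p$parts, `[`, character(1), 9)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1),
                               strand = strand)
  S4Vectors::mcols(gr)$type <- type
  for (key in c("gene_id", "transcript_id", "repeat_name", "repeat_family",
                "repeat_class")) {
    has <- grepl(paste0(key, ' "'), attrs)
    if (any(has)) {
      val <- rep(NA_character_, length(attrs))
      val[has] <- sub(paste0(key, ' "([^"]*)"'), "\\1",
                      regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs)))
      S4Vectors::mcols(gr)[[key]] <- val
    }
  }
  if (!is.null(chrom_sizes)) gr <- with_chrom_sizes(gr, chrom_sizes)
  gr
}

#' Read a gene annotation (transcripts + exons) from a GTF file
#' @inheritParams read_annotation
#' @return A [gene_annotation()] object.
#' @export
read_gene_annotation <- function(path, chrom_sizes = NULL) {
  gr <- read_gtf(path, chrom_sizes)
  tx <- gr[S4Vectors::mcols(gr)$type == "transcript"]
  ex <- gr[S4Vectors::mcols(gr)$type == "exon"]
  gene_annotation(tx, ex)
}

RMOUT_HEADER <- c(
  "   SW   perc perc perc  query          position in query     matching repeat",
  "score   div. del. ins.  sequence       begin  end   (left)   repeat         class/family     begin  end (left)  ID",
  "")

read_rmout <- function(path, chrom_sizes) {
  lines <- split_lines(path)
  if (length(lines) >= 3) lines <- lines[-(1:3)]  # fixed 3-line header
  keep <- which(nzchar(trimws(lines)))
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 11) bad_line("repeatmasker_out", i + 3L,
                                 "expected >=11 whitespace-separated fields")
    start1 <- suppressWarnings(as.integer(f[6]))
    end1 <- suppressWarnings(as.integer(f[7]))
    if (is.na(start1) || is.na(end1) || start1 < 1 || end1 < start1)
      bad_line("repeatmasker_out", i + 3L, "bad coordinates in fields 6-7")
    cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    out[[j]] <- data.frame(
      chrom = f[5], start = start1, end = end1,
      strand = if (f[9] == "C") "-" else "+",
      repeat_name = f[10],
      repeat_class = cf[1],
      repeat_family = if (length(cf) >= 2) cf[2] else cf[1],
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  if (is.null(df)) stop("repeatmasker_out: no repeat records in ", path)
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               strand = df$strand,
                               repeat_name = df$repeat_name,
                               repeat_family = df$repeat_family,
                               repeat_class = df$repeat_class)
  if (!is.null(chrom_sizes)) gr <- with_chrom_sizes(gr, chrom_sizes)
  repeat_annotation(gr)
}

#' Write a repeat annotation as a RepeatMasker .out-style table
#' @param repeats A [repeat_annotation()] `GRanges`.
#' @param path Output path.
#' @export
write_rmout <- function(repeats, path) {
  mc <- S4Vectors::mcols(repeats)
  cf <- ifelse(mc$repeat_family == mc$repeat_class, mc$repeat_class,
               paste0(mc$repeat_class, "/", mc$repeat_family))
  strand <- ifelse(as.character(GenomicRanges::strand(repeats)) == "-", "C", "+")
  rows <- sprintf("%5d %5.1f %4.1f %4.1f  %-14s %7d %7d (%d) %s %-16s %-16s %6d %6d (%d) %5d",
                  1000L, 0, 0, 0,
                  as.character(GenomeInfoDb::seqnames(repeats)),
                  GenomicRanges::start(repeats), GenomicRanges::end(repeats),
                  0L, strand, mc$repeat_name, cf, 1L,
                  GenomicRanges::width(repeats), 0L, seq_along(repeats))
  writeLines(c(RMOUT_HEADER, rows), path)
  invisible(path)
}

#' Write sequences as FASTA
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
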
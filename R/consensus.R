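#' Build a stitched LTR-internal-LTR consensus model
#'
#' LTR retroelement copies carry the long terminal repeat at both ends of
#' the internal coding sequence, but RepeatMasker consensi store the LTR
#' and the internal part separately.  Stitching reconstitutes the
#' full-length element: `LTR + internal + LTR`, with a segment table
#' marking the junctions for display.
#'
#' @param internal Internal consensus sequence (e.g. `IAPEz-int`).
#' @param ltr LTR consensus sequence (e.g. `IAPLTR1a_Mm`).
#' @param name Model name.
#' @return Object of class `consensus_model`: `name`, `sequence`,
#'   `segments` (`data.frame` with `segment`, `start`, `end`, 1-based
#'   closed, tiling the model).
#' @export
stitch_consensus <- function(internal, ltr, name = "stitched") {
  internal <- toupper(as.character(internal))
  ltr <- toupper(as.character(ltr))
  if (!nzchar(internal) || !nzchar(ltr)) stop("empty sequence")
  if (grepl("[^ACGTN]", internal) || grepl("[^ACGTN]", ltr))
    stop("invalid character: alphabet is A, C, G, T, N")
  L <- nchar(ltr); I <- nchar(internal)
  structure(list(
    name = name,
    sequence = paste0(ltr, internal, ltr),
    segments = data.frame(
      segment = c("LTR_5p", "internal", "LTR_3p"),
      start = c(1L, L + 1L, L + I + 1L),
      end = c(L, L + I, 2L * L + I))),
    class = "consensus_model")
}

#' Extract a segment's sequence from a consensus model
#' @param model A [stitch_consensus()] model.
#' @param segment Segment name (`"LTR_5p"`, `"internal"`, `"LTR_3p"`).
#' @export
model_segment <- function(model, segment) {
  s <- model$segments[model$segments$segment == segment, ]
  if (!nrow(s)) stop("unknown segment: ", segment)
  substr(model$sequence, s$start, s$end)
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("consensus_model '%s': %d bp (%s)\n", x$name, nchar(x$sequence),
              paste(sprintf("%s %d-%d", x$segments$segment, x$segments$start,
                            x$segments$end), collapse = ", ")))
  invisible(x)
}

#' Extract fragments overlapping selected repeat families, with sequence
#'
#' Returns exactly the fragments overlapping at least one instance whose
#' `repeat_name` is in `target_names`, each paired with its genomic
#' sequence (plus strand of the reference), ready for consensus
#' alignment.
#'
#' @param fragments A [fragment_set()].
#' @param repeats A [repeat_annotation()] `GRanges`.
#' @param target_names Character vector of `repeat_name` values.
#' @param genome `DNAStringSet` of the genome (for sequence extraction).
#' @return A `fragment_set` restricted to the matching fragments, with a
#'   `sequence` metadata column on its `fragments`.
#' @export
extract_repeat_fragments <- function(fragments, repeats, target_names,
                                     genome = NULL) {
  stopifnot(inherits(fragments, "fragment_set"))
  known <- unique(S4Vectors::mcols(repeats)$repeat_name)
  missing <- setdiff(target_names, known)
  if (length(missing))
    stop("repeat_name(s) not in annotation: ", paste(missing, collapse = ", "),
         "; known: ", paste(sort(known), collapse = ", "))
  targets <- repeats[S4Vectors::mcols(repeats)$repeat_name %in% target_names]
  keep <- GenomicRanges::countOverlaps(fragments$fragments, targets,
                                       ignore.strand = TRUE) > 0
  gr <- fragments$fragments[keep]
  if (!is.null(genome)) {
    seqs <- as.character(Biostrings::subseq(
      genome[as.character(GenomeInfoDb::seqnames(gr))],
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr)))
    S4Vectors::mcols(gr)$sequence <- unname(seqs)
  }
  fragment_set(fragments$sample_id, gr, library_size = fragments$library_size,
               spikein_size = fragments$spikein_size)
}

kmer_index <- function(sequence, k) {
  n <- nchar(sequence) - k + 1L
  if (n < 1L) stop("consensus shorter than seed length")
  kmers <- substring(sequence, seq_len(n), seq_len(n) + k - 1L)
  split(seq_len(n), kmers)
}

# mismatch count of `read` placed at consensus offset(s) `starts`
# (full-length, ungapped); raw-byte comparison, vectorized over offsets
mismatches_at <- function(cons_raw, read_raw, starts) {
  rl <- length(read_raw)
  vapply(starts, function(s)
    sum(cons_raw[s:(s + rl - 1L)] != read_raw), integer(1))
}

#' Ungapped seeded alignment of reads to a consensus model
#'
#' Finds, per read, the best full-read ungapped placement on the
#' consensus: exact `seed_length`-mer seeding at non-overlapping read
#' offsets (guaranteeing a hit whenever the best placement carries fewer
#' than `read_length / seed_length` mismatches), on both strands, then
#' mismatch counting over the full read span.  Score is
#' `matches - mismatches`.  An alignment is reported iff its mismatch
#' rate over the aligned span is at most `max_mismatch_rate`; ties are
#' broken by higher score, then leftmost start, then plus strand.
#'
#' @param reads Character vector of read sequences (shorter than the
#'   consensus).
#' @param model A [stitch_consensus()] model (or any list with a
#'   `sequence` and `name`).
#' @param seed_length Exact-match seed length (default 15).
#' @param max_mismatch_rate Maximum mismatch fraction (default 0.1).
#' @return `data.frame` of class `consensus_alignment`: `read_id`,
#'   `start`, `end` (1-based closed on the consensus), `strand`,
#'   `mismatches`, `score`, `aligned`; unaligned reads have `NA`
#'   coordinates and `aligned = FALSE`.
#' @export
align_to_consensus <- function(reads, model, seed_length = 15L,
                               max_mismatch_rate = 0.1) {
  cons <- model$sequence
  clen <- nchar(cons)
  if (any(nchar(reads) > clen)) stop("read longer than the consensus")
  if (any(nchar(reads) < seed_length))
    stop("seed_length exceeds a read length")
  idx <- kmer_index(cons, seed_length)
  cons_raw <- charToRaw(cons)
  n <- length(reads)
  out <- data.frame(read_id = seq_len(n), start = NA_integer_,
                    end = NA_integer_, strand = NA_character_,
                    mismatches = NA_integer_, score = NA_integer_,
                    aligned = FALSE)
  for (i in seq_len(n)) {
    best <- NULL
    for (strand in c("+", "-")) {
      seq <- if (strand == "+") reads[i] else revcomp(reads[i])
      rl <- nchar(seq)
      read_raw <- charToRaw(seq)
      seed_pos <- seq(1L, rl - seed_length + 1L, by = seed_length)
      cand <- integer(0)
      for (p in seed_pos) {
        hits <- idx[[substr(seq, p, p + seed_length - 1L)]]
        if (!is.null(hits)) cand <- c(cand, hits - p + 1L)
      }
      cand <- unique(cand)
      cand <- cand[cand >= 1L & cand + rl - 1L <= clen]
      if (!length(cand)) next
      mm <- mismatches_at(cons_raw, read_raw, cand)
      sc <- (rl - mm) - mm
      for (j in order(-sc, cand)) {
        hit <- list(start = cand[j], end = cand[j] + rl - 1L, strand = strand,
                    mismatches = mm[j], score = sc[j], rl = rl)
        if (is.null(best) || hit$score > best$score ||
            (hit$score == best$score && hit$start < best$start))
          best <- hit
        break  # candidates already ordered; only the top one can win
      }
    }
    if (!is.null(best) && best$mismatches / best$rl <= max_mismatch_rate) {
      out$start[i] <- best$start; out$end[i] <- best$end
      out$strand[i] <- best$strand
      out$mismatches[i] <- best$mismatches; out$score[i] <- best$score
      out$aligned[i] <- TRUE
    }
  }
  attr(out, "consensus") <- model$name
  attr(out, "consensus_length") <- clen
  class(out) <- c("consensus_alignment", "data.frame")
  out
}

#' Per-base normalized coverage on a consensus model, with replicate
#' mean and SD
#'
#' Depth at a base is the number of alignments covering it, scaled to
#' cpm by each sample's library size; mean and SD are taken across the
#' replicate samples per base.
#'
#' @param alignments Named list of [align_to_consensus()] results, one
#'   per replicate sample.
#' @param model The consensus model the alignments reference.
#' @param library_sizes Named numeric vector of per-sample library
#'   sizes.
#' @return Object of class `coverage_trace`: `position` (1-based),
#'   `cpm` (bases x samples matrix), `mean`, `sd`, `segments`.
#' @export
consensus_coverage <- function(alignments, model, library_sizes) {
  clen <- nchar(model$sequence)
  depth <- vapply(seq_along(alignments), function(k) {
    a <- alignments[[k]]
    a <- a[a$aligned, , drop = FALSE]
    if (any(a$start < 1 | a$end > clen))
      stop("alignment outside model bounds")
    d <- numeric(clen)
    if (nrow(a)) {
      # difference-array accumulation of interval coverage
      inc <- numeric(clen + 1L)
      for (r in seq_len(nrow(a))) {
        inc[a$start[r]] <- inc[a$start[r]] + 1
        inc[a$end[r] + 1L] <- inc[a$end[r] + 1L] - 1
      }
      d <- cumsum(inc[seq_len(clen)])
    }
    d / library_sizes[[k]] * 1e6
  }, numeric(clen))
  colnames(depth) <- names(alignments) %||% paste0("sample_", seq_along(alignments))
  structure(list(position = seq_len(clen), cpm = depth,
                 mean = rowMeans(depth),
                 sd = apply(depth, 1, sd),
                 segments = model$segments, name = model$name),
            class = "coverage_trace")
}

#' @export
print.coverage_trace <- function(x, ...) {
  cat(sprintf("coverage_trace '%s': %d bp, %d sample(s), mean depth %.3g cpm\n",
              x$name, length(x$position), ncol(x$cpm), mean(x$mean)))
  invisible(x)
}

#' Mean normalized depth per model segment
#' @param trace A [consensus_coverage()] result.
#' @return `data.frame` with `segment` and `mean_cpm`.
#' @export
segment_means <- function(trace) {
  seg <- trace$segments
  data.frame(segment = seg$segment,
             mean_cpm = vapply(seq_len(nrow(seg)), function(i)
               mean(trace$mean[seg$start[i]:seg$end[i]]), numeric(1)))
}
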
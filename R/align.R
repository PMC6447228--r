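#' Build decoy sequences spanning the natural IR boundaries
#'
#' Reads crossing the junctions of the second inverted repeat with the
#' single-copy regions are structurally normal but, after IR folding, look
#' like rearrangements. Two decoy sequences of `width` bp, one centered on
#' the SSC/IRb boundary and one on the IRb/LSC boundary (the origin-wrapping
#' join of the circle), are added to the reference set so such reads have a
#' contiguous placement and are never called as junctions.
#'
#' @param ref A `plastome_ref`.
#' @param width Decoy width in bp (even, default 400); half the width lies
#'   on either side of the boundary.
#' @return Named character vector of two decoy sequences
#'   (`decoy_SSC_IRb`, `decoy_IRb_LSC`).
#' @export
build_decoys <- function(ref, width = 400L) {
  if (width %% 2 != 0 || width < 40) stop("decoy width must be even and >= 40")
  half <- width %/% 2
  irb <- region_interval(ref, "IRb")
  reg_len <- ref$regions$end - ref$regions$start
  if (half > min(reg_len)) stop("decoy width larger than an adjacent region")
  d1 <- ref_sub(ref, irb["start"] - half, irb["start"] + half)
  d2 <- paste0(ref_sub(ref, ref$length - half, ref$length),
               ref_sub(ref, 0, half))
  c(decoy_SSC_IRb = unname(d1), decoy_IRb_LSC = unname(d2))
}

#' Assemble the reference set used for alignment
#'
#' The plastome is extended by `circular_ext` bases copied from its start so
#' reads crossing the origin align contiguously (coordinates are reduced
#' modulo the genome length afterwards); decoys and any extra compartments
#' (e.g. mitochondrial or nuclear sequences) are registered as additional
#' reference sequences.
#'
#' @param ref A `plastome_ref`.
#' @param decoy_width Width of the IR-boundary decoys (0 disables them).
#' @param extra Optional named character vector of additional reference
#'   sequences.
#' @param circular_ext Number of origin bases appended for circular
#'   alignment (default: one read length minus one; pass the read length
#'   in use).
#' @return An object of class `ref_set`.
#' @export
reference_set <- function(ref, decoy_width = 400L, extra = character(0),
                          circular_ext = 149L) {
  stopifnot(inherits(ref, "plastome_ref"))
  seqs <- c(stats::setNames(
    paste0(ref$seq, substr(ref$seq, 1, circular_ext)), ref$name))
  decoys <- character(0)
  if (decoy_width > 0) {
    d <- build_decoys(ref, decoy_width)
    seqs <- c(seqs, d)
    decoys <- names(d)
  }
  if (length(extra)) {
    if (is.null(names(extra)) || any(names(extra) == "")) {
      stop("extra reference sequences must be named")
    }
    seqs <- c(seqs, toupper(extra))
  }
  structure(list(seqs = seqs, plastome = ref$name, decoys = decoys,
                 extra = names(extra), L = ref$length, ref = ref),
            class = "ref_set")
}

#' Align reads to a reference set (gap-free local alignment)
#'
#' Seed-and-extend gap-free local alignment on both strands against every
#' sequence in the reference set, reporting all maximal local alignments
#' scoring at least `min_score` (match +1, mismatch -2 by default) and at
#' least `min_len` bases long on the read. Plastome coordinates are reduced
#' modulo the genome length (alignments may wrap the origin, in which case
#' `ref_end` exceeds the genome length). Deterministic for fixed parameters.
#'
#' @param reads Named character vector of read sequences (uppercase ACGT).
#' @param refset A `ref_set` from [reference_set()].
#' @param k Seed k-mer length (default 12).
#' @param match,mismatch Scoring scheme (defaults +1 / -2).
#' @param min_score Minimum alignment score (default 20).
#' @param min_len Minimum aligned length on the read (default 20).
#' @return data.frame with columns `read_id`, `read_start`, `read_end`
#'   (0-based half-open on the read), `ref_name`, `ref_start`, `ref_end`
#'   (0-based half-open), `strand`, `mismatches`, `score`.
#' @export
align_reads <- function(reads, refset, k = 12L, match = 1L, mismatch = -2L,
                        min_score = 20L, min_len = 20L) {
  stopifnot(inherits(refset, "ref_set"))
  if (length(reads) == 0) stop("no reads supplied")
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  bad <- !nzchar(reads) | grepl("[^ACGT]", reads)
  if (any(bad)) {
    stop("empty or non-ACGT read sequence(s): ",
         paste(utils::head(names(reads)[bad], 3), collapse = ", "))
  }
  hits <- ungapped_align_cpp(unname(reads), unname(refset$seqs),
                             as.integer(k), as.integer(match),
                             as.integer(mismatch), as.integer(min_score),
                             as.integer(min_len))
  aln <- data.frame(
    read_id = names(reads)[hits$read_idx],
    read_start = hits$read_start, read_end = hits$read_end,
    ref_name = names(refset$seqs)[hits$ref_idx],
    ref_start = hits$ref_start, ref_end = hits$ref_end,
    strand = hits$strand, mismatches = hits$mismatches, score = hits$score,
    stringsAsFactors = FALSE
  )
  # reduce plastome coordinates modulo L (circular extension) and drop
  # duplicate placements created by the extension
  on_pt <- aln$ref_name == refset$plastome
  L <- refset$L
  shift <- on_pt & aln$ref_start >= L
  aln$ref_start[shift] <- aln$ref_start[shift] - L
  aln$ref_end[shift] <- aln$ref_end[shift] - L
  key <- paste(aln$read_id, aln$read_start, aln$read_end, aln$ref_name,
               aln$ref_start, aln$strand)
  aln <- aln[!duplicated(key), , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

#' Import / export alignments as 12-column tabular records
#'
#' The standard tabular alignment format (query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, query start, query
#' end, subject start, subject end, e-value, score) with 1-based inclusive
#' coordinates and minus-strand alignments encoded by `sstart > send`. This
#' lets an external local-alignment search tool stand in for the built-in
#' engine.
#'
#' @param aln Alignment data.frame as returned by [align_reads()].
#' @param path Tab-separated file path.
#' @return `write_tabular_alignments` returns `path` invisibly;
#'   `read_tabular_alignments` returns an alignment data.frame.
#' @export
write_tabular_alignments <- function(aln, path) {
  len <- aln$read_end - aln$read_start
  minus <- aln$strand == "-"
  sstart <- ifelse(minus, aln$ref_end, aln$ref_start + 1L)
  send <- ifelse(minus, aln$ref_start + 1L, aln$ref_end)
  out <- data.frame(
    qseqid = aln$read_id, sseqid = aln$ref_name,
    pident = round(100 * (len - aln$mismatches) / len, 2),
    length = len, mismatch = aln$mismatches, gapopen = 0L,
    qstart = aln$read_start + 1L, qend = aln$read_end,
    sstart = sstart, send = send, evalue = 0, bitscore = aln$score,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tabular_alignments
#' @export
read_tabular_alignments <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("qseqid", "sseqid", "pident", "length",
                                       "mismatch", "gapopen", "qstart", "qend",
                                       "sstart", "send", "evalue", "bitscore"))
  minus <- x$sstart > x$send
  data.frame(
    read_id = x$qseqid,
    read_start = x$qstart - 1L, read_end = x$qend,
    ref_name = x$sseqid,
    ref_start = ifelse(minus, x$send, x$sstart) - 1L,
    ref_end = ifelse(minus, x$sstart, x$send),
    strand = ifelse(minus, "-", "+"),
    mismatches = x$mismatch, score = x$bitscore,
    stringsAsFactors = FALSE
  )
}
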
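#' Parameters controlling split-read junction detection
#'
#' @param min_seg_len Minimum aligned length per split segment (bp).
#' @param min_score Minimum local alignment score per segment.
#' @param min_covered_fraction Fraction of the read that must be explained
#'   by the two segments plus any inserted bases.
#' @param max_middle_gap Maximum unaligned middle (inserted bases) in bp;
#'   caps the detectable insertion size.
#' @param collinear_tol Pairs whose implied reference adjacency matches the
#'   reference within this many bp are reference-consistent, not junctions.
#' @param max_mismatch_full Mismatches tolerated in a "fully aligned" read.
#' @param merge_tol Breakpoint tolerance (bp) when deduplicating junction
#'   candidates into unique events.
#' @param seed_k Seed k-mer length of the alignment engine.
#' @return A named list of parameters.
#' @export
split_params <- function(min_seg_len = 20L, min_score = 20L,
                         min_covered_fraction = 0.9, max_middle_gap = 50L,
                         collinear_tol = 2L, max_mismatch_full = 5L,
                         merge_tol = 0L, seed_k = 12L) {
  list(min_seg_len = min_seg_len, min_score = min_score,
       min_covered_fraction = min_covered_fraction,
       max_middle_gap = max_middle_gap, collinear_tol = collinear_tol,
       max_mismatch_full = max_mismatch_full, merge_tol = merge_tol,
       seed_k = seed_k)
}

# is a pair of same-strand alignments consistent with the (circular)
# reference, i.e. the implied shift between read and reference gaps is ~0?
is_collinear <- function(a, b, L, tol) {
  if (a$ref_name != b$ref_name || a$strand != b$strand) return(FALSE)
  read_gap <- b$read_start - a$read_end
  ref_gap <- if (a$strand == "+") b$ref_start - a$ref_end else
    a$ref_start - b$ref_end
  diff <- ref_gap - read_gap
  if (!is.null(L)) diff <- min(abs(c(diff, diff - L, diff + L)))
  abs(diff) <= tol
}

# a segment is decoy-dominated if a decoy alignment covers >= 80% of its
# read interval with at least its score
decoy_dominated <- function(seg, group, decoys) {
  d <- group[group$ref_name %in% decoys, , drop = FALSE]
  if (nrow(d) == 0) return(FALSE)
  ov <- pmin(d$read_end, seg$read_end) - pmax(d$read_start, seg$read_start)
  any(ov >= 0.8 * (seg$read_end - seg$read_start) & d$score >= seg$score)
}

#' Detect a split-read junction candidate among one read's alignments
#'
#' Returns a candidate only if a pair of alignments covers the read's 5' and
#' 3' ends (combined coverage, counting any unaligned middle as inserted
#' bases, of at least `min_covered_fraction`), the implied adjacency differs
#' from the reference, both segments lie on the plastome and neither
#' segment's placement is dominated by a decoy. Among valid pairs the
#' highest combined score wins; ties are broken by smallest absolute
#' overlap, then by reference position.
#'
#' @param group data.frame of alignments for a single read (from
#'   [align_reads()]).
#' @param read_len Read length (bp).
#' @param refset The `ref_set` used for alignment.
#' @param params See [split_params()].
#' @return A list with `aln_a`, `aln_b` (one-row data.frames, `aln_a` covers
#'   the 5' part of the read) and `overlap`, or `NULL` if the read is not a
#'   split candidate.
#' @export
detect_split <- function(group, read_len, refset, params = split_params()) {
  if (nrow(group) == 0) return(NULL)
  stopifnot(length(unique(group$read_id)) == 1)
  # a read explained by one alignment is not split
  covered <- group$read_end - group$read_start
  if (any(covered >= params$min_covered_fraction * read_len &
          group$mismatches <= params$max_mismatch_full)) return(NULL)
  pt <- group[group$ref_name == refset$plastome, , drop = FALSE]
  if (nrow(pt) < 2) return(NULL)
  max_end_gap <- (1 - params$min_covered_fraction) * read_len

  best <- NULL
  for (i in seq_len(nrow(pt))) {
    for (j in seq_len(nrow(pt))) {
      if (i == j) next
      a <- pt[i, ]; b <- pt[j, ]
      if (a$read_start >= b$read_start) next
      if (b$read_end <= a$read_end) next        # containment
      if (a$read_start + (read_len - b$read_end) > max_end_gap) next
      mid_gap <- b$read_start - a$read_end
      if (mid_gap > params$max_middle_gap) next
      if (is_collinear(a, b, refset$L, params$collinear_tol)) next
      if (decoy_dominated(a, group, refset$decoys) ||
          decoy_dominated(b, group, refset$decoys)) next
      ov <- compute_overlap(a, b, read_len)
      cand <- list(aln_a = a, aln_b = b, overlap = ov,
                   key = c(-(a$score + b$score), abs(ov),
                           a$ref_start, b$ref_start))
      if (is.null(best) ||
          isTRUE(vector_less(cand$key, best$key))) best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  best$key <- NULL
  best
}

# lexicographic comparison of numeric vectors
vector_less <- function(x, y) {
  for (i in seq_along(x)) {
    if (x[i] < y[i]) return(TRUE)
    if (x[i] > y[i]) return(FALSE)
  }
  FALSE
}

#' Select a fully aligned plastid read pair for coverage analysis
#'
#' A pair qualifies if each mate has a full-length plastome placement
#' (coverage of at least `min_covered_fraction` of the read with at most
#' `max_mismatch_full` mismatches) and no decoy or extra-compartment
#' placement scores strictly higher. When a mate has several equal-best
#' plastome placements (inverted repeat copies), the one with the smallest
#' reference coordinate is used, which folds IR reads onto the first IR.
#'
#' @param group1,group2 Alignments for mate 1 and mate 2 of one pair.
#' @param read_len Read length (bp).
#' @param refset The `ref_set` used for alignment.
#' @param params See [split_params()].
#' @return Integer vector of the two mates' reference start positions
#'   (0-based, reduced modulo genome length), or `NULL` if the pair does not
#'   qualify.
#' @export
filter_full_pairs <- function(group1, group2, read_len, refset,
                              params = split_params()) {
  pos <- integer(2)
  groups <- list(group1, group2)
  for (m in 1:2) {
    g <- groups[[m]]
    if (nrow(g) == 0) return(NULL)
    full <- g[g$read_end - g$read_start >=
                params$min_covered_fraction * read_len &
              g$mismatches <= params$max_mismatch_full, , drop = FALSE]
    if (nrow(full) == 0) return(NULL)
    on_pt <- full$ref_name == refset$plastome
    if (!any(on_pt)) return(NULL)
    best_pt <- max(full$score[on_pt])
    if (any(!on_pt & full$score > best_pt)) return(NULL)  # off-plastome wins
    cand <- full[on_pt & full$score == best_pt, , drop = FALSE]
    pos[m] <- min(cand$ref_start %% refset$L)
  }
  pos
}
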
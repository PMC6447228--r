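#' Overlap (microhomology) statistic of a split read
#'
#' The sum of the two split-alignment lengths on the read minus the read
#' length. A positive value is the length of sequence shared by both
#' parental loci at the junction (microhomology), zero is a blunt join, and
#' a negative value is the number of bases inserted at the junction.
#'
#' @param aln_a,aln_b The two alignments of one read (rows from
#'   [align_reads()], or any list with `read_start`/`read_end`).
#' @param read_len Read length (bp).
#' @return Integer overlap; `>= 5` is classified as +MH.
#' @export
compute_overlap <- function(aln_a, aln_b, read_len) {
  if (!is.null(aln_a$read_id) && !is.null(aln_b$read_id) &&
      aln_a$read_id != aln_b$read_id) {
    stop("alignments belong to different reads")
  }
  (aln_a$read_end - aln_a$read_start) +
    (aln_b$read_end - aln_b$read_start) - read_len
}

#' Classify an overlap as microhomology-mediated or not
#'
#' Junctions with an overlap of at least 5 bases are considered to have used
#' microhomology (`+MH`); all others, including blunt joins and insertions
#' (negative overlap), are `-MH`. The signed value is retained for
#' homology-length histograms.
#'
#' @param overlap Integer vector of overlap values.
#' @return Character vector, `"+MH"` or `"-MH"`.
#' @export
classify_mh <- function(overlap) {
  ifelse(overlap >= 5, "+MH", "-MH")
}

# breakpoint coordinates of a split candidate: pos_a is the first reference
# base after segment A's end in read-walking direction (homologous bases
# assigned to segment A); pos_b is the reference base where the read enters
# locus B. 0-based, reduced modulo L.
candidate_breakpoints <- function(cand, L) {
  a <- cand$aln_a; b <- cand$aln_b
  p_a <- if (a$strand == "+") a$ref_end else a$ref_start - 1L
  p_b <- if (b$strand == "+") b$ref_start else b$ref_end - 1L
  c(pos_a = as.integer(p_a %% L), pos_b = as.integer(p_b %% L))
}

#' Canonical representation of a junction
#'
#' The same junction observed on the two strands of a molecule yields two
#' coordinate representations; this maps both to one canonical form so
#' deduplication counts them as a single event. Same-strand junctions are
#' reported on the plus strand; for inversion junctions the lexicographically
#' smaller of the two equivalent representations is used.
#'
#' @param pos_a,pos_b Breakpoint coordinates (0-based).
#' @param strand_a,strand_b Segment strands (`"+"`/`"-"`).
#' @param L Genome length (for modular reduction).
#' @return Named list `pos_a`, `pos_b`, `strand_a`, `strand_b`.
#' @export
canonical_junction <- function(pos_a, pos_b, strand_a, strand_b, L) {
  p_a <- pos_a %% L; p_b <- pos_b %% L
  if (strand_a == "-" && strand_b == "-") {
    out <- c((p_b + 1) %% L, (p_a + 1) %% L); s <- c("+", "+")
  } else if (strand_a == "+" && strand_b == "-") {
    alt <- c((p_b + 1) %% L, (p_a - 1) %% L)
    out <- if (vector_less(alt, c(p_a, p_b))) alt else c(p_a, p_b)
    s <- c("+", "-")
  } else if (strand_a == "-" && strand_b == "+") {
    alt <- c((p_b - 1) %% L, (p_a + 1) %% L)
    out <- if (vector_less(alt, c(p_a, p_b))) alt else c(p_a, p_b)
    s <- c("-", "+")
  } else {
    out <- c(p_a, p_b); s <- c("+", "+")
  }
  list(pos_a = as.integer(out[1]), pos_b = as.integer(out[2]),
       strand_a = s[1], strand_b = s[2])
}

#' Classify the event type implied by a junction's geometry
#'
#' Junctions whose segments map to opposite strands are inversions. For
#' same-strand junctions on the circular genome, the forward skip
#' `d = (pos_b - pos_a) mod L` distinguishes deletions (`0 < d < L/2`) from
#' duplication/circularization junctions that loop backwards (`d >= L/2`).
#'
#' @param pos_a,pos_b Canonical breakpoint coordinates (pre-folding).
#' @param strand_a,strand_b Segment strands.
#' @param L Genome length.
#' @return `"deletion"`, `"duplication"` or `"inversion"`.
#' @export
classify_event_type <- function(pos_a, pos_b, strand_a, strand_b, L) {
  if (strand_a != strand_b) return("inversion")
  d <- (pos_b - pos_a) %% L
  if (d == 0) {
    stop("zero-length adjacency is reference-consistent, not a junction")
  }
  if (d < L / 2) "deletion" else "duplication"
}

# fold a junction's breakpoints onto the first IR, flipping the strand of a
# folded side, then re-canonicalize
fold_junction <- function(pos_a, pos_b, strand_a, strand_b, ref) {
  irb <- region_interval(ref, "IRb")
  in_irb <- function(p) p >= irb["start"] && p < irb["end"]
  flip <- c("+" = "-", "-" = "+")
  if (in_irb(pos_a)) { pos_a <- fold_ir(pos_a, ref); strand_a <- flip[[strand_a]] }
  if (in_irb(pos_b)) { pos_b <- fold_ir(pos_b, ref); strand_b <- flip[[strand_b]] }
  canonical_junction(pos_a, pos_b, strand_a, strand_b, ref$length)
}

#' Turn split-read candidates into a junction candidate table
#'
#' Computes, for every candidate, the overlap statistic, canonical
#' breakpoints, the event type (from the pre-folding geometry) and the
#' IR-folded coordinates.
#'
#' @param candidates List of candidates from [detect_split()].
#' @param read_len Read length (bp).
#' @param ref A `plastome_ref`.
#' @return data.frame with one row per supporting read: `read_id`, `pos_a`,
#'   `pos_b`, `strand_a`, `strand_b`, `homology_len`, `event_type`.
#' @export
candidate_table <- function(candidates, read_len, ref) {
  rows <- lapply(candidates, function(cand) {
    bp <- candidate_breakpoints(cand, ref$length)
    cj <- canonical_junction(bp["pos_a"], bp["pos_b"],
                             cand$aln_a$strand, cand$aln_b$strand, ref$length)
    type <- classify_event_type(cj$pos_a, cj$pos_b, cj$strand_a, cj$strand_b,
                                ref$length)
    fj <- fold_junction(cj$pos_a, cj$pos_b, cj$strand_a, cj$strand_b, ref)
    data.frame(read_id = cand$aln_a$read_id,
               pos_a = fj$pos_a, pos_b = fj$pos_b,
               strand_a = fj$strand_a, strand_b = fj$strand_b,
               homology_len = cand$overlap, event_type = type,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(read_id = character(0), pos_a = integer(0),
                      pos_b = integer(0), strand_a = character(0),
                      strand_b = character(0), homology_len = integer(0),
                      event_type = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Deduplicate junction candidates into unique events
#'
#' Candidates are grouped by breakpoints, strands and homology length;
#' with `merge_tol > 0`, breakpoints within the tolerance are merged into
#' one group (useful for noisy data) and the group's homology length and
#' positions are taken from the majority of supporting reads. Support is
#' the group size, so the total read support is conserved.
#'
#' @param cands data.frame from [candidate_table()].
#' @param merge_tol Breakpoint tolerance in bp (default 0: exact keys).
#' @return data.frame of unique events sorted by `(pos_a, pos_b)`: columns
#'   `pos_a`, `pos_b`, `strand_a`, `strand_b`, `homology_len`, `mh_class`,
#'   `event_type`, `support`.
#' @export
deduplicate_junctions <- function(cands, merge_tol = 0L) {
  empty <- data.frame(pos_a = integer(0), pos_b = integer(0),
                      strand_a = character(0), strand_b = character(0),
                      homology_len = integer(0), mh_class = character(0),
                      event_type = character(0), support = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(cands) == 0) return(empty)
  if (merge_tol == 0) {
    key <- paste(cands$pos_a, cands$pos_b, cands$strand_a, cands$strand_b,
                 cands$homology_len)
    groups <- split(seq_len(nrow(cands)), key)
  } else {
    # greedy clustering on sorted breakpoints within the same strand pair
    ord <- order(cands$strand_a, cands$strand_b, cands$pos_a, cands$pos_b)
    grp <- integer(nrow(cands))
    gid <- 0L
    anchor <- NULL
    for (i in ord) {
      if (is.null(anchor) ||
          cands$strand_a[i] != anchor$sa || cands$strand_b[i] != anchor$sb ||
          abs(cands$pos_a[i] - anchor$pa) > merge_tol ||
          abs(cands$pos_b[i] - anchor$pb) > merge_tol) {
        gid <- gid + 1L
        anchor <- list(sa = cands$strand_a[i], sb = cands$strand_b[i],
                       pa = cands$pos_a[i], pb = cands$pos_b[i])
      }
      grp[i] <- gid
    }
    groups <- split(seq_len(nrow(cands)), grp)
  }
  majority <- function(x) as.integer(names(sort(table(x), decreasing = TRUE))[1])
  ev <- lapply(groups, function(idx) {
    g <- cands[idx, , drop = FALSE]
    data.frame(pos_a = majority(g$pos_a), pos_b = majority(g$pos_b),
               strand_a = g$strand_a[1], strand_b = g$strand_b[1],
               homology_len = majority(g$homology_len),
               event_type = names(sort(table(g$event_type),
                                       decreasing = TRUE))[1],
               support = nrow(g), stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  ev$mh_class <- classify_mh(ev$homology_len)
  ev <- ev[order(ev$pos_a, ev$pos_b),
           c("pos_a", "pos_b", "strand_a", "strand_b", "homology_len",
             "mh_class", "event_type", "support")]
  rownames(ev) <- NULL
  ev
}
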
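#' Find the short direct repeat shared at a recombinant junction
#'
#' Decomposes a recombinant junction sequence into a 5' part matching a
#' substring of the upstream parental locus and a 3' part matching a
#' substring of the downstream parental locus, and reports the longest
#' repeat block that ends the upstream-matching part, begins the
#' downstream-matching part, and occurs in both parents at the junction with
#' at most `max_mismatch` substitutions (counted between the two parental
#' repeat copies). Ties are broken by fewest mismatches, then by the
#' leftmost repeat position in the upstream parent.
#'
#' @param parent_a Upstream parental sequence (uppercase ACGT).
#' @param parent_b Downstream parental sequence.
#' @param recombinant Recombinant junction sequence.
#' @param max_mismatch Substitutions tolerated between the parental repeat
#'   copies (default 0).
#' @param allow_gap Also try decompositions in which the recombinant's
#'   junction copy carries one internal deletion of up to `gap_max` bases
#'   relative to the upstream parent (off by default; the gapped scoring is
#'   a heuristic).
#' @param gap_max Maximum internal gap length tried when `allow_gap = TRUE`.
#' @return A list of class `repeat_annotation`: `repeat_seq`, `length`,
#'   `mismatches`, `pos_parent_a`, `pos_parent_b` (0-based half-open
#'   intervals of the repeat copies), `junction` (split offset in the
#'   recombinant) and `gap` (bases deleted in the recombinant copy; 0
#'   without `allow_gap`).
#' @examples
#' find_direct_repeat("GGGTTTAAACCC", "TTTTAAACCCGG", "GGGTTTAAACCCGG")
#' @export
find_direct_repeat <- function(parent_a, parent_b, recombinant,
                               max_mismatch = 0L, allow_gap = FALSE,
                               gap_max = 3L) {
  check_dna <- function(x) {
    x <- toupper(x)
    if (!nzchar(x) || grepl("[^ACGT]", x)) stop("sequences must be non-empty ACGT")
    x
  }
  parent_a <- check_dna(parent_a)
  parent_b <- check_dna(parent_b)
  recombinant <- check_dna(recombinant)

  best <- scan_repeat(parent_a, parent_b, recombinant, max_mismatch)
  if (!is.null(best)) best$gap <- 0L
  if (allow_gap) {
    for (g in seq_len(gap_max)) {
      na <- nchar(parent_a)
      for (p in seq_len(na - g)) {
        pa <- paste0(substr(parent_a, 1, p - 1),
                     substr(parent_a, p + g, na))
        cand <- scan_repeat(pa, parent_b, recombinant, max_mismatch)
        if (is.null(cand)) next
        cand$gap <- g
        cand$length <- cand$length + g   # repeat extent on the parent
        if (is.null(best) || cand$length > best$length ||
            (cand$length == best$length && cand$mismatches < best$mismatches)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) {
    stop("recombinant cannot be decomposed into a parent_a-then-parent_b junction")
  }
  class(best) <- "repeat_annotation"
  best
}

# exhaustive scan over all junction decompositions of the recombinant;
# returns NULL when no decomposition exists
scan_repeat <- function(parent_a, parent_b, recombinant, max_mismatch) {
  n <- nchar(recombinant)
  ra <- strsplit(recombinant, "")[[1]]
  pa <- strsplit(parent_a, "")[[1]]
  pb <- strsplit(parent_b, "")[[1]]
  best <- NULL
  for (k in seq_len(n - 1)) {
    a_part <- substr(recombinant, 1, k)
    b_part <- substr(recombinant, k + 1, n)
    ia <- find_all(parent_a, a_part)          # end positions (1-based)
    if (length(ia) == 0) break                # longer prefixes cannot match
    jb <- find_all_starts(parent_b, b_part)   # start positions (1-based)
    if (length(jb) == 0) next
    for (i_end in ia) {
      for (j in jb) {
        m_max <- min(k, j - 1)
        for (m in m_max:0) {
          if (!is.null(best) && m < best$length) break
          mm <- if (m == 0) 0L else
            sum(ra[(k - m + 1):k] != pb[(j - m):(j - 1)])
          if (mm > max_mismatch) next
          cand <- list(
            repeat_seq = substr(recombinant, k - m + 1, k),
            length = m, mismatches = as.integer(mm),
            pos_parent_a = c(i_end - m, i_end),      # 0-based half-open
            pos_parent_b = c(j - 1 - m, j - 1),
            junction = k
          )
          if (is.null(best) || cand$length > best$length ||
              (cand$length == best$length &&
               (cand$mismatches < best$mismatches ||
                (cand$mismatches == best$mismatches &&
                 cand$pos_parent_a[1] < best$pos_parent_a[1])))) {
            best <- cand
          }
          break   # smaller m at same (k, i, j) cannot improve
        }
      }
    }
  }
  best
}

# all end positions (1-based) of exact occurrences of `pattern` in `x`
find_all <- function(x, pattern) {
  hits <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  as.integer(hits) + nchar(pattern) - 1L
}

# all start positions (1-based)
find_all_starts <- function(x, pattern) {
  hits <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  as.integer(hits)
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat("Direct repeat at junction: ", x$length, " bp",
      if (x$gap > 0) paste0(" (", x$gap, "-bp gap in recombinant copy)"),
      ", ", x$mismatches, " mismatch(es)\n", sep = "")
  if (x$length > 0) cat("  ", x$repeat_seq, "\n", sep = "")
  cat("  parent A [", x$pos_parent_a[1], ",", x$pos_parent_a[2],
      ")  parent B [", x$pos_parent_b[1], ",", x$pos_parent_b[2], ")\n",
      sep = "")
  invisible(x)
}

#' Coverage-normalized homology-length histogram
#'
#' Counts unique events by signed homology length (negative lengths are
#' inserted bases) and normalizes to the coverage per 10,000 genomes.
#'
#' @param events Events data.frame from [deduplicate_junctions()].
#' @param coverage Mean fold-coverage (number or `coverage_profile`, > 0).
#' @return Named numeric vector: normalized unique-event count per signed
#'   homology length.
#' @export
homology_histogram <- function(events, coverage) {
  cov <- coverage_value(coverage)
  if (cov <= 0) stop("coverage must be > 0")
  if (nrow(events) == 0) return(stats::setNames(numeric(0), character(0)))
  tab <- table(events$homology_len)
  stats::setNames(as.numeric(tab) / cov * 1e4, names(tab))
}
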
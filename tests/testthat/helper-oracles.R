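# Independent oracles and small fixtures used across the suite.

# exhaustive gap-free local-alignment score by dynamic programming
# (Smith-Waterman with gaps forbidden), both strands
sw_ungapped_best <- function(read, ref, match = 1, mismatch = -2) {
  one_strand <- function(q, s) {
    qc <- strsplit(q, "")[[1]]
    sc <- strsplit(s, "")[[1]]
    best <- 0
    prev <- numeric(length(sc) + 1)
    for (i in seq_along(qc)) {
      cur <- numeric(length(sc) + 1)
      sub <- ifelse(qc[i] == sc, match, mismatch)
      cur[-1] <- pmax(0, prev[-length(prev)] + sub)
      best <- max(best, cur)
      prev <- cur
    }
    best
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  max(one_strand(read, ref), one_strand(rc, ref))
}

# brute-force direct-repeat annotation: scans every junction decomposition
# (split point, occurrence in each parent, repeat extent) by naive substring
# comparison; returns NULL when the recombinant has no valid decomposition
brute_repeat <- function(parent_a, parent_b, rec, max_mm = 0) {
  n <- nchar(rec)
  na <- nchar(parent_a); nb <- nchar(parent_b)
  cs <- function(x) strsplit(x, "")[[1]]
  rc <- cs(rec); ac <- cs(parent_a); bc <- cs(parent_b)
  best <- NULL
  for (k in 1:(n - 1)) {
    if (k > na) break
    ends_a <- integer(0)
    for (i in k:na) {
      if (all(rc[1:k] == ac[(i - k + 1):i])) ends_a <- c(ends_a, i)
    }
    if (!length(ends_a)) next
    lb <- n - k
    starts_b <- integer(0)
    if (lb <= nb) {
      for (j in 1:(nb - lb + 1)) {
        if (all(rc[(k + 1):n] == bc[j:(j + lb - 1)])) starts_b <- c(starts_b, j)
      }
    }
    for (i in ends_a) {
      for (j in starts_b) {
        for (m in 0:min(k, j - 1)) {
          mm <- if (m == 0) 0 else
            sum(rc[(k - m + 1):k] != bc[(j - m):(j - 1)])
          if (mm > max_mm) next
          cand <- list(length = m, mismatches = mm, left = i - m + 1)
          if (is.null(best) || cand$length > best$length ||
              (cand$length == best$length &&
               (cand$mismatches < best$mismatches ||
                (cand$mismatches == best$mismatches &&
                 cand$left < best$left)))) best <- cand
        }
      }
    }
  }
  best
}

# closed-form Pearson chi-squared statistic on a 2x2 table
pearson_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# small quadripartite reference for fast tests
small_ref <- function(seed = 1) plastome_reference(3000, 1000, 1500, seed = seed)

# the canonical, IR-folded event a planted junction should produce
expected_event <- function(tr, ref) {
  cj <- canonical_junction(tr$pos_a, tr$pos_b, "+", tr$strand_b, ref$length)
  list(pos_a = cj$pos_a, pos_b = cj$pos_b,
       homology = tr$expected_homology, type = tr$kind)
}

# locate a planted junction among called events; returns matching row count
match_planted <- function(events, tr, ref) {
  ex <- expected_event(tr, ref)
  sum(events$pos_a == ex$pos_a & events$pos_b == ex$pos_b &
      events$homology_len == ex$homology & events$event_type == ex$type)
}
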
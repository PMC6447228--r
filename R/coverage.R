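#' Per-kb coverage profile with IR folding
#'
#' Each fully aligned plastid read contributes one count to the bin obtained
#' by folding its start position onto the first IR and rounding down to the
#' nearest kb. Mean fold-coverage (genome copies) is total read bases over
#' the IR-folded genome length.
#'
#' @param positions Integer vector of read start positions (0-based,
#'   unfolded) from [filter_full_pairs()].
#' @param ref A `plastome_ref`.
#' @param read_len Read length in bp (used for fold-coverage).
#' @param bin_size Bin width in bp (default 1000).
#' @return Object of class `coverage_profile`: list with `bin_size`,
#'   `counts` (one per folded bin, named by bin index), `n_copies` (copy
#'   number of each bin: 2 inside the IR, 1 elsewhere),
#'   `total_plastid_reads`, `mean_fold_coverage`, `folded_length`,
#'   `read_len`.
#' @export
per_kb_profile <- function(positions, ref, read_len = 150L, bin_size = 1000L) {
  fl <- folded_length(ref)
  n_bins <- ceiling(fl / bin_size)
  counts <- integer(n_bins)
  if (length(positions)) {
    folded <- fold_ir(as.integer(positions), ref)
    bin <- floor(folded / bin_size)
    tab <- tabulate(bin + 1L, nbins = n_bins)
    counts <- tab
  }
  names(counts) <- seq_len(n_bins) - 1L
  ira <- region_interval(ref, "IRa")
  bin_start <- (seq_len(n_bins) - 1L) * bin_size
  bin_end <- pmin(bin_start + bin_size, fl)
  ov <- pmin(bin_end, ira["end"]) - pmax(bin_start, ira["start"])
  frac_ir <- pmax(ov, 0) / (bin_end - bin_start)
  n_copies <- 1 + frac_ir
  total <- length(positions)
  structure(list(
    bin_size = as.integer(bin_size), counts = counts, n_copies = n_copies,
    total_plastid_reads = total,
    mean_fold_coverage = total * read_len / fl,
    folded_length = fl, read_len = as.integer(read_len)
  ), class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("Plastid coverage profile: ", x$total_plastid_reads, " reads, ",
      sprintf("%.1f", x$mean_fold_coverage), "x mean fold-coverage over ",
      x$folded_length, " bp (IR-folded), ", length(x$counts), " bins of ",
      x$bin_size, " bp\n", sep = "")
  invisible(x)
}

coverage_value <- function(coverage) {
  if (inherits(coverage, "coverage_profile")) coverage$mean_fold_coverage
  else as.numeric(coverage)
}

#' Normalize an event count by genome coverage
#'
#' `per_1x` expresses a count as events per genome copy (count / coverage);
#' `per_10k_genomes` as events per 10,000 genome copies.
#'
#' @param count Numeric event count(s).
#' @param coverage Mean fold-coverage in genome copies (a number or a
#'   `coverage_profile`); must be positive.
#' @param scale `"per_1x"` or `"per_10k_genomes"`.
#' @return Normalized value(s).
#' @export
normalize_events <- function(count, coverage,
                             scale = c("per_1x", "per_10k_genomes")) {
  scale <- match.arg(scale)
  cov <- coverage_value(coverage)
  if (cov <= 0) stop("coverage must be > 0")
  if (scale == "per_1x") count / cov else count / cov * 1e4
}

#' Windowed breakpoint density track
#'
#' Counts unique-event breakpoint endpoints (both `pos_a` and `pos_b`, on
#' folded coordinates) in sliding windows, scaled to events per million
#' plastid reads. With the default 100-nt windows stepping by 50 nt every
#' endpoint falls into `window / step` windows.
#'
#' @param events Events data.frame from [deduplicate_junctions()].
#' @param total_plastid_reads Total fully aligned plastid reads.
#' @param folded_len IR-folded genome length (bp).
#' @param window,step Window width and step in bp (defaults 100 and 50).
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `value`.
#' @export
window_density <- function(events, total_plastid_reads, folded_len,
                           window = 100L, step = 50L) {
  if (window <= 0 || step > window) stop("need window > 0 and step <= window")
  starts <- seq(0L, max(0L, folded_len - 1L), by = step)
  ends <- pmin(starts + window, folded_len)
  pos <- c(events$pos_a, events$pos_b)
  counts <- vapply(seq_along(starts), function(i) {
    sum(pos >= starts[i] & pos < starts[i] + window)
  }, numeric(1))
  scale <- if (total_plastid_reads > 0) 1e6 / total_plastid_reads else 0
  data.frame(start = starts, end = ends, value = counts * scale)
}

#' Breakpoint heat-map matrix
#'
#' Accumulates event support at the intersection of the two breakpoint
#' positions, one tile per `tile` bp along each axis, with
#' `(pos_a, pos_b)` canonicalized so the first coordinate is the smaller.
#' Values are normalized to the coverage per 10,000 plastid genomes unless
#' `normalize = FALSE`.
#'
#' @param events Events data.frame (folded coordinates).
#' @param coverage Mean fold-coverage (number or `coverage_profile`).
#' @param folded_len IR-folded genome length (bp).
#' @param tile Tile width in bp (default 1000).
#' @param normalize Normalize to per-10,000-genomes (default TRUE).
#' @return Numeric matrix (upper triangle populated), dimnames are tile
#'   start positions.
#' @export
breakpoint_heatmap <- function(events, coverage, folded_len, tile = 1000L,
                               normalize = TRUE) {
  n <- ceiling(folded_len / tile)
  M <- matrix(0, n, n,
              dimnames = list((seq_len(n) - 1L) * tile,
                              (seq_len(n) - 1L) * tile))
  if (nrow(events)) {
    lo <- pmin(events$pos_a, events$pos_b)
    hi <- pmax(events$pos_a, events$pos_b)
    i <- floor(lo / tile) + 1L
    j <- floor(hi / tile) + 1L
    for (k in seq_along(i)) M[i[k], j[k]] <- M[i[k], j[k]] + events$support[k]
  }
  if (normalize) M <- normalize_events(M, coverage, "per_10k_genomes")
  M
}

#' Export a coverage or density track as BedGraph
#'
#' @param track Either a `coverage_profile` or a data.frame with `start`,
#'   `end`, `value`.
#' @param path Output file path.
#' @param seqname Chromosome name used in the track.
#' @param per_million For a `coverage_profile`, report reads per million
#'   total plastid reads (default) rather than raw counts.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(track, path, seqname = "plastome",
                            per_million = TRUE) {
  if (inherits(track, "coverage_profile")) {
    starts <- (as.integer(names(track$counts))) * track$bin_size
    value <- as.numeric(track$counts)
    if (per_million && track$total_plastid_reads > 0) {
      value <- value * 1e6 / track$total_plastid_reads
    }
    track <- data.frame(start = starts,
                        end = pmin(starts + track$bin_size,
                                   track$folded_length),
                        value = value)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$value
  )
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}
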
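#' Detect and classify plastid rearrangement junctions from paired-end reads
#'
#' The central entry point: aligns both mates of every pair to the plastome
#' (plus IR-boundary decoys and any extra compartments), separates fully
#' aligned plastid pairs for coverage analysis from split reads spanning
#' candidate junctions, computes each junction's overlap (microhomology)
#' statistic, folds inverted-repeat coordinates onto the first IR,
#' classifies events as deletion / duplication / inversion and +MH / -MH,
#' deduplicates them into unique events, and builds the IR-folded per-kb
#' coverage profile used for per-genome normalization.
#'
#' @param ref A `plastome_ref` (the reference the reads were generated
#'   from / should be aligned to).
#' @param reads A `read_sim` object from [simulate_read_pairs()] /
#'   [simulate_cohort()], or a character vector of two FASTQ paths
#'   `c(r1, r2)`.
#' @param params Detection parameters, see [split_params()].
#' @param extra Optional named character vector of extra reference
#'   sequences (e.g. mitochondrial); junctions touching them are excluded
#'   from plastid statistics.
#' @param decoy_width Width of the IR-boundary decoy sequences (bp).
#' @return Object of class `rearr_scan`: list with `events` (unique
#'   junction events), `candidates` (read-level junction table), `coverage`
#'   (a `coverage_profile`), `accounting` (read fate counts), `params`,
#'   `ref`.
#' @seealso [summary.rearr_scan()], [write_junctions()], [rearr_report()]
#' @export
detect_rearrangements <- function(ref, reads, params = split_params(),
                                  extra = character(0), decoy_width = 400L) {
  stopifnot(inherits(ref, "plastome_ref"))
  if (inherits(reads, "read_sim")) {
    read_len <- reads$read_len
    seqs <- c(stats::setNames(reads$pairs$mate1, paste0(reads$pairs$id, "/1")),
              stats::setNames(reads$pairs$mate2, paste0(reads$pairs$id, "/2")))
  } else if (is.character(reads) && length(reads) == 2) {
    r1 <- read_fastq_seqs(reads[1])
    r2 <- read_fastq_seqs(reads[2])
    names(r1) <- sub("/[12]$", "/1", names(r1))
    names(r2) <- sub("/[12]$", "/2", names(r2))
    seqs <- c(r1, r2)
    read_len <- max(nchar(seqs))
  } else {
    stop("reads must be a read_sim object or c(r1.fastq, r2.fastq)")
  }

  refset <- reference_set(ref, decoy_width = decoy_width, extra = extra,
                          circular_ext = as.integer(read_len - 1))
  aln <- align_reads(seqs, refset, k = params$seed_k,
                     min_score = params$min_score,
                     min_len = params$min_seg_len)

  groups <- split(seq_len(nrow(aln)), aln$read_id)
  read_ids <- names(seqs)
  candidates <- list()
  full_pos <- new.env(parent = emptyenv())   # read_id -> plastome start
  fate <- stats::setNames(integer(4), c("full", "split", "unassigned", "no_alignment"))

  frac <- params$min_covered_fraction
  for (rid in read_ids) {
    idx <- groups[[rid]]
    if (is.null(idx)) { fate["no_alignment"] <- fate["no_alignment"] + 1L; next }
    g <- aln[idx, , drop = FALSE]
    covered <- g$read_end - g$read_start
    is_full <- covered >= frac * read_len & g$mismatches <= params$max_mismatch_full
    if (any(is_full)) {
      full <- g[is_full, , drop = FALSE]
      on_pt <- full$ref_name == refset$plastome
      if (any(on_pt) && max(full$score[on_pt]) >= max(full$score)) {
        best <- max(full$score[on_pt])
        cand <- full[on_pt & full$score == best, , drop = FALSE]
        assign(rid, min(cand$ref_start %% refset$L), envir = full_pos)
        fate["full"] <- fate["full"] + 1L
      } else {
        fate["unassigned"] <- fate["unassigned"] + 1L
      }
      next
    }
    cand <- detect_split(g, read_len, refset, params)
    if (!is.null(cand)) {
      candidates[[length(candidates) + 1L]] <- cand
      fate["split"] <- fate["split"] + 1L
    } else {
      fate["unassigned"] <- fate["unassigned"] + 1L
    }
  }

  # coverage: pairs with both mates fully aligned on the plastome
  pair_ids <- unique(sub("/[12]$", "", read_ids))
  pos1 <- mget(paste0(pair_ids, "/1"), envir = full_pos, ifnotfound = NA)
  pos2 <- mget(paste0(pair_ids, "/2"), envir = full_pos, ifnotfound = NA)
  keep <- !is.na(pos1) & !is.na(pos2)
  positions <- c(unlist(pos1[keep]), unlist(pos2[keep]))

  cand_tab <- candidate_table(candidates, read_len, ref)
  events <- deduplicate_junctions(cand_tab, merge_tol = params$merge_tol)
  coverage <- per_kb_profile(positions, ref, read_len = read_len)

  structure(list(events = events, candidates = cand_tab,
                 coverage = coverage,
                 accounting = c(fate, full_pairs = sum(keep),
                                total_reads = length(read_ids)),
                 params = params, read_len = read_len, ref = ref),
            class = "rearr_scan")
}

#' @export
print.rearr_scan <- function(x, ...) {
  cat("Plastid rearrangement scan\n")
  cat("  reads: ", x$accounting["total_reads"],
      " (full ", x$accounting["full"],
      ", split ", x$accounting["split"],
      ", unassigned ", x$accounting["unassigned"] + x$accounting["no_alignment"],
      ")\n", sep = "")
  cat("  coverage: ", sprintf("%.1f", x$coverage$mean_fold_coverage),
      "x over ", x$coverage$folded_length, " bp (IR-folded)\n", sep = "")
  cat("  unique junction events: ", nrow(x$events), "\n", sep = "")
  invisible(x)
}

#' Summarize a rearrangement scan
#'
#' @param object A `rearr_scan`.
#' @param ... Unused.
#' @return List of class `summary.rearr_scan` with event counts by MH class
#'   and type, coverage, and per-genome normalized rates.
#' @export
summary.rearr_scan <- function(object, ...) {
  ev <- object$events
  cov <- object$coverage$mean_fold_coverage
  n_plus <- sum(ev$mh_class == "+MH")
  n_minus <- sum(ev$mh_class == "-MH")
  by_type <- table(factor(ev$event_type,
                          levels = c("deletion", "duplication", "inversion")))
  rates <- if (cov > 0) c(plus_mh_per_genome = n_plus / cov,
                          minus_mh_per_genome = n_minus / cov)
           else c(plus_mh_per_genome = NA_real_, minus_mh_per_genome = NA_real_)
  structure(list(
    n_events = nrow(ev), n_plus_mh = n_plus, n_minus_mh = n_minus,
    by_type = by_type, coverage = cov,
    total_plastid_reads = object$coverage$total_plastid_reads,
    rates = rates, support_total = sum(ev$support),
    accounting = object$accounting
  ), class = "summary.rearr_scan")
}

#' @export
print.summary.rearr_scan <- function(x, ...) {
  cat("Unique junction events: ", x$n_events,
      " (+MH ", x$n_plus_mh, ", -MH ", x$n_minus_mh, ")\n", sep = "")
  cat("  by type: ", paste(names(x$by_type), x$by_type, collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  coverage: %.2f genome copies (%d plastid reads)\n",
              x$coverage, x$total_plastid_reads))
  cat(sprintf("  rates: %.4g +MH/genome, %.4g -MH/genome\n",
              x$rates["plus_mh_per_genome"], x$rates["minus_mh_per_genome"]))
  invisible(x)
}

#' Extract microhomology counts from a scan
#'
#' @param scan A `rearr_scan`.
#' @param sample Sample label.
#' @return An [mh_counts()] object.
#' @export
scan_mh_counts <- function(scan, sample = "sample") {
  s <- summary(scan)
  mh_counts(sample, s$n_plus_mh, s$n_minus_mh, s$coverage)
}

#' Plot a rearrangement scan
#'
#' Two panels: the IR-folded per-kb coverage profile and the breakpoint
#' heat map (support per 10,000 genomes) with the quadripartite regions
#' marked.
#'
#' @param x A `rearr_scan`.
#' @param ... Passed to [graphics::image()] for the heat map.
#' @return `x`, invisibly.
#' @export
plot.rearr_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cp <- x$coverage
  starts <- as.integer(names(cp$counts)) * cp$bin_size / 1000
  graphics::plot(starts, cp$counts, type = "h", lwd = 3, col = "steelblue",
                 xlab = "position (kb, IR-folded)", ylab = "reads per kb",
                 main = "plastid coverage")
  M <- breakpoint_heatmap(x$events, cp, cp$folded_length)
  if (max(M) == 0) M[1, 1] <- NA
  graphics::image(x = as.integer(rownames(M)) / 1000,
                  y = as.integer(colnames(M)) / 1000, z = M,
                  col = grDevices::hcl.colors(32, "inferno"),
                  xlab = "breakpoint A (kb)", ylab = "breakpoint B (kb)",
                  main = "junctions per 10,000 genomes", ...)
  invisible(x)
}

#' Write unique junction events as TSV (1-based positions)
#'
#' @param scan A `rearr_scan` or an events data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(scan, path) {
  ev <- if (inherits(scan, "rearr_scan")) scan$events else scan
  out <- ev
  out$pos_a <- out$pos_a + 1L
  out$pos_b <- out$pos_b + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a BED-like paired-breakpoint track (0-based half-open)
#'
#' @param scan A `rearr_scan` or an events data.frame.
#' @param path Output path.
#' @param seqname Chromosome name.
#' @return `path`, invisibly.
#' @export
write_junction_bedpe <- function(scan, path, seqname = "plastome") {
  ev <- if (inherits(scan, "rearr_scan")) scan$events else scan
  out <- data.frame(
    chrom1 = seqname, start1 = ev$pos_a, end1 = ev$pos_a + 1L,
    chrom2 = seqname, start2 = ev$pos_b, end2 = ev$pos_b + 1L,
    name = paste0(ev$event_type, "_mh", ev$homology_len),
    score = ev$support, strand1 = ev$strand_a, strand2 = ev$strand_b,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Consolidated scan report
#'
#' @param scan A `rearr_scan`.
#' @return A list (versioned schema) with thresholds, read accounting,
#'   coverage, event counts and normalized rates.
#' @export
rearr_report <- function(scan) {
  s <- summary(scan)
  list(
    schema_version = "1.0",
    params = scan$params,
    reads = as.list(s$accounting),
    coverage = list(mean_fold_coverage = s$coverage,
                    total_plastid_reads = s$total_plastid_reads,
                    folded_length = scan$coverage$folded_length),
    events = list(unique = s$n_events, support = s$support_total,
                  plus_mh = s$n_plus_mh, minus_mh = s$n_minus_mh,
                  by_type = as.list(s$by_type)),
    rates = as.list(s$rates)
  )
}

#' @rdname rearr_report
#' @param path JSON output path.
#' @return `write_rearr_report` returns `path` invisibly.
#' @export
write_rearr_report <- function(scan, path) {
  jsonlite::write_json(rearr_report(scan), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
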
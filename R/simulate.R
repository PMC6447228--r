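#' Specify a rearrangement junction to plant in a synthetic plastome
#'
#' A junction joins two reference loci. `pos_a` is the last reference
#' position of the upstream (5') parental locus, exclusive (0-based: the
#' first base *after* the upstream flank); `pos_b` is the first reference
#' position of the downstream parental locus in read order. The junction may
#' carry a shared direct repeat of `mh_len` bases (microhomology) or
#' `ins_len` inserted random bases, but not both.
#'
#' @param kind One of `"deletion"`, `"duplication"`, `"inversion"`.
#' @param pos_a,pos_b 0-based reference breakpoint coordinates.
#' @param mh_len Shared direct-repeat length at the junction (>= 0).
#' @param ins_len Inserted bases at the junction (>= 0; mutually exclusive
#'   with `mh_len > 0`).
#' @return An object of class `junction_spec`.
#' @export
junction_spec <- function(kind, pos_a, pos_b, mh_len = 0L, ins_len = 0L) {
  kind <- match.arg(kind, c("deletion", "duplication", "inversion"))
  if (mh_len < 0 || ins_len < 0) stop("mh_len and ins_len must be >= 0")
  if (mh_len > 0 && ins_len > 0) {
    stop("a junction cannot have both microhomology and inserted bases")
  }
  structure(list(kind = kind, pos_a = as.integer(pos_a),
                 pos_b = as.integer(pos_b), mh_len = as.integer(mh_len),
                 ins_len = as.integer(ins_len)),
            class = "junction_spec")
}

# pick a base different from all bases in `avoid`, deterministically random
other_base <- function(avoid) {
  pool <- setdiff(c("A", "C", "G", "T"), avoid)
  pool[sample.int(length(pool), 1)]
}

#' Plant a rearrangement junction and derive the recombinant molecule
#'
#' Builds a linear amplicon-like molecule consisting of `flank_len`
#' reference bases ending at `pos_a`, then `ins_len` random bases if any,
#' then `flank_len` bases of the downstream locus (entered at `pos_b`;
#' reverse-complement orientation for inversions). For `mh_len > 0` the
#' repeat ending the upstream flank is written into the reference at the
#' start of the downstream locus, so both parental loci genuinely share the
#' direct repeat and the molecule carries it once — exactly the situation the
#' split-read overlap statistic measures.
#'
#' Two reference bases on each side of the junction are additionally
#' constrained to differ between the parental loci ("non-extension guards"),
#' so the planted homology length is exactly `mh_len` rather than a lower
#' bound: without the guards a chance match just beyond the repeat would
#' genuinely lengthen the shared homology. Edits inside an inverted repeat
#' are mirrored into the partner copy to preserve the quadripartite
#' invariant. The (possibly edited) reference is returned and must be used
#' for downstream alignment.
#'
#' @param ref A `plastome_ref`.
#' @param spec A `junction_spec`.
#' @param flank_len Parental flank length in bp (use >= 2 read lengths so
#'   reads fully span the junction).
#' @param seed Integer seed for inserted bases and guard-base choices.
#' @param molecule_id Identifier for the derived molecule.
#' @return A list with `molecule` (list with `id`, `seq`), `truth` (one-row
#'   data.frame: molecule_id, kind, pos_a, pos_b, strand_b, mh_len, ins_len,
#'   expected_homology, junction_offset) and `ref` (the edited reference).
#' @export
plant_rearrangement <- function(ref, spec, flank_len, seed,
                                molecule_id = "rearranged") {
  stopifnot(inherits(ref, "plastome_ref"), inherits(spec, "junction_spec"))
  if (flank_len < 50) stop("flank_len must be >= 50 bp")
  set.seed(as.integer(seed))
  pos_a <- spec$pos_a; pos_b <- spec$pos_b
  mh <- spec$mh_len; ins <- spec$ins_len
  L <- ref$length
  if (pos_a < 0 || pos_a >= L || pos_b < 0 || pos_b >= L) {
    stop("breakpoints must lie in [0, L)")
  }
  inverted <- spec$kind == "inversion"

  # parental intervals on the reference (0-based half-open), linear construction
  a_iv <- c(pos_a - flank_len, pos_a)
  b_iv <- if (inverted) c(pos_b - flank_len + 1L, pos_b + 1L)
          else c(pos_b, pos_b + flank_len)
  # widen B by the guard zone so guard edits never touch the A flank
  b_guard <- if (inverted) c(b_iv[1] - 2L, b_iv[2] + 2L) else c(b_iv[1] - 2L, b_iv[2] + 2L)
  if (a_iv[1] < 0 || b_guard[1] < 0 || b_guard[2] > L || a_iv[2] > L) {
    stop("flanks extend past the ends of the linear construction")
  }
  if (a_iv[1] < b_guard[2] && b_guard[1] < a_iv[2]) {
    stop("overlapping flanks make the junction ill-defined")
  }
  if (mh >= flank_len || ins >= flank_len) {
    stop("mh_len / ins_len must be smaller than flank_len")
  }
  if (!inverted) {
    d <- (pos_b - pos_a) %% L
    geo <- if (d > 0 && d < L / 2) "deletion" else "duplication"
    if (geo != spec$kind) {
      stop("breakpoint geometry implies a ", geo, ", not a ", spec$kind)
    }
  }

  # map a read-order index g (0-based) within the downstream flank to the
  # underlying reference position; for inversions the flank walks downward
  b_ref_pos <- function(g) if (inverted) pos_b - g else pos_b + g
  # read-order base at downstream flank index g
  b_read_base <- function(g) {
    b <- ref_base(ref, b_ref_pos(g))
    if (inverted) comp_base(b) else b
  }
  # write read-order base `base` at downstream flank index g
  b_write <- function(g, base) {
    edit_ref_base(ref, b_ref_pos(g), if (inverted) comp_base(base) else base)
  }

  # plant the shared direct repeat: downstream flank must begin with the
  # repeat that ends the upstream flank
  if (mh > 0) {
    rep_seq <- strsplit(ref_sub(ref, pos_a - mh, pos_a), "")[[1]]
    for (g in seq_len(mh)) {
      if (b_read_base(g - 1L) != rep_seq[g]) ref <- b_write(g - 1L, rep_seq[g])
    }
  }

  # inserted bases (random, then guard-constrained below)
  mid <- if (ins > 0) sample(c("A", "C", "G", "T"), ins, replace = TRUE) else character(0)

  # non-extension guards, two bases on each side of the junction:
  # (1) the g-th molecule base after the upstream alignment's end must differ
  #     from ref[pos_a + g - 1], else the upstream alignment chance-extends
  for (g in 1:2) {
    a_next <- ref_base(ref, pos_a + g - 1L)
    if (ins >= g) {
      if (mid[g] == a_next) mid[g] <- other_base(a_next)
    } else {
      idx <- mh + (g - ins) - 1L           # read-order index in downstream flank
      if (b_read_base(idx) == a_next) ref <- b_write(idx, other_base(a_next))
    }
  }
  # (2) the g-th molecule base before the downstream alignment's start must
  #     differ from the reference base preceding pos_b in walk direction
  for (g in 1:2) {
    b_prev <- if (inverted) comp_base(ref_base(ref, pos_b + g)) else
      ref_base(ref, pos_b - g)
    if (ins >= g) {
      k <- ins - g + 1L
      if (mid[k] == b_prev) {
        avoid <- b_prev
        if (k <= 2) avoid <- c(avoid, ref_base(ref, pos_a + k - 1L))
        mid[k] <- other_base(avoid)
      }
    } else {
      # molecule base is upstream-flank sequence ref[pos_a - mh - (g - ins)]
      mol_base <- ref_base(ref, pos_a - mh - (g - ins))
      if (mol_base == b_prev) {
        pb_pos <- if (inverted) pos_b + g else pos_b - g
        new_b <- other_base(if (inverted) comp_base(mol_base) else mol_base)
        ref <- edit_ref_base(ref, pb_pos, new_b)
      }
    }
  }

  left <- ref_sub(ref, pos_a - flank_len, pos_a)
  b_full <- vapply(seq_len(flank_len) - 1L, b_read_base, character(1))
  right <- paste(b_full[(mh + 1):flank_len], collapse = "")
  mol_seq <- paste0(left, paste(mid, collapse = ""), right)

  truth <- data.frame(
    molecule_id = molecule_id, kind = spec$kind,
    pos_a = pos_a, pos_b = pos_b,
    strand_b = if (inverted) "-" else "+",
    mh_len = mh, ins_len = ins,
    expected_homology = if (ins > 0) -ins else mh,
    junction_offset = flank_len,
    stringsAsFactors = FALSE
  )
  list(molecule = list(id = molecule_id, seq = mol_seq), truth = truth, ref = ref)
}

#' Declare a molecule for read simulation
#'
#' @param id Molecule identifier (recorded in the truth table).
#' @param seq DNA sequence (character scalar) or a `plastome_ref`.
#' @param weight Non-negative sampling weight.
#' @param circular Sample fragments across the origin (sequence is extended
#'   internally by one maximal insert length).
#' @return A list of class `sim_molecule`.
#' @export
sim_molecule <- function(id, seq, weight = 1, circular = FALSE) {
  if (inherits(seq, "plastome_ref")) {
    circular <- seq$circular
    seq <- seq$seq
  }
  structure(list(id = id, seq = toupper(seq), weight = weight,
                 circular = circular),
            class = "sim_molecule")
}

#' Simulate paired-end reads from a weighted set of molecules
#'
#' Fragments are drawn from molecules proportionally to weight, with uniform
#' start positions and insert lengths from a Normal(`insert_mean`,
#' `insert_sd`) truncated to `[read_len, molecule length]`. Mate 1 is the
#' first `read_len` bases of the fragment and mate 2 the reverse complement
#' of its last `read_len` bases; with probability 1/2 the fragment is read
#' from the opposite strand (mates swapped). Sequencing noise is applied as
#' i.i.d. base substitutions at `error_rate`. Circular molecules are sampled
#' across the origin by internal sequence doubling.
#'
#' @param molecules A list of [sim_molecule()] objects.
#' @param n_pairs Number of read pairs to draw (> 0).
#' @param read_len Read length in bp (default 150).
#' @param insert_mean,insert_sd Insert-size distribution in bp (defaults
#'   320 and 50).
#' @param error_rate Per-base substitution probability in `[0, 0.25)`.
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @return An object of class `read_sim`: list with `pairs` (data.frame:
#'   id, mate1, mate2), `truth` (id, molecule, start, insert, flipped),
#'   `excluded` (molecules shorter than `read_len`, with draw counts),
#'   `read_len`.
#' @export
simulate_read_pairs <- function(molecules, n_pairs, read_len = 150L,
                                insert_mean = 320, insert_sd = 50,
                                error_rate = 0, seed = 1L) {
  if (inherits(molecules, "sim_molecule")) molecules <- list(molecules)
  stopifnot(length(molecules) > 0)
  if (n_pairs <= 0) stop("n_pairs must be > 0")
  if (error_rate < 0 || error_rate >= 0.25) stop("error_rate must be in [0, 0.25)")
  if (insert_mean < read_len) stop("insert_mean must be >= read_len")
  w <- vapply(molecules, `[[`, numeric(1), "weight")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be >= 0 and sum to > 0")
  set.seed(as.integer(seed))

  lens <- vapply(molecules, function(m) nchar(m$seq), integer(1))
  ids <- vapply(molecules, `[[`, character(1), "id")
  circ <- vapply(molecules, `[[`, logical(1), "circular")
  max_ext <- as.integer(min(max(lens), ceiling(insert_mean + 6 * insert_sd)))
  ext_seq <- vapply(seq_along(molecules), function(i) {
    if (circ[i]) paste0(molecules[[i]]$seq,
                        substr(molecules[[i]]$seq, 1, max_ext)) else
      molecules[[i]]$seq
  }, character(1))

  draw <- sample.int(length(molecules), n_pairs, replace = TRUE, prob = w)
  too_short <- which(lens < read_len)
  excluded <- data.frame(molecule = character(0), draws = integer(0))
  if (length(too_short)) {
    n_dropped <- tabulate(draw, nbins = length(molecules))[too_short]
    excluded <- data.frame(molecule = ids[too_short], draws = n_dropped,
                           stringsAsFactors = FALSE)
    warning("excluding ", length(too_short),
            " molecule(s) shorter than read_len (",
            sum(n_dropped), " draws dropped)")
    draw <- draw[!(draw %in% too_short)]
  }
  n <- length(draw)
  if (n == 0) stop("no molecule is long enough to sample reads from")

  mol_len <- lens[draw]
  insert <- as.integer(round(stats::rnorm(n, insert_mean, insert_sd)))
  insert <- pmin(pmax(insert, read_len), mol_len)
  start <- ifelse(circ[draw],
                  floor(stats::runif(n) * mol_len),
                  floor(stats::runif(n) * (mol_len - insert + 1)))
  start <- as.integer(start)
  frag <- substr(ext_seq[draw], start + 1L, start + insert)
  fwd <- substr(frag, 1L, read_len)
  rev <- vapply(substr(frag, insert - read_len + 1L, insert), revcomp,
                character(1), USE.NAMES = FALSE)
  flip <- stats::runif(n) < 0.5
  mate1 <- ifelse(flip, rev, fwd)
  mate2 <- ifelse(flip, fwd, rev)

  if (error_rate > 0) {
    mate1 <- add_substitutions(mate1, error_rate)
    mate2 <- add_substitutions(mate2, error_rate)
  }
  pid <- sprintf("pair%06d", seq_len(n))
  structure(list(
    pairs = data.frame(id = pid, mate1 = mate1, mate2 = mate2,
                       stringsAsFactors = FALSE),
    truth = data.frame(id = pid, molecule = ids[draw], start = start,
                       insert = insert, flipped = flip,
                       stringsAsFactors = FALSE),
    excluded = excluded, read_len = as.integer(read_len)
  ), class = "read_sim")
}

# i.i.d. substitution noise on a character vector of reads
add_substitutions <- function(reads, rate) {
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(length(chars), n_err[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Write simulated read pairs as a FASTQ pair
#'
#' Writes `<prefix>_R1.fastq` and `<prefix>_R2.fastq` with constant Q37
#' base qualities (qualities are not used downstream).
#'
#' @param sim A `read_sim` object.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_fastq_pair <- function(sim, dir, prefix = "reads") {
  stopifnot(inherits(sim, "read_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_R1.fastq", "_R2.fastq")))
  for (m in 1:2) {
    seqs <- Biostrings::DNAStringSet(sim$pairs[[paste0("mate", m)]])
    names(seqs) <- paste0(sim$pairs$id, "/", m)
    quals <- Biostrings::BStringSet(strrep("F", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, paths[m], format = "fastq",
                                qualities = quals)
  }
  invisible(paths)
}

#' Read a FASTQ file into a named character vector of sequences
#' @param path FASTQ file path.
#' @return Named character vector (names are read ids).
#' @export
read_fastq_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a junction truth table as TSV
#' @param truth data.frame of planted-junction truth rows (as produced by
#'   [plant_rearrangement()] / [simulate_cohort()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a full cohort: intact genome plus rearranged molecules
#'
#' Plants each junction specification into the reference (accumulating the
#' repeat/guard edits), then simulates reads from the intact circular genome
#' and every rearranged molecule at the requested fold-coverages.
#'
#' @param ref A `plastome_ref`.
#' @param specs List of [junction_spec()] objects.
#' @param flank_len Flank length per rearranged molecule (default 400 bp).
#' @param junction_coverage Fold-coverage per rearranged molecule.
#' @param intact_coverage Fold-coverage of the intact genome.
#' @param read_len,insert_mean,insert_sd,error_rate Passed to
#'   [simulate_read_pairs()].
#' @param seed Integer seed.
#' @return List with `ref` (edited reference), `sim` (a `read_sim`),
#'   `junction_truth` (data.frame, one row per planted junction) and
#'   `molecules`.
#' @export
simulate_cohort <- function(ref, specs, flank_len = 400L,
                            junction_coverage = 50, intact_coverage = 50,
                            read_len = 150L, insert_mean = 320,
                            insert_sd = 50, error_rate = 0, seed = 1L) {
  truth <- NULL
  molecules <- list()
  for (i in seq_along(specs)) {
    pl <- plant_rearrangement(ref, specs[[i]], flank_len = flank_len,
                              seed = seed + i,
                              molecule_id = sprintf("junction%02d", i))
    ref <- pl$ref
    truth <- rbind(truth, pl$truth)
    molecules[[i]] <- pl$molecule
  }
  mols <- list()
  n_by_mol <- integer(0)
  if (intact_coverage > 0) {
    mols[[1]] <- sim_molecule("intact", ref, weight = 1, circular = TRUE)
    n_by_mol <- ceiling(ref$length * intact_coverage / (2 * read_len))
  }
  for (m in molecules) {
    mols[[length(mols) + 1]] <- sim_molecule(m$id, m$seq, weight = 1)
    n_by_mol <- c(n_by_mol,
                  ceiling(nchar(m$seq) * junction_coverage / (2 * read_len)))
  }
  # fix the per-molecule pair counts exactly by weighting with the counts
  for (i in seq_along(mols)) mols[[i]]$weight <- n_by_mol[i]
  sim <- simulate_read_pairs(mols, n_pairs = sum(n_by_mol),
                             read_len = read_len, insert_mean = insert_mean,
                             insert_sd = insert_sd, error_rate = error_rate,
                             seed = seed)
  list(ref = ref, sim = sim, junction_truth = truth, molecules = molecules)
}
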
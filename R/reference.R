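#' Construct a synthetic circular quadripartite plastome reference
#'
#' Builds a miniature plastid genome with the canonical architecture of land
#' plant plastomes: a large single-copy region (LSC), a first inverted repeat
#' (IRa), a small single-copy region (SSC) and a second inverted repeat (IRb)
#' that is the exact reverse complement of IRa. The four regions tile the
#' whole circle in that order, using 0-based half-open coordinates.
#'
#' @param lsc_len,ira_len,ssc_len Region lengths in bp (all >= 1000). The
#'   total genome length is `lsc_len + 2 * ira_len + ssc_len`.
#' @param seed Integer seed; the sequence is deterministic for a fixed seed.
#' @param name Sequence name used in FASTA output and alignments.
#' @return An object of class `plastome_ref` with elements `name`, `seq`
#'   (uppercase ACGT character scalar), `length`, `regions` (data.frame with
#'   columns `region`, `start`, `end`; 0-based half-open) and `circular`.
#' @examples
#' ref <- plastome_reference(10000, 2000, 4000, seed = 42)
#' ref$length  # 18000
#' @export
plastome_reference <- function(lsc_len, ira_len, ssc_len, seed,
                               name = "synthetic_plastome") {
  lens <- c(lsc = lsc_len, ira = ira_len, ssc = ssc_len)
  if (any(!is.finite(lens)) || any(lens < 1000)) {
    stop("all region lengths must be >= 1000 bp (got ",
         paste(lens, collapse = ", "), ")")
  }
  set.seed(as.integer(seed))
  n_random <- lsc_len + ira_len + ssc_len
  bases <- sample(c("A", "C", "G", "T"), n_random, replace = TRUE)
  lsc <- paste(bases[seq_len(lsc_len)], collapse = "")
  ira <- paste(bases[lsc_len + seq_len(ira_len)], collapse = "")
  ssc <- paste(bases[lsc_len + ira_len + seq_len(ssc_len)], collapse = "")
  irb <- revcomp(ira)
  L <- lsc_len + 2L * ira_len + ssc_len
  regions <- data.frame(
    region = c("LSC", "IRa", "SSC", "IRb"),
    start = c(0L, lsc_len, lsc_len + ira_len, lsc_len + ira_len + ssc_len),
    end = c(lsc_len, lsc_len + ira_len, lsc_len + ira_len + ssc_len, L),
    stringsAsFactors = FALSE
  )
  structure(
    list(name = name, seq = paste0(lsc, ira, ssc, irb), length = L,
         regions = regions, circular = TRUE),
    class = "plastome_ref"
  )
}

#' Assemble a plastome reference from an explicit sequence
#'
#' Used when reading a reference from FASTA or after editing the sequence
#' (e.g. planting microhomology repeats). Validates the quadripartite
#' invariants: regions tile `[0, L)` in order LSC, IRa, SSC, IRb and IRb is
#' the reverse complement of IRa.
#'
#' @param seq Uppercase ACGT character scalar.
#' @param regions data.frame with columns `region`, `start`, `end` (0-based
#'   half-open) for LSC, IRa, SSC, IRb in order.
#' @param name Sequence name.
#' @return A `plastome_ref` object.
#' @export
as_plastome_ref <- function(seq, regions, name = "plastome") {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (grepl("[^ACGT]", seq)) stop("reference sequence contains non-ACGT characters")
  stopifnot(identical(regions$region, c("LSC", "IRa", "SSC", "IRb")))
  if (regions$start[1] != 0 || regions$end[4] != L ||
      any(regions$start[-1] != regions$end[-4])) {
    stop("regions must tile [0, L) exactly in order LSC, IRa, SSC, IRb")
  }
  ira <- substr(seq, regions$start[2] + 1, regions$end[2])
  irb <- substr(seq, regions$start[4] + 1, regions$end[4])
  if (nchar(ira) != nchar(irb) || revcomp(ira) != irb) {
    stop("IRb must be the reverse complement of IRa")
  }
  structure(list(name = name, seq = seq, length = L,
                 regions = regions, circular = TRUE),
            class = "plastome_ref")
}

#' @export
print.plastome_ref <- function(x, ...) {
  cat("Circular plastome reference '", x$name, "': ", x$length, " bp\n", sep = "")
  r <- x$regions
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-4s %6d..%6d  (%d bp)\n", r$region[i], r$start[i],
                r$end[i], r$end[i] - r$start[i]))
  }
  invisible(x)
}

region_interval <- function(ref, region) {
  i <- match(region, ref$regions$region)
  c(start = ref$regions$start[i], end = ref$regions$end[i])
}

#' Reverse complement of a DNA string
#'
#' @param x Character scalar (ACGT).
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Fold a reference position from the second inverted repeat onto the first
#'
#' Positions inside IRb are mapped to their mirror position in IRa
#' (`p -> IRa_start + (IRb_end - 1 - p)`); all other positions are returned
#' unchanged. The map is idempotent. This implements the convention that all
#' reads and breakpoints mapping to either inverted repeat copy are assigned
#' to the first IR.
#'
#' @param pos Integer vector of 0-based positions in `[0, L)`.
#' @param ref A `plastome_ref`.
#' @return Integer vector of folded positions (all outside IRb).
#' @export
fold_ir <- function(pos, ref) {
  if (any(pos < 0 | pos >= ref$length)) {
    stop("position out of range [0, ", ref$length, ")")
  }
  ira <- region_interval(ref, "IRa")
  irb <- region_interval(ref, "IRb")
  in_irb <- pos >= irb["start"] & pos < irb["end"]
  pos[in_irb] <- ira["start"] + (irb["end"] - 1L - pos[in_irb])
  as.integer(pos)
}

#' Length of the IR-folded genome (IRs counted once)
#' @param ref A `plastome_ref`.
#' @return Integer; `L - |IRb|`.
#' @export
folded_length <- function(ref) {
  irb <- region_interval(ref, "IRb")
  as.integer(ref$length - (irb["end"] - irb["start"]))
}

#' Write / read a plastome reference as FASTA
#'
#' Region coordinates are carried in the FASTA description line as
#' `region=start-end` tokens (0-based half-open) so a round trip restores
#' the full object.
#'
#' @param ref A `plastome_ref`.
#' @param path FASTA file path.
#' @return `write_plastome_fasta` returns `path` invisibly;
#'   `read_plastome_fasta` returns a `plastome_ref`.
#' @export
write_plastome_fasta <- function(ref, path) {
  desc <- paste(sprintf("%s=%d-%d", ref$regions$region, ref$regions$start,
                        ref$regions$end), collapse = " ")
  x <- Biostrings::DNAStringSet(ref$seq)
  names(x) <- paste(ref$name, desc)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_plastome_fasta
#' @param name Optional sequence name override on read.
#' @export
read_plastome_fasta <- function(path, name = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1) stop("expected a single-sequence reference FASTA")
  header <- names(x)[1]
  toks <- strsplit(header, "\\s+")[[1]]
  seq_name <- if (is.null(name)) toks[1] else name
  reg_toks <- grep("^(LSC|IRa|SSC|IRb)=", toks, value = TRUE)
  if (length(reg_toks) != 4) {
    stop("FASTA header does not carry LSC/IRa/SSC/IRb region annotations")
  }
  parts <- do.call(rbind, strsplit(sub("^.*=", "", reg_toks), "-"))
  regions <- data.frame(
    region = sub("=.*$", "", reg_toks),
    start = as.integer(parts[, 1]), end = as.integer(parts[, 2]),
    stringsAsFactors = FALSE
  )
  regions <- regions[match(c("LSC", "IRa", "SSC", "IRb"), regions$region), ]
  rownames(regions) <- NULL
  as_plastome_ref(as.character(x[[1]]), regions, name = seq_name)
}

# Edit one reference base, mirroring the edit into the partner IR copy when
# the position lies inside IRa or IRb, so the quadripartite invariant holds.
edit_ref_base <- function(ref, pos, base) {
  stopifnot(pos >= 0, pos < ref$length, base %in% c("A", "C", "G", "T"))
  s <- ref$seq
  substr(s, pos + 1, pos + 1) <- base
  ira <- region_interval(ref, "IRa")
  irb <- region_interval(ref, "IRb")
  mirror <- NA_integer_
  if (pos >= ira["start"] && pos < ira["end"]) {
    mirror <- irb["start"] + (ira["end"] - 1L - pos)
  } else if (pos >= irb["start"] && pos < irb["end"]) {
    mirror <- ira["start"] + (irb["end"] - 1L - pos)
  }
  if (!is.na(mirror)) {
    substr(s, mirror + 1, mirror + 1) <- comp_base(base)
  }
  ref$seq <- s
  ref
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

ref_base <- function(ref, pos) substr(ref$seq, pos + 1, pos + 1)

ref_sub <- function(ref, start, end) {
  # 0-based half-open extraction
  substr(ref$seq, start + 1, end)
}
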
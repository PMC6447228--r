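---
title: "Detecting plastid genome rearrangements from split reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting plastid genome rearrangements from split reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptrearr)
```

## The problem

Land-plant plastid genomes are small (~150 kb), circular, highly multi-copy
molecules with a quadripartite architecture: a large single-copy region
(LSC), a small single-copy region (SSC), and two identical inverted repeats
(IRa, IRb) separating them. Double-strand breaks in plastid DNA are repaired
either conservatively (homologous recombination) or by error-prone pathways.
Microhomology-mediated recombination (MHMR) joins loci that share a short
direct repeat — conventionally 5–25 bp — while NHEJ-like joining uses less
than 5 bp of homology and often inserts a few bases at the junction. The
footprint of these pathways is visible in whole-genome DNA sequencing as
*split reads*: reads whose two parts align to discontiguous or oppositely
oriented reference loci.

`ptrearr` implements the full desk-scale analysis: a seeded simulator of
plastomes carrying engineered junctions, a gap-free local alignment engine,
split-read junction calling, microhomology classification, inverted-repeat
coordinate folding, coverage-normalized rates and tracks, direct-repeat
annotation of junction sequences, and between-sample chi-squared comparison
of microhomology usage.

## The overlap statistic

For a split read with two local alignments of lengths $\ell_a$ and
$\ell_b$ (on the read) and read length $r$, the junction's signed homology
is

$$h = \ell_a + \ell_b - r.$$

If the two parental loci share a direct repeat of $m$ bases at the
junction, both alignments extend across the repeat and overlap on the read
by exactly $m$, so $h = m$. A blunt join gives $h = 0$, and $k$ bases
inserted between the two parental segments leave $k$ read bases unaligned,
giving $h = -k$. Junctions with $h \ge 5$ are classified `+MH`
(microhomology-mediated); everything below, including all insertions, is
`-MH`. The signed value is kept for homology-length histograms.

```{r overlap}
compute_overlap(list(read_start = 0, read_end = 80),
                list(read_start = 60, read_end = 150), read_len = 150)
classify_mh(c(4, 5, -3))
```

## Alignment engine

Reads are aligned with a seed-and-extend, *gap-free* local aligner
(match +1, mismatch −2, minimum score 20, minimum segment length 20 bp,
seed k-mer 12). Gap-free alignment makes read-interval and
reference-interval lengths equal, which is what makes the overlap statistic
well-defined; it is implemented in C++ as a per-diagonal maximal-scoring
segment scan, so each reported alignment is provably the best gap-free
local alignment on its diagonal. The engine is a contract, not a mandate:
12-column tabular alignments from an external local-search tool can be
imported with `read_tabular_alignments()` and used instead.

Three structural features of the plastome need special handling:

* **Circularity.** The first `read_len − 1` bases are appended to the
  plastome before alignment and coordinates are reduced modulo the genome
  length, so origin-spanning reads align contiguously.
* **Inverted repeats.** A read mapping to IRa maps equally to IRb on the
  opposite strand. Deterministic tie-breaking (highest combined score,
  then smallest absolute overlap, then smallest reference coordinate)
  places IR-ambiguous alignments on the first IR; any breakpoint that does
  land in IRb is folded onto IRa by the mirror
  $p \mapsto \mathrm{IRa}_{start} + (\mathrm{IRb}_{end} - 1 - p)$, with the
  strand flipped for the folded side.
* **IR boundaries.** Reads crossing the joins of the second IR with the
  single-copy regions are structurally normal but can masquerade as
  junctions after folding. Two 400-bp decoy sequences centered on the
  SSC/IRb and IRb/LSC (origin) boundaries are added to the reference set;
  a candidate segment whose placement is matched or beaten by a decoy is
  discarded. For *fully aligned* reads the decoy must score strictly
  higher to disqualify the pair — decoys are plastome subsequences, so
  equal-score decoy ties are expected for normal reads near the
  boundaries and must not punch holes in the coverage profile.

## Split-read calling and deduplication

For each read, a junction candidate is a pair of alignments covering the
read's 5′ and 3′ ends with at most 10% of the read unexplained at the ends
and at most 50 unaligned middle bases (the cap on detectable insertions),
whose implied adjacency differs from the reference by more than 2 bp (the
collinearity tolerance). The breakpoint on the upstream side is the first
reference base after segment A's end, with the homologous bases assigned to
segment A; the downstream breakpoint is the base at which the read enters
locus B. Because the same junction read can be sequenced from either
strand, candidates are mapped to a canonical representation
(`canonical_junction()`) before deduplication; unique events are grouped by
breakpoints, strands and homology length, with an optional merge tolerance
(`merge_tol = 2`) for noisy data that takes the majority homology within a
group. Support sums are conserved by construction.

Event types follow the junction geometry on the circle: opposite strands
mean inversion; otherwise the forward skip $d = (pos_b - pos_a) \bmod L$
distinguishes deletions ($0 < d < L/2$) from duplication/circularization
junctions that loop backwards. The half-genome rule generalizes the
outward-facing-primer semantics used to classify such junctions in
amplicon assays.

## Coverage normalization

Rearrangement counts are only comparable between samples per genome copy.
Fully aligned plastid pairs give a per-kb profile on folded coordinates
(reads starting in either IR are assigned to the first IR), and

$$\text{mean fold-coverage} =
  \frac{\text{total plastid reads} \times \text{read length}}
       {\text{IR-folded genome length}}.$$

Base-count fold-coverage over the folded length is the default because
event counts are also IR-folded; a read-count interpretation can be had by
using the profile's raw totals. Rates are reported per genome copy
(`per_1x`) or per 10,000 genomes (`per_10k_genomes = 10^4 x per_1x`).
Windowed breakpoint-density tracks (100-nt windows, 50-nt step) count both
endpoints of every unique event in each overlapping window, scaled per
million plastid reads; note the track total is therefore
$2 \times \text{events} \times (\text{window}/\text{step}) \times 10^6 / \text{reads}$.
The breakpoint heat map accumulates support per 1-kb tile pair with
$(pos_a, pos_b)$ ordered so the smaller coordinate comes first.

## What the simulator emulates — and what it does not

`plastome_reference()` builds a miniature quadripartite circle with
uniform base composition; `plant_rearrangement()` derives linear,
amplicon-like rearranged molecules: a parental flank ending at $pos_a$,
optional inserted bases, and a flank entering $pos_b$ (reverse complement
for inversions). Defaults mirror the study conditions the package targets:
2×150 bp paired-end reads, ~320 bp median insert (the spread is not
published for such libraries; a truncated Normal with SD 50 bp is a
conventional choice), uniform fragment starts, i.i.d. substitution errors,
constant Q37 qualities (qualities are unused downstream). The intact circle
is sampled across the origin by sequence doubling.

Two design points deserve emphasis:

* **The repeat must live in the reference.** A junction's measurable
  homology is a property of the *reference* at both parental loci, not of
  the recombinant alone. Planting an `mh_len`-bp repeat therefore writes
  the repeat that ends the upstream flank into the reference at the start
  of the downstream locus (mirrored into the partner IR when inside an
  IR, preserving the quadripartite invariant), and the edited reference is
  returned and used for alignment.
* **Non-extension guards.** If the reference base just past the planted
  repeat happened to match the molecule's next base, the junction's true
  homology would genuinely be one base longer than requested — the planted
  value would be a lower bound, not a truth. Two bases on each side of
  every junction are therefore constrained to differ between the parental
  loci, making `expected_homology` exact and parameter-recovery tests
  well-posed.

The simulator does **not** model GC-biased coverage, indel sequencing
errors, optical duplicates, chimeric library artifacts, quality decay, or
the heteroplasmic copy-number structure of real plastid preparations.
Passing recovery tests therefore demonstrate the correctness of the
detection arithmetic (breakpoints, homology, typing, folding,
normalization) on reads that satisfy the library model — they do not
certify recall on real libraries, where alignability, repeats beyond the
IRs, and error structure matter.

## Worked example

```{r example}
ref <- plastome_reference(lsc_len = 10000, ira_len = 2000, ssc_len = 4000,
                          seed = 42)
specs <- list(
  junction_spec("deletion",  2000, 6000, mh_len = 10),
  junction_spec("inversion", 4000, 9000, mh_len = 3),
  junction_spec("deletion",  2500, 7000, ins_len = 7)
)
cohort <- simulate_cohort(ref, specs, junction_coverage = 30,
                          intact_coverage = 20, seed = 5)
scan <- detect_rearrangements(cohort$ref, cohort$sim)
scan
scan$events
summary(scan)
```

Every planted junction is recovered with its exact breakpoints, homology
length and type; the insertion appears with negative homology. Unique
events can be normalized and compared between samples:

```{r stats}
wt <- scan_mh_counts(scan, "example")
wt
homology_histogram(scan$events, scan$coverage)
```

## Direct-repeat annotation of junction sequences

`find_direct_repeat()` reproduces nucleotide-level junction annotation:
given the two parental sequences and the sequenced recombinant, it finds
the longest block that ends the upstream-matching part of the recombinant,
begins the downstream-matching part, and occurs in both parents at the
junction (ties: fewest mismatches, then leftmost in the upstream parent).
Mismatches are counted between the two *parental* repeat copies. The
package bundles junction sequences characterized around the psbD locus:

```{r repeats}
tab <- read.table(system.file("extdata", "psbD_junction_examples.tsv",
                              package = "ptrearr"),
                  sep = "\t", header = TRUE)
r <- tab[tab$junction_id == "31900F_17341R", ]
find_direct_repeat(r$parent_a, r$parent_b, r$recombinant)
```

A recombinant whose junction copy carries an internal deletion relative to
the parents (as one bundled example does) has no gap-free decomposition and
raises an error; `allow_gap = TRUE` retries with a single internal gap of
up to `gap_max` bases excised from the upstream parent. The gapped scoring
is a heuristic — the annotation convention for gapped repeat copies with
cross-parent mismatches is not standardized — and is off by default.

## Numerical and design choices

* Coordinates are 0-based half-open internally; TSV reports are 1-based.
* Thresholds: MH cutoff 5 bp; minimum segment 20 bp; minimum score 20;
  covered fraction 0.9; middle gap cap 50 bp; collinearity tolerance 2 bp;
  decoy width 400 bp; 1-kb coverage bins and heat-map tiles; 100/50-nt
  windows. All are surfaced in `split_params()` and the function
  signatures.
* `merge_tol` defaults to 0 (exact junction keys); use 2 bp with noisy
  reads.
* Deduplication counts *unique events* (the default throughout); read-level
  support is retained in the `support` column for per-read rates.
* The chi-squared comparison uses raw event counts, df = 1, no continuity
  correction by default (selectable); normalized rates would invalidate
  the test's sampling model. No multiple-testing correction is applied.
* Test and example problem sizes (18-kb genomes, 25–50× coverage, 150-bp
  reads) were chosen so the whole suite exercises every code path in
  minutes on one core while leaving per-bin and per-junction counts large
  enough for the stated statistical checks.

## Known limitations

* Gap-free segments: an indel *inside* a segment truncates it rather than
  being absorbed; junctions are still called if both flanks clear the
  minimum segment length.
* Insertions larger than the middle-gap cap (50 bp) are not detectable.
* Junctions with one side in another compartment (nuclear, mitochondrial
  insertions) are out of scope; extra compartments can be supplied as
  additional reference sequences and such reads are excluded from plastid
  statistics.
* Event typing of junctions wholly inside an inverted repeat is
  intrinsically ambiguous (an IRb+ placement equals an IRa− placement);
  the deterministic first-IR tie-break makes calls reproducible rather
  than resolving the ambiguity.
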
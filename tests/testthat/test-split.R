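# hand-built alignment rows for direct detect_split / filter_full_pairs tests
mk_aln <- function(read_id, read_start, read_end, ref_name, ref_start,
                   strand = "+", mismatches = 0) {
  data.frame(read_id = read_id, read_start = read_start, read_end = read_end,
             ref_name = ref_name, ref_start = ref_start,
             ref_end = ref_start + (read_end - read_start),
             strand = strand, mismatches = mismatches,
             score = (read_end - read_start) - 3 * mismatches,
             stringsAsFactors = FALSE)
}

test_that("fully aligned and reference-consistent reads are not split candidates", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 1)
  refset <- reference_set(ref)
  # single full-length alignment
  g <- mk_aln("r", 0, 150, ref$name, 1000)
  expect_null(detect_split(g, 150, refset))
  # two collinear, adjacent segments (reference-consistent)
  g2 <- rbind(mk_aln("r", 0, 80, ref$name, 1000),
              mk_aln("r", 80, 150, ref$name, 1080))
  expect_null(detect_split(g2, 150, refset))
  # collinear within tolerance (1 bp slip)
  g3 <- rbind(mk_aln("r", 0, 80, ref$name, 1000),
              mk_aln("r", 80, 150, ref$name, 1081))
  expect_null(detect_split(g3, 150, refset))
})

test_that("distant same-strand segments form a junction candidate", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 1)
  refset <- reference_set(ref)
  g <- rbind(mk_aln("r", 0, 80, ref$name, 1000),
             mk_aln("r", 70, 150, ref$name, 5000))
  cand <- detect_split(g, 150, refset)
  expect_false(is.null(cand))
  expect_equal(cand$overlap, 10)
  expect_equal(cand$aln_a$ref_end, 1080)
  expect_equal(cand$aln_b$ref_start, 5000)
})

test_that("decoy-dominated segments are rejected", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 1)
  refset <- reference_set(ref)
  g <- rbind(mk_aln("r", 0, 80, ref$name, 15960),
             mk_aln("r", 80, 150, ref$name, 11000, strand = "-"),
             mk_aln("r", 0, 100, "decoy_SSC_IRb", 120))
  # the decoy covers the first segment with at least its score -> no candidate
  expect_null(detect_split(g, 150, refset))
  # without the decoy row the same pair is a candidate
  expect_false(is.null(detect_split(g[1:2, ], 150, refset)))
})

test_that("reads mostly unexplained or with huge middle gaps are not candidates", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 1)
  refset <- reference_set(ref)
  # ends coverage too low (60 unaligned terminal bases)
  g <- rbind(mk_aln("r", 30, 80, ref$name, 1000),
             mk_aln("r", 80, 120, ref$name, 5000))
  expect_null(detect_split(g, 150, refset))
  # middle gap beyond the insertion cap
  g2 <- rbind(mk_aln("r", 0, 45, ref$name, 1000),
              mk_aln("r", 100, 150, ref$name, 5000))
  expect_null(detect_split(g2, 150, refset))
})

test_that("full pairs must have plastome-best placements on both mates", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 1)
  refset <- reference_set(ref)
  g1 <- mk_aln("p/1", 0, 150, ref$name, 1000)
  g2 <- mk_aln("p/2", 0, 150, ref$name, 1170)
  expect_equal(filter_full_pairs(g1, g2, 150, refset), c(1000, 1170))
  # one mate split -> pair excluded from coverage
  gs <- rbind(mk_aln("p/2", 0, 80, ref$name, 1000),
              mk_aln("p/2", 80, 150, ref$name, 5000))
  expect_null(filter_full_pairs(g1, gs, 150, refset))
  # both mates only on a decoy -> excluded
  d1 <- mk_aln("p/1", 0, 150, "decoy_SSC_IRb", 10)
  d2 <- mk_aln("p/2", 0, 150, "decoy_SSC_IRb", 200)
  expect_null(filter_full_pairs(d1, d2, 150, refset))
  # IR mate with two equal placements is folded to the first IR
  ir1 <- rbind(mk_aln("p/1", 0, 150, ref$name, 10100),
               mk_aln("p/1", 0, 150, ref$name, 16700, strand = "-"))
  expect_equal(filter_full_pairs(ir1, g2, 150, refset)[1], 10100)
})

test_that("every read gets exactly one fate and counts are conserved", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 3)
  cohort <- simulate_cohort(ref, list(junction_spec("deletion", 2000, 6000,
                                                    mh_len = 6)),
                            junction_coverage = 15, intact_coverage = 8,
                            seed = 4)
  scan <- detect_rearrangements(cohort$ref, cohort$sim)
  acc <- scan$accounting
  expect_equal(unname(acc["full"] + acc["split"] + acc["unassigned"] +
                        acc["no_alignment"]),
               unname(acc["total_reads"]))
  expect_equal(unname(acc["total_reads"]), 2 * nrow(cohort$sim$pairs))
})

test_that("the intact genome yields no split candidates (decoy soundness)", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 5)
  sim <- simulate_read_pairs(list(sim_molecule("g", ref, circular = TRUE)),
                             n_pairs = 800, seed = 6)
  scan <- detect_rearrangements(ref, sim)
  expect_equal(nrow(scan$events), 0)
  expect_equal(unname(scan$accounting["split"]), 0L)
})
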
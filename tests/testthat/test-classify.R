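test_that("the overlap statistic is segment lengths minus read length", {
  a <- list(read_id = "r", read_start = 0, read_end = 80)
  b <- list(read_id = "r", read_start = 60, read_end = 150)
  expect_equal(compute_overlap(a, b, 150), 20)
  b$read_start <- 75; b$read_end <- 150; a$read_end <- 75
  expect_equal(compute_overlap(a, b, 150), 0)
  a$read_end <- 70; b$read_start <- 78
  expect_equal(compute_overlap(a, b, 150), -8)
  b$read_id <- "other"
  expect_error(compute_overlap(a, b, 150), "different reads")
})

test_that("the microhomology classification threshold sits exactly at 5", {
  expect_identical(classify_mh(c(5, 4, -3, 0, 25)),
                   c("+MH", "-MH", "-MH", "-MH", "+MH"))
})

test_that("event types follow the circular forward-skip geometry", {
  L <- 18000
  expect_identical(classify_event_type(1080, 3000, "+", "+", L), "deletion")
  expect_identical(classify_event_type(5080, 2000, "+", "+", L), "duplication")
  expect_identical(classify_event_type(1000, 3000, "+", "-", L), "inversion")
  expect_error(classify_event_type(1000, 1000, "+", "+", L), "reference-consistent")
})

test_that("junctions observed from either strand canonicalize identically", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 42)
  pl <- plant_rearrangement(ref, junction_spec("deletion", 2000, 6000,
                                               mh_len = 6),
                            flank_len = 400, seed = 2)
  refset <- reference_set(pl$ref)
  read <- substr(pl$molecule$seq, 331, 480)
  for (seq in c(read, revcomp(read))) {
    aln <- align_reads(c(r = seq), refset)
    cand <- detect_split(aln, 150, refset, split_params())
    tab <- candidate_table(list(cand), 150, pl$ref)
    expect_equal(tab$pos_a, 2000)
    expect_equal(tab$pos_b, 6000)
    expect_identical(c(tab$strand_a, tab$strand_b), c("+", "+"))
    expect_equal(tab$homology_len, 6)
  }
  # inversion junction from both strands
  pinv <- plant_rearrangement(ref, junction_spec("inversion", 4000, 9000,
                                                 mh_len = 3),
                              flank_len = 400, seed = 3)
  refset2 <- reference_set(pinv$ref)
  read2 <- substr(pinv$molecule$seq, 331, 480)
  keys <- lapply(c(read2, revcomp(read2)), function(seq) {
    aln <- align_reads(c(r = seq), refset2)
    cand <- detect_split(aln, 150, refset2, split_params())
    candidate_table(list(cand), 150, pinv$ref)[
      , c("pos_a", "pos_b", "strand_a", "strand_b", "homology_len")]
  })
  expect_equal(keys[[1]], keys[[2]], ignore_attr = TRUE)
  expect_identical(keys[[1]]$strand_b, "-")
})

test_that("deduplication groups identical junction keys and sums support", {
  cands <- data.frame(
    read_id = c("a", "b", "c", "d"),
    pos_a = c(2000, 2000, 2000, 5000), pos_b = c(6000, 6000, 6000, 9000),
    strand_a = "+", strand_b = "+",
    homology_len = c(7, 7, 7, 0),
    event_type = "deletion", stringsAsFactors = FALSE
  )
  ev <- deduplicate_junctions(cands)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$support, c(3, 1))
  expect_equal(sum(ev$support), nrow(cands))   # fold conservation
  expect_identical(ev$mh_class, c("+MH", "-MH"))
})

test_that("merge tolerance pools error-shifted reads and keeps the majority call", {
  cands <- data.frame(
    read_id = letters[1:5],
    pos_a = c(2000, 2000, 2001, 2000, 2000),
    pos_b = c(6000, 6000, 6000, 6001, 6000),
    strand_a = "+", strand_b = "+",
    homology_len = c(6, 6, 7, 6, 6),
    event_type = "deletion", stringsAsFactors = FALSE
  )
  ev <- deduplicate_junctions(cands, merge_tol = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$support, 5)
  expect_equal(ev$homology_len, 6)
  expect_equal(ev$pos_a, 2000)
  expect_equal(ev$pos_b, 6000)
})

test_that("a junction inside the IR is reported once on the first IR", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 7)
  # both breakpoints inside IRa; reads match IRa and IRb equally
  cohort <- simulate_cohort(ref, list(junction_spec("deletion", 10450, 11600,
                                                    mh_len = 9)),
                            junction_coverage = 25, intact_coverage = 0,
                            seed = 8)
  scan <- detect_rearrangements(cohort$ref, cohort$sim)
  expect_equal(nrow(scan$events), 1)
  expect_equal(scan$events$pos_a, 10450)
  expect_equal(scan$events$pos_b, 11600)
  expect_equal(scan$events$homology_len, 9)
  irb_start <- ref$regions$start[4]
  expect_true(all(c(scan$events$pos_a, scan$events$pos_b) < irb_start))
})

test_that("measured homology equals the planted repeat length (oracle check)", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 9)
  for (mh in c(0, 3, 12)) {
    pl <- plant_rearrangement(ref, junction_spec("deletion", 3000, 7500,
                                                 mh_len = mh),
                              flank_len = 400, seed = mh + 1)
    # direct measurement on the sequences: longest k such that the k bases
    # ending the left flank equal the k bases entering locus B
    r <- pl$ref$seq
    direct <- 0
    while (substr(r, 3000 - direct, 3000 - direct) ==
           substr(r, 7500 + mh - direct, 7500 + mh - direct)) {
      direct <- direct + 1
    }
    expect_equal(direct, mh)
    refset <- reference_set(pl$ref)
    read <- substr(pl$molecule$seq, 326, 475)
    cand <- detect_split(align_reads(c(r = read), refset), 150, refset)
    expect_equal(cand$overlap, mh)
  }
})
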
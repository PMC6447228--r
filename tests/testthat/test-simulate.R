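test_that("junction specs validate microhomology/insertion exclusivity", {
  expect_error(junction_spec("deletion", 100, 200, mh_len = 3, ins_len = 2),
               "both")
  expect_error(junction_spec("deletion", 100, 200, mh_len = -1), ">= 0")
  expect_identical(junction_spec("inversion", 10, 20)$kind, "inversion")
})

test_that("planting writes the shared repeat into both parental loci", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 42)
  sp <- junction_spec("deletion", 2000, 6000, mh_len = 10)
  pl <- plant_rearrangement(ref, sp, flank_len = 400, seed = 7)
  # molecule counts the repeat once
  expect_equal(nchar(pl$molecule$seq), 2 * 400 - 10)
  r <- pl$ref
  rep_a <- substr(r$seq, 2000 - 10 + 1, 2000)
  rep_b <- substr(r$seq, 6000 + 1, 6000 + 10)
  expect_identical(rep_a, rep_b)
  # last mh bases of the left molecule flank equal the repeat
  expect_identical(substr(pl$molecule$seq, 391, 400), rep_a)
  expect_equal(pl$truth$expected_homology, 10)
  expect_equal(pl$truth$junction_offset, 400)
})

test_that("insertions and inversions are constructed as specified", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 42)
  ins <- plant_rearrangement(ref, junction_spec("deletion", 2500, 7000,
                                                ins_len = 7),
                             flank_len = 300, seed = 3)
  expect_equal(nchar(ins$molecule$seq), 2 * 300 + 7)
  expect_equal(ins$truth$expected_homology, -7)
  inv <- plant_rearrangement(ref, junction_spec("inversion", 4000, 9000),
                             flank_len = 300, seed = 4)
  # downstream flank is the reverse complement of the reference interval
  right <- substr(inv$molecule$seq, 301, 600)
  expect_identical(right,
                   revcomp(substr(inv$ref$seq, 9000 + 1 - 299, 9000 + 1)))
  expect_identical(inv$truth$strand_b, "-")
})

test_that("planting inside an inverted repeat preserves IR symmetry", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 42)
  sp <- junction_spec("deletion", 10500, 11500, mh_len = 8)
  pl <- plant_rearrangement(ref, sp, flank_len = 400, seed = 9)
  expect_no_error(as_plastome_ref(pl$ref$seq, pl$ref$regions))
})

test_that("ill-posed plantings are rejected", {
  ref <- plastome_reference(10000, 2000, 4000, seed = 42)
  expect_error(plant_rearrangement(ref, junction_spec("deletion", 100, 6000),
                                   flank_len = 400, seed = 1),
               "past the ends")
  expect_error(plant_rearrangement(ref, junction_spec("duplication", 2000, 1900),
                                   flank_len = 400, seed = 1),
               "ill-defined")
  expect_error(plant_rearrangement(ref, junction_spec("duplication", 2000, 6000),
                                   flank_len = 400, seed = 1),
               "deletion")
})

test_that("error-free reads are exact substrings of their source molecule", {
  ref <- small_ref()
  mol <- sim_molecule("m1", substr(ref$seq, 1, 2000))
  sim <- simulate_read_pairs(list(mol), n_pairs = 200, read_len = 100,
                             insert_mean = 250, insert_sd = 30, seed = 2)
  expect_equal(nrow(sim$pairs), 200)
  for (i in c(1, 57, 200)) {
    tr <- sim$truth[i, ]
    frag <- substr(mol$seq, tr$start + 1, tr$start + tr$insert)
    fwd <- substr(frag, 1, 100)
    rev <- revcomp(substr(frag, tr$insert - 99, tr$insert))
    if (tr$flipped) expect_identical(c(sim$pairs$mate1[i], sim$pairs$mate2[i]),
                                     c(rev, fwd))
    else expect_identical(c(sim$pairs$mate1[i], sim$pairs$mate2[i]),
                          c(fwd, rev))
  }
})

test_that("zero-weight molecules contribute no reads; short ones are excluded", {
  ref <- small_ref()
  m1 <- sim_molecule("m1", substr(ref$seq, 1, 1500), weight = 1)
  m2 <- sim_molecule("m2", substr(ref$seq, 1501, 3000), weight = 0)
  sim <- simulate_read_pairs(list(m1, m2), n_pairs = 100, read_len = 100,
                             insert_mean = 200, seed = 5)
  expect_true(all(sim$truth$molecule == "m1"))
  short <- sim_molecule("tiny", substr(ref$seq, 1, 80), weight = 1)
  expect_warning(
    sim2 <- simulate_read_pairs(list(m1, short), n_pairs = 300, read_len = 100,
                                insert_mean = 200, seed = 6),
    "excluding")
  expect_equal(nrow(sim2$truth), 300 - sum(sim2$excluded$draws))
})

test_that("substitution noise matches the binomial expectation", {
  ref <- plastome_reference(4000, 1000, 2000, seed = 8)
  mol <- sim_molecule("g", ref, circular = TRUE)
  rate <- 0.01
  noisy <- simulate_read_pairs(list(mol), n_pairs = 10000, read_len = 150,
                               insert_mean = 320, error_rate = rate, seed = 11)
  clean <- simulate_read_pairs(list(mol), n_pairs = 10000, read_len = 150,
                               insert_mean = 320, error_rate = 0, seed = 11)
  mism <- function(a, b) {
    sum(vapply(seq_along(a), function(i) {
      sum(strsplit(a[i], "")[[1]] != strsplit(b[i], "")[[1]])
    }, numeric(1)))
  }
  n_mm <- mism(noisy$pairs$mate1, clean$pairs$mate1) +
    mism(noisy$pairs$mate2, clean$pairs$mate2)
  n_bases <- 2 * 10000 * 150
  se <- sqrt(rate * (1 - rate) / n_bases)
  expect_lt(abs(n_mm / n_bases - rate), 3 * se)
})

test_that("simulation is deterministic for a fixed seed", {
  ref <- small_ref()
  mol <- sim_molecule("g", ref, circular = TRUE)
  s1 <- simulate_read_pairs(list(mol), 50, seed = 42, error_rate = 0.01)
  s2 <- simulate_read_pairs(list(mol), 50, seed = 42, error_rate = 0.01)
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(s1$truth, s2$truth)
})

test_that("FASTQ pairs round-trip through write and read", {
  ref <- small_ref()
  sim <- simulate_read_pairs(list(sim_molecule("g", ref, circular = TRUE)),
                             n_pairs = 25, seed = 3)
  dir <- tempfile()
  paths <- write_fastq_pair(sim, dir, prefix = "t")
  r1 <- read_fastq_seqs(file.path(dir, "t_R1.fastq"))
  expect_identical(unname(r1), sim$pairs$mate1)
  expect_identical(names(r1), paste0(sim$pairs$id, "/1"))
  r2 <- read_fastq_seqs(file.path(dir, "t_R2.fastq"))
  expect_identical(unname(r2), sim$pairs$mate2)
})
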
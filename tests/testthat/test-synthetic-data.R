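# Generators: truth bookkeeping, determinism, the 3'-position bias, and
# decoy behaviour.

test_that("zero-noise libraries plant exactly the requested elements with intact cores", {
  spec0 <- element_spec(per_base_mutation_rate = 0, core_mutation_rate = 0,
                        indel_rate = 0)
  lib <- make_library(n_families = 50, frac_with_element = 0.2,
                      spec = spec0, seed = 401)
  expect_equal(nrow(lib$truth), 10)
  expect_true(all(lib$truth$n_core_mutations == 0))
  # every carrier contains the exact core: step-1 recall is 1
  hits <- find_exact_motif(lib$families)
  expect_setequal(families_with_hit(hits), lib$truth$seq_id)
  # planted intervals really contain the element
  for (i in seq_len(nrow(lib$truth))) {
    tr <- lib$truth[i, ]
    cons <- lib$families$consensus[lib$families$family_id == tr$seq_id]
    frag <- substr(cons, tr$start + 1, tr$end)
    if (tr$strand == "-") frag <- revcomp(frag)
    expect_true(grepl("TCAGCAGGAAGCAGTTA", frag, fixed = TRUE))
  }
})

test_that("generation is a pure function of parameters and seed", {
  a <- make_library(n_families = 20, seed = 403)
  b <- make_library(n_families = 20, seed = 403)
  expect_identical(a$families, b$families)
  expect_identical(a$truth, b$truth)
  c <- make_library(n_families = 20, seed = 404)
  expect_false(identical(a$families$consensus, c$families$consensus))
  d1 <- make_decoys(9, seed = 405)
  d2 <- make_decoys(9, seed = 405)
  expect_identical(d1$seqs, d2$seqs)
})

test_that("planted midpoints recover the Beta(5, 1.5) 3' bias", {
  lib <- make_library(n_families = 2000, frac_with_element = 1,
                      length_range = c(1500L, 3000L), seed = 407)
  tr <- lib$truth
  realized <- relative_position_score(tr$start + 1L, tr$end,
                                      lib$families$length[
                                        match(tr$seq_id,
                                              lib$families$family_id)],
                                      tr$strand)
  n <- length(realized)
  expect_gte(n, 1000)
  se <- sd(realized) / sqrt(n)
  expect_lt(abs(mean(realized) - 5 / 6.5), 3 * se)
  # and the draws themselves match what was realized up to clamping
  expect_lt(max(abs(realized - tr$position_drawn)), 0.06)
})

test_that("genome copies carry annotations that round-trip and respect strand", {
  spec0 <- element_spec(per_base_mutation_rate = 0, core_mutation_rate = 0,
                        indel_rate = 0)
  lib <- make_library(n_families = 20, frac_with_element = 0.5,
                      spec = spec0, seed = 409)
  gen <- make_genome(lib, layout = "copies", n_copies_per_family = 1,
                     genome_len = 100000L, divergence = 0, seed = 410)
  expect_equal(nrow(gen$annotations), nrow(lib$truth))
  # annotation spans contain the inserted copy exactly
  for (i in seq_len(nrow(gen$annotations))) {
    a <- gen$annotations[i, ]
    cons <- lib$families$consensus[lib$families$name == a$repeat_name]
    frag <- substr(gen$genome[[1]], a$start + 1, a$end)
    expected <- if (a$strand == "-") revcomp(cons) else cons
    expect_identical(frag, expected)
  }
  # the .out writer/reader round-trips the truth annotations
  tmp <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(gen$annotations, tmp)
  expect_equal(read_repeatmasker_out(tmp), gen$annotations)
  # element truth intervals land inside their family's annotation span
  pairs <- stranded_intersect(gen$truth, gen$annotations, stranded = FALSE)
  expect_gte(nrow(pairs), nrow(gen$truth))
})

test_that("decoy sets cycle types, plant bare cores, and honour n = 0", {
  dec <- make_decoys(9, seed = 411)
  expect_equal(nrow(dec$types), 9)
  expect_equal(sort(unique(dec$types$type)),
               c("background", "core_only", "shuffled_core"))
  core_only <- dec$seqs[dec$types$type == "core_only"]
  hits <- find_exact_motif(core_only)
  expect_setequal(families_with_hit(hits), names(core_only))
  none <- make_decoys(0)
  expect_length(none$seqs, 0)
})

test_that("core-only decoys score below full planted elements under a refined model", {
  spec0 <- element_spec(per_base_mutation_rate = 0, core_mutation_rate = 0,
                        indel_rate = 0)
  lib <- make_library(n_families = 30, frac_with_element = 0.4,
                      spec = spec0, seed = 413)
  s1 <- find_exact_motif(lib$families)
  m <- profile_hmm(anchor_align(extract_seed_windows(lib$families, s1)),
                   bg = estimate_background(lib$families$consensus))
  m <- calibrate(m, n_samples = 400, seed = 413)
  full_scores <- vapply(lib$truth$seq_id, function(fid) {
    cons <- lib$families$consensus[lib$families$family_id == fid]
    max(viterbi_local(m, cons, min_bits = -1e6)$bit_score)
  }, numeric(1))
  dec <- make_decoys(6, len = 500, types = "core_only", seed = 415)
  decoy_scores <- vapply(dec$seqs, function(s) {
    max(viterbi_local(m, s, min_bits = -1e6)$bit_score)
  }, numeric(1))
  expect_lt(max(decoy_scores), min(full_scores))
})

test_that("generator argument validation", {
  expect_error(make_library(frac_with_element = 1.2), "\\[0, 1\\]")
  expect_error(element_spec(per_base_mutation_rate = 1), "\\[0, 1\\)")
  spec0 <- element_spec()
  lib <- make_library(n_families = 5, frac_with_element = 1, seed = 417)
  expect_error(make_genome(lib, layout = "copies", genome_len = 5000L,
                           n_copies_per_family = 3, seed = 1),
               "exceeds genome length")
})
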
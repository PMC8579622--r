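# The step-2 refinement loop: fixed points, monotonicity, determinism,
# peak-cycle selection, and recovery beyond exact matching.

clean_spec <- element_spec(per_base_mutation_rate = 0, core_mutation_rate = 0,
                           indel_rate = 0)

test_that("a library of exact element copies is a fixed point selected at cycle 1", {
  lib <- make_library(n_families = 30, frac_with_element = 0.3,
                      spec = clean_spec, seed = 101)
  hits <- find_exact_motif(lib$families)
  wins <- extract_seed_windows(lib$families, hits)
  res <- iterate_search(anchor_align(wins), lib$families, seed = 101,
                        calib_n = 400)
  tab <- summary(res)$cycles
  expect_lt(nrow(tab), res$params$max_cycles)  # early stop triggered
  expect_equal(res$selected_cycle, 1)          # earliest of the tied peak
  expect_true(all(tab$n_hits == tab$n_hits[1]))
})

test_that("identical planted windows make the rebuilt consensus a fixed point", {
  # six families share one literal 97-nt element window in distinct
  # random backgrounds: realignment reproduces the training rows exactly
  set.seed(111)
  window <- paste0(random_dna(1, 40), "TCAGCAGGAAGCAGTTA", random_dna(1, 40))
  seqs <- vapply(1:6, function(i) {
    paste0(random_dna(1, 300), window, random_dna(1, 300))
  }, character(1))
  fam <- data.frame(family_id = sprintf("SF%02d", 1:6), name = "syn",
                    repeat_class = "LTR", consensus = seqs,
                    length = nchar(seqs), stringsAsFactors = FALSE)
  hits <- find_exact_motif(fam)
  res <- iterate_search(
    anchor_align(extract_seed_windows(fam, hits)), fam, seed = 111,
    calib_n = 400)
  expect_gte(length(res$cycles), 2)
  expect_identical(res$cycles[[2]]$model$consensus,
                   res$cycles[[1]]$model$consensus)
  expect_equal(res$selected_cycle, 1)
})

test_that("lowering the E threshold never increases a cycle's hit count", {
  lib <- make_library(n_families = 30, frac_with_element = 0.3, seed = 103)
  hits <- find_exact_motif(lib$families)
  m <- profile_hmm(anchor_align(extract_seed_windows(lib$families, hits)),
                   bg = estimate_background(lib$families$consensus))
  m <- calibrate(m, n_samples = 400, seed = 103)
  n_strict <- run_cycle(m, lib$families, e_threshold = 1e-8)$n_hits
  n_mid <- run_cycle(m, lib$families, e_threshold = 1e-5)$n_hits
  n_loose <- run_cycle(m, lib$families, e_threshold = 1e-2)$n_hits
  expect_lte(n_strict, n_mid)
  expect_lte(n_mid, n_loose)
})

test_that("duplicating a hit-bearing family adds exactly its hit count", {
  lib <- make_library(n_families = 25, frac_with_element = 0.4,
                      spec = clean_spec, seed = 105)
  hits <- find_exact_motif(lib$families)
  m <- profile_hmm(anchor_align(extract_seed_windows(lib$families, hits)),
                   bg = estimate_background(lib$families$consensus))
  m <- calibrate(m, n_samples = 400, seed = 105)
  base <- run_cycle(m, lib$families, e_threshold = 1e-5)
  carrier <- base$hits$target_id[1]
  per_carrier <- sum(base$hits$target_id == carrier)
  dup <- lib$families[lib$families$family_id == carrier, ]
  dup$family_id <- "FAMDUP"
  more <- run_cycle(m, rbind(lib$families, dup), e_threshold = 1e-5)
  expect_equal(more$n_hits, base$n_hits + per_carrier)
  expect_equal(more$n_families, base$n_families + 1)
})

test_that("iteration recovers families with mutated cores that exact match misses", {
  spec <- element_spec(per_base_mutation_rate = 0.15,
                       core_mutation_rate = 0.06)
  lib <- make_library(n_families = 60, frac_with_element = 0.3,
                      spec = spec, seed = 11)
  expect_gt(sum(lib$truth$n_core_mutations > 0), 0)
  hits <- find_exact_motif(lib$families)
  exact_families <- length(families_with_hit(hits))
  wins <- extract_seed_windows(lib$families, hits)
  res <- iterate_search(anchor_align(wins), lib$families, seed = 11)
  tab <- summary(res)$cycles
  # hit counts do not decrease over the early cycles
  expect_true(all(diff(tab$n_hits[1:min(3, nrow(tab))]) >= 0))
  sel <- selected_record(res)
  expect_gt(sel$n_families, exact_families)
  ev <- evaluate_hits(sel$hits, lib$truth)
  exact_ev <- evaluate_hits(
    data.frame(target_id = hits$family_id, S = hits$start + 1L,
               E = hits$end, strand = hits$strand), lib$truth)
  expect_gte(ev$recall, exact_ev$recall)
  expect_lte(ev$fdr, 0.05)
})

test_that("identical inputs and seeds give identical cycle records", {
  lib <- make_library(n_families = 20, frac_with_element = 0.3, seed = 107)
  hits <- find_exact_motif(lib$families)
  wins <- anchor_align(extract_seed_windows(lib$families, hits))
  r1 <- iterate_search(wins, lib$families, seed = 107, max_cycles = 3,
                       calib_n = 300)
  r2 <- iterate_search(wins, lib$families, seed = 107, max_cycles = 3,
                       calib_n = 300)
  expect_identical(summary(r1)$cycles, summary(r2)$cycles)
  expect_identical(selected_record(r1)$hits, selected_record(r2)$hits)
})

test_that("empty seed alignments and uncalibrated models are rejected", {
  expect_error(iterate_search(character(0), c(f = "ACGT")), "empty seed")
  m <- profile_hmm(c(a = "ACGTACGTAA", b = "ACGTACGTAA"))
  expect_error(run_cycle(m, c(f = "ACGTACGT")), "not calibrated")
})

test_that("position and column-frequency reports describe the selected cycle", {
  lib <- make_library(n_families = 30, frac_with_element = 0.4,
                      spec = clean_spec, seed = 109)
  hits <- find_exact_motif(lib$families)
  res <- iterate_search(
    anchor_align(extract_seed_windows(lib$families, hits)),
    lib$families, seed = 109, max_cycles = 2, calib_n = 400)
  sel <- selected_record(res)
  pos <- positions_report(sel, lib$families)
  expect_equal(nrow(pos), sel$n_hits)
  expect_true(all(pos$score >= 0 & pos$score <= 1))
  expect_true(all(pos$S >= 1 & pos$E <= pos$L))
  freq <- column_frequency_report(sel)
  expect_equal(dim(freq), c(sel$model$M, 4L))
  expect_true(all(abs(rowSums(freq) - 1) < 1e-9 | rowSums(freq) == 0))
  # modal residues of the core columns spell the 17-nt motif
  core_cols <- 41:57
  modal <- paste(colnames(freq)[apply(freq[core_cols, ], 1, which.max)],
                 collapse = "")
  expect_identical(modal, "TCAGCAGGAAGCAGTTA")
  # frequencies are invariant to hit order
  shuf <- sel
  set.seed(1)
  shuf$hits <- shuf$hits[sample(nrow(shuf$hits)), ]
  expect_equal(column_frequency_report(shuf), freq)
})
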
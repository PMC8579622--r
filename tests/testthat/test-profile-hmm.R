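# Model construction, local Viterbi/forward scoring against an exhaustive
# path-enumeration oracle, and hit realignment.

test_that("identical ungapped rows with zero pseudocount give one-hot emissions", {
  h <- profile_hmm(c(a = "ACG", b = "ACG", c = "ACG"), pseudocount = 0)
  expect_equal(h$M, 3)
  expect_equal(unname(h$match_emissions),
               rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0)))
  expect_identical(h$consensus, "ACG")
})

test_that("columns at or above the gap-fraction threshold are not match states", {
  # middle column gapped in 2 of 3 rows (0.667 >= 0.5): insert column
  h <- profile_hmm(c(a = "A-G", b = "A-G", c = "ACG"))
  expect_equal(h$M, 2)
  expect_equal(h$match_cols, c(1L, 3L))
  # strictly-below rule: gap fraction exactly 0.5 is excluded too
  h2 <- profile_hmm(c(a = "A-G", b = "ACG"))
  expect_equal(h2$M, 2)
})

test_that("emission pseudocounts follow (counts + pc*q)/(total + pc)", {
  # column counts A=2, C=1, pseudocount 1, uniform q
  h <- profile_hmm(c(a = "A", b = "A", c = "C"), pseudocount = 1)
  expect_equal(unname(h$match_emissions[1, "A"]), (2 + 0.25) / (3 + 1))
  expect_equal(unname(h$match_emissions[1, "C"]), (1 + 0.25) / (3 + 1))
  expect_equal(unname(h$match_emissions[1, "G"]), 0.25 / 4)
})

test_that("emission and transition rows are normalized on random alignments", {
  set.seed(31)
  for (rep in 1:10) {
    aln <- random_small_alignment(sample(3:8, 1), sample(4:12, 1))
    h <- try(profile_hmm(aln, bg = c(0.3, 0.2, 0.2, 0.3)), silent = TRUE)
    if (inherits(h, "try-error")) next  # all-gap draw
    expect_equal(rowSums(h$match_emissions), rep(1, h$M), tolerance = 1e-9)
    expect_equal(rowSums(h$insert_emissions), rep(1, h$M + 1),
                 tolerance = 1e-9)
    expect_equal(unname(rowSums(h$transitions[, 1:3, drop = FALSE])),
                 rep(1, h$M), tolerance = 1e-9)
    expect_equal(unname(rowSums(h$transitions[, 4:5, drop = FALSE])),
                 rep(1, h$M), tolerance = 1e-9)
    expect_equal(unname(rowSums(h$transitions[, 6:7, drop = FALSE])),
                 rep(1, h$M), tolerance = 1e-9)
  }
})

test_that("all-gap alignments are rejected", {
  expect_error(profile_hmm(c(a = "--", b = "--")), "gap threshold")
})

test_that("a single match state emitting A scores 2 bits on target A", {
  h <- profile_hmm(c(a = "A", b = "A"), pseudocount = 0)
  hit <- viterbi_local(h, "A", both_strands = FALSE)
  expect_equal(hit$bit_score, 2)
  expect_equal(hit$S, 1)
  expect_equal(hit$E, 1)
  # single legal path: forward equals Viterbi
  expect_equal(forward_local(h, "A"), 2)
})

test_that("the model consensus outscores every single-substitution variant", {
  set.seed(33)
  aln <- setNames(rep(paste(sample(c("A", "C", "G", "T"), 12,
                                   replace = TRUE), collapse = ""), 5),
                  paste0("r", 1:5))
  h <- profile_hmm(aln)
  cons <- h$consensus
  best <- function(s) max(viterbi_local(h, s, min_bits = -1e6,
                                        both_strands = FALSE)$bit_score)
  ref <- best(cons)
  for (i in c(1, 6, 12)) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(cons, i, i))) {
      variant <- paste0(substr(cons, 1, i - 1), b,
                        substr(cons, i + 1, nchar(cons)))
      expect_lt(best(variant), ref)
    }
  }
})

test_that("Viterbi and forward match exhaustive path enumeration (M <= 3, targets <= 6 nt)", {
  set.seed(37)
  n_checked <- 0
  while (n_checked < 25) {
    width <- sample(1:3, 1)
    aln <- random_small_alignment(sample(2:5, 1), width, gap_prob = 0.2)
    h <- try(profile_hmm(aln, bg = c(0.2, 0.3, 0.3, 0.2)), silent = TRUE)
    if (inherits(h, "try-error") || h$M > 3) next
    target <- random_dna(1, sample(1:6, 1))
    orc <- oracle_enumerate(h, target)
    vit <- viterbi_local(h, target, min_bits = -1e6, both_strands = FALSE)
    expect_equal(max(vit$bit_score), orc$viterbi, tolerance = 1e-9)
    expect_equal(forward_local(h, target), orc$forward, tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
})

test_that("forward dominates Viterbi on random model/target pairs", {
  set.seed(41)
  for (rep in 1:100) {
    aln <- random_small_alignment(4, sample(3:8, 1), gap_prob = 0.1)
    h <- try(profile_hmm(aln), silent = TRUE)
    if (inherits(h, "try-error")) next
    target <- random_dna(1, sample(5:30, 1))
    vit <- viterbi_local(h, target, min_bits = -1e6, both_strands = FALSE)
    expect_gte(forward_local(h, target) + 1e-9, max(vit$bit_score))
  }
})

test_that("scanning the reverse complement flips strands and reflects coordinates", {
  set.seed(43)
  aln <- setNames(rep(random_dna(1, 15), 6), paste0("r", 1:6))
  h <- profile_hmm(aln)
  target <- paste0(random_dna(1, 40), aln[[1]], random_dna(1, 40))
  fwd <- viterbi_local(h, target, min_bits = 5)
  rev <- viterbi_local(h, revcomp(target), min_bits = 5)
  n <- nchar(target)
  expect_equal(nrow(fwd), nrow(rev))
  key_fwd <- paste(fwd$S, fwd$E, fwd$strand, round(fwd$bit_score, 6))
  key_rev <- paste(n - rev$E + 1, n - rev$S + 1,
                   chartr("+-", "-+", rev$strand), round(rev$bit_score, 6))
  expect_setequal(key_fwd, key_rev)
})

test_that("E-values follow the Gumbel closed form and are monotone in score", {
  expect_equal(e_value(10, mu = 10, lambda = 0.7, n_eff = 100),
               100 * (1 - exp(-1)), tolerance = 1e-12)
  # strictly decreasing over the usable score range (below mu the tail
  # probability saturates at 1 in double precision)
  s <- seq(8, 60, by = 2.5)
  ev <- e_value(s, mu = 12, lambda = 0.65, n_eff = 500)
  expect_true(all(diff(ev) < 0))
  expect_lt(e_value(1e4, 12, 0.65, 500), 1e-200)
  expect_error(e_value(1, 0, -1, 10))
})

test_that("hit realignment places residues by path and stops on empty sets", {
  set.seed(47)
  cons <- random_dna(1, 10)
  h <- profile_hmm(setNames(rep(cons, 4), paste0("r", 1:4)))
  hit <- viterbi_local(h, cons, both_strands = FALSE, min_bits = 1)
  expect_identical(hit$aligned_row[1], cons)  # all-match path
  aln <- hits_to_alignment(hit)
  expect_equal(unname(nchar(aln)), rep(h$M, nrow(hit)))
  expect_error(hits_to_alignment(hit[0, ]), "empty hit set")
})

test_that("a deletion in the target shows as a gap at the deleted column", {
  cons <- "ACGTACGTAC"
  h <- profile_hmm(setNames(rep(cons, 8), paste0("r", 1:8)),
                   pseudocount = 0.5)
  delected <- paste0(substr(cons, 1, 4), substr(cons, 6, 10))
  hit <- viterbi_local(h, delected, both_strands = FALSE, min_bits = 1)
  expect_match(hit$path[1], "D")
  expect_equal(substr(hit$aligned_row[1], 5, 5), "-")
})

test_that("a model rebuilt from perfect hits keeps its consensus (fixed point)", {
  set.seed(49)
  cons <- random_dna(1, 30)
  h <- profile_hmm(setNames(rep(cons, 6), paste0("r", 1:6)))
  targets <- setNames(paste0(random_dna(4, 50), cons, random_dna(4, 50)),
                      paste0("t", 1:4))
  hits <- do.call(rbind, lapply(names(targets), function(id) {
    viterbi_local(h, targets[[id]], min_bits = 10, both_strands = FALSE,
                  target_id = id)
  }))
  h2 <- profile_hmm(hits_to_alignment(hits))
  expect_identical(h2$consensus, h$consensus)
})

test_that("model serialization round-trips exactly", {
  set.seed(51)
  h <- profile_hmm(random_small_alignment(5, 20, gap_prob = 0.1))
  h <- calibrate(h, n_samples = 200, sample_len = 80, seed = 9)
  tmp <- withr::local_tempfile(fileext = ".hmm")
  write_hmm(h, tmp)
  back <- read_hmm(tmp)
  expect_equal(back$match_emissions, h$match_emissions, tolerance = 1e-14)
  expect_equal(back$transitions, h$transitions, tolerance = 1e-14)
  expect_equal(back$mu, h$mu, tolerance = 1e-14)
  expect_equal(back$lambda, h$lambda, tolerance = 1e-14)
  expect_identical(back$consensus, h$consensus)
  # the reloaded model scores identically
  t <- random_dna(1, 60)
  expect_equal(viterbi_local(back, t, min_bits = -1e6)$bit_score,
               viterbi_local(h, t, min_bits = -1e6)$bit_score)
})

test_that("print, summary, coef and simulate methods work on a fitted model", {
  set.seed(53)
  cons <- random_dna(1, 20)
  h <- profile_hmm(setNames(rep(cons, 5), paste0("r", 1:5)))
  expect_output(print(h), "match states")
  expect_output(print(summary(h)), "information")
  co <- coef(h)
  expect_named(co, c("match_emissions", "insert_emissions", "transitions"))
  sims <- simulate(h, nsim = 5, seed = 2)
  expect_length(sims, 5)
  # with a tight consensus model, simulated sequences stay close to it
  expect_true(all(nchar(sims) >= h$M - 2 & nchar(sims) <= h$M + 8))
  expect_identical(simulate(h, nsim = 3, seed = 7),
                   simulate(h, nsim = 3, seed = 7))
})
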
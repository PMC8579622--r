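# Position-bias scores, directional extension, stranded intersection
# against an all-pairs oracle, tallies, LTR fractions, codon frequencies.

test_that("relative position scores follow [(S+E)/2]/L with strand reflection", {
  expect_equal(relative_position_score(80, 100, 100, "+"), 0.90)
  expect_equal(relative_position_score(80, 100, 100, "-"), 0.10)
  expect_equal(relative_position_score(80, 100, 100, "-",
                                       strand_reflect = FALSE), 0.90)
  # a full-length hit sits at the midpoint regardless of strand
  L <- 250
  expect_equal(relative_position_score(1, L, L, "+"), 0.5 + 1 / (2 * L))
  expect_equal(relative_position_score(1, L, L, "-"), 0.5 - 1 / (2 * L))
  expect_error(relative_position_score(0, 10, 100), "1 <= S")
  expect_error(relative_position_score(5, 120, 100), "1 <= S")
})

test_that("interval extension is strand-aware, clamped, and composes additively", {
  iv <- function(s, e, st) data.frame(seq_id = "chr1", start = s, end = e,
                                      strand = st, stringsAsFactors = FALSE)
  expect_equal(extend_interval(iv(100, 200, "+"), 50, "3p")$end, 250)
  expect_equal(extend_interval(iv(100, 200, "+"), 50, "3p")$start, 100)
  expect_equal(extend_interval(iv(100, 200, "-"), 50, "3p")$start, 50)
  expect_equal(extend_interval(iv(100, 200, "+"), 50, "5p")$start, 50)
  expect_equal(extend_interval(iv(100, 200, "-"), 50, "5p")$end, 250)
  # clamping at the sequence edges
  expect_equal(extend_interval(iv(10, 60, "-"), 50, "3p")$start, 0)
  expect_equal(extend_interval(iv(100, 180, "+"), 50, "3p",
                               chrom_len = 200)$end, 200)
  # extending by a then b equals extending by a+b absent clamping
  set.seed(301)
  r <- random_intervals(30, max_pos = 10000)
  ab <- extend_interval(extend_interval(r, 20, "3p"), 30, "3p")
  once <- extend_interval(r, 50, "3p")
  expect_equal(ab, once)
  expect_equal(extend_interval(r, 0, "3p"), r)
})

test_that("stranded intersection has bedtools -s -wa -wb semantics", {
  a <- data.frame(seq_id = "chr1", start = 100L, end = 200L, strand = "+",
                  stringsAsFactors = FALSE)
  b <- data.frame(seq_id = "chr1", start = 150L, end = 300L, strand = "+",
                  repeat_name = "X", repeat_class_family = "LTR/x",
                  stringsAsFactors = FALSE)
  expect_equal(nrow(stranded_intersect(a, b)), 1)
  b_minus <- transform(b, strand = "-")
  expect_equal(nrow(stranded_intersect(a, b_minus)), 0)
  expect_equal(nrow(stranded_intersect(a, b_minus, stranded = FALSE)), 1)
  # bookended intervals (zero overlap) do not pair
  b_touch <- transform(b, start = 200L)
  expect_equal(nrow(stranded_intersect(a, b_touch)), 0)
})

test_that("stranded intersection equals the all-pairs oracle on random sets", {
  set.seed(303)
  for (rep in 1:5) {
    a <- random_intervals(200)
    b <- random_intervals(200)
    b$repeat_name <- sprintf("rep%03d", seq_len(nrow(b)))
    for (stranded in c(TRUE, FALSE)) {
      pairs <- stranded_intersect(a, b, stranded = stranded)
      orc <- oracle_intersect(a, b, stranded = stranded)
      expect_equal(nrow(pairs), nrow(orc))
      got <- paste(pairs$a_start, pairs$a_end, pairs$b_start, pairs$b_end)
      want <- paste(a$start[orc[, 1]], a$end[orc[, 1]],
                    b$start[orc[, 2]], b$end[orc[, 2]])
      expect_setequal(got, want)
    }
  }
})

test_that("overlap summaries degrade sensibly without annotations or extension", {
  hits <- random_intervals(10)
  empty_ann <- data.frame(seq_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          repeat_name = character(),
                          stringsAsFactors = FALSE)
  ov <- overlap_summary(hits, empty_ann)
  expect_equal(ov$n_overlapping, c(0L, 0L, 0L))
  expect_equal(ov$n_total, rep(10L, 3))
  # zero extension collapses the three variants
  set.seed(305)
  ann <- random_intervals(30)
  ann$repeat_name <- "r"
  ov0 <- overlap_summary(hits, ann, amount = 0)
  expect_equal(length(unique(ov0$n_overlapping)), 1L)
})

test_that("repeat tallies count annotation records, descending, conserving totals", {
  pairs <- data.frame(b_repeat_name = c("X", "Y", "X"))
  tab <- tally_by_repeat(pairs)
  expect_equal(tab$repeat_name, c("X", "Y"))
  expect_equal(tab$count, c(2L, 1L))
  expect_equal(sum(tab$count), nrow(pairs))
  expect_equal(nrow(tally_by_repeat(pairs[0, , drop = FALSE])), 0)
})

test_that("LTR fractions use prefix matching over a complete denominator", {
  fam <- data.frame(repeat_class = c(rep("LTR", 300), rep("LTR-int", 64),
                                     rep("SINE", 10), rep("other", 4)))
  expect_equal(round(ltr_fraction(fam), 1), 96.3)   # 364 of 378
  expect_equal(ltr_fraction(data.frame(repeat_class = rep("DNA", 5))), 0)
  expect_equal(ltr_fraction(data.frame(repeat_class = rep("LTR-int", 5))),
               100)
})

test_that("relative codon frequencies normalise within synonymous families", {
  # Leu codons CTG, CTG, TTA plus one Met
  cds <- paste0("ATG", "CTG", "CTG", "TTA")
  rf <- relative_codon_frequencies(cds)
  expect_equal(rf$rel_freq[rf$codon == "CTG"], 2 / 3)
  expect_equal(rf$rel_freq[rf$codon == "TTA"], 1 / 3)
  expect_equal(rf$rel_freq[rf$codon == "ATG"], 1)
  expect_equal(nrow(rf), 64)
  # unused families are all-zero
  expect_true(all(rf$rel_freq[rf$amino_acid == "P"] == 0))
  # permuting codon order changes nothing
  rf2 <- relative_codon_frequencies(paste0("CTG", "TTA", "ATG", "CTG"))
  expect_equal(rf2, rf)
  expect_error(relative_codon_frequencies("ACGTA"), "multiple of 3")
  expect_error(relative_codon_frequencies(paste0("ATG", "TAA", "CTG")),
               "internal stop")
  # a single terminal stop is allowed
  expect_silent(relative_codon_frequencies(paste0("ATG", "CTG", "TAA")))
})
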
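# Synthetic-data generators: consensus libraries in which a subset of
# (predominantly LTR-class) families carry a 3'-biased tripartite element
# (5' C-rich motif, 17-nt core, 3' C-rich motif), genomes with diverged
# inserted copies and matching RepeatMasker-style annotation truth, and
# decoy sets. Every generator is a pure function of its parameters and
# seed, and ships a machine-readable truth table.

#' Specification of a synthetic SPRE-like element
#'
#' The C-rich flanking motifs are declared synthetic stand-ins (the true
#' flanking consensus is not a tabulated quantity); only the 17-nt core
#' default is the real motif. Mutation parameters apply per planted copy:
#' `per_base_mutation_rate` to the flanking motifs and spacers,
#' `core_mutation_rate` to the core (0 keeps every planted core intact, so
#' exact-match recall on clean cores is 1 by construction), `indel_rate`
#' per flank position with geometric insertion lengths.
#'
#' @param core core motif (A,C,G,T).
#' @param five_prime_motif,three_prime_motif C-rich flanking motifs.
#' @param spacer_len_5,spacer_len_3 integer ranges `c(min, max)` for the
#'   spacers between motifs and core.
#' @param per_base_mutation_rate substitution rate in flanks, in `[0, 1)`.
#' @param core_mutation_rate substitution rate in the core, in `[0, 1)`.
#' @param indel_rate per-position indel rate in flanks, in `[0, 1)`.
#' @return object of class `"element_spec"`.
#' @export
element_spec <- function(core = SPRE_CORE_MOTIF,
                         five_prime_motif = "CCTCCCC",
                         three_prime_motif = "CCCACCC",
                         spacer_len_5 = c(3L, 8L), spacer_len_3 = c(3L, 8L),
                         per_base_mutation_rate = 0.1,
                         core_mutation_rate = 0,
                         indel_rate = 0) {
  rates <- c(per_base_mutation_rate, core_mutation_rate, indel_rate)
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  if (grepl("[^ACGT]", core)) stop("core must be over A,C,G,T")
  structure(list(core = core, five_prime_motif = five_prime_motif,
                 three_prime_motif = three_prime_motif,
                 spacer_len_5 = spacer_len_5, spacer_len_3 = spacer_len_3,
                 per_base_mutation_rate = per_base_mutation_rate,
                 core_mutation_rate = core_mutation_rate,
                 indel_rate = indel_rate),
            class = "element_spec")
}

# substitute each base independently with one of the other three
.mutate_seq <- function(s, rate) {
  if (rate <= 0 || !nchar(s)) return(list(seq = s, n = 0L))
  chars <- strsplit(s, "")[[1]]
  hit <- runif(length(chars)) < rate
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1)
  }
  list(seq = paste(chars, collapse = ""), n = sum(hit))
}

# geometric-length indels: each position may delete itself or gain an
# insertion after it
.apply_indels <- function(s, rate) {
  if (rate <= 0 || !nchar(s)) return(s)
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  for (ch in chars) {
    if (runif(1) < rate) {
      if (runif(1) < 0.5) next  # deletion
      ins <- paste(sample(DNA_BASES, rgeom(1, 0.5) + 1L, replace = TRUE),
                   collapse = "")
      out <- c(out, ch, ins)
    } else {
      out <- c(out, ch)
    }
  }
  paste(out, collapse = "")
}

# one mutated element instance; returns sequence and core mutation count
.build_element <- function(spec) {
  sp5 <- paste(sample(DNA_BASES, sample(spec$spacer_len_5[1]:
                                          spec$spacer_len_5[2], 1),
                      replace = TRUE), collapse = "")
  sp3 <- paste(sample(DNA_BASES, sample(spec$spacer_len_3[1]:
                                          spec$spacer_len_3[2], 1),
                      replace = TRUE), collapse = "")
  flank5 <- .apply_indels(
    .mutate_seq(paste0(spec$five_prime_motif, sp5),
                spec$per_base_mutation_rate)$seq, spec$indel_rate)
  flank3 <- .apply_indels(
    .mutate_seq(paste0(sp3, spec$three_prime_motif),
                spec$per_base_mutation_rate)$seq, spec$indel_rate)
  core <- .mutate_seq(spec$core, spec$core_mutation_rate)
  list(seq = paste0(flank5, core$seq, flank3),
       n_core_mutations = core$n)
}

#' Generate a synthetic repeat-family consensus library with planted elements
#'
#' `round(n_families * frac_with_element)` families carry one element copy
#' each. The element midpoint's relative position along the consensus is
#' drawn from `Beta(position_beta[1], position_beta[2])` (default
#' Beta(5, 1.5), mean about 0.77 — a 3'-terminal bias), minimally shifted
#' when the element would not fit. Elements are planted on the minus strand
#' with probability `1 - plus_strand_prob` (reverse-complemented in place,
#' with the drawn position measured along the element's own 5'->3'
#' reading). Carrier families are predominantly LTR-class. Deterministic
#' given `seed`.
#'
#' @param n_families library size.
#' @param frac_with_element fraction of families carrying the element.
#' @param frac_ltr LTR-class fraction among non-carrier families.
#' @param length_range consensus length range `c(min, max)` in nt.
#' @param position_beta Beta shape parameters for the 3' position bias.
#' @param spec an [element_spec()].
#' @param seed RNG seed.
#' @param plus_strand_prob probability a planted element is on the plus
#'   strand of its consensus.
#' @return list with `families` (repeat-family data.frame), `truth`
#'   (data.frame `seq_id`, `start`, `end`, `strand`, `element_variant`,
#'   `n_core_mutations`, `position_drawn`), and the generating parameters.
#' @export
make_library <- function(n_families = 50, frac_with_element = 0.2,
                         frac_ltr = 0.6, length_range = c(1500L, 3000L),
                         position_beta = c(5, 1.5), spec = element_spec(),
                         seed = 42, plus_strand_prob = 0.7) {
  if (frac_with_element < 0 || frac_with_element > 1 ||
      frac_ltr < 0 || frac_ltr > 1)
    stop("fractions must lie in [0, 1]")
  with_seed(seed, {
    ids <- sprintf("FAM%04d", seq_len(n_families))
    lens <- sample(length_range[1]:length_range[2], n_families,
                   replace = TRUE)
    n_carry <- round(n_families * frac_with_element)
    carriers <- sort(sample(n_families, n_carry))
    is_carrier <- seq_len(n_families) %in% carriers
    cls <- character(n_families)
    cls[is_carrier] <- ifelse(
      runif(n_carry) < 0.95,
      sample(c("LTR", "LTR-int"), n_carry, replace = TRUE,
             prob = c(0.7, 0.3)),
      "other")
    n_other <- n_families - n_carry
    cls[!is_carrier] <- ifelse(
      runif(n_other) < frac_ltr, "LTR",
      sample(c("SINE", "LINE", "DNA", "other"), n_other, replace = TRUE))
    seqs <- random_dna(n_families, lens)
    truth <- list()
    for (i in carriers) {
      el <- .build_element(spec)
      elen <- nchar(el$seq)
      if (elen > lens[i]) stop("element longer than consensus")
      x <- rbeta(1, position_beta[1], position_beta[2])
      strand <- if (runif(1) < plus_strand_prob) "+" else "-"
      mid_frac <- if (strand == "+") x else 1 - x
      start <- round(mid_frac * lens[i] - elen / 2)
      start <- max(0L, min(start, lens[i] - elen))  # minimal shift to fit
      insert <- if (strand == "+") el$seq else revcomp(el$seq)
      seqs[i] <- paste0(substr(seqs[i], 1, start), insert,
                        substr(seqs[i], start + elen + 1, lens[i]))
      truth[[length(truth) + 1L]] <- data.frame(
        seq_id = ids[i], start = start, end = start + elen,
        strand = strand, element_variant = "full",
        n_core_mutations = el$n_core_mutations, position_drawn = x,
        stringsAsFactors = FALSE)
    }
    families <- data.frame(family_id = ids, name = ids, repeat_class = cls,
                           consensus = seqs, length = lens,
                           stringsAsFactors = FALSE)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(seq_id = character(), start = integer(), end = integer(),
                 strand = character(), element_variant = character(),
                 n_core_mutations = integer(), position_drawn = numeric(),
                 stringsAsFactors = FALSE)
    list(families = families, truth = truth, spec = spec,
         params = list(n_families = n_families,
                       frac_with_element = frac_with_element,
                       frac_ltr = frac_ltr, length_range = length_range,
                       position_beta = position_beta, seed = seed,
                       plus_strand_prob = plus_strand_prob))
  })
}

# sample non-overlapping insertion starts for pieces of given lengths
.place_nonoverlapping <- function(lens, genome_len, min_gap = 10L) {
  if (sum(lens) + min_gap * length(lens) > genome_len)
    stop("total insert length exceeds genome length")
  placed <- matrix(numeric(0), ncol = 2)
  starts <- integer(length(lens))
  for (i in seq_along(lens)) {
    ok <- FALSE
    for (try in 1:2000) {
      s <- sample.int(genome_len - lens[i] + 1L, 1) - 1L
      if (!nrow(placed) ||
          all(s + lens[i] + min_gap <= placed[, 1] |
              s >= placed[, 2] + min_gap)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place inserts without overlap; genome too full")
    placed <- rbind(placed, c(s, s + lens[i]))
    starts[i] <- s
  }
  starts
}

#' Generate a synthetic genome with planted copies and annotation truth
#'
#' Two layouts. `"copies"` inserts diverged copies of library families at
#' random non-overlapping loci on both strands, writing one annotation
#' record per inserted copy (the RepeatMasker-style truth) and one element
#' truth record per copy of a carrier family, with coordinates and strand
#' composed through the insertion. `"element_upstream_ltr"` plants bare
#' elements, each followed in its own 3' direction by an "LTR" annotation
#' record separated by `gap` nt — the construction in which raw hits
#' overlap nothing but 3'-extended hits overlap everything.
#'
#' @param library a [make_library()] result (or a compatible list with
#'   `families`, `truth`, `spec`).
#' @param layout `"copies"` or `"element_upstream_ltr"`.
#' @param n_copies_per_family copies inserted per selected family
#'   (`"copies"` layout).
#' @param family_ids families to insert; default the element carriers.
#' @param genome_len genome length in nt.
#' @param divergence per-base substitution rate applied to each inserted
#'   copy.
#' @param n_elements number of bare elements (`"element_upstream_ltr"`).
#' @param gap nt between element end and LTR annotation start
#'   (`"element_upstream_ltr"`).
#' @param ltr_len length of the synthetic LTR annotation span.
#' @param chrom_id name of the generated sequence.
#' @param seed RNG seed.
#' @return list with `genome` (named character vector), `truth`
#'   (element intervals, 0-based half-open, genome frame), `annotations`
#'   (RepeatMasker-style data.frame), and `params`.
#' @export
make_genome <- function(library, layout = c("copies",
                                            "element_upstream_ltr"),
                        n_copies_per_family = 1L, family_ids = NULL,
                        genome_len = 1000000L, divergence = 0,
                        n_elements = 20L, gap = 30L, ltr_len = 400L,
                        chrom_id = "chr1", seed = 43) {
  layout <- match.arg(layout)
  fam <- library$families
  with_seed(seed, {
    genome <- random_dna(1, genome_len)
    truth <- list(); anns <- list()
    if (layout == "copies") {
      if (is.null(family_ids)) family_ids <- unique(library$truth$seq_id)
      pick <- rep(family_ids, each = n_copies_per_family)
      lens <- fam$length[match(pick, fam$family_id)]
      starts <- .place_nonoverlapping(lens, genome_len)
      for (j in seq_along(pick)) {
        fid <- pick[j]
        frow <- fam[fam$family_id == fid, ]
        copy <- .mutate_seq(frow$consensus, divergence)$seq
        cstrand <- sample(c("+", "-"), 1)
        ins <- if (cstrand == "+") copy else revcomp(copy)
        g0 <- starts[j]
        genome <- paste0(substr(genome, 1, g0), ins,
                         substr(genome, g0 + nchar(ins) + 1, genome_len))
        anns[[length(anns) + 1L]] <- data.frame(
          seq_id = chrom_id, start = g0, end = g0 + nchar(ins),
          strand = cstrand, repeat_name = frow$name,
          repeat_class_family = frow$repeat_class, stringsAsFactors = FALSE)
        tr <- library$truth[library$truth$seq_id == fid, , drop = FALSE]
        for (k in seq_len(nrow(tr))) {
          Lf <- frow$length
          if (cstrand == "+") {
            es <- g0 + tr$start[k]; ee <- g0 + tr$end[k]
            estrand <- tr$strand[k]
          } else {
            es <- g0 + (Lf - tr$end[k]); ee <- g0 + (Lf - tr$start[k])
            estrand <- if (tr$strand[k] == "+") "-" else "+"
          }
          truth[[length(truth) + 1L]] <- data.frame(
            seq_id = chrom_id, start = es, end = ee, strand = estrand,
            element_variant = tr$element_variant[k],
            n_core_mutations = tr$n_core_mutations[k],
            source_family = fid, stringsAsFactors = FALSE)
        }
      }
    } else {
      # overlap-geometry construction: plant element instances with their
      # family window context (the hits a profile search reports are such
      # windows), each followed in its own 3' direction by an LTR
      # annotation record at `gap` nt
      carriers <- library$truth
      if (!nrow(carriers))
        stop("element_upstream_ltr layout needs a library with carriers")
      wflank <- 40L
      pick <- rep_len(seq_len(nrow(carriers)), n_elements)
      wins <- character(n_elements); wstrand <- character(n_elements)
      core_mut <- integer(n_elements); src <- character(n_elements)
      for (j in seq_len(n_elements)) {
        tr <- carriers[pick[j], ]
        frow <- fam[fam$family_id == tr$seq_id, ]
        # context on the element's own 5' side only, so its 3' terminus is
        # flush with the insert edge the gap is measured from
        if (tr$strand == "+") {
          ws <- max(0L, tr$start - wflank); we <- tr$end
        } else {
          ws <- tr$start; we <- min(frow$length, tr$end + wflank)
        }
        wins[j] <- substr(frow$consensus, ws + 1L, we)
        wstrand[j] <- tr$strand
        core_mut[j] <- tr$n_core_mutations
        src[j] <- tr$seq_id
      }
      wlens <- nchar(wins)
      block <- wlens + gap + ltr_len
      starts <- .place_nonoverlapping(block, genome_len, min_gap = 150L)
      for (j in seq_len(n_elements)) {
        g <- sample(c("+", "-"), 1)              # insertion orientation
        ins <- if (g == "+") wins[j] else revcomp(wins[j])
        estrand <- if (wstrand[j] == g) "+" else "-"
        b0 <- starts[j]
        if (estrand == "+") {
          es <- b0; ee <- b0 + wlens[j]
          as_ <- ee + gap; ae <- as_ + ltr_len
        } else {
          as_ <- b0; ae <- b0 + ltr_len
          es <- ae + gap; ee <- es + wlens[j]
        }
        genome <- paste0(substr(genome, 1, es), ins,
                         substr(genome, es + wlens[j] + 1, genome_len))
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = chrom_id, start = es, end = ee, strand = estrand,
          element_variant = "windowed", n_core_mutations = core_mut[j],
          source_family = src[j], stringsAsFactors = FALSE)
        anns[[length(anns) + 1L]] <- data.frame(
          seq_id = chrom_id, start = as_, end = ae, strand = estrand,
          repeat_name = sprintf("SYNLTR%02d", j),
          repeat_class_family = "LTR/ERV-syn", stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    anns <- do.call(rbind, anns)
    list(genome = setNames(genome, chrom_id), truth = truth,
         annotations = anns,
         params = list(layout = layout, genome_len = genome_len,
                       divergence = divergence, gap = gap,
                       ltr_len = ltr_len, seed = seed))
  })
}

#' Generate decoy target sequences
#'
#' Background sequences plus hard negatives: core-only decoys (the exact
#' core motif planted in random background with no C-rich flanks) and
#' shuffled-core decoys. Types cycle over `c("background", "core_only",
#' "shuffled_core")` unless restricted.
#'
#' @param n number of decoys.
#' @param len decoy length in nt.
#' @param spec an [element_spec()] (supplies the core motif).
#' @param types decoy types to cycle over.
#' @param seed RNG seed.
#' @return list with `seqs` (named character vector) and `types`
#'   (data.frame `seq_id`, `type`).
#' @export
make_decoys <- function(n, len = 500L, spec = element_spec(),
                        types = c("background", "core_only",
                                  "shuffled_core"), seed = 44) {
  if (n == 0) {
    return(list(seqs = setNames(character(0), character(0)),
                types = data.frame(seq_id = character(),
                                   type = character(),
                                   stringsAsFactors = FALSE)))
  }
  with_seed(seed, {
    type <- rep_len(types, n)
    seqs <- random_dna(n, len)
    for (i in seq_len(n)) {
      if (type[i] == "background") next
      core <- if (type[i] == "core_only") spec$core else
        paste(sample(strsplit(spec$core, "")[[1]]), collapse = "")
      pos <- sample.int(len - nchar(core) + 1L, 1)
      seqs[i] <- paste0(substr(seqs[i], 1, pos - 1L), core,
                        substr(seqs[i], pos + nchar(core), len))
    }
    ids <- sprintf("DEC%04d", seq_len(n))
    list(seqs = setNames(seqs, ids),
         types = data.frame(seq_id = ids, type = type,
                            stringsAsFactors = FALSE))
  })
}

#' Evaluate recovered hits against planted truth
#'
#' A hit is a true positive when it overlaps a planted element interval by
#' at least 1 nt on the same sequence and strand; a truth record is
#' recovered when at least one hit overlaps it. Recall is the fraction of
#' truth records recovered, FDR the fraction of hits that are not true
#' positives.
#'
#' @param hits hit data.frame (`target_id`, `S`, `E` 1-based inclusive,
#'   `strand`).
#' @param truth truth data.frame (`seq_id`, `start`, `end` 0-based
#'   half-open, `strand`).
#' @return list with `recall`, `fdr`, `n_hits`, `n_truth`, `tp`, `fp`,
#'   `recovered` (logical per truth row).
#' @export
evaluate_hits <- function(hits, truth) {
  if (!nrow(truth)) {
    return(list(recall = NaN, fdr = if (nrow(hits)) 1 else NaN,
                n_hits = nrow(hits), n_truth = 0L,
                tp = 0L, fp = nrow(hits), recovered = logical(0)))
  }
  hit_iv <- if (nrow(hits)) hits_to_intervals(hits) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               name = character(), score = numeric(), strand = character())
  hit_iv$hit_id <- seq_len(nrow(hit_iv))
  truth$truth_id <- seq_len(nrow(truth))
  pairs <- stranded_intersect(hit_iv, truth, stranded = TRUE)
  recovered <- truth$truth_id %in% pairs$b_truth_id
  tp_hits <- unique(pairs$a_hit_id)
  list(recall = mean(recovered),
       fdr = if (nrow(hits)) 1 - length(tp_hits) / nrow(hits) else NaN,
       n_hits = nrow(hits), n_truth = nrow(truth),
       tp = length(tp_hits), fp = nrow(hits) - length(tp_hits),
       recovered = recovered)
}
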
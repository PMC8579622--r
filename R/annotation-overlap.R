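# Downstream analytics: position-bias scores along family consensuses,
# strand-aware directional interval extension, stranded intersection with
# repeat annotations (bedtools "-s -wa -wb" semantics), per-family tallies,
# LTR-class fractions, and relative synonymous codon frequencies.

#' Relative position score of a hit along its family consensus
#'
#' `[(S + E)/2] / L`: the hit midpoint as a fraction of the consensus
#' length, with `S`, `E` 1-based inclusive. Values near 1 indicate
#' 3'-terminal placement. With `strand_reflect = TRUE` (default)
#' minus-strand hits are reflected to `1 - score`, measuring position along
#' the element's own 5'->3' reading; `strand_reflect = FALSE` gives the
#' unreflected value.
#'
#' @param S,E 1-based inclusive hit coordinates (`1 <= S <= E <= L`).
#' @param L family consensus length.
#' @param strand `"+"` or `"-"` (recycled).
#' @param strand_reflect reflect minus-strand scores.
#' @return numeric score(s) in `[0, 1]`.
#' @export
relative_position_score <- function(S, E, L, strand = "+",
                                    strand_reflect = TRUE) {
  if (any(S < 1 | S > E | E > L))
    stop("require 1 <= S <= E <= L")
  score <- ((S + E) / 2) / L
  if (strand_reflect) {
    minus <- rep_len(strand == "-", length(score))
    score[minus] <- 1 - score[minus]
  }
  score
}

#' Extend intervals directionally, strand-aware
#'
#' Extends each interval by `amount` nt in its own 5' or 3' direction: on
#' the plus strand 3' grows the end and 5' grows upstream of the start; on
#' the minus strand the roles are swapped. Coordinates are clamped to
#' `[0, chrom_len]`. Extending by `a` then `b` equals extending by `a + b`
#' absent clamping.
#'
#' @param intervals data.frame with `seq_id`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param amount extension in nt (>= 0).
#' @param direction `"3p"` or `"5p"`.
#' @param chrom_len scalar, or named vector by `seq_id`, giving sequence
#'   lengths for clamping; `Inf` disables the upper clamp.
#' @return the data.frame with adjusted `start`/`end`.
#' @export
extend_interval <- function(intervals, amount = 50L,
                            direction = c("3p", "5p"), chrom_len = Inf) {
  direction <- match.arg(direction)
  if (amount < 0) stop("amount must be >= 0")
  if (!nrow(intervals)) return(intervals)
  len <- if (length(chrom_len) > 1L || !is.null(names(chrom_len))) {
    unname(chrom_len[intervals$seq_id])
  } else rep_len(chrom_len, nrow(intervals))
  plus <- intervals$strand != "-"
  grow_end <- (plus & direction == "3p") | (!plus & direction == "5p")
  intervals$end[grow_end] <- intervals$end[grow_end] + amount
  intervals$start[!grow_end] <- intervals$start[!grow_end] - amount
  intervals$start <- pmax(intervals$start, 0L)
  intervals$end <- pmin(intervals$end, len)
  intervals
}

.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$seq_id,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (!is.null(df$strand)) df$strand else "*")
}

#' Stranded interval intersection (wa/wb semantics)
#'
#' Emits every pair of intervals from `a` and `b` overlapping by at least
#' 1 nt on the same sequence (and the same strand when `stranded = TRUE`),
#' reporting both records of each pair — the semantics of
#' `bedtools intersect -s -wa -wb`.
#'
#' @param a data.frame of query intervals (`seq_id`, `start`, `end`,
#'   `strand`, plus any payload columns).
#' @param b data.frame of subject intervals/annotations.
#' @param stranded require matching strands.
#' @return data.frame with the `a` columns (prefix `a_`) and `b` columns
#'   (prefix `b_`) of every overlapping pair.
#' @export
stranded_intersect <- function(a, b, stranded = TRUE) {
  empty <- cbind(setNames(a[0, , drop = FALSE], paste0("a_", names(a))),
                 setNames(b[0, , drop = FALSE], paste0("b_", names(b))))
  if (!nrow(a) || !nrow(b)) return(empty)
  ga <- .as_granges(a)
  gb <- .as_granges(b)
  ov <- GenomicRanges::findOverlaps(ga, gb, minoverlap = 1L,
                                    ignore.strand = !stranded)
  if (!length(ov)) return(empty)
  qa <- a[S4Vectors::queryHits(ov), , drop = FALSE]
  qb <- b[S4Vectors::subjectHits(ov), , drop = FALSE]
  names(qa) <- paste0("a_", names(qa))
  names(qb) <- paste0("b_", names(qb))
  out <- cbind(qa, qb)
  rownames(out) <- NULL
  out
}

#' Overlap summary for raw and directionally extended hits
#'
#' For each variant — the hit intervals as-is, extended 50 nt (default) in
#' the 5' direction, and extended in the 3' direction — counts how many
#' hits overlap at least one annotation record (stranded).
#'
#' @param hits data.frame of hit intervals (0-based half-open with strand).
#' @param annotations data.frame of repeat annotations.
#' @param amount extension in nt.
#' @param stranded require matching strands.
#' @param chrom_len clamp bound passed to [extend_interval()].
#' @return data.frame with columns `variant` (`SPRE`, `SPRE+5`, `SPRE+3`),
#'   `n_overlapping`, `n_total`.
#' @export
overlap_summary <- function(hits, annotations, amount = 50L,
                            stranded = TRUE, chrom_len = Inf) {
  variants <- list(
    "SPRE" = hits,
    "SPRE+5" = extend_interval(hits, amount, "5p", chrom_len),
    "SPRE+3" = extend_interval(hits, amount, "3p", chrom_len))
  rows <- lapply(names(variants), function(v) {
    iv <- variants[[v]]
    iv$..hit_id <- seq_len(nrow(iv))
    pairs <- stranded_intersect(iv, annotations, stranded = stranded)
    data.frame(variant = v,
               n_overlapping = length(unique(pairs$a_..hit_id)),
               n_total = nrow(hits), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tally overlapping annotation records by repeat name
#'
#' Counts annotation records per repeat name among intersection pairs
#' (i.e. the number of annotation tracks overlapping the extended hits),
#' descending.
#'
#' @param pairs data.frame from [stranded_intersect()] with a
#'   `b_repeat_name` column.
#' @return data.frame with `repeat_name` and `count`, descending.
#' @export
tally_by_repeat <- function(pairs) {
  if (!nrow(pairs)) {
    return(data.frame(repeat_name = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- sort(table(pairs$b_repeat_name), decreasing = TRUE)
  data.frame(repeat_name = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Percentage of families with an LTR-type class
#'
#' A family counts as LTR-type when its `repeat_class` starts with "LTR"
#' (covering both solo LTRs and internal regions labelled e.g. "LTR-int").
#'
#' @param families repeat-family data.frame with a `repeat_class` column.
#' @return percentage in `[0, 100]`.
#' @export
ltr_fraction <- function(families) {
  if (!nrow(families)) return(NaN)
  100 * mean(startsWith(families$repeat_class, "LTR"))
}

#' Relative synonymous codon frequencies of a coding sequence
#'
#' For each amino acid, the frequencies of its synonymous codons are
#' normalised to sum to 1 within the family; codon families unused in the
#' sequence get all-zero frequencies. The standard genetic code is used,
#' with stop codons grouped as their own family.
#'
#' @param cds DNA string; length must be a multiple of 3 and internal stop
#'   codons are rejected (a single terminal stop is allowed).
#' @return data.frame with one row per codon (64 rows): `codon`,
#'   `amino_acid`, `count`, `rel_freq`.
#' @export
relative_codon_frequencies <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0 || n %% 3 != 0)
    stop("coding sequence length must be a positive multiple of 3")
  if (grepl("[^ACGT]", cds))
    stop("coding sequence must be over the A,C,G,T alphabet")
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  if (any(aa[-length(aa)] == "*"))
    stop("internal stop codon in coding sequence")
  counts <- table(factor(codons, levels = names(code)))
  out <- data.frame(codon = names(code), amino_acid = unname(code),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  out$rel_freq <- stats::ave(out$count, out$amino_acid, FUN = function(x) {
    if (sum(x) == 0) rep(0, length(x)) else x / sum(x)
  })
  out[order(out$amino_acid, out$codon), ]
}
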
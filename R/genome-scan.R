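# Applying a frozen, selected-cycle model to long targets (genomes, viral
# sequence sets): chunked scanning with coordinate lifting, ownership-based
# deduplication across chunk overlaps, and per-target hit counts.

#' Scan long targets with a calibrated profile HMM
#'
#' Targets longer than `chunk` are scanned in overlapping chunks on both
#' strands and chunk-local coordinates are lifted to the global frame. Each
#' hit is kept only by the chunk that owns its start (the region excluding
#' the trailing overlap), so a match straddling a chunk boundary is
#' reported exactly once and never truncated; identical span+strand
#' duplicates are additionally removed. The effective trial count is
#' `total residues / model length` (genome mode). Hits with
#' `e_threshold <= E < near_threshold` can be recorded separately — they
#' are excluded from the main table but mirror the kind of sub-threshold
#' match worth inspecting by hand.
#'
#' @param hmm a calibrated `profile_hmm`.
#' @param targets named character vector of target sequences.
#' @param e_threshold E-value cutoff for reported hits.
#' @param chunk chunk length in nt (`> overlap`).
#' @param overlap chunk overlap in nt (`>= model length`).
#' @param near_threshold E-value bound for the optional near-miss log.
#' @param record_near keep near-threshold hits in
#'   `attr(result, "near_hits")`.
#' @return hit data.frame as in [scan_targets()]; attribute `near_hits`
#'   when requested.
#' @export
scan_genome <- function(hmm, targets, e_threshold = 1e-5, chunk = 100000L,
                        overlap = 500L, near_threshold = 0.01,
                        record_near = FALSE) {
  if (!is_calibrated(hmm))
    stop("model is not calibrated; run calibrate() first")
  stopifnot(!is.null(names(targets)))
  if (overlap < hmm$M)
    stop("overlap (", overlap, ") must be at least the model length (",
         hmm$M, "): hits could be split across chunks")
  if (chunk <= overlap) stop("chunk must exceed overlap")
  n_eff <- max(sum(nchar(targets)) / hmm$M, 1)
  hmm$n_eff <- n_eff
  report_cut <- if (record_near) max(e_threshold, near_threshold) else
    e_threshold
  min_bits <- .min_bits_for(hmm$mu, hmm$lambda, n_eff, report_cut)
  step <- chunk - overlap
  all_hits <- list()
  for (tid in names(targets)) {
    s <- targets[[tid]]
    L <- nchar(s)
    starts <- seq.int(1L, max(L - overlap, 1L), by = step)
    for (cs in starts) {
      ce <- min(cs + chunk - 1L, L)
      h <- viterbi_local(hmm, substr(s, cs, ce), min_bits = min_bits,
                         both_strands = TRUE, target_id = tid)
      if (!nrow(h)) next
      h$S <- h$S + cs - 1L
      h$E <- h$E + cs - 1L
      last_chunk <- (ce >= L)
      own_end <- cs + step - 1L
      h <- h[last_chunk | h$S <= own_end, , drop = FALSE]
      h$e_value <- e_value(h$bit_score, hmm$mu, hmm$lambda, n_eff)
      all_hits[[length(all_hits) + 1L]] <-
        h[h$e_value < report_cut, , drop = FALSE]
    }
  }
  hits <- do.call(rbind, c(all_hits, list(.empty_hits())))
  hits <- hits[!duplicated(hits[, c("target_id", "S", "E", "strand")]), ,
               drop = FALSE]
  near <- hits[hits$e_value >= e_threshold, , drop = FALSE]
  hits <- hits[hits$e_value < e_threshold, , drop = FALSE]
  hits <- hits[order(hits$e_value, hits$target_id, hits$S), , drop = FALSE]
  rownames(hits) <- NULL
  if (record_near) attr(hits, "near_hits") <- near
  hits
}

#' Hit counts per target, zero-filled
#'
#' @param hits a hit data.frame.
#' @param target_ids all target ids (targets without hits get count 0);
#'   defaults to the ids present in `hits`.
#' @return data.frame with `target_id` and `n_hits`, in `target_ids` order.
#' @export
per_target_counts <- function(hits, target_ids = NULL) {
  if (is.null(target_ids)) target_ids <- sort(unique(hits$target_id))
  counts <- table(factor(hits$target_id, levels = target_ids))
  data.frame(target_id = target_ids, n_hits = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Hit table as 0-based half-open intervals
#'
#' Converts the 1-based inclusive `S`/`E` hit coordinates to the internal
#' interval convention (for BED export and overlap analysis).
#'
#' @param hits a hit data.frame.
#' @return data.frame with `seq_id`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
hits_to_intervals <- function(hits) {
  data.frame(seq_id = hits$target_id,
             start = hits$S - 1L, end = hits$E,
             name = sprintf("hit%04d", seq_len(nrow(hits))),
             score = 0L,
             strand = hits$strand, stringsAsFactors = FALSE)
}
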
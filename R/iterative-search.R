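# Step 2: iterative profile refinement. Each cycle scans the library with
# the current model, keeps significant hits, realigns them in model-column
# coordinates and rebuilds the model; the cycle with the most hits is
# selected (earliest cycle on ties, mirroring a hit-count trajectory that
# rises to a peak and then drifts).

#' Run a single search cycle over a consensus library
#'
#' @param hmm a calibrated `profile_hmm`.
#' @param library repeat-family data.frame (or named character vector of
#'   consensus sequences).
#' @param e_threshold E-value cutoff.
#' @return a cycle record: list with `n_hits`, `n_families`, `model`,
#'   `hits`.
#' @export
run_cycle <- function(hmm, library, e_threshold = 1e-5) {
  if (!is_calibrated(hmm))
    stop("model is not calibrated; run calibrate() first")
  fam <- .as_family_df(library)
  seqs <- setNames(fam$consensus, fam$family_id)
  hits <- scan_targets(hmm, seqs, e_threshold = e_threshold,
                       n_eff = max(2 * length(seqs), 1),
                       merge_overlaps = TRUE)
  list(n_hits = nrow(hits),
       n_families = length(unique(hits$target_id)),
       model = hmm, hits = hits)
}

#' Iterative profile-HMM search over a consensus library
#'
#' Cycle 1 builds a model from `seed_alignment` (typically the anchored
#' step-1 windows); every later cycle is built from the previous cycle's
#' realigned hits. Each cycle's model is recalibrated with the same seed
#' (model length and entropy change between cycles). Iteration stops early
#' when a cycle yields no hits or exactly the hit set of the previous cycle
#' (a fixed point; under the earliest-cycle tie rule this cannot change the
#' selected cycle), or after `max_cycles`.
#'
#' @param seed_alignment named character vector of equal-width rows.
#' @param library repeat-family data.frame or named character vector.
#' @param max_cycles maximum number of search cycles.
#' @param e_threshold E-value cutoff per cycle.
#' @param seed RNG seed for calibration.
#' @param early_stop stop on zero hits or a repeated hit set; `FALSE`
#'   reproduces a fixed `max_cycles` run.
#' @param gap_threshold,pseudocount passed to [profile_hmm()].
#' @param calib_n,calib_len calibration sample count and length.
#' @param bg background composition; default estimated from the library
#'   (floored at 0.05 per base).
#' @return object of class `"iterative_search"`: list with `cycles` (one
#'   record per executed cycle), `selected_cycle`, and `params`.
#' @export
iterate_search <- function(seed_alignment, library, max_cycles = 10,
                           e_threshold = 1e-5, seed = 42, early_stop = TRUE,
                           gap_threshold = 0.5, pseudocount = 1.0,
                           calib_n = 1000, calib_len = 200, bg = NULL) {
  if (!length(seed_alignment)) stop("empty seed alignment")
  fam <- .as_family_df(library)
  if (is.null(bg)) bg <- estimate_background(fam$consensus)
  aln <- seed_alignment
  cycles <- list()
  prev_key <- NULL
  for (cy in seq_len(max_cycles)) {
    model <- profile_hmm(aln, gap_threshold = gap_threshold,
                         pseudocount = pseudocount, bg = bg)
    model <- calibrate(model, n_samples = calib_n, sample_len = calib_len,
                       seed = seed)
    rec <- run_cycle(model, fam, e_threshold = e_threshold)
    rec$cycle_index <- cy
    cycles[[cy]] <- rec
    if (rec$n_hits == 0) break
    key <- paste(rec$hits$target_id, rec$hits$S, rec$hits$E,
                 rec$hits$strand, collapse = ";")
    if (early_stop && identical(key, prev_key)) break
    prev_key <- key
    aln <- hits_to_alignment(rec$hits)
  }
  n_hits <- vapply(cycles, `[[`, integer(1), "n_hits")
  structure(list(cycles = cycles,
                 selected_cycle = which.max(n_hits),
                 params = list(max_cycles = max_cycles,
                               e_threshold = e_threshold, seed = seed,
                               early_stop = early_stop,
                               gap_threshold = gap_threshold,
                               pseudocount = pseudocount,
                               calib_n = calib_n, calib_len = calib_len,
                               bg = bg)),
            class = "iterative_search")
}

#' @export
print.iterative_search <- function(x, ...) {
  cat("Iterative profile-HMM search:", length(x$cycles), "cycle(s),",
      "selected cycle", x$selected_cycle, "\n")
  print(summary(x)$cycles)
  invisible(x)
}

#' @export
summary.iterative_search <- function(object, ...) {
  tab <- data.frame(
    cycle = vapply(object$cycles, `[[`, integer(1), "cycle_index"),
    n_hits = vapply(object$cycles, `[[`, integer(1), "n_hits"),
    n_families = vapply(object$cycles, `[[`, integer(1), "n_families"),
    model_M = vapply(object$cycles, function(r) r$model$M, integer(1)))
  tab$selected <- tab$cycle == object$selected_cycle
  out <- list(cycles = tab, selected_cycle = object$selected_cycle,
              e_threshold = object$params$e_threshold)
  class(out) <- "summary.iterative_search"
  out
}

#' @export
print.summary.iterative_search <- function(x, ...) {
  cat("Search trajectory (E <", format(x$e_threshold), "):\n")
  print(x$cycles, row.names = FALSE)
  invisible(x)
}

#' @export
plot.iterative_search <- function(x, ...) {
  tab <- summary(x)$cycles
  graphics::plot(tab$cycle, tab$n_hits, type = "b", xlab = "cycle",
                 ylab = "hits below E threshold", ...)
  graphics::abline(v = x$selected_cycle, lty = 2)
  invisible(x)
}

#' Selected-cycle record of an iterative search
#'
#' @param x an `iterative_search` object.
#' @return the cycle record of the selected (peak) cycle.
#' @export
selected_record <- function(x) {
  stopifnot(inherits(x, "iterative_search"))
  x$cycles[[x$selected_cycle]]
}

#' Relative position scores of a cycle's hits along their families
#'
#' One score per hit: the hit midpoint as a fraction of the family
#' consensus length, strand-aware (see [relative_position_score()]).
#'
#' @param record a cycle record (e.g. from [selected_record()]).
#' @param library the searched repeat-family data.frame.
#' @param strand_reflect reflect minus-strand scores as `1 - score`.
#' @return data.frame with `family_id`, `S`, `E`, `L`, `strand`, `score`.
#' @export
positions_report <- function(record, library, strand_reflect = TRUE) {
  fam <- .as_family_df(library)
  hits <- record$hits
  L <- fam$length[match(hits$target_id, fam$family_id)]
  data.frame(family_id = hits$target_id, S = hits$S, E = hits$E, L = L,
             strand = hits$strand,
             score = relative_position_score(hits$S, hits$E, L, hits$strand,
                                             strand_reflect = strand_reflect),
             stringsAsFactors = FALSE)
}

#' Per-model-column residue frequencies of a cycle's hit alignment
#'
#' The data behind a sequence logo: for each model column the A,C,G,T
#' frequencies among the realigned hits, normalised over non-gap counts
#' (columns with no residues give all-zero rows). Invariant to hit order.
#'
#' @param record a cycle record.
#' @return M x 4 matrix of frequencies, columns A,C,G,T.
#' @export
column_frequency_report <- function(record) {
  if (!record$n_hits) stop("cycle has no hits")
  rows <- record$hits$aligned_row
  mat <- do.call(rbind, strsplit(rows, ""))
  freq <- t(apply(mat, 2, function(col) {
    counts <- c(sum(col == "A"), sum(col == "C"),
                sum(col == "G"), sum(col == "T"))
    if (sum(counts) == 0) rep(0, 4) else counts / sum(counts)
  }))
  colnames(freq) <- DNA_BASES
  freq
}
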
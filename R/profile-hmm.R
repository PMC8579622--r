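# Profile HMM over DNA: model construction from an alignment, S3 methods,
# and plain-text serialization.
#
# Architecture: Plan-7-style local mode. Uniform local entry into any match
# state (probability 1/M), free exit from any match state, no flanking
# self-loop segment; multi-hit behaviour is obtained downstream by
# mask-and-rescan. Bit scores are log2 odds of the best local path against
# an i.i.d. background.

#' Fit a nucleotide profile HMM to a DNA alignment
#'
#' Columns whose gap fraction is below `gap_threshold` become match states;
#' residues falling in the remaining columns feed the insert-state
#' emissions of the preceding node. Emission probabilities are
#' `(counts + pseudocount * q) / (total + pseudocount)` with `q` the
#' background composition; transition probabilities are estimated from the
#' per-row match/insert/delete state paths with the same additive
#' pseudocount spread uniformly over each state's outgoing options.
#'
#' Leading and trailing gap runs in a row are treated as a local fragment
#' (missing data), not as deletions, which keeps anchor-padded seed windows
#' from inflating delete transitions. `N` counts as state occupancy but
#' contributes no emission count.
#'
#' @param alignment named character vector of equal-width rows over
#'   A,C,G,T,N,- (e.g. from [anchor_align()] or [hits_to_alignment()]).
#' @param gap_threshold columns with gap fraction strictly below this become
#'   match states.
#' @param pseudocount additive pseudocount weight for emissions and
#'   transitions.
#' @param bg background base composition (A,C,G,T); defaults to uniform.
#' @return an object of class `"profile_hmm"` with match/insert emission
#'   matrices, per-node transition matrix, background `q`, consensus string,
#'   and (after [calibrate()]) Gumbel parameters `mu`, `lambda`.
#' @seealso [calibrate()], [viterbi_local()], [predict.profile_hmm()]
#' @export
profile_hmm <- function(alignment, gap_threshold = 0.5, pseudocount = 1.0,
                        bg = NULL) {
  rows <- toupper(as.character(alignment))
  if (!length(rows)) stop("empty alignment")
  rows <- gsub("\\.", "-", rows)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows must all have the same width")
  q <- if (is.null(bg)) rep(0.25, 4) else bg / sum(bg)
  stopifnot(length(q) == 4, all(q > 0))
  mat <- do.call(rbind, strsplit(rows, ""))
  W <- ncol(mat); nseq <- nrow(mat)
  gapfrac <- colMeans(mat == "-")
  match_cols <- which(gapfrac < gap_threshold)
  M <- length(match_cols)
  if (M == 0) stop("no usable columns: every column is at or above the gap threshold")

  # --- emissions -----------------------------------------------------------
  emit_row <- function(counts) {
    tot <- sum(counts)
    if (tot + pseudocount == 0) return(q)
    (counts + pseudocount * q) / (tot + pseudocount)
  }
  count_bases <- function(chars) {
    c(sum(chars == "A"), sum(chars == "C"),
      sum(chars == "G"), sum(chars == "T"))
  }
  match_emissions <- t(vapply(match_cols, function(j) {
    emit_row(count_bases(mat[, j]))
  }, numeric(4)))
  colnames(match_emissions) <- DNA_BASES

  # node index of each column: number of match columns at or before it
  node_of_col <- findInterval(seq_len(W), match_cols)
  insert_counts <- matrix(0, nrow = M + 1, ncol = 4)
  for (j in setdiff(seq_len(W), match_cols)) {
    insert_counts[node_of_col[j] + 1L, ] <-
      insert_counts[node_of_col[j] + 1L, ] + count_bases(mat[, j])
  }
  insert_emissions <- t(apply(insert_counts, 1, emit_row))
  colnames(insert_emissions) <- DNA_BASES

  # --- transitions ---------------------------------------------------------
  # columns: MM MI MD | IM II | DM DD
  tcounts <- matrix(0, nrow = M, ncol = 7,
                    dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                            "DM", "DD")))
  is_res <- mat %in% c("A", "C", "G", "T", "N")
  dim(is_res) <- dim(mat)
  for (r in seq_len(nseq)) {
    occ <- which(is_res[r, ])
    if (length(occ) < 1L) next
    lo <- occ[1]; hi <- occ[length(occ)]
    nodes <- match_cols[match_cols >= lo & match_cols <= hi]
    if (length(nodes) < 2L) next
    node_idx <- match(nodes, match_cols)
    state <- ifelse(mat[r, nodes] == "-", "D", "M")
    for (t in seq_len(length(nodes) - 1L)) {
      between <- seq.int(nodes[t] + 1L, nodes[t + 1L] - 1L)
      between <- between[!(between %in% match_cols)]
      nins <- if (length(between)) sum(is_res[r, between]) else 0L
      k <- node_idx[t]
      from <- state[t]; to <- state[t + 1L]
      if (from == "M") {
        if (nins == 0L) {
          tcounts[k, if (to == "M") "MM" else "MD"] <-
            tcounts[k, if (to == "M") "MM" else "MD"] + 1
        } else {
          tcounts[k, "MI"] <- tcounts[k, "MI"] + 1
          tcounts[k, "II"] <- tcounts[k, "II"] + nins - 1L
          # I -> D is outside the state alphabet; only I -> M is counted
          if (to == "M") tcounts[k, "IM"] <- tcounts[k, "IM"] + 1
        }
      } else {
        # inserts flanked by a deletion are rare and have no D<->I edge in
        # this architecture; the node-to-node transition is kept
        tcounts[k, if (to == "M") "DM" else "DD"] <-
          tcounts[k, if (to == "M") "DM" else "DD"] + 1
      }
    }
  }
  norm_block <- function(counts, pc_each) {
    tot <- sum(counts) + length(counts) * pc_each
    if (tot == 0) return(rep(1 / length(counts), length(counts)))
    (counts + pc_each) / tot
  }
  transitions <- matrix(0, nrow = M, ncol = 7,
                        dimnames = dimnames(tcounts))
  for (k in seq_len(M)) {
    transitions[k, 1:3] <- norm_block(tcounts[k, 1:3], pseudocount / 3)
    transitions[k, 4:5] <- norm_block(tcounts[k, 4:5], pseudocount / 2)
    transitions[k, 6:7] <- norm_block(tcounts[k, 6:7], pseudocount / 2)
  }
  # the last node has no outgoing core transitions; pin to a valid point mass
  transitions[M, ] <- c(1, 0, 0, 1, 0, 1, 0)

  consensus <- paste(DNA_BASES[max.col(match_emissions, ties.method =
                                         "first")], collapse = "")
  structure(list(M = M, match_emissions = match_emissions,
                 insert_emissions = insert_emissions,
                 transitions = transitions, q = q, consensus = consensus,
                 mu = NA_real_, lambda = NA_real_, n_eff = NA_real_,
                 nseq = nseq, alignment_width = W, match_cols = match_cols,
                 gap_threshold = gap_threshold, pseudocount = pseudocount,
                 calibration = NULL),
            class = "profile_hmm")
}

is_calibrated <- function(hmm) {
  inherits(hmm, "profile_hmm") && is.finite(hmm$mu) && is.finite(hmm$lambda)
}

# precompute log2-odds matrices for the C++ kernels
.model_matrices <- function(hmm) {
  clamp <- function(x) pmax(x, -1e30)
  M <- hmm$M
  lom <- clamp(log2(sweep(hmm$match_emissions, 2, hmm$q, "/")))
  # C++ row j (0-based) is insert node j+1; node M's row is never read
  ins <- hmm$insert_emissions
  loi <- if (M > 1) {
    rbind(clamp(log2(sweep(ins[2:M, , drop = FALSE], 2, hmm$q, "/"))),
          rep(0, 4))
  } else matrix(0, 1, 4)
  trans <- clamp(log2(hmm$transitions))
  list(lom = lom, loi = loi, trans = trans)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("Profile HMM (nucleotide, local)\n")
  cat("  match states:    ", x$M, "\n")
  cat("  fitted from:     ", x$nseq, "alignment rows of width",
      x$alignment_width, "\n")
  cat("  consensus:       ", x$consensus, "\n")
  if (is_calibrated(x)) {
    cat(sprintf("  calibration:      Gumbel mu = %.3f bits, lambda = %.4f\n",
                x$mu, x$lambda))
  } else {
    cat("  calibration:      none (run calibrate() before E-value search)\n")
  }
  invisible(x)
}

#' @export
summary.profile_hmm <- function(object, ...) {
  ic <- apply(object$match_emissions, 1, function(p) {
    2 + sum(ifelse(p > 0, p * log2(p), 0))
  })
  out <- list(M = object$M, consensus = object$consensus,
              information_bits = ic, total_information = sum(ic),
              q = object$q, mu = object$mu, lambda = object$lambda,
              nseq = object$nseq)
  class(out) <- "summary.profile_hmm"
  out
}

#' @export
print.summary.profile_hmm <- function(x, ...) {
  cat("Profile HMM summary\n")
  cat("  match states:", x$M, " rows fitted:", x$nseq, "\n")
  cat("  consensus:   ", x$consensus, "\n")
  cat(sprintf("  information content: total %.1f bits, per-column mean %.2f\n",
              x$total_information, mean(x$information_bits)))
  if (is.finite(x$mu))
    cat(sprintf("  Gumbel calibration: mu = %.3f bits, lambda = %.4f\n",
                x$mu, x$lambda))
  invisible(x)
}

#' @export
coef.profile_hmm <- function(object, ...) {
  list(match_emissions = object$match_emissions,
       insert_emissions = object$insert_emissions,
       transitions = object$transitions)
}

#' Simulate sequences from a fitted profile HMM
#'
#' Draws glocal paths (node 1 through node M) using the model's transition
#' and emission probabilities. Useful for fixed-point and round-trip checks.
#'
#' @param object a `profile_hmm`.
#' @param nsim number of sequences.
#' @param seed optional RNG seed (caller's RNG state is restored).
#' @param ... unused.
#' @return character vector of simulated sequences.
#' @export
simulate.profile_hmm <- function(object, nsim = 1, seed = NULL, ...) {
  do_sim <- function() {
    vapply(seq_len(nsim), function(i) {
      out <- character(0)
      k <- 1L; state <- "M"
      while (k <= object$M) {
        if (state == "M") {
          out <- c(out, sample(DNA_BASES, 1,
                               prob = object$match_emissions[k, ]))
        }
        if (k == object$M) break
        tr <- object$transitions[k, ]
        if (state == "M") {
          nxt <- sample(c("M", "I", "D"), 1, prob = tr[c("MM", "MI", "MD")])
        } else if (state == "I") {
          nxt <- sample(c("M", "I"), 1, prob = tr[c("IM", "II")])
        } else {
          nxt <- sample(c("M", "D"), 1, prob = tr[c("DM", "DD")])
        }
        if (nxt == "I") {
          out <- c(out, sample(DNA_BASES, 1,
                               prob = object$insert_emissions[k + 1L, ]))
          state <- "I"
        } else {
          k <- k + 1L
          state <- nxt
        }
      }
      paste(out, collapse = "")
    }, character(1))
  }
  if (is.null(seed)) do_sim() else with_seed(seed, do_sim())
}

#' Plot per-column information content of a profile HMM
#'
#' @param x a `profile_hmm`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.profile_hmm <- function(x, ...) {
  ic <- apply(x$match_emissions, 1, function(p) {
    2 + sum(ifelse(p > 0, p * log2(p), 0))
  })
  graphics::barplot(ic, names.arg = strsplit(x$consensus, "")[[1]],
                    ylab = "information (bits)", xlab = "model column",
                    border = NA, ...)
  invisible(x)
}

#' Serialize a profile HMM to a plain-text file
#'
#' A documented key/value + matrix layout (HMMER3-like in spirit, not
#' byte-compatible). Probabilities are written with full precision so
#' `read_hmm(write_hmm(x))` round-trips exactly.
#'
#' @param hmm a `profile_hmm`.
#' @param path output path.
#' @export
write_hmm <- function(hmm, path) {
  fmt <- function(x) format(x, digits = 17, scientific = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("SPRETRACE-HMM 1", con)
  writeLines(paste("M", hmm$M), con)
  writeLines(paste("NSEQ", hmm$nseq), con)
  writeLines(paste("WIDTH", hmm$alignment_width), con)
  writeLines(paste("GAPTHRESH", fmt(hmm$gap_threshold)), con)
  writeLines(paste("PSEUDOCOUNT", fmt(hmm$pseudocount)), con)
  writeLines(paste("Q", paste(fmt(hmm$q), collapse = " ")), con)
  writeLines(paste("MU", fmt(hmm$mu)), con)
  writeLines(paste("LAMBDA", fmt(hmm$lambda)), con)
  writeLines(paste("NEFF", fmt(hmm$n_eff)), con)
  writeLines(paste("CONSENSUS", hmm$consensus), con)
  writeLines("MATCH_EMISSIONS", con)
  write.table(format(hmm$match_emissions, digits = 17), con,
              col.names = FALSE, row.names = FALSE, quote = FALSE)
  writeLines("INSERT_EMISSIONS", con)
  write.table(format(hmm$insert_emissions, digits = 17), con,
              col.names = FALSE, row.names = FALSE, quote = FALSE)
  writeLines("TRANSITIONS", con)
  write.table(format(hmm$transitions, digits = 17), con,
              col.names = FALSE, row.names = FALSE, quote = FALSE)
  writeLines("//", con)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "SPRETRACE-HMM"))
    stop("not a spretrace HMM file: ", path)
  kv <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    trimws(sub(paste0("^", key, " "), "", ln))
  }
  num <- function(s) if (s %in% c("NA", "NaN")) NA_real_ else as.numeric(s)
  M <- as.integer(kv("M"))
  read_block <- function(label, nrows) {
    at <- which(lines == label)[1]
    block <- lines[(at + 1):(at + nrows)]
    m <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
    m
  }
  me <- read_block("MATCH_EMISSIONS", M); colnames(me) <- DNA_BASES
  ie <- read_block("INSERT_EMISSIONS", M + 1); colnames(ie) <- DNA_BASES
  tr <- read_block("TRANSITIONS", M)
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  structure(list(M = M, match_emissions = me, insert_emissions = ie,
                 transitions = tr,
                 q = as.numeric(strsplit(kv("Q"), "\\s+")[[1]]),
                 consensus = kv("CONSENSUS"),
                 mu = num(kv("MU")), lambda = num(kv("LAMBDA")),
                 n_eff = num(kv("NEFF")),
                 nseq = as.integer(kv("NSEQ")),
                 alignment_width = as.integer(kv("WIDTH")),
                 match_cols = NULL,
                 gap_threshold = as.numeric(kv("GAPTHRESH")),
                 pseudocount = as.numeric(kv("PSEUDOCOUNT")),
                 calibration = NULL),
            class = "profile_hmm")
}
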
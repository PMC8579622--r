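# Step 1 of the two-step search: exact-match scan of the core motif over a
# consensus library and extraction of fixed-width, core-anchored flanking
# windows that seed the first profile HMM.

SPRE_CORE_MOTIF <- "TCAGCAGGAAGCAGTTA"

.as_family_df <- function(library) {
  if (is.character(library)) {
    stopifnot(!is.null(names(library)))
    return(data.frame(family_id = names(library), name = names(library),
                      repeat_class = "other",
                      consensus = unname(library),
                      length = nchar(library), stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(library),
            all(c("family_id", "consensus") %in% names(library)))
  if (is.null(library$length)) library$length <- nchar(library$consensus)
  library
}

#' Find exact occurrences of a core motif in a consensus library
#'
#' Reports every exact occurrence of `motif` (overlapping occurrences
#' included). `N` in a consensus never matches, so windows with N in the
#' core are excluded from step 1 by construction. With
#' `both_strands = TRUE` occurrences of the reverse complement are reported
#' on strand "-"; coordinates are always on the consensus forward frame,
#' 0-based half-open.
#'
#' @param library a named character vector of consensus sequences, or a
#'   repeat-family data.frame with `family_id` and `consensus` columns.
#' @param motif DNA string over A,C,G,T.
#' @param both_strands also search the reverse complement of the motif.
#' @return data.frame with columns `family_id`, `start`, `end`, `strand`.
#' @export
find_exact_motif <- function(library, motif = SPRE_CORE_MOTIF,
                             both_strands = TRUE) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    stop("motif must be a non-empty DNA string")
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif))
    stop("motif must be over the A,C,G,T alphabet")
  fam <- .as_family_df(library)
  rc <- revcomp(motif)
  hits <- vector("list", nrow(fam))
  for (i in seq_len(nrow(fam))) {
    subj <- Biostrings::DNAString(fam$consensus[i])
    plus <- Biostrings::matchPattern(motif, subj)
    starts <- BiocGenerics::start(plus) - 1L
    strands <- rep("+", length(starts))
    if (both_strands) {
      minus <- Biostrings::matchPattern(rc, subj)
      mstarts <- BiocGenerics::start(minus) - 1L
      # a palindromic motif would be double-reported; keep plus only
      if (identical(motif, rc)) mstarts <- integer(0)
      starts <- c(starts, mstarts)
      strands <- c(strands, rep("-", length(mstarts)))
    }
    if (length(starts)) {
      hits[[i]] <- data.frame(family_id = fam$family_id[i],
                              start = starts,
                              end = starts + nchar(motif),
                              strand = strands, stringsAsFactors = FALSE)
    }
  }
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    return(data.frame(family_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(match(out$family_id, fam$family_id), out$start), , drop = FALSE]
}

#' Distinct families carrying at least one motif hit
#'
#' @param hits data.frame from [find_exact_motif()].
#' @return sorted character vector of family ids.
#' @export
families_with_hit <- function(hits) {
  sort(unique(hits$family_id))
}

#' Extract a core-anchored flanking window around a motif hit
#'
#' Returns the motif occurrence with `flank` nucleotides of 5' and 3'
#' context (default 40 + 17 + 40 = 97 columns for the SPRE core), read in
#' the hit's orientation: minus-strand windows are reverse-complemented so
#' the core reads 5'->3' as the motif. Flanks that run off the consensus are
#' padded with "-" so every window has the same fixed width, with the core
#' always occupying columns `flank + 1 .. flank + core length`.
#'
#' @param family one row of a repeat-family data.frame (or a single named
#'   sequence).
#' @param hit one row of a [find_exact_motif()] data.frame.
#' @param flank flank width in nt (>= 0).
#' @return single character string of width `2 * flank + core length`.
#' @export
extract_window <- function(family, hit, flank = 40L) {
  if (flank < 0) stop("flank must be >= 0")
  fam <- .as_family_df(family)
  stopifnot(nrow(fam) == 1L)
  cons <- fam$consensus
  L <- nchar(cons)
  if (hit$start < 0 || hit$end > L || hit$start >= hit$end)
    stop("hit does not lie within the family consensus")
  lo <- hit$start - flank        # 0-based target span [lo, hi)
  hi <- hit$end + flank
  left_pad <- max(0L, -lo)
  right_pad <- max(0L, hi - L)
  core_seq <- substr(cons, max(lo, 0L) + 1L, min(hi, L))
  win <- paste0(strrep("-", left_pad), core_seq, strrep("-", right_pad))
  if (identical(hit$strand, "-")) win <- revcomp(win)
  win
}

#' Stack fixed-width anchored windows into an alignment
#'
#' The first-cycle alignment is anchor-based: the core is fixed at columns
#' `flank + 1 .. flank + core length` and flanks are ungapped, so stacking
#' the equal-width windows *is* the alignment (no general MSA step is
#' needed, and the first profile is deterministic).
#'
#' @param windows character vector of equal-width windows.
#' @return named character vector of alignment rows (class `"anchored_alignment"`).
#' @export
anchor_align <- function(windows) {
  if (!length(windows)) stop("no windows to align")
  w <- nchar(windows)
  if (length(unique(w)) != 1L)
    stop("window width mismatch: ", paste(unique(w), collapse = ", "))
  if (is.null(names(windows)))
    names(windows) <- paste0("row", seq_along(windows))
  structure(windows, class = "anchored_alignment")
}

#' Extract seed windows for all step-1 hits
#'
#' Convenience wrapper: one anchored window per motif hit, named
#' `family_id/start-end(strand)`.
#'
#' @param library repeat-family data.frame or named character vector.
#' @param hits data.frame from [find_exact_motif()].
#' @param flank flank width in nt.
#' @return named character vector of windows.
#' @export
extract_seed_windows <- function(library, hits, flank = 40L) {
  fam <- .as_family_df(library)
  out <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    out[i] <- extract_window(fam[fam$family_id == h$family_id, ][1, ], h,
                             flank = flank)
    names(out)[i] <- sprintf("%s/%d-%d(%s)", h$family_id, h$start, h$end,
                             h$strand)
  }
  out
}
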
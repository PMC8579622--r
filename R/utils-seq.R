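# Low-level sequence helpers shared by all modules. Sequences are plain
# uppercase character strings over {A,C,G,T,N}; alignments additionally use
# "-" for gaps. All coordinates handed between modules are 0-based half-open;
# 1-based formats are converted at the I/O boundary.

DNA_BASES <- c("A", "C", "G", "T")

# byte -> integer code lookup: A/C/G/T -> 0..3, N (and anything else) -> 4,
# "-"/masked handled by callers
.dna_code_map <- local({
  m <- rep.int(4L, 256L)
  m[utf8ToInt("A")] <- 0L; m[utf8ToInt("C")] <- 1L
  m[utf8ToInt("G")] <- 2L; m[utf8ToInt("T")] <- 3L
  m
})

encode_dna <- function(x) {
  stopifnot(length(x) == 1L)
  .dna_code_map[utf8ToInt(x)]
}

#' Reverse complement of a DNA string
#'
#' Complements A/C/G/T, leaves N and the alignment gap character unchanged,
#' and reverses the string. Vectorised over its input.
#'
#' @param x character vector of DNA strings (may contain `N` and `-`).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca", intToUtf8(rev(utf8ToInt(s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Sample random DNA sequences from a background composition
#'
#' @param n number of sequences.
#' @param len sequence length (recycled).
#' @param q background probabilities over A,C,G,T.
#' @return character vector of `n` sequences.
#' @export
random_dna <- function(n, len, q = rep(0.25, 4)) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len[i], replace = TRUE, prob = q), collapse = "")
  }, character(1))
}

#' Estimate background base composition from a sequence set
#'
#' Counts A/C/G/T over all sequences (N ignored) and floors each frequency
#' at `floor` before renormalising, which keeps log-odds finite on skewed
#' synthetic backgrounds.
#'
#' @param seqs character vector of DNA strings.
#' @param floor minimum frequency per base.
#' @return numeric vector of length 4 (A,C,G,T) summing to 1.
#' @export
estimate_background <- function(seqs, floor = 0.05) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in seqs) {
    codes <- .dna_code_map[utf8ToInt(s)]
    tab <- tabulate(codes + 1L, nbins = 5L)[1:4]
    counts <- counts + tab
  }
  if (sum(counts) == 0) return(rep(0.25, 4))
  q <- counts / sum(counts)
  q <- pmax(q, floor)
  unname(q / sum(q))
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# normalize free-text sequence to uppercase ACGTN (gap optionally preserved)
normalize_dna <- function(x, allow_gaps = FALSE) {
  x <- toupper(x)
  pattern <- if (allow_gaps) "[^ACGTN-]" else "[^ACGTN]"
  gsub(pattern, "N", x)
}
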
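# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own computational paths: motif finding
# by substring comparison, Viterbi/forward by exhaustive path enumeration
# over the model grammar, interval intersection by an all-pairs loop.

# every exact occurrence of `motif` in `seq`, both strands, by checking
# each offset
oracle_find_motif <- function(seq, motif) {
  m <- nchar(motif)
  n <- nchar(seq)
  out <- data.frame(start = integer(), strand = character())
  if (m > n) return(out)
  rc <- revcomp(motif)
  for (i in seq_len(n - m + 1)) {
    sub <- substr(seq, i, i + m - 1)
    if (sub == motif)
      out <- rbind(out, data.frame(start = i - 1L, strand = "+"))
    if (sub == rc && motif != rc)
      out <- rbind(out, data.frame(start = i - 1L, strand = "-"))
  }
  out
}

# exhaustive enumeration of every legal local path of a profile HMM on a
# target: entry B->M_k1 with prob 1/M, core transitions, exit free from any
# match state. Returns max (Viterbi) and log2-sum (forward) path log-odds.
oracle_enumerate <- function(hmm, target) {
  M <- hmm$M
  codes <- match(strsplit(target, "")[[1]], c("A", "C", "G", "T"))
  n <- length(codes)
  lom <- log2(sweep(hmm$match_emissions, 2, hmm$q, "/"))
  ins <- hmm$insert_emissions
  loi_node <- function(k) log2(ins[k + 1L, ] / hmm$q)  # insert node k
  tr <- log2(hmm$transitions)
  scores <- numeric(0)
  # state: just arrived in M (k) having consumed residue at position pos
  rec_from_M <- function(k, pos, acc) {
    scores[[length(scores) + 1L]] <<- acc  # exit allowed here
    if (k >= M) return()
    if (pos < n) {
      rec_from_M(k + 1L, pos + 1L,
                 acc + tr[k, "MM"] + lom[k + 1L, codes[pos + 1L]])
      rec_from_I(k, pos + 1L, acc + tr[k, "MI"] + loi_node(k)[codes[pos + 1L]])
    }
    rec_from_D(k + 1L, pos, acc + tr[k, "MD"])
  }
  rec_from_I <- function(k, pos, acc) {
    if (pos < n) {
      rec_from_I(k, pos + 1L, acc + tr[k, "II"] + loi_node(k)[codes[pos + 1L]])
      rec_from_M(k + 1L, pos + 1L,
                 acc + tr[k, "IM"] + lom[k + 1L, codes[pos + 1L]])
    }
  }
  rec_from_D <- function(k, pos, acc) {
    if (k >= M) return()
    if (pos < n)
      rec_from_M(k + 1L, pos + 1L,
                 acc + tr[k, "DM"] + lom[k + 1L, codes[pos + 1L]])
    rec_from_D(k + 1L, pos, acc + tr[k, "DD"])
  }
  for (s in seq_len(n)) {
    for (k1 in seq_len(M)) {
      rec_from_M(k1, s, -log2(M) + lom[k1, codes[s]])
    }
  }
  list(viterbi = max(scores),
       forward = log2(sum(2^unlist(scores))))
}

# all-pairs interval intersection with bedtools -s -wa -wb semantics
oracle_intersect <- function(a, b, stranded = TRUE) {
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$seq_id[i] != b$seq_id[j]) next
      if (stranded && a$strand[i] != b$strand[j]) next
      if (min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) >= 1)
        pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  if (!length(pairs)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, pairs)
}

# small random gapped alignment whose profile has at most max_match match
# states (used for enumeration-oracle tests)
random_small_alignment <- function(n_rows, width, gap_prob = 0.15) {
  rows <- vapply(seq_len(n_rows), function(i) {
    chars <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
    gaps <- runif(width) < gap_prob
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  names(rows) <- paste0("r", seq_len(n_rows))
  rows
}

random_intervals <- function(n, seq_ids = c("chr1", "chr2"),
                            max_pos = 1000L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(seq_id = sample(seq_ids, n, replace = TRUE),
             start = start,
             end = start + sample.int(50L, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# minimal Dfam-style EMBL fixture text for `n` entries
dfam_fixture_lines <- function(entries) {
  unlist(lapply(entries, function(e) {
    c(paste0("ID   ", e$id, "; SV 1; linear; DNA; STD; UNC; ",
             nchar(e$seq), " BP."),
      paste0("NM   ", e$name),
      "CC   RepeatMasker Annotations:",
      if (!is.null(e$type)) paste0("CC        Type: ", e$type),
      if (!is.null(e$subtype)) paste0("CC        SubType: ", e$subtype),
      paste0("SQ   Sequence ", nchar(e$seq), " BP;"),
      paste0("     ", tolower(e$seq), " ", nchar(e$seq)),
      "//")
  }))
}

# RepeatMasker .out fixture text
rmout_fixture_lines <- function(rows) {
  c("   SW   perc perc perc  query      position in query",
    "score   div. del. ins.  sequence   begin end (left)  repeat class",
    "",
    vapply(rows, function(r) {
      sprintf("  283   10.0  0.0  0.0  %s  %d %d (0) %s %s %s 1 100 (0) 1",
              r$seq_id, r$begin, r$end, r$strand, r$name, r$class)
    }, character(1)))
}
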
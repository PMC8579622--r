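# Readers and writers for the external formats the pipeline touches.
# Internal convention: intervals are 0-based half-open with strand "+"/"-";
# RepeatMasker (1-based inclusive, strand "C") and BED are converted here.

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased and any character outside A,C,G,T,N is mapped to
#' N (with `allow_gaps = TRUE` the alignment gap "-" is also kept, for
#' aligned FASTA).
#'
#' @param path path to a FASTA file.
#' @param allow_gaps keep "-" characters (aligned FASTA) instead of mapping
#'   them to N.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  ids <- names(set)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("malformed FASTA header in ", path)
  bad <- which(!nzchar(seqs))
  if (length(bad))
    stop("empty sequence for FASTA record '", ids[bad[1]], "' in ", path)
  setNames(normalize_dna(seqs, allow_gaps = allow_gaps), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq.int(1L, max(n, 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a Dfam-style EMBL flat file of repeat-family consensus sequences
#'
#' Parses the minimal subset used by Dfam releases: `ID` (accession), `NM`
#' (name), `CC` classification comments (`Type:` / `SubType:`), and the `SQ`
#' sequence block, each entry terminated by `//`. The repeat class is taken
#' from the `Type:` comment; entries without a parseable type get class
#' `"other"` (never dropped, so class percentages keep a complete
#' denominator). The raw classification string is kept so users can apply
#' their own mapping.
#'
#' @param path path to the EMBL flat file.
#' @return data.frame with columns `family_id`, `name`, `repeat_class`,
#'   `classification`, `consensus`, `length`.
#' @export
read_dfam_embl <- function(path) {
  if (!file.exists(path)) stop("EMBL file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  id_at <- grep("^ID\\s", lines)
  if (!length(id_at)) stop("no EMBL entries (ID lines) found in ", path)
  end_at <- grep("^//", lines)
  out <- vector("list", length(id_at))
  for (i in seq_along(id_at)) {
    from <- id_at[i]
    ends <- end_at[end_at > from]
    next_id <- id_at[id_at > from]
    to <- if (length(ends)) ends[1] else NA_integer_
    fid <- sub(";.*$", "", sub("^ID\\s+", "", lines[from]))
    fid <- strsplit(trimws(fid), "\\s+")[[1]][1]
    if (is.na(to) || (length(next_id) && next_id[1] < to))
      stop("truncated EMBL entry (missing //): ", fid)
    entry <- lines[from:to]
    nm <- grep("^NM\\s", entry, value = TRUE)
    name <- if (length(nm)) trimws(sub("^NM\\s+", "", nm[1])) else fid
    name <- sub(";$", "", name)
    cc <- grep("^CC", entry, value = TRUE)
    type_ln <- grep("Type:", cc, value = TRUE)
    subtype_ln <- grep("SubType:", cc, value = TRUE)
    type <- if (length(type_ln))
      trimws(sub(".*Type:\\s*", "", type_ln[1])) else ""
    subtype <- if (length(subtype_ln))
      trimws(sub(".*SubType:\\s*", "", subtype_ln[1])) else ""
    repeat_class <- if (nzchar(type)) type else "other"
    classification <- paste0(type, if (nzchar(subtype))
      paste0("/", subtype) else "")
    sq_at <- grep("^SQ", entry)
    consensus <- ""
    if (length(sq_at)) {
      block <- entry[(sq_at[1] + 1):(length(entry) - 1)]
      consensus <- normalize_dna(gsub("[^A-Za-z]", "", paste(block,
                                                             collapse = "")))
    }
    out[[i]] <- data.frame(family_id = fid, name = name,
                           repeat_class = repeat_class,
                           classification = classification,
                           consensus = consensus,
                           length = nchar(consensus),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (anyDuplicated(res$family_id))
    warning("duplicated family_id values in ", path)
  res
}

#' Read a RepeatMasker .out annotation file
#'
#' Standard layout: three header lines, whitespace-delimited columns, query
#' coordinates 1-based inclusive, strand "+" or "C" (complement). Converted
#' to 0-based half-open with strand "-" for complement rows.
#'
#' @param path path to the .out file.
#' @return data.frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `repeat_name`, `repeat_class_family`.
#' @export
read_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop("RepeatMasker .out file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) <= 3) return(.empty_annotation())
  body <- lines[-(1:3)]
  keep <- which(nzchar(trimws(body)))
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 11)
      stop("malformed RepeatMasker row at line ", i + 3, " of ", path)
    qb <- suppressWarnings(as.integer(f[6]))
    qe <- suppressWarnings(as.integer(f[7]))
    if (is.na(qb) || is.na(qe))
      stop("non-numeric coordinate at line ", i + 3, " of ", path)
    data.frame(seq_id = f[5], start = qb - 1L, end = qe,
               strand = if (identical(f[9], "C")) "-" else "+",
               repeat_name = f[10], repeat_class_family = f[11],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.empty_annotation <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             strand = character(), repeat_name = character(),
             repeat_class_family = character(), stringsAsFactors = FALSE)
}

#' Write annotations in RepeatMasker .out layout
#'
#' Inverse of [read_repeatmasker_out()]: 0-based half-open intervals are
#' written as 1-based inclusive with strand "C" for minus. Used by the
#' synthetic-data generator so annotation truth round-trips through the
#' same reader as real data.
#'
#' @param annotations data.frame as returned by [read_repeatmasker_out()].
#' @param path output path.
#' @export
write_repeatmasker_out <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching  repeat       position in repeat",
    "score   div. del. ins.  sequence  begin end   (left)   repeat    class/family  begin end (left)",
    ""), con)
  if (nrow(annotations)) {
    for (i in seq_len(nrow(annotations))) {
      a <- annotations[i, ]
      writeLines(sprintf(
        "%5d %6.1f %4.1f %4.1f  %s %d %d (0) %s %s %s 1 %d (0) %d",
        1000L, 0, 0, 0, a$seq_id, a$start + 1L, a$end,
        if (a$strand == "-") "C" else "+", a$repeat_name,
        a$repeat_class_family, a$end - a$start, i), con)
    }
  }
  invisible(path)
}

#' Read and write BED6 interval files
#'
#' Columns chrom, start, end, name, score, strand with 0-based half-open
#' coordinates (the native BED convention, identical to the internal one).
#' Reading and writing are exact inverses.
#'
#' @param path file path.
#' @return `read_bed6`: data.frame with columns `seq_id`, `start`, `end`,
#'   `name`, `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0 || !length(readLines(path, n = 1L)))
    return(.empty_bed())
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = if (!is.null(gr$name)) gr$name else ".",
                   score = if (!is.null(gr$score)) gr$score else 0,
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("BED interval with start >= end in ", path)
  df
}

.empty_bed <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             stringsAsFactors = FALSE)
}

#' @param intervals data.frame with columns `seq_id`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @rdname read_bed6
#' @export
write_bed6 <- function(intervals, path) {
  if (!nrow(intervals)) {
    file.create(path)
    return(invisible(path))
  }
  if (any(intervals$start >= intervals$end))
    stop("cannot write BED interval with start >= end")
  nm <- if (!is.null(intervals$name)) intervals$name else "."
  sc <- if (!is.null(intervals$score)) intervals$score else 0
  st <- if (!is.null(intervals$strand)) intervals$strand else "+"
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$seq_id,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    strand = st)
  gr$name <- nm
  gr$score <- sc
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a tabular hit file
#'
#' One row per hit with 1-based inclusive alignment coordinates (always
#' `S <= E`; orientation is carried by the explicit strand column), sorted
#' by E-value ascending.
#'
#' @param hits data.frame with columns `target_id`, `S`, `E`, `strand`,
#'   `bit_score`, `e_value`.
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("target_id", "S", "E", "strand", "bit_score", "e_value")
  if (nrow(hits)) {
    hits <- hits[order(hits$e_value, hits$target_id, hits$S), cols,
                 drop = FALSE]
  } else {
    hits <- hits[, cols, drop = FALSE]
  }
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(target_id = "character", strand = "character"))
}
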
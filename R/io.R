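# Format handling.  FASTA/FASTQ go through Biostrings; GFF3 is read with a
# tolerant line-oriented reader so malformed lines can be skipped and
# counted (the pipeline accepts user-supplied annotation files of variable
# quality).  All in-memory and TSV coordinates are 0-based half-open; GFF3's
# 1-based closed convention is converted at this boundary.

#' Read a FASTA file
#'
#' @param path file path.
#' @return named character vector (ids truncated at first whitespace).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  stats::setNames(toupper(as.character(x)), ids)
}

#' Write a FASTA file
#'
#' @param seqs named character vector.
#' @param path file path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta", width = width)
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#'
#' Base qualities are ignored by the pipeline (reads are assumed
#' quality-filtered upstream).  Structural problems raise an error naming
#' the offending line.
#'
#' @param path file path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ record near line %d in %s",
                 length(lines) - length(lines) %% 4L + 1L, path),
         call. = FALSE)
  }
  hdr <- seq(1L, length(lines), by = 4L)
  bad <- hdr[!startsWith(lines[hdr], "@")]
  if (length(bad) > 0L) {
    stop(sprintf("malformed FASTQ header at line %d in %s", bad[1], path),
         call. = FALSE)
  }
  plus <- hdr + 2L
  badp <- plus[!startsWith(lines[plus], "+")]
  if (length(badp) > 0L) {
    stop(sprintf("malformed FASTQ separator at line %d in %s", badp[1], path),
         call. = FALSE)
  }
  ids <- sub("\\s.*$", "", substring(lines[hdr], 2L))
  stats::setNames(toupper(lines[hdr + 1L]), ids)
}

#' Write a FASTQ file with constant Phred+33 qualities
#'
#' @param seqs named character vector of read sequences.
#' @param path file path.
#' @param quality_char constant quality character (default `"I"`, Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(seqs))
  qual <- vapply(nchar(seqs), function(n) {
    paste(rep(quality_char, n), collapse = "")
  }, character(1))
  out <- character(4L * length(seqs))
  out[seq(1L, by = 4L, length.out = length(seqs))] <- paste0("@", ids)
  out[seq(2L, by = 4L, length.out = length(seqs))] <- unname(seqs)
  out[seq(3L, by = 4L, length.out = length(seqs))] <- "+"
  out[seq(4L, by = 4L, length.out = length(seqs))] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Read a GFF3 annotation file
#'
#' Comment and pragma lines are skipped; malformed feature lines (not 9
#' tab-separated fields, or non-numeric coordinates) are skipped with a
#' warning that reports how many.  Coordinates are converted to 0-based
#' half-open.  The `category` column is taken from the `category=`
#' attribute, falling back to `product=` and then `"unannotated"`.
#'
#' @param path file path.
#' @return `data.frame`: `seqid`, `source`, `type`, `start`, `end`
#'   (0-based half-open), `strand`, `attributes`, `category`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) == 9L
  parse1 <- function(f) {
    s <- suppressWarnings(as.integer(f[4]))
    e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || e < s) return(NULL)
    attr <- f[9]
    cat <- .gff_attr(attr, "category")
    if (is.na(cat)) cat <- .gff_attr(attr, "product")
    if (is.na(cat)) cat <- "unannotated"
    data.frame(seqid = f[1], source = f[2], type = f[3],
               start = s - 1L, end = e, strand = f[7],
               attributes = attr, category = cat, stringsAsFactors = FALSE)
  }
  rows <- lapply(fields[ok], parse1)
  n_bad <- sum(!ok) + sum(vapply(rows, is.null, logical(1)))
  if (n_bad > 0L) {
    warning(sprintf("skipped %d malformed GFF3 line(s) in %s", n_bad, path))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(seqid = character(0), source = character(0),
                      type = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      attributes = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.gff_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attr))[[1]]
  if (length(m) < 2L) NA_character_ else m[2]
}

#' Write hits as a BLAST-like tabular file
#'
#' Emits the 12 standard tabular-alignment columns plus `sstrand`, `qlen`
#' and `slen`.  Alignment coordinates follow the emitting convention
#' (1-based closed, subject coordinates reversed on the minus strand);
#' e-value and bit score are placeholders (no e-value model is used —
#' thresholding is purely identity/coverage).
#'
#' @param hits hit `data.frame` from [match_to_database()].
#' @param spacers named character vector of the query spacers.
#' @param refs reference set (for subject lengths).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, spacers, refs, path) {
  lens <- .ref_lengths(refs)
  qlen <- nchar(spacers)[match(hits$spacer_id, names(spacers))]
  ncols <- round(hits$coverage / 100 * qlen)
  mism <- round((1 - hits$identity / 100) * ncols)
  minus <- hits$strand == "-"
  sstart <- ifelse(minus, hits$end, hits$start + 1L)
  send <- ifelse(minus, hits$start + 1L, hits$end)
  out <- data.frame(
    qseqid = hits$spacer_id, sseqid = hits$ref_id,
    pident = sprintf("%.3f", hits$identity),
    length = ncols, mismatch = mism, gapopen = 0L,
    qstart = 1L, qend = ncols,
    sstart = sstart, send = send,
    evalue = 0, bitscore = 0,
    sstrand = ifelse(minus, "minus", "plus"),
    qlen = qlen, slen = unname(lens[hits$ref_id]),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  listcols <- vapply(x, is.list, logical(1))
  x[listcols] <- lapply(x[listcols], function(col) {
    vapply(col, paste, character(1), collapse = ",")
  })
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
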
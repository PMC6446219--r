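#' Read a FASTQ file into a ReadBatch
#'
#' Parses 4-line FASTQ records (gzip accepted transparently, detected from
#' the file's magic bytes, not its extension) and decodes quality strings at
#' the given ASCII offset. Use [detectEncoding()] first when the offset is
#' unknown.
#'
#' @param path FASTQ file, plain or gzipped.
#' @param offset Quality ASCII offset: 33 (Sanger / Illumina 1.9) or
#'   64 (Illumina 1.3--1.7).
#' @param maxReads Optional cap on the number of records read; supports the
#'   pipeline's 4,000- and 10,000-read sampling stages.
#' @param mate Mate tag to assign to all reads.
#' @return A \linkS4class{ReadBatch}.
#' @seealso [writeFastq()], [detectEncoding()]
#' @export
readFastq <- function(path, offset = 33L, maxReads = NULL, mate = "single") {
  stopifnot(offset %in% c(33L, 64L))
  if (!file.exists(path))
    stop("FASTQ file not found: ", path)
  nrec <- if (is.null(maxReads)) -1L else as.integer(maxReads)
  qs <- tryCatch(
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(path, nrec = nrec)),
    error = function(e) .diagnoseFastq(path, nrec, conditionMessage(e))
  )
  if (length(qs) == 0L)
    return(readBatch(Biostrings::DNAStringSet(), IRanges::IntegerList(),
                     mate = character(0)))
  # decode from the raw quality characters so both offsets share one path
  # (Biostrings nul-pads short quality strings instead of erroring, so both
  # the width check and the conversion route to the diagnostic rescan)
  if (!all(BiocGenerics::width(Biostrings::quality(qs)) ==
           BiocGenerics::width(qs)))
    .diagnoseFastq(path, nrec, "sequence/quality length mismatch")
  qchr <- tryCatch(as.character(Biostrings::quality(qs)),
                   error = function(e)
                     .diagnoseFastq(path, nrec, conditionMessage(e)))
  quals <- IRanges::IntegerList(lapply(qchr, function(s)
    as.integer(charToRaw(s)) - offset))
  ids <- sub("[ \t].*$", "", names(qs))
  seqs <- Biostrings::DNAStringSet(qs)
  names(seqs) <- ids
  readBatch(seqs, quals, mate = mate)
}

# On a parse failure, rescan the file to report which record is malformed.
.diagnoseFastq <- function(path, nrec, original) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  i <- 0L
  repeat {
    rec <- readLines(con, n = 4L)
    if (length(rec) == 0L) break
    i <- i + 1L
    if (length(rec) < 4L)
      stop(sprintf("malformed FASTQ record %d: truncated record", i))
    if (!startsWith(rec[1L], "@"))
      stop(sprintf("malformed FASTQ record %d: header does not start with '@'", i))
    if (!startsWith(rec[3L], "+"))
      stop(sprintf("malformed FASTQ record %d: separator line is not '+'", i))
    if (nchar(rec[2L]) != nchar(rec[4L]))
      stop(sprintf(
        "malformed FASTQ record %d: sequence length %d != quality length %d",
        i, nchar(rec[2L]), nchar(rec[4L])))
    if (nrec > 0L && i >= nrec) break
  }
  stop("FASTQ parse error: ", original)
}

#' Write a ReadBatch as FASTQ
#'
#' @param batch A \linkS4class{ReadBatch}.
#' @param path Output file; a \code{.gz} suffix triggers gzip compression.
#' @param offset Quality ASCII offset to encode with (default 33).
#' @return Invisibly, \code{path}.
#' @export
writeFastq <- function(batch, path, offset = 33L) {
  ids <- names(batch)
  if (is.null(ids))
    ids <- paste0("read", seq_len(length(batch)))
  qchar <- vapply(as.list(qualities(batch)), function(q)
    rawToChar(as.raw(q + offset)), character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (length(batch)) {
    out <- rbind(paste0("@", ids), as.character(sequences(batch)), "+", qchar)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' Detect the FASTQ quality encoding from a read sample
#'
#' Applies the range heuristic used by the per-run format check: a sample of
#' up to \code{nSample} reads (4,000 by default) is inspected; any quality
#' character below ASCII 59 implies phred+33 ("Sanger", reported by FastQC
#' as Illumina 1.9), while a range confined to [64, 104] with at least one
#' character at or above 75 implies phred+64 (Illumina 1.5). An ambiguous
#' range is an error prompting an explicit offset.
#'
#' @param x Path to a FASTQ file, or a character vector of raw quality
#'   strings.
#' @param nSample Number of reads to sample from the file head.
#' @return A list with elements \code{name} (\code{"sanger_33"} or
#'   \code{"illumina15_64"}) and \code{offset} (33 or 64).
#' @examples
#' detectEncoding("II!I")$offset   # 33: '!' is ASCII 33
#' @export
detectEncoding <- function(x, nSample = 4000L) {
  if (length(x) == 1L && file.exists(x)) {
    con <- gzfile(x, open = "rt")
    on.exit(close(con))
    lines <- readLines(con, n = 4L * nSample)
    if (length(lines) < 4L)
      stop("cannot detect encoding: no complete FASTQ record in sample")
    x <- lines[seq(4L, length(lines), by = 4L)]
  }
  codes <- as.integer(unlist(lapply(x, function(s) as.integer(charToRaw(s)))))
  if (length(codes) == 0L)
    stop("cannot detect encoding: empty quality sample")
  if (any(codes < 59L))
    return(list(name = "sanger_33", offset = 33L))
  if (min(codes) >= 64L && max(codes) >= 75L)
    return(list(name = "illumina15_64", offset = 64L))
  stop("undetermined quality encoding (all codes in an ambiguous range); ",
       "supply the offset explicitly")
}
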
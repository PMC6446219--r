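#' Default member names of the dataset bundle archive
#'
#' @return Named character vector mapping slot names to the TSV member
#'   names inside the zip archive.
#' @export
bundleMemberNames <- function() {
  c(geneCounts  = "GeneCountMatrix.tsv",
    txCounts    = "TxCountMatrix.tsv",
    geneInfo    = "GeneInfo.tsv",
    txInfo      = "TxInfo.tsv",
    qcMetrics   = "QC_summary.tsv",
    summaryMeta = "MetadataSummary.tsv",
    fullMeta    = "MetadataFull.tsv")
}

#' Construct a DatasetBundle
#'
#' @param geneCounts,txCounts Numeric matrices, features x runs, with run
#'   ids as column names and feature ids as row names.
#' @param geneInfo,txInfo Feature annotation data.frames (see
#'   \linkS4class{DatasetBundle}).
#' @param qcMetrics,summaryMeta,fullMeta Per-run tables whose first column
#'   \code{Run} matches the count-matrix run ids.
#' @param logs Named list (by run id) of log-line character vectors.
#' @return A \linkS4class{DatasetBundle}.
#' @export
datasetBundle <- function(geneCounts, txCounts, geneInfo, txInfo,
                          qcMetrics, summaryMeta, fullMeta, logs = list()) {
  new("DatasetBundle", geneCounts = geneCounts, txCounts = txCounts,
      geneInfo = geneInfo, txInfo = txInfo, qcMetrics = qcMetrics,
      summaryMeta = summaryMeta, fullMeta = fullMeta, logs = logs)
}

setMethod("show", "DatasetBundle", function(object) {
  cat(sprintf(
    "DatasetBundle: %d run%s, %d genes, %d transcripts, %d log%s\n",
    ncol(object@geneCounts), if (ncol(object@geneCounts) == 1L) "" else "s",
    nrow(object@geneCounts), nrow(object@txCounts),
    length(object@logs), if (length(object@logs) == 1L) "" else "s"))
})

# Full-precision numeric rendering so count matrices survive a round trip
# bit-exactly; integers render without an exponent.
.numToChr <- function(x) {
  out <- character(length(x))
  isInt <- !is.na(x) & x == round(x) & abs(x) < 2^53
  out[isInt] <- sprintf("%.0f", x[isInt])
  out[!isInt & !is.na(x)] <- sprintf("%.17g", x[!isInt & !is.na(x)])
  out[is.na(x)] <- "NA"
  out
}

.writeMatrixTsv <- function(m, path, idCol) {
  chr <- matrix(.numToChr(m), nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(id = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idCol
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readMatrixTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

.writeTableTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- .numToChr(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

.readTableTsv <- function(path, numeric = character(),
                          integer = character()) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (j in intersect(numeric, colnames(df)))
    df[[j]] <- as.numeric(df[[j]])
  for (j in intersect(integer, colnames(df)))
    df[[j]] <- as.integer(df[[j]])
  df
}

#' Write / read a DatasetBundle zip archive
#'
#' The archive contains the seven TSV tables (see [bundleMemberNames()])
#' plus one \code{logs/<run>.log} member per run. A written bundle read
#' back reproduces the original value for value: counts bit-exact, log text
#' verbatim. Missing QC metrics are written as \code{"NA"}.
#'
#' @param bundle A \linkS4class{DatasetBundle}.
#' @param path Output \code{.zip} path.
#' @param members Member-name mapping, defaulting to [bundleMemberNames()].
#' @return \code{writeBundle} invisibly returns \code{path};
#'   \code{readBundle} returns the reconstructed
#'   \linkS4class{DatasetBundle}.
#' @export
writeBundle <- function(bundle, path, members = bundleMemberNames()) {
  stopifnot(is(bundle, "DatasetBundle"))
  validObject(bundle)
  root <- tempfile("bundle")
  dir.create(root)
  on.exit(unlink(root, recursive = TRUE))
  .writeMatrixTsv(bundle@geneCounts, file.path(root, members[["geneCounts"]]),
                  "GeneID")
  .writeMatrixTsv(bundle@txCounts, file.path(root, members[["txCounts"]]),
                  "TxID")
  .writeTableTsv(bundle@geneInfo, file.path(root, members[["geneInfo"]]))
  .writeTableTsv(bundle@txInfo, file.path(root, members[["txInfo"]]))
  .writeTableTsv(bundle@qcMetrics, file.path(root, members[["qcMetrics"]]))
  .writeTableTsv(bundle@summaryMeta, file.path(root, members[["summaryMeta"]]))
  .writeTableTsv(bundle@fullMeta, file.path(root, members[["fullMeta"]]))
  files <- unname(members)
  if (length(bundle@logs)) {
    dir.create(file.path(root, "logs"))
    for (run in names(bundle@logs)) {
      lf <- file.path("logs", paste0(run, ".log"))
      writeLines(bundle@logs[[run]], file.path(root, lf))
      files <- c(files, lf)
    }
  }
  .zipCreate(path, files, root)
  invisible(path)
}

#' @rdname writeBundle
#' @export
readBundle <- function(path, members = bundleMemberNames()) {
  if (!file.exists(path))
    stop("bundle archive not found: ", path)
  root <- tempfile("bundle")
  dir.create(root)
  on.exit(unlink(root, recursive = TRUE))
  got <- utils::unzip(path, exdir = root)
  present <- substring(got, nchar(root) + 2L)
  missing <- setdiff(unname(members), present)
  if (length(missing))
    stop("bundle format error: missing member table(s): ",
         paste(missing, collapse = ", "))
  numericQc <- c("NumReadsQcPass", "QcPassRate", "STAR_UniqMapRate",
                 "STAR_AssignRate", "STAR_AssignedReads", "Kallisto_MapRate",
                 "Kallisto_MappedReads", "DatasetCorrel", "G")
  logFiles <- grep("^logs/.*\\.log$", present, value = TRUE)
  logs <- lapply(logFiles, function(f) readLines(file.path(root, f)))
  names(logs) <- sub("^logs/(.*)\\.log$", "\\1", logFiles)
  gi <- .readTableTsv(file.path(root, members[["geneInfo"]]),
                      integer = "GeneLength")
  ti <- .readTableTsv(file.path(root, members[["txInfo"]]),
                      integer = "TxLength")
  datasetBundle(
    geneCounts  = .readMatrixTsv(file.path(root, members[["geneCounts"]])),
    txCounts    = .readMatrixTsv(file.path(root, members[["txCounts"]])),
    geneInfo    = gi,
    txInfo      = ti,
    qcMetrics   = .readTableTsv(file.path(root, members[["qcMetrics"]]),
                                numeric = numericQc),
    summaryMeta = .readTableTsv(file.path(root, members[["summaryMeta"]]),
                                numeric = c("ReadLength", "Seed")),
    fullMeta    = .readTableTsv(file.path(root, members[["fullMeta"]])),
    logs        = logs[order(names(logs))]
  )
}
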
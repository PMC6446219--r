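# Per-run orchestration: QC -> adapter decision -> 5' clip optimization ->
# mapping -> counting -> strandedness -> classification -> bundle.

#' Run the full per-run processing pipeline
#'
#' Executes every stage on one run: quality-encoding detection (for file
#' input), 3' quality trimming, adapter inference and conditional clipping,
#' progressive 5'-clip optimization on a read sample, genomic mapping,
#' stranded gene counting, strandedness calling, transcript counting,
#' QC-metric computation and pass/warn/fail classification, and finally
#' assembly of a single-run \linkS4class{DatasetBundle} plus a structured
#' run log. Sampling stages use the file head (first \code{sampleChecks} /
#' \code{clipSample} reads), so the pipeline is fully deterministic for a
#' given input.
#'
#' @param input A \linkS4class{ReadBatch}, or the path to a FASTQ file
#'   (quality encoding auto-detected).
#' @param ref A \linkS4class{ToyReference}.
#' @param runId Run identifier used in tables and logs.
#' @param sampleChecks Reads sampled for encoding/adapter checks
#'   (default 4,000).
#' @param clipSample Reads sampled for 5'-clip optimization
#'   (default 10,000).
#' @param passAverage Optional [buildPassAverage()] result; enables the
#'   \code{DatasetCorrel} metric.
#' @param outZip Optional path; when given, the bundle is written there
#'   with [writeBundle()].
#' @param maxMismatch Mapper mismatch allowance (default 2).
#' @param seedLen Mapper seed length (default 18).
#' @return A list: \code{bundle} (\linkS4class{DatasetBundle}),
#'   \code{metrics} (\linkS4class{QcMetrics}), \code{classification}
#'   (\linkS4class{QcClassification}), \code{adapterCall},
#'   \code{clipResult}, \code{strandedness}, \code{mapSummary} and
#'   \code{log} (character lines).
#' @export
runPipeline <- function(input, ref, runId = "run1", sampleChecks = 4000L,
                        clipSample = 10000L, passAverage = NULL,
                        outZip = NULL, maxMismatch = 2L, seedLen = 18L) {
  logLines <- c(sprintf("run\t%s", runId))
  if (is.character(input)) {
    enc <- detectEncoding(input, nSample = sampleChecks)
    logLines <- c(logLines, sprintf("encoding\t%s", enc$name))
    batch <- readFastq(input, offset = enc$offset)
  } else {
    stopifnot(is(batch <- input, "ReadBatch"))
    logLines <- c(logLines, "encoding\tsanger_33")
  }
  nInput <- length(batch)
  logLines <- c(logLines, sprintf("reads_in\t%d", nInput))

  ## 3' quality trim + minimum length filter
  tr <- trimReads(batch)
  qcBatch <- tr$batch

  ## adapter inference on a sample, clip if the rule fires
  sampleN <- min(length(qcBatch), sampleChecks)
  adapterCall <- list(candidate = NULL, frequency = 0, inGenome = FALSE,
                      decision = "no_clip")
  if (sampleN >= 100L)
    adapterCall <- inferAdapter(qcBatch[seq_len(sampleN)], ref)
  logLines <- c(logLines,
    sprintf("adapter_candidate\t%s", adapterCall$candidate %||% "none"),
    sprintf("adapter_frequency\t%.6g", adapterCall$frequency),
    sprintf("adapter_decision\t%s", adapterCall$decision))
  if (adapterCall$decision == "clip") {
    cl <- clipAdapterReads(qcBatch, adapterCall$candidate)
    qcBatch <- cl$batch
    logLines <- c(logLines, sprintf("adapter_clipped_reads\t%d", cl$nClipped))
  }
  numReadsQcPass <- length(qcBatch)
  qcPassRate <- numReadsQcPass / nInput

  ## 5' clip optimization on a sample, then applied to all reads
  index <- buildMapperIndex(ref, seedLen = seedLen)
  clipN <- min(length(qcBatch), clipSample)
  clipResult <- optimizeFivePrimeClip(qcBatch[seq_len(clipN)], index,
                                      maxMismatch = maxMismatch)
  chosen <- clipResult$chosenClip
  logLines <- c(logLines, sprintf("fiveprime_clip\t%d", chosen))
  if (chosen > 0L) {
    keep <- width(qcBatch) >= chosen + 18L
    qcBatch <- qcBatch[keep]
    seqs <- Biostrings::subseq(sequences(qcBatch), start = chosen + 1L)
    quals <- IRanges::IntegerList(lapply(as.list(qualities(qcBatch)),
                                         function(q) q[-seq_len(chosen)]))
    qcBatch <- readBatch(seqs, quals, mate = qcBatch@mate)
  }

  ## genomic mapping and gene counting
  mapRes <- mapReads(qcBatch, index, maxMismatch = maxMismatch)
  gc <- countGenes(mapRes, ref)
  strandedness <- tryCatch(callStrandedness(gc),
                           error = function(e)
                             list(call = "unstranded", ratio = NA_real_))
  logLines <- c(logLines,
    sprintf("strandedness\t%s", strandedness$call),
    sprintf("strand_ratio\t%.4g", strandedness$ratio))

  ## transcript counting, strand-aware
  tx <- countTranscripts(qcBatch, ref, strandedness,
                         maxMismatch = maxMismatch, seedLen = seedLen)

  ## metrics + classification
  lens <- featureLengths(ref)
  correl <- NA_real_
  strandCol <- switch(strandedness$call, unstranded = "unstranded",
                      stranded_positive = "fwd", stranded_negative = "rev")
  geneVec <- geneCounts(gc)[, strandCol]
  if (!is.null(passAverage) && sum(geneVec) > 0)
    correl <- datasetCorrel(rpm(geneVec)[, 1L], passAverage)
  metrics <- qcMetrics(
    NumReadsQcPass = numReadsQcPass,
    QcPassRate = qcPassRate,
    STAR_UniqMapRate = mapRes$summary$uniqMapRate,
    STAR_AssignRate = assignRate(gc),
    STAR_AssignedReads = gc@nAssigned,
    Kallisto_MapRate = tx$mapRate,
    Kallisto_MappedReads = sum(tx$counts),
    G = length(geneIds(ref)),
    DatasetCorrel = correl)
  classification <- classifyQc(metrics)
  for (nm in slotNames(metrics))
    logLines <- c(logLines, sprintf("%s\t%s", nm,
                                    format(slot(metrics, nm), digits = 10)))
  logLines <- c(logLines,
    sprintf("status\t%s", qcStatus(classification)),
    sprintf("codes\t%s", paste(qcCodes(classification), collapse = ",")))

  ## single-run bundle
  qcRow <- data.frame(Run = runId, t(vapply(slotNames(metrics), function(nm)
    slot(metrics, nm), numeric(1))),
    Status = qcStatus(classification),
    Codes = paste(qcCodes(classification), collapse = ","),
    stringsAsFactors = FALSE, check.names = FALSE)
  readLen <- if (nInput) max(width(batch)) else NA_integer_
  layout <- if (all(mates(batch) == "single")) "SE" else "PE"
  bundle <- datasetBundle(
    geneCounts = matrix(as.double(geneVec), ncol = 1L,
                        dimnames = list(names(geneVec), runId)),
    txCounts = matrix(tx$counts, ncol = 1L,
                      dimnames = list(names(tx$counts), runId)),
    geneInfo = lens$geneInfo,
    txInfo = lens$txInfo,
    qcMetrics = qcRow,
    summaryMeta = data.frame(Run = runId, Layout = layout,
                             ReadLength = readLen, stringsAsFactors = FALSE),
    fullMeta = data.frame(Run = runId, Source = "deskseq pipeline",
                          stringsAsFactors = FALSE),
    logs = setNames(list(logLines), runId))
  if (!is.null(outZip))
    writeBundle(bundle, outZip)
  list(bundle = bundle, metrics = metrics, classification = classification,
       adapterCall = adapterCall, clipResult = clipResult,
       strandedness = strandedness, mapSummary = mapRes$summary,
       log = logLines)
}
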
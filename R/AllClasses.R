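#' @import methods
#' @importFrom S4Vectors metadata isSorted
#' @importFrom IRanges IRanges IntegerList
#' @importFrom GenomicRanges GRanges
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' ReadBatch: sequencing reads with per-base phred scores
#'
#' A batch of single-end or paired-end reads. Sequences are held as a
#' \link[Biostrings]{DNAStringSet}; qualities as an
#' \link[IRanges]{IntegerList} of decoded phred scores (always offset-free;
#' the quality encoding of a FASTQ file is resolved at read time).
#'
#' @slot sequences A \code{DNAStringSet}, one element per read.
#' @slot qualities An \code{IntegerList} of phred scores, parallel to
#'   \code{sequences} (same lengths, same per-read widths).
#' @slot mate Character vector: \code{"single"}, \code{"mate1"} or
#'   \code{"mate2"} per read.
#'
#' @seealso [readFastq()], [writeFastq()], [trimReads()]
#' @export
setClass("ReadBatch",
  representation(
    sequences = "DNAStringSet",
    qualities = "IntegerList",
    mate      = "character"
  )
)

setValidity("ReadBatch", function(object) {
  n <- length(object@sequences)
  if (length(object@qualities) != n)
    return("sequences and qualities must have equal length")
  if (length(object@mate) != n)
    return("mate must have one entry per read")
  if (n > 0L) {
    if (!all(BiocGenerics::width(object@sequences) ==
             lengths(object@qualities)))
      return("per-read sequence and quality lengths differ")
    qr <- range(unlist(object@qualities, use.names = FALSE), na.rm = TRUE)
    if (length(unlist(object@qualities)) && (qr[1L] < 0L || qr[2L] > 93L))
      return("phred scores must lie in [0, 93]")
    if (!all(object@mate %in% c("single", "mate1", "mate2")))
      return("mate must be 'single', 'mate1' or 'mate2'")
  }
  TRUE
})

#' ToyReference: a small genome with gene and transcript models
#'
#' Holds chromosome sequences and an exon-level annotation. Each exon row of
#' \code{exons} carries \code{gene_id}, \code{tx_id} and \code{symbol}
#' metadata columns; a gene's strand is the strand of its exons. Transcript
#' sequences are derived on demand with [transcriptSequences()].
#'
#' @slot genome A named \code{DNAStringSet} of chromosome sequences.
#' @slot exons A \code{GRanges} of exons with \code{gene_id}, \code{tx_id}
#'   and \code{symbol} metadata columns.
#' @slot refmeta List of free-form metadata (e.g. the adapter sequence a
#'   simulation guaranteed absent from the genome).
#'
#' @seealso [simulateReference()], [readGtf()], [featureLengths()]
#' @export
setClass("ToyReference",
  representation(
    genome  = "DNAStringSet",
    exons   = "GRanges",
    refmeta = "list"
  )
)

setValidity("ToyReference", function(object) {
  if (length(object@genome) == 0L)
    return("genome must contain at least one chromosome")
  if (is.null(names(object@genome)) || anyDuplicated(names(object@genome)))
    return("chromosomes must be uniquely named")
  mc <- S4Vectors::mcols(object@exons)
  need <- c("gene_id", "tx_id", "symbol")
  if (length(object@exons) && !all(need %in% colnames(mc)))
    return("exons must carry gene_id, tx_id and symbol metadata columns")
  if (length(object@exons)) {
    chr <- as.character(GenomeInfoDb::seqnames(object@exons))
    if (!all(chr %in% names(object@genome)))
      return("exon seqnames must name genome chromosomes")
    ends <- BiocGenerics::end(object@exons)
    lim <- BiocGenerics::width(object@genome)[match(chr, names(object@genome))]
    if (any(ends > lim) || any(BiocGenerics::start(object@exons) < 1L))
      return("exons must lie within their chromosome")
  }
  TRUE
})

#' GeneCountsTable: stranded gene-count triple
#'
#' Per-gene counts under the three assignment conventions of STAR-style
#' \code{GeneCounts} output: unstranded, forward-stranded (read strand equal
#' to gene strand) and reverse-stranded. Only uniquely mapped reads
#' overlapping exactly one gene's exon union are counted.
#'
#' @slot counts Integer matrix, genes in rows, columns
#'   \code{c("unstranded", "fwd", "rev")}.
#' @slot nInput Number of reads given to the mapper.
#' @slot nAssigned Number of reads assigned to exactly one gene.
#'
#' @seealso [countGenes()], [callStrandedness()]
#' @export
setClass("GeneCountsTable",
  representation(
    counts    = "matrix",
    nInput    = "integer",
    nAssigned = "integer"
  )
)

setValidity("GeneCountsTable", function(object) {
  if (!identical(colnames(object@counts), c("unstranded", "fwd", "rev")))
    return("counts columns must be unstranded, fwd, rev")
  if (any(object@counts < 0L))
    return("counts must be non-negative")
  if (object@nAssigned > object@nInput)
    return("nAssigned cannot exceed nInput")
  TRUE
})

#' QcMetrics: the per-run quality metric set
#'
#' The eight metrics the quality-classification engine consumes, plus the
#' transcriptome complexity estimator \code{G} (number of protein-coding
#' genes in the reference; for toy references every gene counts).
#' \code{DatasetCorrel} may be \code{NA} when no pass-average profile is
#' available, in which case the correlation rule is skipped.
#'
#' @slot NumReadsQcPass Reads that passed QC filtering.
#' @slot QcPassRate Proportion of input reads passing QC, in [0, 1].
#' @slot STAR_UniqMapRate Proportion of reads mapped uniquely to the genome.
#' @slot STAR_AssignRate Proportion of reads assigned to genes.
#' @slot STAR_AssignedReads Number of reads assigned to genes.
#' @slot Kallisto_MapRate Proportion of reads assigned to transcripts.
#' @slot Kallisto_MappedReads Number of reads assigned to transcripts (may be
#'   fractional under uniform splitting).
#' @slot DatasetCorrel Pearson correlation to the pass-average profile,
#'   rounded to 2 significant figures, or \code{NA}.
#' @slot G Number of (protein-coding) genes in the reference annotation.
#'
#' @seealso [qcMetrics()], [classifyQc()]
#' @export
setClass("QcMetrics",
  representation(
    NumReadsQcPass       = "numeric",
    QcPassRate           = "numeric",
    STAR_UniqMapRate     = "numeric",
    STAR_AssignRate      = "numeric",
    STAR_AssignedReads   = "numeric",
    Kallisto_MapRate     = "numeric",
    Kallisto_MappedReads = "numeric",
    DatasetCorrel        = "numeric",
    G                    = "numeric"
  )
)

setValidity("QcMetrics", function(object) {
  rates <- c(object@QcPassRate, object@STAR_UniqMapRate,
             object@STAR_AssignRate, object@Kallisto_MapRate)
  if (any(rates < 0 | rates > 1))
    return("rates must lie in [0, 1]")
  counts <- c(object@NumReadsQcPass, object@STAR_AssignedReads,
              object@Kallisto_MappedReads)
  if (any(counts < 0))
    return("counts must be non-negative")
  if (object@G < 1)
    return("G must be at least 1")
  if (!is.na(object@DatasetCorrel) &&
      (object@DatasetCorrel < -1 || object@DatasetCorrel > 1))
    return("DatasetCorrel must lie in [-1, 1] or be NA")
  TRUE
})

#' QcClassification: pass/warn/fail status with rule codes
#'
#' @slot status One of \code{"pass"}, \code{"warn"}, \code{"fail"}.
#' @slot codes Integer codes (subset of 1..8) of the triggered rules.
#' @slot levels Named character vector, \code{"warn"} or \code{"fail"} per
#'   triggered code.
#'
#' @seealso [classifyQc()]
#' @export
setClass("QcClassification",
  representation(
    status = "character",
    codes  = "integer",
    levels = "character"
  )
)

setValidity("QcClassification", function(object) {
  if (!object@status %in% c("pass", "warn", "fail"))
    return("status must be pass, warn or fail")
  if (length(object@codes) && !all(object@codes %in% 1:8))
    return("codes must be in 1..8")
  if (length(object@levels) != length(object@codes))
    return("levels must be parallel to codes")
  anyFail <- any(object@levels == "fail")
  want <- if (anyFail) "fail" else if (length(object@codes)) "warn" else "pass"
  if (!identical(object@status, want))
    return("status inconsistent with triggered codes")
  TRUE
})

#' DatasetBundle: the seven-table per-project archive
#'
#' The distribution unit of the pipeline: gene counts, transcript counts,
#' gene info, transcript info, QC metrics, summary and full metadata as
#' seven TSV tables plus per-run processing logs, packaged as a zip archive.
#' Count matrices hold features in rows and runs in columns.
#'
#' @slot geneCounts Numeric matrix, genes x runs.
#' @slot txCounts Numeric matrix, transcripts x runs.
#' @slot geneInfo data.frame with columns \code{GeneID}, \code{GeneSymbol},
#'   \code{GeneLength}; covers every row of \code{geneCounts}.
#' @slot txInfo data.frame with columns \code{TxID}, \code{GeneID},
#'   \code{GeneSymbol}, \code{TxLength}.
#' @slot qcMetrics data.frame, one row per run (column \code{Run} first).
#' @slot summaryMeta data.frame of key run metadata, one row per run.
#' @slot fullMeta data.frame of extended run metadata, one row per run.
#' @slot logs Named list of per-run log text (character vectors of lines).
#'
#' @seealso [datasetBundle()], [writeBundle()], [readBundle()]
#' @export
setClass("DatasetBundle",
  representation(
    geneCounts  = "matrix",
    txCounts    = "matrix",
    geneInfo    = "data.frame",
    txInfo      = "data.frame",
    qcMetrics   = "data.frame",
    summaryMeta = "data.frame",
    fullMeta    = "data.frame",
    logs        = "list"
  )
)

setValidity("DatasetBundle", function(object) {
  runs <- colnames(object@geneCounts)
  if (is.null(runs))
    return("geneCounts must have run identifiers as column names")
  for (nm in c("txCounts")) {
    if (!identical(colnames(slot(object, nm)), runs))
      return(sprintf("%s run identifiers disagree with geneCounts", nm))
  }
  for (nm in c("qcMetrics", "summaryMeta", "fullMeta")) {
    tab <- slot(object, nm)
    if (!"Run" %in% colnames(tab) || !identical(tab$Run, runs))
      return(sprintf("%s must have a Run column matching geneCounts", nm))
  }
  if (any(object@geneCounts < 0) || any(object@txCounts < 0))
    return("counts must be non-negative")
  if (!all(rownames(object@geneCounts) %in% object@geneInfo$GeneID))
    return("geneInfo must cover every gene in geneCounts")
  if (length(object@logs) && !all(names(object@logs) %in% runs))
    return("log names must be run identifiers")
  TRUE
})

#' MapperIndex: exact-seed k-mer index over a toy genome
#'
#' Positions of every \code{seedLen}-mer of the (plus strand of the)
#' concatenated genome, stored in a hashed environment. Reads are looked up
#' in both orientations so both strands are covered.
#'
#' @slot kmers Environment mapping k-mer strings to global start offsets.
#' @slot genomeStr The concatenated genome as a single character string.
#' @slot chromNames,chromOffsets,chromLengths Per-chromosome bookkeeping for
#'   converting global offsets back to chromosome coordinates.
#' @slot seedLen Seed length in bases.
#'
#' @seealso [buildMapperIndex()], [mapReads()]
#' @export
setClass("MapperIndex",
  representation(
    kmers        = "environment",
    genomeStr    = "character",
    chromNames   = "character",
    chromOffsets = "integer",
    chromLengths = "integer",
    seedLen      = "integer"
  )
)
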
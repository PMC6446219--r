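# Expression-matrix algebra: transcript-to-gene aggregation, RPM
# normalization, and feature-length computation for length normalization.
# Matrices hold features in rows and runs in columns.

#' Aggregate transcript counts to gene level
#'
#' Sums the rows of a transcript-level count matrix into their parent
#' genes. Column totals are conserved exactly.
#'
#' @param txMat Numeric matrix, transcripts x runs, with transcript ids as
#'   row names.
#' @param txToGene Named character vector mapping transcript id to parent
#'   gene id (e.g. from [featureLengths()]'s \code{txInfo}), or a
#'   data.frame with columns \code{TxID} and \code{GeneID}.
#' @return Numeric matrix, genes x runs.
#' @export
tx2gene <- function(txMat, txToGene) {
  if (is.data.frame(txToGene))
    txToGene <- setNames(txToGene$GeneID, txToGene$TxID)
  if (is.null(dim(txMat)))
    txMat <- matrix(txMat, ncol = 1L, dimnames = list(names(txMat), "run1"))
  orphans <- setdiff(rownames(txMat), names(txToGene))
  if (length(orphans))
    stop("transcripts without a parent gene: ",
         paste(orphans, collapse = ", "))
  grp <- txToGene[rownames(txMat)]
  rowsum(txMat, group = grp, reorder = TRUE)
}

#' Reads-per-million normalization
#'
#' Scales each column so it sums to 1e6. Idempotent, and invariant to
#' uniform scaling of a column's raw counts.
#'
#' @param m Numeric matrix, features x runs, all column sums > 0.
#' @return The RPM matrix.
#' @export
rpm <- function(m) {
  if (is.null(dim(m)))
    m <- matrix(m, ncol = 1L, dimnames = list(names(m), "run1"))
  cs <- colSums(m)
  bad <- which(cs <= 0)
  if (length(bad))
    stop("zero-sum column(s): ",
         paste(colnames(m)[bad] %||% bad, collapse = ", "))
  sweep(m, 2L, cs, "/") * 1e6
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene and transcript lengths from exon models
#'
#' Transcript length is the sum of its exon lengths; gene length is the
#' size of the union of all its transcripts' exon intervals (the
#' merged-exon gene length used for length normalization).
#'
#' @param ref A \linkS4class{ToyReference}.
#' @return A list of two data.frames: \code{geneInfo} (\code{GeneID},
#'   \code{GeneSymbol}, \code{GeneLength}) and \code{txInfo} (\code{TxID},
#'   \code{GeneID}, \code{GeneSymbol}, \code{TxLength}).
#' @export
featureLengths <- function(ref) {
  ex <- exons(ref)
  if (length(ex) == 0L)
    stop("reference has no exons")
  mc <- S4Vectors::mcols(ex)
  counts <- table(mc$gene_id)
  grl <- exonsByGene(ref)
  geneLen <- sum(BiocGenerics::width(grl))
  if (any(geneLen == 0L))
    stop("gene(s) with no exons: ",
         paste(names(geneLen)[geneLen == 0L], collapse = ", "))
  sym <- vapply(split(mc$symbol, mc$gene_id), `[`, character(1), 1L)
  txl <- exonsByTx(ref)
  txLen <- sum(BiocGenerics::width(txl))
  parents <- txParents(ref)
  list(
    geneInfo = data.frame(
      GeneID = names(geneLen), GeneSymbol = unname(sym[names(geneLen)]),
      GeneLength = as.integer(geneLen), stringsAsFactors = FALSE),
    txInfo = data.frame(
      TxID = names(txLen), GeneID = unname(parents[names(txLen)]),
      GeneSymbol = unname(sym[parents[names(txLen)]]),
      TxLength = as.integer(txLen), stringsAsFactors = FALSE)
  )
}
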
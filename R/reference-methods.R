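#' Construct a ToyReference
#'
#' @param genome Named \code{DNAStringSet} of chromosome sequences.
#' @param exons \code{GRanges} of exons with \code{gene_id}, \code{tx_id},
#'   \code{symbol} metadata columns.
#' @param refmeta Optional metadata list.
#' @return A \linkS4class{ToyReference}.
#' @export
toyReference <- function(genome, exons, refmeta = list()) {
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  new("ToyReference", genome = genome, exons = exons, refmeta = refmeta)
}

#' @rdname ToyReference-class
#' @export
setMethod("genome", "ToyReference", function(x) x@genome)

#' @rdname ToyReference-class
#' @export
setMethod("exons", "ToyReference", function(x) x@exons)

#' @rdname ToyReference-class
#' @export
setMethod("geneIds", "ToyReference", function(x)
  unique(S4Vectors::mcols(x@exons)$gene_id))

#' @rdname ToyReference-class
#' @export
setMethod("txIds", "ToyReference", function(x)
  unique(S4Vectors::mcols(x@exons)$tx_id))

#' @rdname ToyReference-class
#' @export
setMethod("length", "ToyReference", function(x) length(geneIds(x)))

setMethod("show", "ToyReference", function(object) {
  cat(sprintf(
    "ToyReference: %d chromosome%s (%s bp), %d genes, %d transcripts\n",
    length(object@genome), if (length(object@genome) == 1L) "" else "s",
    format(sum(BiocGenerics::width(object@genome)), big.mark = ","),
    length(geneIds(object)), length(txIds(object))))
})

#' Exons grouped by gene or transcript
#'
#' @param x A \linkS4class{ToyReference}.
#' @return A \code{GRangesList}, one element per gene (exon union reduced)
#'   or per transcript (exons in transcription order).
#' @export
exonsByGene <- function(x) {
  GenomicRanges::reduce(
    GenomicRanges::split(x@exons, S4Vectors::mcols(x@exons)$gene_id))
}

#' @rdname exonsByGene
#' @export
exonsByTx <- function(x) {
  grl <- GenomicRanges::split(x@exons, S4Vectors::mcols(x@exons)$tx_id)
  GenomicRanges::sort(grl)
}

#' Strand of each gene / transcript
#' @param x A \linkS4class{ToyReference}.
#' @return Named character vector of strands.
#' @export
geneStrands <- function(x) {
  mc <- S4Vectors::mcols(x@exons)
  st <- as.character(BiocGenerics::strand(x@exons))
  vapply(split(st, mc$gene_id), function(s) s[1L], character(1))
}

txParents <- function(x) {
  mc <- S4Vectors::mcols(x@exons)
  vapply(split(mc$gene_id, mc$tx_id), function(g) g[1L], character(1))
}

#' @rdname ToyReference-class
#' @details \code{transcriptSequences} splices each transcript's exon
#'   sequences in genomic order, reverse-complementing minus-strand
#'   transcripts, mirroring how cDNA references are built from a genome and
#'   its annotation.
#' @export
setMethod("transcriptSequences", "ToyReference", function(x) {
  grl <- exonsByTx(x)
  seqs <- vapply(names(grl), function(tx) {
    gr <- grl[[tx]]
    chr <- as.character(GenomeInfoDb::seqnames(gr))[1L]
    pieces <- Biostrings::extractAt(
      x@genome[[chr]],
      IRanges::IRanges(BiocGenerics::start(gr), BiocGenerics::end(gr)))
    s <- unlist(pieces)
    if (as.character(BiocGenerics::strand(gr))[1L] == "-")
      s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  Biostrings::DNAStringSet(seqs)
})
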
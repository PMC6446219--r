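#' Read / write FASTA genomes
#'
#' Thin wrappers over Biostrings keeping all file I/O in one place.
#'
#' @param path FASTA file (gzip accepted on read).
#' @return \code{readFasta} returns a named \code{DNAStringSet}.
#' @export
readFasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("[ \t].*$", "", names(x))
  x
}

#' @rdname readFasta
#' @param seqs Named \code{DNAStringSet}.
#' @export
writeFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a GTF-style annotation into an exon GRanges
#'
#' Imports a GTF (1-based inclusive coordinates, per the standard), keeps
#' \code{exon} features, and returns a \code{GRanges} carrying
#' \code{gene_id}, \code{tx_id} and \code{symbol} metadata columns, the
#' exon-level representation every other component consumes. Exon order in
#' the file is irrelevant.
#'
#' @param path GTF file.
#' @return \code{GRanges} of exons.
#' @export
readGtf <- function(path) {
  if (!file.exists(path))
    stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id) || anyNA(mc$gene_id) ||
      is.null(mc$transcript_id) || anyNA(mc$transcript_id))
    stop("GTF parse error: exon feature lacking gene_id/transcript_id attributes")
  sym <- if (!is.null(mc$gene_name)) mc$gene_name else mc$gene_id
  out <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(gr),
    IRanges::IRanges(BiocGenerics::start(gr), BiocGenerics::end(gr)),
    strand = BiocGenerics::strand(gr))
  S4Vectors::mcols(out)$gene_id <- as.character(mc$gene_id)
  S4Vectors::mcols(out)$tx_id <- as.character(mc$transcript_id)
  S4Vectors::mcols(out)$symbol <- as.character(sym)
  BiocGenerics::sort(out)
}

#' @rdname readGtf
#' @param exons Exon \code{GRanges} as returned by [readGtf()] or held in a
#'   \linkS4class{ToyReference}.
#' @export
writeGtf <- function(exons, path) {
  gr <- exons
  mc <- S4Vectors::mcols(gr)
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$source <- "deskseq"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- mc$gene_id
  S4Vectors::mcols(gr)$transcript_id <- mc$tx_id
  S4Vectors::mcols(gr)$gene_name <- mc$symbol
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Load a reference from FASTA + GTF files
#'
#' @param fastaPath Genome FASTA.
#' @param gtfPath Annotation GTF.
#' @return A \linkS4class{ToyReference}.
#' @export
readReference <- function(fastaPath, gtfPath) {
  toyReference(readFasta(fastaPath), readGtf(gtfPath))
}

#' Write a reference to disk
#'
#' Emits \code{genome.fa}, \code{annotation.gtf} and \code{transcripts.fa}
#' under \code{dir}.
#'
#' @param ref A \linkS4class{ToyReference}.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
writeReference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "annotation.gtf"),
             tx = file.path(dir, "transcripts.fa"))
  writeFasta(genome(ref), paths[["genome"]])
  writeGtf(exons(ref), paths[["gtf"]])
  writeFasta(transcriptSequences(ref), paths[["tx"]])
  invisible(paths)
}
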
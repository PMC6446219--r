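#' @rdname ReadBatch-class
#' @importFrom BiocGenerics width strand start end
#' @export width
NULL

#' @rdname ReadBatch-class
#' @param object,x A \code{ReadBatch}.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname ReadBatch-class
#' @export
setGeneric("qualities", function(x) standardGeneric("qualities"))

#' @rdname ReadBatch-class
#' @export
setGeneric("mates", function(x) standardGeneric("mates"))

#' @rdname ToyReference-class
#' @importFrom GenomeInfoDb genome
#' @export genome
NULL

#' @rdname ToyReference-class
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname ToyReference-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ToyReference-class
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))

#' @rdname ToyReference-class
#' @export
setGeneric("transcriptSequences", function(x) standardGeneric("transcriptSequences"))

#' @rdname GeneCountsTable-class
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))

#' @rdname QcClassification-class
#' @export
setGeneric("qcStatus", function(x) standardGeneric("qcStatus"))

#' @rdname QcClassification-class
#' @export
setGeneric("qcCodes", function(x) standardGeneric("qcCodes"))
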
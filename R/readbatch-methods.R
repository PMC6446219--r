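#' Construct a ReadBatch
#'
#' @param sequences A \code{DNAStringSet} (or character vector) of read
#'   sequences, ideally named by read id.
#' @param qualities An \code{IntegerList} (or list of integer vectors) of
#'   phred scores parallel to \code{sequences}.
#' @param mate Per-read mate tag; recycled if scalar.
#' @return A \linkS4class{ReadBatch}.
#' @examples
#' rb <- readBatch(c(r1 = "ACGT"), list(c(30L, 30L, 30L, 30L)))
#' length(rb)
#' @export
readBatch <- function(sequences, qualities, mate = "single") {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (!is(qualities, "IntegerList"))
    qualities <- IRanges::IntegerList(lapply(qualities, as.integer))
  if (length(mate) == 1L)
    mate <- rep(mate, length(sequences))
  new("ReadBatch", sequences = sequences, qualities = qualities,
      mate = as.character(mate))
}

#' @rdname ReadBatch-class
#' @export
setMethod("sequences", "ReadBatch", function(x) x@sequences)

#' @rdname ReadBatch-class
#' @export
setMethod("qualities", "ReadBatch", function(x) x@qualities)

#' @rdname ReadBatch-class
#' @export
setMethod("mates", "ReadBatch", function(x) x@mate)

#' @rdname ReadBatch-class
#' @export
setMethod("length", "ReadBatch", function(x) length(x@sequences))

#' @rdname ReadBatch-class
#' @export
setMethod("names", "ReadBatch", function(x) names(x@sequences))

#' @rdname ReadBatch-class
#' @export
setMethod("width", "ReadBatch", function(x) BiocGenerics::width(x@sequences))

#' @rdname ReadBatch-class
#' @param i Index.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "ReadBatch", function(x, i, j, ..., drop = TRUE) {
  initialize(x, sequences = x@sequences[i], qualities = x@qualities[i],
             mate = x@mate[i])
})

setMethod("show", "ReadBatch", function(object) {
  n <- length(object)
  w <- if (n) range(width(object)) else c(0L, 0L)
  cat(sprintf("ReadBatch of %d read%s", n, if (n == 1L) "" else "s"))
  if (n) {
    lay <- if (all(object@mate == "single")) "single-end" else "paired-end"
    cat(sprintf(" (%s, widths %d..%d)", lay, w[1L], w[2L]))
  }
  cat("\n")
})

#' @rdname ReadBatch-class
#' @export
setMethod("c", "ReadBatch", function(x, ...) {
  args <- c(list(x), list(...))
  new("ReadBatch",
      sequences = do.call(c, lapply(args, slot, "sequences")),
      qualities = do.call(c, lapply(args, slot, "qualities")),
      mate      = do.call(c, lapply(args, slot, "mate")))
})
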
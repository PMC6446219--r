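# Minimal exact-seed read mapper over the toy reference. Deliberately
# simple: an exact 5'-anchored seed, full-length extension allowing a few
# mismatches, unique/multi/unmapped calls. The bespoke pipeline logic
# (clip optimization, strandedness, QC) needs only these mapping outcomes;
# toy references are built so reads do not span splice junctions.

#' Build an exact-seed k-mer index over a reference genome
#'
#' @param ref A \linkS4class{ToyReference} or a named \code{DNAStringSet}.
#' @param seedLen Seed length in bases (default 18).
#' @return A \linkS4class{MapperIndex}.
#' @export
buildMapperIndex <- function(ref, seedLen = 18L) {
  genomeSeqs <- if (is(ref, "ToyReference")) genome(ref) else ref
  if (length(genomeSeqs) == 0L || sum(BiocGenerics::width(genomeSeqs)) == 0L)
    stop("empty genome")
  seedLen <- as.integer(seedLen)
  lens <- BiocGenerics::width(genomeSeqs)
  if (seedLen > min(lens))
    stop("seedLen exceeds the shortest chromosome")
  chromStr <- as.character(genomeSeqs)
  genomeStr <- paste(chromStr, collapse = "")
  offsets <- as.integer(cumsum(c(0L, lens[-length(lens)])))
  kmers <- new.env(hash = TRUE, parent = emptyenv(),
                   size = sum(lens))
  for (i in seq_along(chromStr)) {
    L <- lens[i]
    if (L < seedLen) next
    starts <- seq_len(L - seedLen + 1L)
    km <- substring(chromStr[i], starts, starts + seedLen - 1L)
    glob <- starts + offsets[i]
    byk <- split(glob, km)
    for (k in names(byk)) {
      prev <- kmers[[k]]
      kmers[[k]] <- if (is.null(prev)) byk[[k]] else c(prev, byk[[k]])
    }
  }
  new("MapperIndex", kmers = kmers, genomeStr = genomeStr,
      chromNames = names(genomeSeqs), chromOffsets = offsets,
      chromLengths = as.integer(lens), seedLen = seedLen)
}

setMethod("show", "MapperIndex", function(object) {
  cat(sprintf("MapperIndex: %d chromosome%s, %s bp, seed length %d\n",
              length(object@chromNames),
              if (length(object@chromNames) == 1L) "" else "s",
              format(nchar(object@genomeStr), big.mark = ","),
              object@seedLen))
})

# Candidate alignment windows for a set of oriented read strings. Seeds
# are taken from the 5' end of the oriented read; reads whose primary seed
# finds nothing fall back to a secondary seed offset by seedLen (window
# shifted back accordingly), so a single substitution in the seed region
# does not disqualify an otherwise mappable read. Full-length extension
# still counts every mismatch, so unclipped 5' extras fail extension.
.seedCandidates <- function(fwd, rev, w, index) {
  sl <- index@seedLen
  eligible <- which(w >= sl)
  empty <- data.frame(read = integer(0), gpos = integer(0),
                      orient = character(0), stringsAsFactors = FALSE)
  if (length(eligible) == 0L) return(empty)
  lookup <- function(keys) mget(keys, envir = index@kmers,
                                ifnotfound = list(NULL))
  tier <- function(reads, oriented, offsets) {
    keep <- w[reads] >= offsets + sl
    ok <- reads[keep]
    offs <- offsets[keep]
    if (length(ok) == 0L) return(empty)
    seeds <- substring(oriented[ok], offs + 1L, offs + sl)
    hits <- lookup(seeds)
    nh <- lengths(hits)
    data.frame(read = rep(ok, nh),
               gpos = unlist(hits, use.names = FALSE) - rep(offs, nh),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (orient in c("F", "R")) {
    oriented <- if (orient == "F") fwd else rev
    t1 <- tier(eligible, oriented, rep(0L, length(eligible)))
    missed <- setdiff(eligible, unique(t1$read))
    t2 <- tier(missed, oriented, rep(sl, length(missed)))
    missed2 <- setdiff(missed, unique(t2$read))
    # last resort: a seed anchored at the 3' end; together the three
    # windows guarantee any single-substitution read keeps one clean seed
    t3 <- tier(missed2, oriented, pmax(0L, w[missed2] - sl))
    tt <- rbind(t1, t2, t3)
    if (nrow(tt)) tt$orient <- orient
    out[[orient]] <- tt
  }
  res <- do.call(rbind, out)
  res[res$gpos >= 1L, , drop = FALSE]
}

# Map a DNAStringSet against the index. Each read is seeded from its 5'
# end in both orientations; candidate loci are extended full-length and
# kept at <= maxMismatch mismatches. Returns per-read status plus a
# GRanges of the unique alignments (strand = strand of the genome the read
# sequence matches).
#' @rdname mapReads
#' @export
mapSequences <- function(seqs, index, maxMismatch = 2L) {
  n <- length(seqs)
  status <- rep("unmapped", n)
  w <- BiocGenerics::width(seqs)
  fwd <- as.character(seqs)
  rev <- as.character(Biostrings::reverseComplement(seqs))
  cand <- .seedCandidates(fwd, rev, w, index)
  uniqueGr <- GenomicRanges::GRanges()
  if (nrow(cand)) {
    # the seed anchors the oriented read's 5' end, so the alignment window
    # is [gpos, gpos + w - 1] in both orientations
    rw <- w[cand$read]
    cand$gend <- cand$gpos + rw - 1L
    # reject windows that leave the genome or cross a chromosome boundary
    chromIdx <- findInterval(cand$gpos, index@chromOffsets + 1L)
    lim <- index@chromOffsets[chromIdx] + index@chromLengths[chromIdx]
    keep <- cand$gend <= lim & cand$gend <= nchar(index@genomeStr)
    cand <- cand[keep, , drop = FALSE]
    chromIdx <- chromIdx[keep]
    if (nrow(cand)) {
      win <- substring(index@genomeStr, cand$gpos, cand$gend)
      readStr <- ifelse(cand$orient == "F", fwd[cand$read], rev[cand$read])
      mm <- .hamming(readStr, win)
      ok <- mm <= maxMismatch
      cand <- cand[ok, , drop = FALSE]
      chromIdx <- chromIdx[ok]
      if (nrow(cand)) {
        key <- paste(cand$read, cand$gpos, cand$orient)
        dup <- duplicated(key)
        cand <- cand[!dup, , drop = FALSE]
        chromIdx <- chromIdx[!dup]
        nHits <- table(cand$read)
        nh <- as.integer(nHits[as.character(cand$read)])
        status[as.integer(names(nHits))] <-
          ifelse(nHits == 1L, "unique", "multi")
        uniq <- which(nh == 1L)
        if (length(uniq)) {
          u <- cand[uniq, , drop = FALSE]
          ci <- chromIdx[uniq]
          localStart <- u$gpos - index@chromOffsets[ci]
          uniqueGr <- GenomicRanges::GRanges(
            index@chromNames[ci],
            IRanges::IRanges(localStart, width = w[u$read]),
            strand = ifelse(u$orient == "F", "+", "-"))
          S4Vectors::mcols(uniqueGr)$read <- u$read
        }
      }
    }
  }
  nUnique <- sum(status == "unique")
  nMulti <- sum(status == "multi")
  list(
    status = status,
    alignments = uniqueGr,
    summary = list(nInput = n, nUnique = nUnique, nMulti = nMulti,
                   nUnmapped = n - nUnique - nMulti,
                   uniqMapRate = if (n) nUnique / n else NA_real_)
  )
}

#' Map reads and summarize unique/multi/unmapped outcomes
#'
#' @param batch A \linkS4class{ReadBatch} (or, for \code{mapSequences}, a
#'   bare \code{DNAStringSet}).
#' @param index A \linkS4class{MapperIndex}.
#' @param maxMismatch Maximum mismatches in the full-length extension
#'   (default 2).
#' @param seqs A \code{DNAStringSet}.
#' @return A list: \code{status} (per-read \code{"unique"}/\code{"multi"}/
#'   \code{"unmapped"}), \code{alignments} (a \code{GRanges} of unique
#'   alignments with a \code{read} index column) and \code{summary}
#'   (\code{nInput}, \code{nUnique}, \code{nMulti}, \code{nUnmapped},
#'   \code{uniqMapRate}); the three outcome counts always partition
#'   \code{nInput}.
#' @export
mapReads <- function(batch, index, maxMismatch = 2L) {
  mapSequences(sequences(batch), index, maxMismatch = maxMismatch)
}

#' Count uniquely mapped reads per gene, stranded three ways
#'
#' Emulates STAR's \code{--quantMode GeneCounts} layout: a unique alignment
#' overlapping the exon union of exactly one gene increments that gene's
#' \code{unstranded} column always, its \code{fwd} column when the read
#' strand equals the gene strand, and its \code{rev} column otherwise.
#' Alignments overlapping zero or several genes are unassigned;
#' multi-mappers are never assigned.
#'
#' @param mapResult Result of [mapReads()].
#' @param ref A \linkS4class{ToyReference}.
#' @return A \linkS4class{GeneCountsTable}.
#' @export
countGenes <- function(mapResult, ref) {
  grl <- exonsByGene(ref)
  gids <- names(grl)
  counts <- matrix(0L, nrow = length(gids), ncol = 3L,
                   dimnames = list(gids, c("unstranded", "fwd", "rev")))
  aln <- mapResult$alignments
  nAssigned <- 0L
  if (length(aln)) {
    ov <- GenomicRanges::findOverlaps(aln, grl, ignore.strand = TRUE)
    nGenesHit <- table(S4Vectors::queryHits(ov))
    okReads <- as.integer(names(nGenesHit)[nGenesHit == 1L])
    ov <- ov[S4Vectors::queryHits(ov) %in% okReads]
    if (length(ov)) {
      gIdx <- S4Vectors::subjectHits(ov)
      readStrand <- as.character(BiocGenerics::strand(aln))[
        S4Vectors::queryHits(ov)]
      gStrand <- geneStrands(ref)[gids[gIdx]]
      same <- readStrand == gStrand
      for (col in c("unstranded", "fwd", "rev")) {
        sel <- switch(col, unstranded = rep(TRUE, length(gIdx)),
                      fwd = same, rev = !same)
        if (any(sel)) {
          tab <- table(gIdx[sel])
          counts[as.integer(names(tab)), col] <-
            counts[as.integer(names(tab)), col] + as.integer(tab)
        }
      }
      nAssigned <- length(ov)
    }
  }
  new("GeneCountsTable", counts = counts,
      nInput = as.integer(mapResult$summary$nInput),
      nAssigned = as.integer(nAssigned))
}

#' @rdname GeneCountsTable-class
#' @export
setMethod("geneCounts", "GeneCountsTable", function(x) x@counts)

#' @rdname GeneCountsTable-class
#' @param object A \code{GeneCountsTable}.
#' @export
assignRate <- function(object) {
  if (object@nInput == 0L) return(NA_real_)
  object@nAssigned / object@nInput
}

setMethod("show", "GeneCountsTable", function(object) {
  cat(sprintf(
    "GeneCountsTable: %d genes; %d/%d reads assigned (rate %.3f)\n",
    nrow(object@counts), object@nAssigned, object@nInput,
    assignRate(object)))
  tot <- colSums(object@counts)
  cat(sprintf("  totals: unstranded %d, fwd %d, rev %d\n",
              tot[1L], tot[2L], tot[3L]))
})

#' Call library strandedness from stranded gene counts
#'
#' A library is called strand-specific when the assigned reads show at
#' least a 5:1 bias between the forward-stranded and reverse-stranded
#' totals (the boundary is inclusive: a ratio of exactly 5 is called
#' stranded).
#'
#' @param gc A \linkS4class{GeneCountsTable}.
#' @param ratioThreshold Bias threshold (default 5).
#' @return A list: \code{call} (\code{"unstranded"},
#'   \code{"stranded_positive"} or \code{"stranded_negative"}) and
#'   \code{ratio} (max total over min total, with a floor of 1 on the
#'   denominator).
#' @export
callStrandedness <- function(gc, ratioThreshold = 5) {
  tot <- colSums(gc@counts)
  fwdTotal <- tot[["fwd"]]
  revTotal <- tot[["rev"]]
  if (fwdTotal + revTotal == 0)
    stop("no assigned reads: strandedness cannot be called")
  ratio <- max(fwdTotal, revTotal) / max(1, min(fwdTotal, revTotal))
  call <- if (fwdTotal >= ratioThreshold * revTotal) "stranded_positive"
          else if (revTotal >= ratioThreshold * fwdTotal) "stranded_negative"
          else "unstranded"
  list(call = call, ratio = ratio)
}

#' Estimate transcript counts by compatibility matching
#'
#' Matches each read against the transcript sequences (restricted to the
#' sense orientation when the library is called stranded) using the same
#' seed-and-extend engine as the genomic mapper. A read compatible with one
#' transcript contributes 1 to it; a read compatible with \eqn{m > 1}
#' transcripts contributes \eqn{1/m} to each (uniform splitting, a
#' simplified stand-in for expectation-maximization quantifiers). The sum
#' of estimated counts equals the number of matched reads.
#'
#' @param batch A \linkS4class{ReadBatch}.
#' @param ref A \linkS4class{ToyReference}.
#' @param strandedness Result of [callStrandedness()] (or one of its
#'   \code{call} strings).
#' @param maxMismatch Maximum mismatches (default 2).
#' @param seedLen Seed length for the transcriptome index (default 18).
#' @return A list: \code{counts} (named numeric per transcript),
#'   \code{nInput}, \code{nMapped} (reads matching >= 1 transcript) and
#'   \code{mapRate}.
#' @export
countTranscripts <- function(batch, ref, strandedness = "unstranded",
                             maxMismatch = 2L, seedLen = 18L) {
  call <- if (is.list(strandedness)) strandedness$call else strandedness
  txSeqs <- transcriptSequences(ref)
  idx <- buildMapperIndex(txSeqs, seedLen = min(seedLen, min(
    BiocGenerics::width(txSeqs))))
  seqs <- sequences(batch)
  if (!all(batch@mate == "single")) {
    seqs <- seqs[batch@mate != "mate2"]
  }
  compat <- .transcriptCompatibility(seqs, idx, call, maxMismatch)
  counts <- setNames(numeric(length(txSeqs)), names(txSeqs))
  nMapped <- 0L
  if (nrow(compat)) {
    m <- table(compat$read)
    compat$wt <- 1 / as.numeric(m[as.character(compat$read)])
    agg <- tapply(compat$wt, compat$txIdx, sum)
    counts[as.integer(names(agg))] <- as.numeric(agg)
    nMapped <- length(m)
  }
  n <- length(seqs)
  list(counts = counts, nInput = n, nMapped = nMapped,
       mapRate = if (n) nMapped / n else NA_real_)
}

# Transcript-compatibility table (read index, transcript index), honouring
# the strandedness restriction. "chromosomes" of the transcript index are
# transcripts; orientation F = read matches the transcript sense strand.
.transcriptCompatibility <- function(seqs, idx, call, maxMismatch) {
  res <- mapSequencesAll(seqs, idx, maxMismatch)
  if (call == "stranded_positive") res <- res[res$orient == "F", , drop = FALSE]
  if (call == "stranded_negative") res <- res[res$orient == "R", , drop = FALSE]
  unique(res[, c("read", "txIdx")])
}

# Like mapSequences but returns every passing candidate (not just unique
# calls), with the chromosome index exposed. Used for transcript matching.
mapSequencesAll <- function(seqs, index, maxMismatch = 2L) {
  w <- BiocGenerics::width(seqs)
  fwd <- as.character(seqs)
  rev <- as.character(Biostrings::reverseComplement(seqs))
  empty <- data.frame(read = integer(0), txIdx = integer(0),
                      orient = character(0), stringsAsFactors = FALSE)
  cand <- .seedCandidates(fwd, rev, w, index)
  if (nrow(cand) == 0L) return(empty)
  rw <- w[cand$read]
  cand$gend <- cand$gpos + rw - 1L
  chromIdx <- findInterval(cand$gpos, index@chromOffsets + 1L)
  lim <- index@chromOffsets[chromIdx] + index@chromLengths[chromIdx]
  keep <- cand$gend <= lim & cand$gend <= nchar(index@genomeStr)
  cand <- cand[keep, , drop = FALSE]
  chromIdx <- chromIdx[keep]
  if (nrow(cand) == 0L) return(empty)
  win <- substring(index@genomeStr, cand$gpos, cand$gend)
  readStr <- ifelse(cand$orient == "F", fwd[cand$read], rev[cand$read])
  ok <- .hamming(readStr, win) <= maxMismatch
  cand <- cand[ok, , drop = FALSE]
  cand$txIdx <- chromIdx[ok]
  cand[, c("read", "txIdx", "orient")]
}
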
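# Pre-mapping read QC: 3' quality trimming, adapter inference by k-mer
# overrepresentation with the genome-absence/frequency clip rule, and
# progressive 5' clip optimization against unique mapping rate.

# Hamming distance between equal-length strings, vectorized over pairs.
.hamming <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

#' 3' quality trimming with a minimum-length filter
#'
#' Removes the maximal 3' suffix reached by repeatedly dropping the
#' terminal base while its phred score is below \code{qualThreshold}
#' (strict \code{<}), then discards reads shorter than \code{minLen} bases
#' (a read trimmed to exactly \code{minLen} is kept). For paired-end
#' batches a pair is discarded if either mate fails the length filter.
#'
#' @param batch A \linkS4class{ReadBatch}.
#' @param qualThreshold Phred threshold (default 10).
#' @param minLen Minimum surviving read length (default 18).
#' @return A list: \code{batch} (trimmed survivors) and \code{report}, a
#'   list with \code{readsIn}, \code{readsOut}, \code{basesTrimmed} and
#'   \code{qcPassRate} (= readsOut / readsIn).
#' @export
trimReads <- function(batch, qualThreshold = 10L, minLen = 18L) {
  n <- length(batch)
  if (n == 0L)
    return(list(batch = batch,
                report = list(readsIn = 0L, readsOut = 0L,
                              basesTrimmed = 0L, qcPassRate = NA_real_)))
  quals <- as.list(qualities(batch))
  keepLen <- vapply(quals, function(q) {
    ok <- which(q >= qualThreshold)
    if (length(ok)) max(ok) else 0L
  }, integer(1))
  basesTrimmed <- sum(width(batch) - keepLen)
  keep <- keepLen >= minLen
  if (!all(batch@mate == "single")) {
    # pair-aware: both mates must survive
    pairId <- sub("/[12]$", "", names(batch))
    bad <- unique(pairId[!keep])
    keep <- !(pairId %in% bad)
  }
  idx <- which(keep)
  seqs <- Biostrings::subseq(sequences(batch)[idx], start = 1L,
                             end = keepLen[idx])
  newQuals <- IRanges::IntegerList(mapply(function(q, l) q[seq_len(l)],
                                          quals[idx], keepLen[idx],
                                          SIMPLIFY = FALSE))
  out <- readBatch(seqs, newQuals, mate = batch@mate[idx])
  list(batch = out,
       report = list(readsIn = n, readsOut = length(out),
                     basesTrimmed = as.integer(basesTrimmed),
                     qcPassRate = length(out) / n))
}

#' Infer the 3' adapter and decide whether to clip
#'
#' A Minion-style inference re-expressed natively: k-mers anchored in the
#' 3' third of each sampled read are counted; the most overrepresented
#' k-mer (count exceeding \code{overrepFactor} times its expectation under
#' the sample's base composition, and at least \code{minCount} reads) seeds
#' a candidate that is greedily extended left and right by majority vote
#' over the reads containing it. The clip decision requires both that the
#' final candidate is absent from the genome (exact substring on either
#' strand) and that the fraction of sampled reads containing it strictly
#' exceeds \code{freqThreshold} (default 2.5\%; equality does not clip).
#'
#' @param batch Sampled \linkS4class{ReadBatch} (>= 100 reads). For
#'   paired-end input, inference runs on mate1 only.
#' @param ref A \linkS4class{ToyReference} (or a \code{DNAStringSet}
#'   genome) used for the genome-absence check.
#' @param k Seed k-mer length (default 12).
#' @param freqThreshold Clip frequency threshold (default 0.025, strict).
#' @param overrepFactor Overrepresentation multiple over the composition
#'   expectation (default 10).
#' @param minCount Minimum seed k-mer count; defaults to
#'   \code{max(2, 0.5\% of reads)}.
#' @return A list: \code{candidate} (character or \code{NULL}),
#'   \code{frequency}, \code{inGenome}, \code{decision} (\code{"clip"} or
#'   \code{"no_clip"}).
#' @export
inferAdapter <- function(batch, ref, k = 12L, freqThreshold = 0.025,
                         overrepFactor = 10, minCount = NULL) {
  if (is(batch, "ReadBatch") && !all(batch@mate == "single"))
    batch <- batch[batch@mate != "mate2"]
  seqs <- as.character(sequences(batch))
  n <- length(seqs)
  if (n < 100L)
    stop("adapter inference needs a sample of at least 100 reads")
  if (is.null(minCount))
    minCount <- max(2L, ceiling(0.005 * n))
  w <- nchar(seqs)
  regStart <- pmax(1L, floor(2L * w / 3L) + 1L)
  regions <- substring(seqs, regStart, w)
  regions <- regions[nchar(regions) >= k]
  kmers <- unlist(lapply(regions, function(s) {
    nk <- nchar(s) - k + 1L
    unique(substring(s, seq_len(nk), seq_len(nk) + k - 1L))
  }))
  if (length(kmers) == 0L)
    return(list(candidate = NULL, frequency = 0, inGenome = FALSE,
                decision = "no_clip"))
  counts <- table(kmers)
  # expectation of each specific k-mer under the sample base composition
  comp <- Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs), as.prob = TRUE, collapse = TRUE)
  p <- comp[c("A", "C", "G", "T")]
  p <- p / sum(p)
  nPositions <- sum(pmax(0L, nchar(regions) - k + 1L))
  expect <- vapply(names(counts), function(km) {
    nPositions * prod(p[strsplit(km, "", fixed = TRUE)[[1L]]])
  }, numeric(1))
  ok <- counts > pmax(overrepFactor * expect, minCount - 1)
  if (!any(ok))
    return(list(candidate = NULL, frequency = 0, inGenome = FALSE,
                decision = "no_clip"))
  cand <- names(which.max(counts[ok]))
  cand <- .extendCandidate(cand, seqs, minSupport = max(2L, minCount %/% 2L))
  freq <- mean(grepl(cand, seqs, fixed = TRUE))
  genomeSeqs <- if (is(ref, "ToyReference")) genome(ref) else ref
  pat <- Biostrings::DNAString(cand)
  inGenome <- any(Biostrings::vcountPattern(pat, genomeSeqs) > 0L) ||
    any(Biostrings::vcountPattern(
      Biostrings::reverseComplement(pat), genomeSeqs) > 0L)
  decision <- if (!inGenome && freq > freqThreshold) "clip" else "no_clip"
  list(candidate = cand, frequency = freq, inGenome = inGenome,
       decision = decision)
}

# Greedy majority-vote extension of a candidate over the reads containing
# it; stops when support thins out or no base reaches a 2/3 majority.
.extendCandidate <- function(cand, seqs, minSupport, maxLen = 60L,
                             majority = 2 / 3) {
  repeat {
    if (nchar(cand) >= maxLen) break
    pos <- regexpr(cand, seqs, fixed = TRUE)
    hit <- which(pos > 0L)
    if (length(hit) == 0L) break
    nOcc <- length(hit)
    extended <- FALSE
    # left
    lp <- pos[hit] - 1L
    lhit <- hit[lp >= 1L]
    if (length(lhit) >= max(minSupport, ceiling(0.5 * nOcc))) {
      ch <- substring(seqs[lhit], pos[lhit] - 1L, pos[lhit] - 1L)
      tab <- sort(table(ch), decreasing = TRUE)
      if (tab[1L] / length(ch) >= majority) {
        cand <- paste0(names(tab)[1L], cand)
        extended <- TRUE
      }
    }
    if (!extended) {
      pos <- regexpr(cand, seqs, fixed = TRUE)
      hit <- which(pos > 0L)
      rp <- pos[hit] + nchar(cand)
      rhit <- hit[rp <= nchar(seqs[hit])]
      if (length(rhit) >= max(minSupport, ceiling(0.5 * nOcc))) {
        rpos <- pos[rhit] + nchar(cand)
        ch <- substring(seqs[rhit], rpos, rpos)
        tab <- sort(table(ch), decreasing = TRUE)
        if (tab[1L] / length(ch) >= majority) {
          cand <- paste0(cand, names(tab)[1L])
          extended <- TRUE
        }
      }
    }
    if (!extended) break
  }
  cand
}

#' Clip an inferred 3' adapter from reads
#'
#' Removes, from each read, the longest suffix aligning to a prefix of the
#' adapter with at least \code{minOverlap} bases and a mismatch rate at
#' most \code{maxMismatchRate}, then re-applies the minimum-length filter.
#' Reads without an adapter suffix are untouched.
#'
#' @param batch A \linkS4class{ReadBatch}.
#' @param adapter Adapter sequence (from [inferAdapter()]).
#' @param minOverlap Minimum suffix/prefix overlap (default 5).
#' @param maxMismatchRate Maximum mismatch fraction in the overlap
#'   (default 0.1).
#' @param minLen Minimum surviving read length (default 18).
#' @return A list: \code{batch} (clipped survivors), \code{nClipped}
#'   (reads that lost bases) and \code{nDiscarded}.
#' @export
clipAdapterReads <- function(batch, adapter, minOverlap = 5L,
                             maxMismatchRate = 0.1, minLen = 18L) {
  seqs <- as.character(sequences(batch))
  w <- nchar(seqs)
  aLen <- nchar(adapter)
  clipAt <- w + 1L  # first clipped position; w+1 means untouched
  lMax <- min(aLen, max(w))
  lGrid <- if (lMax >= minOverlap) seq(lMax, minOverlap) else integer(0)
  for (l in lGrid) {
    open <- which(clipAt == w + 1L & w >= l)
    if (length(open) == 0L) next
    suf <- substring(seqs[open], w[open] - l + 1L, w[open])
    mm <- .hamming(suf, rep(substr(adapter, 1L, l), length(open)))
    hit <- open[mm <= floor(maxMismatchRate * l)]
    clipAt[hit] <- w[hit] - l + 1L  # longest l wins: scan is high-to-low
  }
  newLen <- pmin(w, clipAt - 1L)
  keep <- newLen >= minLen
  quals <- as.list(qualities(batch))
  idx <- which(keep)
  seqsOut <- Biostrings::subseq(sequences(batch)[idx], 1L, newLen[idx])
  qualsOut <- IRanges::IntegerList(mapply(function(q, l) q[seq_len(l)],
                                          quals[idx], newLen[idx],
                                          SIMPLIFY = FALSE))
  list(batch = readBatch(seqsOut, qualsOut, mate = batch@mate[idx]),
       nClipped = sum(newLen < w),
       nDiscarded = sum(!keep))
}

#' Optimize the 5' clip length by progressive clipping and mapping
#'
#' For each clip length in \code{clips} (default 0, 4, 8, 12, 20), clips
#' that many 5' bases from every sampled read, maps against the reference,
#' and records the unique-mapping proportion (denominator: all sampled
#' reads). The chosen clip maximizes that proportion; ties break toward the
#' smaller clip. For paired-end input, optimization runs on mate1 only.
#'
#' @param batch Sampled \linkS4class{ReadBatch} (at most the pipeline's
#'   10,000-read sample).
#' @param index A \linkS4class{MapperIndex} from [buildMapperIndex()].
#' @param clips Integer clip grid; 0 is the unclipped baseline.
#' @param maxMismatch Mismatches allowed by the mapper (default 2).
#' @return A list: \code{testedClips} (data.frame of \code{clip} and
#'   \code{uniqMapRate}) and \code{chosenClip}.
#' @export
optimizeFivePrimeClip <- function(batch, index, clips = c(0L, 4L, 8L, 12L, 20L),
                                  maxMismatch = 2L) {
  if (!all(batch@mate == "single"))
    batch <- batch[batch@mate != "mate2"]
  n <- length(batch)
  if (n == 0L) stop("empty read sample")
  clips <- sort(unique(as.integer(clips)))
  seqs <- sequences(batch)
  rates <- vapply(clips, function(cl) {
    keep <- width(seqs) > cl + index@seedLen - 1L
    if (!any(keep)) return(0)
    clipped <- Biostrings::subseq(seqs[keep], start = cl + 1L)
    res <- mapSequences(clipped, index, maxMismatch = maxMismatch)
    res$summary$nUnique / n
  }, numeric(1))
  if (all(rates == 0))
    stop("unmappable sample: no clip setting yields unique mappings")
  chosen <- clips[which.max(rates)]  # which.max takes the first (smallest)
  list(testedClips = data.frame(clip = clips, uniqMapRate = rates),
       chosenClip = chosen)
}
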
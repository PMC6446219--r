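# Seeded toy-reference and read simulation: the ground-truth source for
# every downstream stage. Deliberately simplified relative to full read
# simulators: uniform coverage, iid substitutions, parametric quality decay.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

# sample() treats a length-1 numeric x as 1:x; this always samples from x.
.sampleFrom <- function(x, n) {
  x[sample.int(length(x), n, replace = TRUE)]
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the toy simulation. Defaults follow
#' the validation conditions the package is built around: uniform fold
#' coverage of 2 over the transcriptome, 50 bp single-end reads (100 bp is
#' the paired-end default read length in that validation design), and an
#' unstranded library (\code{strandFraction = 0.5}). The substitution error
#' rate defaults to 0.1\% per base, a typical Illumina HiSeq figure adopted
#' here as the simulator's free parameter.
#'
#' @param seed Integer RNG seed; a fixed seed makes reference, reads and
#'   ground truth byte-identical across calls.
#' @param nGenes,nTxPerGene,nExonsPerGene Reference size knobs.
#' @param exonLengthRange Integer range of exon lengths in bases.
#' @param readLength Read length in bases (>= 18).
#' @param layout \code{"SE"} or \code{"PE"}.
#' @param foldCoverage Target uniform fold coverage (reads per transcript
#'   \eqn{\approx} coverage x length / read length).
#' @param subErrorRate Per-base substitution probability.
#' @param adapterSeq 3' adapter sequence (character) or \code{NULL}.
#' @param adapterFraction Fraction of reads carrying 3' adapter
#'   read-through.
#' @param fivePrimeExtra Number of random nonreference 5' bases prepended
#'   to every read (0, 4, 8, 12 or 20 in the clip-optimization design).
#' @param strandFraction Probability a read is sense-strand, in [0, 1].
#' @param qualMean,qualDecay Mean phred at the 5' end and per-base 3' decay
#'   of the simulated quality profile.
#' @param countMode \code{"exact"} (deterministic reads per transcript,
#'   rounded) or \code{"poisson"}.
#' @param junctionFree If \code{TRUE} (default), read start positions are
#'   restricted to windows lying within a single exon, so simulated reads
#'   are genomically mappable without spliced alignment.
#' @param shortTxPolicy What to do with transcripts offering no full read
#'   window: \code{"skip"} them or pad with \code{"adapter"} (requires
#'   \code{adapterSeq}).
#' @param fragLength Paired-end fragment length.
#' @param insertRange Optional integer range of insert lengths for
#'   adapter-carrying reads; the default leaves 12 to
#'   \code{nchar(adapterSeq)} adapter bases on the read.
#' @return A validated list of class \code{"SimConfig"}.
#' @seealso [simulateReference()], [simulateReads()]
#' @export
simConfig <- function(seed = 1L, nGenes = 20L, nTxPerGene = 2L,
                      nExonsPerGene = 3L, exonLengthRange = c(150L, 400L),
                      readLength = 50L, layout = c("SE", "PE"),
                      foldCoverage = 2, subErrorRate = 0.001,
                      adapterSeq = NULL, adapterFraction = 0,
                      fivePrimeExtra = 0L, strandFraction = 0.5,
                      qualMean = 35, qualDecay = 0.08,
                      countMode = c("exact", "poisson"),
                      junctionFree = TRUE,
                      shortTxPolicy = c("skip", "adapter"),
                      fragLength = 200L, insertRange = NULL) {
  layout <- match.arg(layout)
  countMode <- match.arg(countMode)
  shortTxPolicy <- match.arg(shortTxPolicy)
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    nGenes >= 1L, nTxPerGene >= 1L, nExonsPerGene >= 1L,
    length(exonLengthRange) == 2L, exonLengthRange[1L] <= exonLengthRange[2L],
    readLength >= 18L,
    foldCoverage > 0,
    subErrorRate >= 0, subErrorRate <= 1,
    adapterFraction >= 0, adapterFraction <= 1,
    fivePrimeExtra >= 0L, fivePrimeExtra < readLength,
    strandFraction >= 0, strandFraction <= 1
  )
  if (!is.null(adapterSeq)) {
    adapterSeq <- toupper(adapterSeq)
    stopifnot(grepl("^[ACGT]+$", adapterSeq), nchar(adapterSeq) >= 12L)
  }
  if (adapterFraction > 0 && is.null(adapterSeq))
    stop("adapterFraction > 0 requires an adapterSeq")
  if (shortTxPolicy == "adapter" && is.null(adapterSeq))
    stop("shortTxPolicy 'adapter' requires an adapterSeq")
  structure(list(
    seed = as.integer(seed), nGenes = as.integer(nGenes),
    nTxPerGene = as.integer(nTxPerGene),
    nExonsPerGene = as.integer(nExonsPerGene),
    exonLengthRange = as.integer(exonLengthRange),
    readLength = as.integer(readLength), layout = layout,
    foldCoverage = foldCoverage, subErrorRate = subErrorRate,
    adapterSeq = adapterSeq, adapterFraction = adapterFraction,
    fivePrimeExtra = as.integer(fivePrimeExtra),
    strandFraction = strandFraction,
    qualMean = qualMean, qualDecay = qualDecay, countMode = countMode,
    junctionFree = junctionFree, shortTxPolicy = shortTxPolicy,
    fragLength = as.integer(fragLength), insertRange = insertRange
  ), class = "SimConfig")
}

#' Generate a toy reference genome and annotation
#'
#' Tiles \code{nGenes} multi-exon genes across 1--3 toy chromosomes with
#' intergenic spacers; gene strands alternate. Transcript 1 of each gene
#' uses all exons and further isoforms drop one internal exon each, so
#' transcripts are exon subsets of their gene. If the configuration sets an
#' adapter sequence, the genome is re-drawn locally until the adapter (and
#' its reverse complement) is absent, so the genome-absence clip rule is
#' exercised cleanly.
#'
#' @param cfg A [simConfig()] object.
#' @return A \linkS4class{ToyReference}; the adapter (if any) is recorded
#'   in its \code{refmeta}.
#' @export
simulateReference <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  .withSeed(cfg$seed, {
    nChrom <- min(3L, max(1L, ceiling(cfg$nGenes / 8L)))
    chromOf <- rep(seq_len(nChrom), length.out = cfg$nGenes)
    spacer <- 200L
    intron <- 80L
    chromSeq <- character(nChrom)
    exonList <- list()
    for (g in seq_len(cfg$nGenes)) {
      gid <- sprintf("G%04d", g)
      chrom <- chromOf[g]
      strand <- if (g %% 2L == 1L) "+" else "-"
      nEx <- cfg$nExonsPerGene
      exLens <- .sampleFrom(seq(cfg$exonLengthRange[1L],
                                cfg$exonLengthRange[2L]), nEx)
      pos <- nchar(chromSeq[chrom]) + spacer + 1L
      starts <- integer(nEx)
      for (e in seq_len(nEx)) {
        starts[e] <- pos
        pos <- pos + exLens[e] + intron
      }
      ends <- starts + exLens - 1L
      # extend chromosome up to the gene end plus trailing spacer
      need <- ends[nEx] + spacer - nchar(chromSeq[chrom])
      if (need > 0L)
        chromSeq[chrom] <- paste0(chromSeq[chrom], .randomDna(need))
      txs <- list()
      for (t in seq_len(cfg$nTxPerGene)) {
        keep <- seq_len(nEx)
        if (t > 1L && nEx > 1L) {
          drop <- ((t - 2L) %% (nEx - 1L)) + 2L  # drop internal/last exons
          drop <- min(drop, nEx)
          keep <- setdiff(keep, drop)
        }
        txs[[t]] <- keep
      }
      for (t in seq_along(txs)) {
        keep <- txs[[t]]
        exonList[[length(exonList) + 1L]] <- data.frame(
          chrom = paste0("chr", chrom), start = starts[keep], end = ends[keep],
          strand = strand, gene_id = gid,
          tx_id = sprintf("%s.T%d", gid, t),
          symbol = sprintf("Sym%04d", g),
          stringsAsFactors = FALSE)
      }
    }
    ex <- do.call(rbind, exonList)
    genomeSeqs <- Biostrings::DNAStringSet(chromSeq)
    names(genomeSeqs) <- paste0("chr", seq_len(nChrom))
    if (!is.null(cfg$adapterSeq))
      genomeSeqs <- .scrubAdapter(genomeSeqs, cfg$adapterSeq)
    gr <- GenomicRanges::GRanges(ex$chrom,
                                 IRanges::IRanges(ex$start, ex$end),
                                 strand = ex$strand)
    S4Vectors::mcols(gr)$gene_id <- ex$gene_id
    S4Vectors::mcols(gr)$tx_id <- ex$tx_id
    S4Vectors::mcols(gr)$symbol <- ex$symbol
    toyReference(genomeSeqs, gr,
                 refmeta = list(adapter = cfg$adapterSeq, simConfig = cfg))
  })
}

# Re-draw genome bases under any occurrence of the adapter (either strand)
# until the adapter is absent from the genome.
.scrubAdapter <- function(genomeSeqs, adapter) {
  pat <- Biostrings::DNAString(adapter)
  rcp <- Biostrings::reverseComplement(pat)
  for (iter in 1:100) {
    hitAny <- FALSE
    for (i in seq_along(genomeSeqs)) {
      hits <- c(Biostrings::matchPattern(pat, genomeSeqs[[i]]),
                Biostrings::matchPattern(rcp, genomeSeqs[[i]]))
      if (length(hits) == 0L) next
      hitAny <- TRUE
      s <- as.character(genomeSeqs[[i]])
      for (h in seq_along(hits)) {
        st <- BiocGenerics::start(hits)[h]
        en <- BiocGenerics::end(hits)[h]
        substr(s, st, en) <- .randomDna(en - st + 1L)
      }
      genomeSeqs[[i]] <- Biostrings::DNAString(s)
    }
    if (!hitAny) return(genomeSeqs)
  }
  stop("could not scrub adapter from genome")
}

# Transcript-coordinate windows in which a read of length rl stays inside a
# single exon (used when junctionFree = TRUE).
.exonWindows <- function(exWidths, rl) {
  offs <- cumsum(c(0L, exWidths[-length(exWidths)]))
  starts <- integer(0)
  for (e in seq_along(exWidths)) {
    if (exWidths[e] >= rl)
      starts <- c(starts, offs[e] + seq_len(exWidths[e] - rl + 1L))
  }
  starts
}

.mutate <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (length(hit)) {
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      s <- paste(ch, collapse = "")
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

.simQuals <- function(widths, qualMean, qualDecay) {
  lapply(widths, function(w) {
    q <- round(qualMean - qualDecay * (seq_len(w) - 1L) +
                 stats::rnorm(w, 0, 3))
    as.integer(pmin(40L, pmax(2L, q)))
  })
}

#' Simulate Illumina-like reads with ground truth
#'
#' Draws reads uniformly along each transcript at the configured fold
#' coverage, optionally prepends random nonreference 5' bases, appends 3'
#' adapter read-through on a configured fraction of reads (the insert is
#' shortened so the adapter fills the read to full length), applies iid
#' substitution errors, and simulates decaying phred qualities. Sense
#' orientation is drawn per read with probability \code{strandFraction}.
#'
#' @param ref A \linkS4class{ToyReference} from [simulateReference()].
#' @param cfg The same [simConfig()] used for the reference.
#' @return A list with elements \code{reads} (a \linkS4class{ReadBatch};
#'   for PE layouts mates interleave with tags \code{mate1}/\code{mate2})
#'   and \code{truth} (class \code{"GroundTruth"}: per-read origins,
#'   per-transcript and per-gene true counts, the injected adapter and 5'
#'   clip length).
#' @export
simulateReads <- function(ref, cfg) {
  stopifnot(is(ref, "ToyReference"), inherits(cfg, "SimConfig"))
  .withSeed(cfg$seed + 1L, {
    txSeqs <- transcriptSequences(ref)
    txStrs <- as.character(txSeqs)
    parents <- txParents(ref)
    grl <- exonsByTx(ref)
    rl <- cfg$readLength
    e <- cfg$fivePrimeExtra
    bioLen <- rl - e  # genuine transcript bases per read (no adapter)
    txCounts <- setNames(numeric(length(txSeqs)), names(txSeqs))
    recs <- list()
    for (tx in names(txSeqs)) {
      L <- nchar(txStrs[[tx]])
      target <- cfg$foldCoverage * L / rl
      n <- if (cfg$countMode == "exact") round(target)
           else stats::rpois(1L, target)
      if (n == 0L) next
      exW <- BiocGenerics::width(grl[[tx]])
      if (as.character(BiocGenerics::strand(grl[[tx]]))[1L] == "-")
        exW <- rev(exW)  # transcript coordinates run antiparallel to genome
      windows <- if (cfg$junctionFree)
        .exonWindows(exW, bioLen)
      else if (L >= bioLen) seq_len(L - bioLen + 1L)
      else integer(0)
      if (length(windows) == 0L) {
        if (cfg$shortTxPolicy == "skip") next
        windows <- 1L  # pad with adapter downstream
      }
      txCounts[tx] <- n
      starts <- .sampleFrom(windows, n)
      sense <- stats::runif(n) < cfg$strandFraction
      adapterRead <- stats::runif(n) < cfg$adapterFraction
      recs[[tx]] <- data.frame(
        tx = tx, gene = parents[[tx]], start = starts, sense = sense,
        adapterRead = adapterRead, stringsAsFactors = FALSE)
    }
    if (length(recs) == 0L)
      stop("simulation produced no reads; increase coverage or lengths")
    perRead <- do.call(rbind, recs)
    rownames(perRead) <- NULL
    nr <- nrow(perRead)
    ord <- sample.int(nr)  # shuffle so batches are not transcript-blocked
    perRead <- perRead[ord, ]
    perRead$id <- sprintf("r%06d", seq_len(nr))

    adLen <- if (is.null(cfg$adapterSeq)) 0L else nchar(cfg$adapterSeq)
    insRange <- cfg$insertRange
    if (is.null(insRange) && adLen > 0L)
      insRange <- c(max(18L, rl - e - adLen), max(18L, rl - e - 12L))
    bio <- integer(nr)      # biological bases in the read
    adp <- integer(nr)      # adapter bases appended
    bio[] <- bioLen
    if (any(perRead$adapterRead)) {
      idx <- which(perRead$adapterRead)
      lo <- min(insRange); hi <- max(insRange)
      hi <- min(hi, rl - e - 1L)
      lo <- min(lo, hi)
      bio[idx] <- .sampleFrom(seq(lo, hi), length(idx))
      adp[idx] <- pmin(adLen, rl - e - bio[idx])
    }
    frag <- substring(txStrs[perRead$tx], perRead$start,
                      perRead$start + bio - 1L)
    # short-transcript padding: fill missing biological bases with adapter
    shortBy <- bio - nchar(frag)
    adp <- adp + pmin(pmax(shortBy, 0L), adLen)
    bio <- nchar(frag)
    # orient the biological portion first; read-through adapter always sits
    # on the read's own 3' end, whichever strand was sequenced
    oriented <- ifelse(perRead$sense, frag,
                       as.character(Biostrings::reverseComplement(
                         Biostrings::DNAStringSet(frag))))
    adTail <- rep("", nr)
    if (adLen > 0L && any(adp > 0L))
      adTail[adp > 0L] <- substring(cfg$adapterSeq, 1L, adp[adp > 0L])
    insert <- paste0(oriented, adTail)
    extras <- if (e > 0L)
      vapply(seq_len(nr), function(i) .randomDna(e), character(1))
    else character(nr)
    readsChr <- paste0(extras, insert)
    readsChr <- .mutate(readsChr, cfg$subErrorRate)
    widths <- nchar(readsChr)
    quals <- .simQuals(widths, cfg$qualMean, cfg$qualDecay)

    if (cfg$layout == "SE") {
      seqs <- Biostrings::DNAStringSet(readsChr)
      names(seqs) <- perRead$id
      batch <- readBatch(seqs, quals, mate = "single")
    } else {
      # PE: mate1 as simulated; mate2 is the reverse complement (the
      # opposite end of an insert fully covered at these toy scales).
      m2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(readsChr)))
      inter <- as.vector(rbind(readsChr, m2))
      ids <- as.vector(rbind(paste0(perRead$id, "/1"),
                             paste0(perRead$id, "/2")))
      seqs <- Biostrings::DNAStringSet(inter)
      names(seqs) <- ids
      quals2 <- .simQuals(nchar(m2), cfg$qualMean, cfg$qualDecay)
      qall <- vector("list", 2L * nr)
      qall[seq(1L, 2L * nr, by = 2L)] <- quals
      qall[seq(2L, 2L * nr, by = 2L)] <- quals2
      batch <- readBatch(seqs, qall,
                         mate = rep(c("mate1", "mate2"), nr))
    }
    perRead$adapterLen <- adp
    geneCounts <- tapply(txCounts, parents[names(txCounts)], sum)
    geneCounts <- setNames(as.numeric(geneCounts), names(geneCounts))
    truth <- structure(list(
      perRead = perRead,
      txCounts = txCounts,
      geneCounts = geneCounts,
      adapter = cfg$adapterSeq,
      fivePrimeExtra = e
    ), class = "GroundTruth")
    list(reads = batch, truth = truth)
  })
}

#' True counts from a simulation ground truth
#'
#' @param truth A \code{"GroundTruth"} object from [simulateReads()].
#' @return Named numeric vector of true per-transcript (or per-gene) read
#'   counts.
#' @export
trueTxCounts <- function(truth) {
  stopifnot(inherits(truth, "GroundTruth"))
  truth$txCounts
}

#' @rdname trueTxCounts
#' @export
trueGeneCounts <- function(truth) {
  stopifnot(inherits(truth, "GroundTruth"))
  truth$geneCounts
}
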
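simpleRef <- function(seed = 1, nGenes = 6, ...) {
  cfg <- simConfig(seed = seed, nGenes = nGenes, ...)
  list(cfg = cfg, ref = simulateReference(cfg))
}

test_that("index construction bounds and error cases", {
  set.seed(4)
  g <- Biostrings::DNAStringSet(c(chr1 = rndDna(1000)))
  idx <- buildMapperIndex(g, seedLen = 18)
  expect_lte(length(ls(idx@kmers)), 983L)  # at most L - k + 1 distinct keys
  # duplicated k-mers accumulate multiple positions
  rep2 <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGTACGTACGTACGTACGTAC", 3)))
  idx2 <- buildMapperIndex(rep2, seedLen = 18)
  expect_gt(max(vapply(ls(idx2@kmers), function(k) length(idx2@kmers[[k]]),
                       integer(1))), 1L)
  expect_error(buildMapperIndex(Biostrings::DNAStringSet()), "empty")
  expect_error(buildMapperIndex(g, seedLen = 1001), "seedLen")
})

test_that("verbatim, duplicated and absent reads get the right call", {
  set.seed(8)
  uniqPart <- rndDna(400)
  dupPart <- rndDna(100)
  genomeStr <- paste0(uniqPart, dupPart, rndDna(50), dupPart)
  g <- Biostrings::DNAStringSet(c(chr1 = genomeStr))
  idx <- buildMapperIndex(g)
  reads <- Biostrings::DNAStringSet(c(
    uniq = substr(uniqPart, 10, 59),
    dup = substr(dupPart, 1, 50),
    rc = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(uniqPart, 100, 149))))))
  res <- mapSequences(reads, idx)
  expect_equal(res$status, c("unique", "multi", "unique"))
  expect_equal(as.character(BiocGenerics::strand(res$alignments)),
               c("+", "-"))
  expect_equal(BiocGenerics::start(res$alignments), c(10L, 100L))
  # random read, confirmed absent by exhaustive scan, is unmapped
  repeat {
    rnd <- rndDna(50)
    rrc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rnd)))
    if (gregexpr(rnd, genomeStr, fixed = TRUE)[[1]][1] == -1L &&
        gregexpr(rrc, genomeStr, fixed = TRUE)[[1]][1] == -1L) break
  }
  res2 <- mapSequences(Biostrings::DNAStringSet(rnd), idx)
  expect_equal(res2$status, "unmapped")
})

test_that("unique + multi + unmapped partitions the input on simulations", {
  for (seed in 1:3) {
    sr <- simpleRef(seed = seed, subErrorRate = 0.01)
    sim <- simulateReads(sr$ref, sr$cfg)
    s <- mapReads(sim$reads, buildMapperIndex(sr$ref))$summary
    expect_equal(s$nUnique + s$nMulti + s$nUnmapped, s$nInput)
    expect_equal(s$nInput, length(sim$reads))
  }
})

test_that("gene counting follows the stranded three-column convention", {
  sr <- simpleRef(seed = 21, strandFraction = 1, subErrorRate = 0)
  sim <- simulateReads(sr$ref, sr$cfg)
  mr <- mapReads(sim$reads, buildMapperIndex(sr$ref))
  gc <- countGenes(mr, sr$ref)
  counts <- geneCounts(gc)
  # all sense reads: fwd column carries everything, rev nothing
  expect_equal(sum(counts[, "rev"]), 0)
  expect_equal(counts[, "unstranded"], counts[, "fwd"])
  # fwd + rev totals equal the unstranded-assigned total
  expect_equal(sum(counts[, "fwd"]) + sum(counts[, "rev"]),
               sum(counts[, "unstranded"]))
  expect_equal(sum(counts[, "unstranded"]), gc@nAssigned)
  expect_equal(assignRate(gc), gc@nAssigned / gc@nInput)
})

test_that("intergenic and gene-ambiguous alignments stay unassigned", {
  # hand-built reference: two overlapping genes plus intergenic space
  set.seed(5)
  chrom <- rndDna(1200)
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 301), c(400, 600)), strand = c("+", "+"))
  S4Vectors::mcols(gr)$gene_id <- c("GA", "GB")
  S4Vectors::mcols(gr)$tx_id <- c("GA.T1", "GB.T1")
  S4Vectors::mcols(gr)$symbol <- c("a", "b")
  ref <- toyReference(c(chr1 = chrom), gr)
  idx <- buildMapperIndex(ref)
  reads <- Biostrings::DNAStringSet(c(
    inGA = substr(chrom, 150, 199),      # inside GA only
    overlap = substr(chrom, 330, 379),   # inside both GA and GB -> ambiguous
    intergenic = substr(chrom, 700, 749)))
  mr <- mapSequences(reads, idx)
  expect_equal(mr$status, rep("unique", 3))
  gc <- countGenes(list(alignments = mr$alignments,
                        summary = mr$summary), ref)
  expect_equal(gc@nAssigned, 1L)
  expect_equal(unname(geneCounts(gc)["GA", "unstranded"]), 1L)
  expect_equal(unname(geneCounts(gc)["GB", "unstranded"]), 0L)
})

test_that("strandedness call applies the 5:1 rule inclusively", {
  mk <- function(fwd, rev) {
    counts <- matrix(c(fwd + rev, fwd, rev), nrow = 1,
                     dimnames = list("G1", c("unstranded", "fwd", "rev")))
    new("GeneCountsTable", counts = counts, nInput = as.integer(fwd + rev),
        nAssigned = as.integer(fwd + rev))
  }
  expect_equal(callStrandedness(mk(500, 100))$call, "stranded_positive")
  expect_equal(callStrandedness(mk(499, 100))$call, "unstranded")
  expect_equal(callStrandedness(mk(100, 100))$call, "unstranded")
  expect_equal(callStrandedness(mk(100, 500))$call, "stranded_negative")
  expect_equal(callStrandedness(mk(500, 100))$ratio, 5)
  expect_error(callStrandedness(mk(0, 0)), "no assigned reads")
})

test_that("transcript counting splits multi-compatible reads uniformly", {
  # one gene, two isoforms sharing exon 1; a read in the shared exon
  # contributes 0.5 to each, a read unique to isoform 1 contributes 1
  set.seed(9)
  chrom <- rndDna(2000)
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 501, 101), c(300, 700, 300)),
    strand = "+")
  S4Vectors::mcols(gr)$gene_id <- c("G1", "G1", "G1")
  S4Vectors::mcols(gr)$tx_id <- c("G1.T1", "G1.T1", "G1.T2")
  S4Vectors::mcols(gr)$symbol <- "s"
  ref <- toyReference(c(chr1 = chrom), gr)
  shared <- substr(chrom, 120, 169)   # exon 1: in both isoforms
  uniq1 <- substr(chrom, 520, 569)    # exon 2: only isoform T1
  rb <- flatBatch(c(shared, uniq1))
  tx <- countTranscripts(rb, ref, "unstranded")
  expect_equal(unname(tx$counts["G1.T1"]), 1.5)
  expect_equal(unname(tx$counts["G1.T2"]), 0.5)
  expect_equal(sum(tx$counts), tx$nMapped)
  expect_equal(tx$mapRate, 1)
})

test_that("stranded transcript counting rejects antisense reads", {
  sr <- simpleRef(seed = 33, strandFraction = 1, subErrorRate = 0)
  sim <- simulateReads(sr$ref, sr$cfg)
  sense <- countTranscripts(sim$reads, sr$ref, "stranded_positive")
  anti <- countTranscripts(sim$reads, sr$ref, "stranded_negative")
  expect_gt(sense$mapRate, 0.95)
  expect_equal(anti$nMapped, 0L)
})

test_that("transcript count totals equal matched reads on simulations", {
  sr <- simpleRef(seed = 44, subErrorRate = 0.005)
  sim <- simulateReads(sr$ref, sr$cfg)
  tx <- countTranscripts(sim$reads, sr$ref, "unstranded")
  expect_equal(sum(tx$counts), tx$nMapped, tolerance = 1e-9)
  expect_lte(tx$nMapped, tx$nInput)
})
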
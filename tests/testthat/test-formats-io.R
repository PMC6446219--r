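test_that("FASTQ round trip is lossless at both quality offsets", {
  set.seed(11)
  seqs <- vapply(1:25, function(i) rndDna(sample(30:60, 1)), character(1))
  quals <- lapply(nchar(seqs), function(w) sample(0:41, w, replace = TRUE))
  rb <- readBatch(setNames(seqs, sprintf("read%02d", 1:25)), quals)
  for (off in c(33L, 64L)) {
    f <- tempfile(fileext = ".fastq")
    writeFastq(rb, f, offset = off)
    back <- readFastq(f, offset = off)
    expect_identical(as.character(sequences(back)), setNames(seqs, names(rb)))
    expect_identical(as.list(qualities(back)),
                     lapply(quals, as.integer))
    expect_identical(names(back), names(rb))
  }
})

test_that("FASTQ decoding: 'I' is phred 40 at offset 33", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), f)
  rb <- readFastq(f, offset = 33L)
  expect_identical(as.list(qualities(rb))[[1]], rep(40L, 4))
  expect_identical(names(rb), "r1")
})

test_that("gzipped FASTQ is accepted transparently, regardless of extension", {
  f <- tempfile(fileext = ".fastq")  # gz content behind a plain name
  con <- gzfile(f, "wt")
  writeLines(c("@r1", "ACGTACGTACGTACGTACGT", "+", "IIIIIIIIIIIIIIIIIIII"), con)
  close(con)
  rb <- readFastq(f)
  expect_equal(length(rb), 1L)
  expect_equal(width(rb), 20L)
})

test_that("maxReads truncates the stream and empty input yields empty batch", {
  f <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@r", 1:10), "ACGT", "+", "IIII")), f)
  expect_equal(length(readFastq(f, maxReads = 3)), 3L)
  empty <- tempfile(fileext = ".fastq")
  file.create(empty)
  expect_equal(length(readFastq(empty)), 0L)
})

test_that("malformed FASTQ records produce parse errors naming the record", {
  f1 <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+", "III"), f1)
  expect_error(readFastq(f1), "record 2")
  f2 <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "x", "IIII"), f2)
  expect_error(readFastq(f2), "record 1")
})

test_that("quality-encoding detection follows the range heuristic", {
  expect_equal(detectEncoding("II!I")$name, "sanger_33")
  expect_equal(detectEncoding(strrep("h", 20))$name, "illumina15_64")
  expect_equal(detectEncoding(c("BBBB", "hhhh"))$offset, 64L)
  # ambiguous: all codes in [59, 63]
  expect_error(detectEncoding(rawToChar(as.raw(c(60, 61, 62)))),
               "undetermined")
  expect_error(detectEncoding(character(0)), "empty")
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "!!II"), f)
  expect_equal(detectEncoding(f)$offset, 33L)
})

test_that("GTF round trip preserves exon models and tolerates line order", {
  gr <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1"),
    IRanges::IRanges(c(1, 201, 401), c(100, 300, 500)),
    strand = c("+", "+", "+"))
  S4Vectors::mcols(gr)$gene_id <- "G1"
  S4Vectors::mcols(gr)$tx_id <- "G1.T1"
  S4Vectors::mcols(gr)$symbol <- "SymA"
  f <- tempfile(fileext = ".gtf")
  writeGtf(gr, f)
  back <- readGtf(f)
  expect_equal(BiocGenerics::start(back), c(1L, 201L, 401L))
  expect_equal(BiocGenerics::end(back), c(100L, 300L, 500L))
  expect_equal(unique(S4Vectors::mcols(back)$tx_id), "G1.T1")
  # shuffle feature lines: same model as sorted input
  lines <- readLines(f)
  hdr <- grepl("^#", lines)
  shuffled <- c(lines[hdr], rev(lines[!hdr]))
  f2 <- tempfile(fileext = ".gtf")
  writeLines(shuffled, f2)
  expect_equal(readGtf(f2), back)
})

test_that("invalid GTF input is rejected", {
  f <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "exon", "100", "50", ".", "+", ".",
                   'gene_id "G1"; transcript_id "G1.T1";', sep = "\t"), f)
  expect_error(readGtf(f))
  f2 <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "exon", "1", "100", ".", "+", ".",
                   'note "no ids";', sep = "\t"), f2)
  expect_error(readGtf(f2), "gene_id|parse")
})

makeTestBundle <- function() {
  gm <- matrix(c(5, 0, 12, 7, 3, 1), nrow = 3,
               dimnames = list(c("G1", "G2", "G3"), c("runA", "runB")))
  tm <- matrix(c(2.5, 2.5, 12, 3.5, 3.5, 1), nrow = 3,
               dimnames = list(c("T1", "T2", "T3"), c("runA", "runB")))
  datasetBundle(
    geneCounts = gm, txCounts = tm,
    geneInfo = data.frame(GeneID = c("G1", "G2", "G3"),
                          GeneSymbol = c("a", "b", "c"),
                          GeneLength = c(100L, 250L, 80L)),
    txInfo = data.frame(TxID = c("T1", "T2", "T3"),
                        GeneID = c("G1", "G1", "G2"),
                        GeneSymbol = c("a", "a", "b"),
                        TxLength = c(60L, 90L, 250L)),
    qcMetrics = data.frame(Run = c("runA", "runB"), QcPassRate = c(0.9, NA)),
    summaryMeta = data.frame(Run = c("runA", "runB"), Layout = "SE"),
    fullMeta = data.frame(Run = c("runA", "runB"), Source = "sim"),
    logs = list(runA = c("run\trunA", "reads_in\t100"),
                runB = c("run\trunB", "reads_in\t200")))
}

test_that("bundle zip round trip reproduces every table value-for-value", {
  b <- makeTestBundle()
  z <- tempfile(fileext = ".zip")
  writeBundle(b, z)
  back <- readBundle(z)
  expect_identical(back@geneCounts, b@geneCounts)
  expect_identical(back@txCounts, b@txCounts)
  expect_identical(back@geneInfo, b@geneInfo)
  expect_identical(back@txInfo, b@txInfo)
  expect_identical(back@qcMetrics$QcPassRate, c(0.9, NA))
  expect_identical(back@logs, b@logs)
  # archive is a valid zip for external tools too
  if (nzchar(Sys.which("unzip")))
    expect_identical(system2("unzip", c("-t", "-qq", z),
                             stdout = FALSE, stderr = FALSE), 0L)
})

test_that("integer counts are written as integers in the TSV member", {
  b <- makeTestBundle()
  z <- tempfile(fileext = ".zip")
  writeBundle(b, z)
  d <- tempfile()
  utils::unzip(z, exdir = d)
  lines <- readLines(file.path(d, "GeneCountMatrix.tsv"))
  expect_identical(lines[2], "G1\t5\t7")
  back <- readBundle(z)
  expect_true(all(back@geneCounts == round(back@geneCounts)))
})

test_that("a bundle missing a member table is rejected with its name", {
  b <- makeTestBundle()
  z <- tempfile(fileext = ".zip")
  writeBundle(b, z)
  d <- tempfile()
  utils::unzip(z, exdir = d)
  file.remove(file.path(d, "QC_summary.tsv"))
  z2 <- tempfile(fileext = ".zip")
  keep <- list.files(d, recursive = TRUE)
  deskseq:::.zipCreate(z2, keep, d)
  expect_error(readBundle(z2), "QC_summary.tsv")
})

test_that("bundle validity enforces run consistency and coverage", {
  b <- makeTestBundle()
  bad <- b
  colnames(bad@txCounts) <- c("runA", "runX")
  expect_error(validObject(bad), "disagree")
  bad2 <- b
  bad2@geneInfo <- bad2@geneInfo[1:2, ]
  expect_error(validObject(bad2), "cover")
})
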
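# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and, where possible, the same library calls),
# so agreement is informative.

# Brute-force re-evaluation of the eight-rule classification table,
# written directly from the published rule table rather than via the
# package's rule loop.
oracleClassify <- function(NumReadsQcPass, QcPassRate, STAR_UniqMapRate,
                           STAR_AssignRate, STAR_AssignedReads,
                           Kallisto_MapRate, Kallisto_MappedReads, G,
                           DatasetCorrel = NA) {
  codes <- integer(0); lev <- character(0)
  trig <- function(code, level) {
    codes <<- c(codes, code); lev <<- c(lev, level)
  }
  if (NumReadsQcPass < 50 * G) trig(1L, "fail")
  else if (NumReadsQcPass < 500 * G) trig(1L, "warn")
  if (QcPassRate < 0.60) trig(2L, "fail")
  else if (QcPassRate < 0.80) trig(2L, "warn")
  if (STAR_UniqMapRate < 0.50) trig(3L, "fail")
  else if (STAR_UniqMapRate < 0.70) trig(3L, "warn")
  if (STAR_AssignRate < 0.40) trig(4L, "fail")
  else if (STAR_AssignRate < 0.60) trig(4L, "warn")
  if (STAR_AssignedReads < 50 * G) trig(5L, "fail")
  else if (STAR_AssignedReads < 500 * G) trig(5L, "warn")
  if (Kallisto_MapRate < 0.40) trig(6L, "fail")
  else if (Kallisto_MapRate < 0.60) trig(6L, "warn")
  if (Kallisto_MappedReads < 50 * G) trig(7L, "fail")
  else if (Kallisto_MappedReads < 500 * G) trig(7L, "warn")
  if (!is.na(DatasetCorrel) && DatasetCorrel < 0.5) trig(8L, "warn")
  status <- if (any(lev == "fail")) "fail"
            else if (length(codes)) "warn" else "pass"
  list(status = status, codes = codes, levels = lev)
}

randomMetricSet <- function() {
  list(NumReadsQcPass = sample(0:20000, 1), QcPassRate = runif(1),
       STAR_UniqMapRate = runif(1), STAR_AssignRate = runif(1),
       STAR_AssignedReads = sample(0:20000, 1), Kallisto_MapRate = runif(1),
       Kallisto_MappedReads = round(runif(1, 0, 20000), 2),
       G = sample(1:40, 1),
       DatasetCorrel = if (runif(1) < 0.2) NA_real_ else runif(1, -1, 1))
}

# Rank-transform then Pearson: the textbook Spearman definition, computed
# without stats::cor(method = "spearman").
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

oraclePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Naive O(n^3) agglomerative complete-linkage clustering; returns merge
# heights in merge order.
oracleCompleteLinkageHeights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dc <- max(d[clusters[[i]], clusters[[j]]])
        if (dc < bestD) { bestD <- dc; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestD)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# Merged-exon gene length by brute-force base enumeration.
oracleMergedLength <- function(starts, ends) {
  length(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
}

# Does `candidate` contain >= minRun consecutive bases of `truth`?
sharesRun <- function(candidate, truth, minRun = 10L) {
  if (is.null(candidate) || nchar(candidate) < minRun) return(FALSE)
  nk <- nchar(candidate) - minRun + 1L
  subs <- substring(candidate, seq_len(nk), seq_len(nk) + minRun - 1L)
  any(vapply(subs, function(s) grepl(s, truth, fixed = TRUE), logical(1)))
}

# Random DNA string helper for constructed fixtures.
rndDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")

# A constructed ReadBatch of uniform-quality reads.
flatBatch <- function(seqs, qual = 35L) {
  readBatch(Biostrings::DNAStringSet(setNames(seqs, sprintf(
    "q%05d", seq_along(seqs)))),
    lapply(nchar(seqs), function(w) rep(as.integer(qual), w)))
}
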
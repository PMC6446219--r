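cleanMetrics <- function(...) {
  args <- list(NumReadsQcPass = 1e6, QcPassRate = 0.95,
               STAR_UniqMapRate = 0.9, STAR_AssignRate = 0.8,
               STAR_AssignedReads = 8e5, Kallisto_MapRate = 0.8,
               Kallisto_MappedReads = 8e5, G = 100,
               DatasetCorrel = NA_real_)
  mods <- list(...)
  args[names(mods)] <- mods
  do.call(qcMetrics, args)
}

test_that("single-rule triggers reproduce the published examples", {
  c1 <- classifyQc(cleanMetrics(QcPassRate = 0.55))
  expect_equal(qcStatus(c1), "fail")
  expect_equal(qcCodes(c1), 2L)
  # G = 100: the read-count fail threshold is 50 * 100 = 5000
  c2 <- classifyQc(cleanMetrics(NumReadsQcPass = 4999))
  expect_equal(qcStatus(c2), "fail")
  expect_equal(qcCodes(c2), 1L)
  c3 <- classifyQc(cleanMetrics(DatasetCorrel = 0.49))
  expect_equal(qcStatus(c3), "warn")
  expect_equal(qcCodes(c3), 8L)
  expect_equal(unname(c3@levels), "warn")
  clean <- classifyQc(cleanMetrics())
  expect_equal(qcStatus(clean), "pass")
  expect_length(qcCodes(clean), 0L)
})

test_that("metrics exactly at their thresholds pass (strict inequalities)", {
  atWarn <- cleanMetrics(NumReadsQcPass = 500 * 100, QcPassRate = 0.80,
                         STAR_UniqMapRate = 0.70, STAR_AssignRate = 0.60,
                         STAR_AssignedReads = 500 * 100,
                         Kallisto_MapRate = 0.60,
                         Kallisto_MappedReads = 500 * 100,
                         DatasetCorrel = 0.5)
  expect_equal(qcStatus(classifyQc(atWarn)), "pass")
})

test_that("every code triggers just below its threshold and not at it", {
  G <- 100
  specs <- list(
    list(metric = "NumReadsQcPass", warn = 500 * G, fail = 50 * G,
         eps = 1),
    list(metric = "QcPassRate", warn = 0.80, fail = 0.60, eps = 1e-9),
    list(metric = "STAR_UniqMapRate", warn = 0.70, fail = 0.50, eps = 1e-9),
    list(metric = "STAR_AssignRate", warn = 0.60, fail = 0.40, eps = 1e-9),
    list(metric = "STAR_AssignedReads", warn = 500 * G, fail = 50 * G,
         eps = 1),
    list(metric = "Kallisto_MapRate", warn = 0.60, fail = 0.40, eps = 1e-9),
    list(metric = "Kallisto_MappedReads", warn = 500 * G, fail = 50 * G,
         eps = 1),
    list(metric = "DatasetCorrel", warn = 0.5, fail = NA, eps = 1e-9))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    mk <- function(v) {
      a <- list(v); names(a) <- s$metric; do.call(cleanMetrics, a)
    }
    expect_length(qcCodes(classifyQc(mk(s$warn))), 0L)
    cw <- classifyQc(mk(s$warn - s$eps))
    expect_equal(qcCodes(cw), i)
    expect_equal(unname(cw@levels), "warn")
    if (!is.na(s$fail)) {
      expect_equal(unname(classifyQc(mk(s$fail))@levels), "warn")
      cf <- classifyQc(mk(s$fail - s$eps))
      expect_equal(qcCodes(cf), i)
      expect_equal(unname(cf@levels), "fail")
      expect_equal(qcStatus(cf), "fail")
    }
  }
})

test_that("classifier agrees with a brute-force evaluator on random sets", {
  set.seed(2024)
  for (i in seq_len(10000)) {
    ms <- randomMetricSet()
    got <- classifyQc(do.call(qcMetrics, ms))
    want <- do.call(oracleClassify, ms)
    if (!identical(qcStatus(got), want$status) ||
        !identical(qcCodes(got), want$codes)) {
      fail(sprintf("disagreement on set %d: got %s {%s}, want %s {%s}", i,
                   qcStatus(got), paste(qcCodes(got), collapse = ","),
                   want$status, paste(want$codes, collapse = ",")))
    }
  }
  succeed()
})

test_that("improving any single metric never worsens the status", {
  rankOf <- c(pass = 3, warn = 2, fail = 1)
  set.seed(55)
  upMetrics <- c("NumReadsQcPass", "QcPassRate", "STAR_UniqMapRate",
                 "STAR_AssignRate", "STAR_AssignedReads", "Kallisto_MapRate",
                 "Kallisto_MappedReads", "DatasetCorrel")
  for (i in 1:200) {
    ms <- randomMetricSet()
    base <- rankOf[qcStatus(classifyQc(do.call(qcMetrics, ms)))]
    m <- sample(upMetrics, 1)
    if (is.na(ms[[m]])) next
    ms2 <- ms
    cap <- if (m %in% c("QcPassRate", "STAR_UniqMapRate", "STAR_AssignRate",
                        "Kallisto_MapRate")) 1
           else if (m == "DatasetCorrel") 1 else Inf
    ms2[[m]] <- min(cap, ms[[m]] * 1.5 + 10)
    improved <- rankOf[qcStatus(classifyQc(do.call(qcMetrics, ms2)))]
    expect_gte(improved, base)
  }
})

test_that("missing non-optional metrics are rejected by name", {
  expect_error(qcMetrics(NumReadsQcPass = 1, QcPassRate = 0.5,
                         STAR_UniqMapRate = 0.5, STAR_AssignRate = 0.5,
                         STAR_AssignedReads = 1, Kallisto_MapRate = 0.5,
                         Kallisto_MappedReads = NA, G = 10),
               "Kallisto_MappedReads")
})

test_that("the pass average uses only runs clean on rules 1-7", {
  m <- matrix(c(10, 0, 0, 10, 10, 0, 5, 5), nrow = 2,
              dimnames = list(c("G1", "G2"), paste0("r", 1:4)))
  mets <- list(r1 = cleanMetrics(), r2 = cleanMetrics(),
               r3 = cleanMetrics(), r4 = cleanMetrics(QcPassRate = 0.55))
  pa <- buildPassAverage(m, mets)
  expect_equal(pa$nRuns, 3L)
  expect_false("r4" %in% pa$runs)
  # mean of RPM vectors [1e6,0], [0,1e6], [1e6,0] -> [2/3, 1/3] * 1e6
  expect_equal(unname(pa$profile), c(2e6, 1e6) / 3)
  # identical pass runs: profile equals any single run's RPM vector
  m2 <- matrix(c(4, 6, 8, 12, 2, 3), nrow = 2,
               dimnames = list(c("G1", "G2"), paste0("r", 1:3)))
  pa2 <- buildPassAverage(m2, mets[1:3])
  expect_equal(unname(pa2$profile), c(4e5, 6e5))
  expect_error(buildPassAverage(m, list(r1 = cleanMetrics(QcPassRate = 0.5),
                                        r2 = cleanMetrics(QcPassRate = 0.5),
                                        r3 = cleanMetrics(QcPassRate = 0.5),
                                        r4 = cleanMetrics(QcPassRate = 0.5))),
               "no run passes")
})

test_that("a correlation rule-8 warning only appears below the NA guard", {
  # a run whose profile deviates strongly from the pass average warns
  m <- matrix(c(100, 0, 0, 90, 5, 100, 0, 95), nrow = 4,
              dimnames = list(paste0("G", 1:4), c("rA", "rB")))
  mets <- list(rA = cleanMetrics(), rB = cleanMetrics())
  pa <- buildPassAverage(m, mets)
  r <- datasetCorrel(rpm(m[, "rB", drop = FALSE])[, 1], pa)
  expect_true(is.numeric(r))
  cls <- classifyQc(cleanMetrics(DatasetCorrel = r))
  if (r < 0.5) expect_true(8L %in% qcCodes(cls)) else
    expect_false(8L %in% qcCodes(cls))
})

test_that("datasetCorrel rounds to 2 significant figures of a precise r", {
  set.seed(8)
  for (i in 1:20) {
    x <- runif(50); y <- 0.4 * x + runif(50)
    r <- datasetCorrel(x, y)
    expect_equal(r, signif(oraclePearson(x, y), 2), tolerance = 1e-12)
  }
  v <- runif(20) * 100
  expect_equal(datasetCorrel(v, v), 1)
  expect_equal(datasetCorrel(v, max(v) - v + min(v)), -1)
  # invariance to uniform scaling of raw counts (RPM is scale-free)
  counts <- c(G1 = 30, G2 = 5, G3 = 60, G4 = 1)
  avg <- c(G1 = 2e5, G2 = 1e5, G3 = 6e5, G4 = 1e5)
  expect_identical(datasetCorrel(rpm(counts)[, 1], avg),
                   datasetCorrel(rpm(counts * 9)[, 1], avg))
  expect_true(is.na(datasetCorrel(rep(1, 10), runif(10))))
})
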
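# The eight-code pass/warn/fail quality-classification engine. Integer
# metrics scale with transcriptome complexity (the number of
# protein-coding genes G); all thresholds are strict "<" so a metric
# sitting exactly on a threshold passes that rule.

#' Construct a QcMetrics set
#'
#' @param NumReadsQcPass,QcPassRate,STAR_UniqMapRate,STAR_AssignRate
#'   See \linkS4class{QcMetrics}.
#' @param STAR_AssignedReads,Kallisto_MapRate,Kallisto_MappedReads,G
#'   See \linkS4class{QcMetrics}.
#' @param DatasetCorrel Correlation to the pass average, or \code{NA}.
#' @return A \linkS4class{QcMetrics}.
#' @export
qcMetrics <- function(NumReadsQcPass, QcPassRate, STAR_UniqMapRate,
                      STAR_AssignRate, STAR_AssignedReads, Kallisto_MapRate,
                      Kallisto_MappedReads, G, DatasetCorrel = NA_real_) {
  args <- list(NumReadsQcPass = NumReadsQcPass, QcPassRate = QcPassRate,
               STAR_UniqMapRate = STAR_UniqMapRate,
               STAR_AssignRate = STAR_AssignRate,
               STAR_AssignedReads = STAR_AssignedReads,
               Kallisto_MapRate = Kallisto_MapRate,
               Kallisto_MappedReads = Kallisto_MappedReads,
               G = G, DatasetCorrel = DatasetCorrel)
  miss <- names(args)[names(args) != "DatasetCorrel" &
                        vapply(args, function(x) length(x) != 1L || is.na(x),
                               logical(1))]
  if (length(miss))
    stop("missing QC metric(s): ", paste(miss, collapse = ", "))
  do.call(new, c(list("QcMetrics"), lapply(args, as.numeric)))
}

# Rule table: metric, per-gene scaling, fail and warn thresholds, code.
# Rule 8 is advisory (no fail level). Rates are held in [0,1].
.qcRules <- data.frame(
  code = 1:8,
  metric = c("NumReadsQcPass", "QcPassRate", "STAR_UniqMapRate",
             "STAR_AssignRate", "STAR_AssignedReads", "Kallisto_MapRate",
             "Kallisto_MappedReads", "DatasetCorrel"),
  perGene = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
  fail = c(50, 0.60, 0.50, 0.40, 50, 0.40, 50, NA),
  warn = c(500, 0.80, 0.70, 0.60, 500, 0.60, 500, 0.5),
  stringsAsFactors = FALSE)

#' Classify a run as pass, warn or fail
#'
#' Applies the eight rules in code order. Integer-count rules (codes 1, 5,
#' 7) compare against \code{50 * G} (fail) and \code{500 * G} (warn); rate
#' rules use fixed fractions; the correlation rule (code 8) only warns
#' below 0.5 and is skipped when \code{DatasetCorrel} is \code{NA}. All
#' comparisons are strict \code{<}: a metric exactly at a threshold does
#' not trigger. The status is \code{"fail"} if any rule fails,
#' \code{"warn"} if rules trigger only at warn level, otherwise
#' \code{"pass"}; every triggered code is reported.
#'
#' @param m A \linkS4class{QcMetrics}.
#' @return A \linkS4class{QcClassification}.
#' @examples
#' m <- qcMetrics(NumReadsQcPass = 1e6, QcPassRate = 0.95,
#'                STAR_UniqMapRate = 0.9, STAR_AssignRate = 0.8,
#'                STAR_AssignedReads = 8e5, Kallisto_MapRate = 0.8,
#'                Kallisto_MappedReads = 8e5, G = 100)
#' qcStatus(classifyQc(m))
#' @export
classifyQc <- function(m) {
  stopifnot(is(m, "QcMetrics"))
  validObject(m)
  codes <- integer(0)
  levels <- character(0)
  for (i in seq_len(nrow(.qcRules))) {
    r <- .qcRules[i, ]
    val <- slot(m, r$metric)
    if (is.na(val)) next  # only DatasetCorrel may be NA (rule skipped)
    mult <- if (r$perGene) m@G else 1
    lev <- NULL
    if (!is.na(r$fail) && val < r$fail * mult) lev <- "fail"
    else if (!is.na(r$warn) && val < r$warn * mult) lev <- "warn"
    if (!is.null(lev)) {
      codes <- c(codes, r$code)
      levels <- c(levels, lev)
    }
  }
  status <- if (any(levels == "fail")) "fail"
            else if (length(codes)) "warn" else "pass"
  names(levels) <- as.character(codes)
  new("QcClassification", status = status, codes = as.integer(codes),
      levels = levels)
}

#' @rdname QcClassification-class
#' @export
setMethod("qcStatus", "QcClassification", function(x) x@status)

#' @rdname QcClassification-class
#' @export
setMethod("qcCodes", "QcClassification", function(x) x@codes)

setMethod("show", "QcClassification", function(object) {
  cat(sprintf("QcClassification: %s", toupper(object@status)))
  if (length(object@codes))
    cat(sprintf(" [codes %s]", paste0(object@codes, " (", object@levels, ")",
                                      collapse = ", ")))
  cat("\n")
})

setMethod("show", "QcMetrics", function(object) {
  cat("QcMetrics:\n")
  for (nm in slotNames(object))
    cat(sprintf("  %-20s %s\n", nm, format(slot(object, nm), digits = 4)))
})

#' Mean expression profile of QC-passing runs
#'
#' RPM-normalizes every run that triggers none of rules 1--7 (rule 8 is
#' ignored for eligibility), samples at most \code{maxRuns} of them
#' uniformly without replacement, and returns the per-gene arithmetic mean
#' profile.
#'
#' @param m Numeric matrix, genes x runs.
#' @param metricsList Named list (by run) of \linkS4class{QcMetrics}.
#' @param maxRuns Sample-size cap (default 10,000).
#' @param seed RNG seed for the run sampling.
#' @return A list: \code{profile} (named numeric, per-gene mean RPM),
#'   \code{nRuns} (runs used) and \code{runs} (their ids).
#' @export
buildPassAverage <- function(m, metricsList, maxRuns = 10000L, seed = 1L) {
  stopifnot(identical(sort(colnames(m)), sort(names(metricsList))))
  eligible <- vapply(colnames(m), function(run) {
    met <- metricsList[[run]]
    met@DatasetCorrel <- NA_real_
    length(qcCodes(classifyQc(met))) == 0L
  }, logical(1))
  runs <- colnames(m)[eligible]
  if (length(runs) == 0L)
    stop("no run passes rules 1-7; cannot build a pass average")
  if (length(runs) > maxRuns)
    runs <- .withSeed(seed, sample(runs, maxRuns))
  prof <- rowMeans(rpm(m[, runs, drop = FALSE]))
  list(profile = prof, nRuns = length(runs), runs = runs)
}

#' Correlation of a run to the pass-average profile
#'
#' Pearson correlation between a run's RPM profile and the pass-average
#' RPM profile, rounded to 2 significant figures (the average profile
#' drifts as data accrue, so more precision is not meaningful). Returns
#' \code{NA} (rule 8 skipped) when either vector has zero variance.
#'
#' @param runProfile Named numeric RPM vector for the run.
#' @param passAverage Result of [buildPassAverage()], or a bare numeric
#'   profile on the same genes.
#' @return Pearson r rounded to 2 significant figures, or \code{NA}.
#' @export
datasetCorrel <- function(runProfile, passAverage) {
  avg <- if (is.list(passAverage)) passAverage$profile else passAverage
  if (!is.null(names(runProfile)) && !is.null(names(avg))) {
    common <- intersect(names(runProfile), names(avg))
    runProfile <- runProfile[common]
    avg <- avg[common]
  }
  if (length(runProfile) < 3L)
    stop("need at least 3 shared genes")
  if (stats::sd(runProfile) == 0 || stats::sd(avg) == 0)
    return(NA_real_)
  signif(stats::cor(runProfile, avg), 2)
}
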
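# Meta-analysis machinery: pairwise correlation matrices, complete-linkage
# clustering with fractional-height tree cuts, and the signed
# differential-expression rank statistic.

#' Pairwise correlation matrix over runs or genes
#'
#' Correlates columns (\code{axis = "runs"}) or rows (\code{axis =
#' "genes"}; the matrix is transposed first) of an expression matrix.
#' Constant vectors produce \code{NA} entries with a warning; the diagonal
#' is forced to 1.
#'
#' @param m Numeric matrix, features x runs.
#' @param axis Correlate \code{"runs"} or \code{"genes"}.
#' @param method \code{"spearman"} or \code{"pearson"}.
#' @return Symmetric correlation matrix with a \code{method} attribute.
#' @export
correlationMatrix <- function(m, axis = c("runs", "genes"),
                              method = c("spearman", "pearson")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  x <- if (axis == "runs") m else t(m)
  if (ncol(x) < 2L)
    stop("need at least 2 items on the chosen axis")
  if (nrow(x) < 3L)
    stop("need at least 3 observations per item")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    warning("constant vector(s): ",
            paste(colnames(x)[sds == 0] %||% which(sds == 0), collapse = ", "),
            "; their correlations are NA")
  cm <- suppressWarnings(stats::cor(x, method = method))
  diag(cm) <- 1
  attr(cm, "method") <- method
  cm
}

#' Complete-linkage clustering with a fractional-height tree cut
#'
#' Converts correlations to distances (\code{1 - r} by default; \code{NA}
#' entries are imputed as zero correlation), builds a complete-linkage
#' dendrogram with \code{\link[stats]{hclust}}, and forms flat clusters by
#' cutting at \code{cutFraction} times the maximum merge height. Cluster
#' ids are renumbered in label order, so relabeling inputs permutes the
#' assignment identically.
#'
#' @param cm Symmetric correlation matrix (labels as dimnames).
#' @param cutFraction Cut height as a fraction of the maximum merge height,
#'   in (0, 1]; the pass-level run analysis uses 0.375 and the
#'   transposed gene-level analysis 0.17.
#' @param distTransform \code{"1-r"} (default) or \code{"(1-r)/2"}.
#' @return A list: \code{assignment} (named integer vector),
#'   \code{nClusters}, \code{cutHeight}, \code{cutFraction} and the
#'   \code{hclust} object.
#' @export
clusterCut <- function(cm, cutFraction = 0.375,
                       distTransform = c("1-r", "(1-r)/2")) {
  distTransform <- match.arg(distTransform)
  if (nrow(cm) < 2L)
    stop("need at least 2 items to cluster")
  stopifnot(cutFraction > 0, cutFraction <= 1)
  cm[is.na(cm)] <- 0
  d <- 1 - cm
  if (distTransform == "(1-r)/2") d <- d / 2
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  h <- cutFraction * max(hc$height)
  raw <- stats::cutree(hc, h = h)
  # renumber clusters by first appearance in sorted-label order, so the
  # assignment is equivariant under input relabeling
  assignment <- setNames(match(raw, unique(raw[order(names(raw))])),
                         names(raw))
  list(assignment = assignment, nClusters = length(unique(assignment)),
       cutHeight = h, cutFraction = cutFraction, hclust = hc)
}

#' Signed significance score for differential-expression ranking
#'
#' Scores each gene as \code{sign(fold change) * (-log2(p))}, so strongly
#' significant up-regulated genes rank highest and strongly significant
#' down-regulated genes lowest. A p-value of 1 scores 0 regardless of
#' direction; a fold change of 0 also scores 0.
#'
#' @param de data.frame with columns \code{gene}, \code{fc} (fold change or
#'   logFC) and \code{p} (p-value in (0, 1]).
#' @return Named numeric vector of scores.
#' @export
deRankStatistic <- function(de) {
  stopifnot(all(c("gene", "fc", "p") %in% colnames(de)))
  if (any(de$p <= 0))
    stop("p-values must be > 0")
  if (any(de$p > 1))
    stop("p-values must be <= 1")
  setNames(sign(de$fc) * (-log2(de$p)), de$gene)
}

#' Rank concordance of two differential-expression tables
#'
#' Spearman correlation of the signed significance scores
#' ([deRankStatistic()]) over the gene intersection of the two tables.
#'
#' @param a,b data.frames with columns \code{gene}, \code{fc}, \code{p}.
#' @return Spearman correlation coefficient.
#' @export
deConcordance <- function(a, b) {
  sa <- deRankStatistic(a)
  sb <- deRankStatistic(b)
  common <- intersect(names(sa), names(sb))
  if (length(common) < 3L)
    stop("gene intersection must contain at least 3 genes")
  stats::cor(sa[common], sb[common], method = "spearman")
}
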
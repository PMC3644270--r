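#' Pooled-variance Student t-test for one gene
#'
#' Two-sided Student t with \eqn{df = n_A + n_B - 2}. The p-value is used
#' directly for gene filtering, deliberately without multiple-testing
#' correction. When the pooled variance is zero the statistic degenerates:
#' equal means give \code{t = 0, p = 1}; unequal means give an
#' infinite-magnitude t and \code{p = 0}.
#'
#' @param valuesA,valuesB numeric replicate vectors (each of length >= 2).
#' @return list with \code{statistic}, \code{df} and \code{p.value}.
#' @examples
#' studentT(1:5, 2:6)  # t = -1, df = 8
#' @export
studentT <- function(valuesA, valuesB) {
  if (length(valuesA) < 2L || length(valuesB) < 2L) {
    .stopf("each group needs at least 2 values")
  }
  r <- .rowStudentT(matrix(valuesA, nrow = 1L), matrix(valuesB, nrow = 1L))
  list(statistic = r$t_stat, df = r$df, p.value = r$t_p)
}

# Vectorized pooled-variance t over rows of two matrices.
.rowStudentT <- function(A, B) {
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  sp2 <- ((nA - 1L) * .rowVars(A) + (nB - 1L) * .rowVars(B)) / (nA + nB - 2L)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  diff <- mA - mB
  t <- diff / se
  df <- nA + nB - 2L
  zero <- se == 0
  t[zero & diff == 0] <- 0
  t[zero & diff != 0] <- sign(diff[zero & diff != 0]) * Inf
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(t_stat = t, df = df, t_p = p, log2fc = diff, se = se)
}

#' Mean log2 fold change between two groups
#'
#' Inputs are assumed log2-scaled already, so the A-vs-B fold change is the
#' difference of group means.
#'
#' @param valuesA,valuesB numeric vectors (non-empty).
#' @return \code{mean(valuesA) - mean(valuesB)}.
#' @export
log2FoldChange <- function(valuesA, valuesB) {
  if (!length(valuesA) || !length(valuesB)) {
    .stopf("parameter error: empty group")
  }
  mean(valuesA) - mean(valuesB)
}

#' SAM moderated d statistic for one gene
#'
#' \eqn{d = (mean_A - mean_B) / (s + s_0)} where \eqn{s} is the pooled
#' standard error of the Student t statistic and \eqn{s_0} is the fudge
#' factor stabilizing small-variance genes. With \eqn{s_0 = 0}, d equals
#' the Student t exactly.
#'
#' @param valuesA,valuesB numeric replicate vectors (length >= 2).
#' @param s0 nonnegative fudge factor.
#' @return the d statistic.
#' @seealso [chooseS0()], [samPermutationP()]
#' @export
samStatistic <- function(valuesA, valuesB, s0 = 0) {
  if (length(valuesA) < 2L || length(valuesB) < 2L) {
    .stopf("each group needs at least 2 values")
  }
  if (s0 < 0) .stopf("s0 must be nonnegative")
  r <- .rowStudentT(matrix(valuesA, nrow = 1L), matrix(valuesB, nrow = 1L))
  .samD(r$log2fc, r$se, s0)
}

.samD <- function(num, se, s0) {
  den <- se + s0
  d <- num / den
  zero <- den == 0
  d[zero & num == 0] <- 0
  d[zero & num != 0] <- sign(num[zero & num != 0]) * Inf
  d
}

#' Choose the SAM fudge factor s0
#'
#' Coefficient-of-variation minimization: candidates are zero and the
#' 5th, 10th, ..., 95th percentiles of the per-gene standard errors
#' \code{s}. For each candidate the genes are split into 100 windows by
#' quantiles of \code{s}; the candidate minimizing the coefficient of
#' variation of the median absolute deviation of
#' \eqn{d = r / (s + s_0)} across windows is selected. Deterministic; a
#' constant \code{s} vector yields \code{s0 = 0}.
#'
#' @param s per-gene standard errors (the t denominator), length >= 20.
#' @param r per-gene numerators (mean_A - mean_B).
#' @return the selected s0.
#' @export
chooseS0 <- function(s, r) {
  if (length(s) < 20L || length(s) != length(r)) {
    .stopf("need >= 20 genes with matching s and r")
  }
  if (max(s) - min(s) < .Machine$double.eps) return(0)
  candidates <- c(0, unname(stats::quantile(s, seq(0.05, 0.95, by = 0.05))))
  win <- ceiling(100 * rank(s, ties.method = "first") / length(s))
  cv <- vapply(candidates, function(a) {
    d <- .samD(r, s, a)
    v <- tapply(d, win, stats::mad)
    m <- mean(v)
    if (!is.finite(m) || m == 0) return(Inf)
    stats::sd(v) / m
  }, numeric(1))
  candidates[which.min(cv)]
}

# All ways of assigning nA of n samples to group A. Columns are index sets.
.labelAssignments <- function(n, nA) utils::combn(n, nA)

#' Per-gene SAM permutation p-values
#'
#' Permutes the condition labels of the pooled samples and compares each
#' gene's \eqn{|d^*|} to its observed \eqn{|d|} (with \code{s0} held fixed
#' at its observed value). When the number of distinct label assignments
#' is at most 1000 — e.g. \eqn{C(10,5) = 252} for the five-vs-five design —
#' all assignments are enumerated and the p-value is exact
#' (\eqn{p = \#\{|d^*| \ge |d|\}/\#assignments}, counting the identity);
#' otherwise \code{nPerm} random assignments are drawn and the add-one
#' smoothed estimate is used.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param labels condition label per column, \code{"A"} or \code{"B"}.
#' @param s0 fudge factor from the observed data.
#' @param nPerm number of sampled permutations (>= 50) when enumeration is
#'   not feasible.
#' @param seed seed for sampling mode.
#' @return numeric vector of per-gene p-values.
#' @export
samPermutationP <- function(values, labels, s0 = 0, nPerm = 1000, seed = 1) {
  values <- as.matrix(values)
  if (!all(labels %in% c("A", "B"))) .stopf("labels must be 'A'/'B'")
  n <- ncol(values)
  nA <- sum(labels == "A")
  if (nA < 2L || n - nA < 2L) .stopf("each group needs >= 2 samples")

  dFor <- function(idxA) {
    A <- values[, idxA, drop = FALSE]
    B <- values[, -idxA, drop = FALSE]
    r <- .rowStudentT(A, B)
    .samD(r$log2fc, r$se, s0)
  }
  dObs <- abs(dFor(which(labels == "A")))

  nAssign <- choose(n, nA)
  if (nAssign <= 1000) {
    assigns <- .labelAssignments(n, nA)
    count <- integer(nrow(values))
    for (j in seq_len(ncol(assigns))) {
      count <- count + (abs(dFor(assigns[, j])) >= dObs)
    }
    count / ncol(assigns)
  } else {
    if (nPerm < 50L) .stopf("parameter error: nPerm must be >= 50")
    .withSeed(seed, {
      count <- integer(nrow(values))
      for (j in seq_len(nPerm)) {
        count <- count + (abs(dFor(sample.int(n, nA))) >= dObs)
      }
      (1 + count) / (1 + nPerm)
    })
  }
}

#' Per-gene A-vs-B statistics for one test site
#'
#' Computes, over the supplied gene list, the Student t statistic and
#' p-value, the mean log2 fold change (A - B), the signal-to-noise ratio,
#' and the SAM d statistic with its permutation p-value (s0 chosen from the
#' observed data by [chooseS0()]).
#'
#' @param study an [ExpressionStudy-class].
#' @param site site label to analyse.
#' @param platform platform label; may be omitted when the study holds a
#'   single platform.
#' @param genes gene ids to restrict to (e.g. the cross-platform common
#'   genes); defaults to all genes of the study.
#' @param nPerm,seed passed to [samPermutationP()] (used only when label
#'   assignments cannot be enumerated).
#' @return data.frame with one row per gene: \code{gene}, \code{n_A},
#'   \code{n_B}, \code{t_stat}, \code{t_p}, \code{log2fc}, \code{snr},
#'   \code{sam_d}, \code{sam_p}; the chosen s0 is attached as attribute
#'   \code{"s0"}.
#' @export
geneStatistics <- function(study, site, platform = NULL, genes = NULL,
                           nPerm = 1000, seed = 1) {
  stopifnot(is(study, "ExpressionStudy"))
  cd <- designInfo(study)
  if (is.null(platform)) {
    platform <- unique(cd$platform)
    if (length(platform) > 1L) {
      .stopf("study holds several platforms; specify one")
    }
  }
  keep <- cd$platform == platform & cd$site == as.character(site)
  if (!any(keep)) .stopf("no samples for platform '%s', site '%s'",
                         platform, site)
  vals <- SummarizedExperiment::assay(study)[, keep, drop = FALSE]
  cond <- cd$condition[keep]
  if (is.null(genes)) genes <- rownames(vals)
  miss <- setdiff(genes, rownames(vals))
  if (length(miss)) .stopf("gene(s) absent from study: %s",
                           paste(utils::head(miss, 5L), collapse = ", "))
  vals <- vals[genes, , drop = FALSE]

  A <- vals[, cond == "A", drop = FALSE]
  B <- vals[, cond == "B", drop = FALSE]
  tt <- .rowStudentT(A, B)
  snr <- (rowMeans(A) - rowMeans(B)) /
    (sqrt(.rowVars(A)) + sqrt(.rowVars(B)))
  s0 <- chooseS0(tt$se, tt$log2fc)
  d <- .samD(tt$log2fc, tt$se, s0)
  samP <- samPermutationP(vals, cond, s0 = s0, nPerm = nPerm, seed = seed)

  out <- data.frame(gene = genes, n_A = ncol(A), n_B = ncol(B),
                    t_stat = tt$t_stat, t_p = tt$t_p, log2fc = tt$log2fc,
                    snr = snr, sam_d = d, sam_p = samP,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "s0") <- s0
  attr(out, "platform") <- platform
  attr(out, "site") <- as.character(site)
  out
}

#' Define a DEG selection criterion
#'
#' The three criteria of the study: \code{"FC"} (fold-change ranking after
#' a non-stringent t-test p filter, requiring \code{|log2FC| > fcCutoff}),
#' \code{"SAM"} (permutation p of the moderated d statistic) and
#' \code{"TTEST"} (plain Student t p-value).
#'
#' @param method one of \code{"FC"}, \code{"SAM"}, \code{"TTEST"}.
#' @param pCutoff p-value cutoff, conventionally 0.05 or 0.01.
#' @param fcCutoff absolute log2 fold-change cutoff (FC criterion only).
#' @return a list of class \code{"DEGCriterion"}.
#' @export
degCriterion <- function(method = c("FC", "SAM", "TTEST"), pCutoff = 0.05,
                         fcCutoff = 1) {
  method <- match.arg(method)
  if (pCutoff <= 0 || pCutoff >= 1) .stopf("pCutoff must be in (0, 1)")
  if (fcCutoff <= 0) .stopf("fcCutoff must be positive")
  structure(list(method = method, pCutoff = pCutoff, fcCutoff = fcCutoff),
            class = "DEGCriterion")
}

#' Select differentially expressed genes under one criterion
#'
#' \itemize{
#'   \item FC: genes with \code{t_p < pCutoff} and
#'     \code{|log2fc| > fcCutoff}, ordered by \code{|log2fc|} descending;
#'   \item SAM: genes with \code{sam_p < pCutoff}, ordered by
#'     \code{|sam_d|} descending;
#'   \item TTEST: genes with \code{t_p < pCutoff}, ordered by \code{t_p}
#'     ascending.
#' }
#' Ties are broken by gene id (lexicographic ascending) so lists are
#' reproducible. An empty result is valid.
#'
#' @param stats a [geneStatistics()] table.
#' @param criterion a [degCriterion()].
#' @return data.frame of class \code{"DEGList"} with columns \code{gene}
#'   and \code{metric} (the ordering metric), criterion attached as
#'   attribute \code{"criterion"}.
#' @export
selectDegs <- function(stats, criterion) {
  stopifnot(inherits(criterion, "DEGCriterion"))
  keep <- switch(criterion$method,
    FC = stats$t_p < criterion$pCutoff &
         abs(stats$log2fc) > criterion$fcCutoff,
    SAM = stats$sam_p < criterion$pCutoff,
    TTEST = stats$t_p < criterion$pCutoff)
  sub <- stats[keep, , drop = FALSE]
  metric <- switch(criterion$method,
    FC = abs(sub$log2fc), SAM = abs(sub$sam_d), TTEST = sub$t_p)
  ord <- if (criterion$method == "TTEST") {
    order(metric, sub$gene)
  } else {
    order(-metric, sub$gene)
  }
  out <- data.frame(gene = sub$gene[ord], metric = metric[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!nrow(out)) {
    message(sprintf("criterion %s (p < %g) selected no genes",
                    criterion$method, criterion$pCutoff))
  }
  attr(out, "criterion") <- criterion
  class(out) <- c("DEGList", "data.frame")
  out
}
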
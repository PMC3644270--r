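#' Significance transform for logistic-regression enrichment
#'
#' Maps per-gene p-values to \eqn{x = -\log(p)} (natural log), the
#' predictor of the logistic enrichment model. Exact zeros are floored at
#' 1e-15 with a warning; p-values outside [0, 1] are a data error.
#'
#' @param pValues numeric vector of p-values.
#' @return numeric vector of transformed significances.
#' @export
significanceTransform <- function(pValues) {
  if (any(!is.finite(pValues)) || any(pValues < 0) || any(pValues > 1)) {
    .stopf("data error: p-values must be finite and within [0, 1]")
  }
  if (any(pValues == 0)) {
    warning("p-value(s) of 0 floored at 1e-15", call. = FALSE)
    pValues[pValues == 0] <- 1e-15
  }
  -log(pValues)
}

#' Logistic regression of set membership on significance
#'
#' Maximum-likelihood fit of \eqn{logit P(y = 1) = \beta_0 + \beta_1 x}
#' by iteratively reweighted least squares (deviance tolerance 1e-8, at
#' most 100 iterations), with a two-sided normal Wald test on the slope.
#' Complete separation (non-convergence or a degenerate fit) yields a
#' flagged result with \code{waldP = NA}.
#'
#' @param y 0/1 membership indicator per gene (both classes present).
#' @param x transformed significance per gene (non-constant).
#' @return list with \code{b0}, \code{b1}, \code{se}, \code{waldP},
#'   \code{flagged}.
#' @export
fitSetLogistic <- function(y, x) {
  if (length(unique(y)) < 2L) .stopf("data error: y must contain 0s and 1s")
  if (max(x) - min(x) < .Machine$double.eps) {
    .stopf("data error: constant predictor")
  }
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sepWarn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[2L]
  flagged <- sepWarn || !fit$converged || !is.finite(se) || se > 1e3 ||
    abs(b[2L]) > 1e3
  waldP <- if (flagged) NA_real_ else 2 * stats::pnorm(-abs(b[2L] / se))
  list(b0 = unname(b[1L]), b1 = unname(b[2L]), se = unname(se),
       waldP = waldP, flagged = flagged)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at one and
#' returned in input order.
#'
#' @param pValues numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values.
#' @export
bhAdjust <- function(pValues) {
  if (any(!is.finite(pValues)) || any(pValues < 0) || any(pValues > 1)) {
    .stopf("p-values must be finite and within [0, 1]")
  }
  stats::p.adjust(pValues, method = "BH")
}

#' Logistic-regression enrichment over a gene-set collection
#'
#' For each size-filtered set, fits set membership against the transformed
#' per-gene significance over the gene universe of the statistics table
#' (optionally restricted, e.g. to a DEG list), tests the slope, and
#' adjusts across sets by Benjamini-Hochberg. Enriched sets are those with
#' \code{bh_q < fdrCutoff}; the slope sign labels direction.
#'
#' @param stats a [geneStatistics()] table for the common-gene universe.
#' @param pSource per-gene evidence driving the model: \code{"t_p"} or
#'   \code{"sam_p"} (transformed as \eqn{-\log p}), or \code{"log2fc"}
#'   (the absolute log2 fold change used directly as the evidence scale
#'   of the fold-change criterion).
#' @param sets a [GeneSetCollection-class].
#' @param minSize,maxSize size filter on members present in the universe.
#' @param fdrCutoff significance cutoff on the BH q-value.
#' @param restrict optional character vector of gene ids: restrict the
#'   regression universe to these genes (intersected with \code{stats}).
#' @return data.frame with one row per fitted set: \code{set_id},
#'   \code{size}, \code{b0}, \code{b1}, \code{se}, \code{wald_p},
#'   \code{bh_q}, \code{direction}, \code{significant}. Sets flagged for
#'   complete separation keep \code{NA} p/q and are excluded from ranking.
#' @export
runLrpath <- function(stats, pSource = c("t_p", "sam_p", "log2fc"), sets,
                      minSize = 5, maxSize = 500, fdrCutoff = 0.25,
                      restrict = NULL) {
  pSource <- match.arg(pSource)
  stopifnot(is(sets, "GeneSetCollection"))
  genes <- stats$gene
  ev <- stats[[pSource]]
  if (!is.null(restrict)) {
    keep <- genes %in% restrict
    genes <- genes[keep]
    ev <- ev[keep]
  }
  if (length(genes) < 10L) .stopf("analysis error: universe too small")
  x <- if (pSource == "log2fc") {
    abs(ev)
  } else {
    suppressWarnings(significanceTransform(pmax(ev, 1e-15)))
  }

  membership <- lapply(geneSets(sets), function(m) genes %in% m)
  sizes <- vapply(membership, sum, 1L)
  keep <- sizes >= minSize & sizes <= maxSize & sizes < length(genes)
  if (!any(keep)) .stopf("analysis error: no gene set passes the size filter")
  if (any(!keep)) {
    message(sum(!keep), " set(s) outside the size filter; skipped")
  }

  fits <- lapply(which(keep), function(i) {
    fitSetLogistic(as.integer(membership[[i]]), x)
  })
  out <- data.frame(
    set_id = names(membership)[keep],
    size = unname(sizes[keep]),
    b0 = vapply(fits, `[[`, numeric(1), "b0"),
    b1 = vapply(fits, `[[`, numeric(1), "b1"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    wald_p = vapply(fits, `[[`, numeric(1), "waldP"),
    stringsAsFactors = FALSE, row.names = NULL)
  flagged <- is.na(out$wald_p)
  if (any(flagged)) {
    message(sum(flagged), " set(s) flagged for complete separation; ",
            "excluded from ranking")
  }
  out$bh_q <- NA_real_
  out$bh_q[!flagged] <- bhAdjust(out$wald_p[!flagged])
  out$direction <- ifelse(out$b1 > 0, "pos", "neg")
  out$significant <- !is.na(out$bh_q) & out$bh_q < fdrCutoff
  out
}
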
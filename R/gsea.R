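#' Build a ranked gene list for enrichment
#'
#' Orders genes by a signed criterion-native metric, descending, with ties
#' broken by gene id: fold-change lists use the signed log2 fold change,
#' SAM lists the d statistic, t-test lists
#' \eqn{sign(log2fc) \cdot (-log_{10} p)}. The signal-to-noise ratio is
#' available as an alternative metric. With \code{degList = NULL} the whole
#' statistics table (the common-gene universe) is ranked, the standard
#' pre-ranked usage.
#'
#' @param degList a \code{"DEGList"} from [selectDegs()], or \code{NULL}
#'   to rank every gene in \code{stats}.
#' @param stats a [geneStatistics()] table covering the listed genes.
#' @param method ranking metric source, \code{"FC"}, \code{"SAM"} or
#'   \code{"TTEST"}; defaults to the DEG list's criterion.
#' @param metric \code{"criterion"} (default) or \code{"snr"}.
#' @return data.frame with columns \code{gene} and \code{score}, sorted
#'   descending.
#' @export
buildRankedList <- function(degList = NULL, stats, method = NULL,
                            metric = c("criterion", "snr")) {
  metric <- match.arg(metric)
  if (is.null(degList)) {
    genes <- stats$gene
    if (is.null(method) && metric == "criterion") {
      .stopf("method is required when ranking the full universe")
    }
  } else {
    if (!nrow(degList)) .stopf("DEG list is empty")
    genes <- degList$gene
    if (is.null(method)) method <- attr(degList, "criterion")$method
  }
  idx <- match(genes, stats$gene)
  if (anyNA(idx)) {
    .stopf("analysis error: metric missing for gene(s) %s",
           paste(utils::head(genes[is.na(idx)], 5L), collapse = ", "))
  }
  score <- if (metric == "snr") {
    stats$snr[idx]
  } else {
    switch(method,
      FC = stats$log2fc[idx],
      SAM = stats$sam_d[idx],
      TTEST = sign(stats$log2fc[idx]) *
              (-log10(pmax(stats$t_p[idx], 1e-300))),
      .stopf("unknown ranking method '%s'", method))
  }
  if (anyNA(score)) .stopf("analysis error: NA ranking metric")
  ord <- order(-score, genes)
  data.frame(gene = genes[ord], score = score[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating a running sum: a member gene ("hit")
#' increments by its weighted share
#' \eqn{|score|^{weight} / \sum_{hits} |score|^{weight}}, a non-member
#' decrements by \eqn{1/(N - N_{hits})}. The enrichment score is the
#' signed maximum deviation of the running sum from zero. With
#' \code{weightExponent = 0} this is the classic unweighted KS statistic.
#'
#' @param ranked a [buildRankedList()] table.
#' @param members character vector of member gene ids.
#' @param weightExponent nonnegative weighting exponent (1 by default).
#' @return list with \code{es}, \code{position} (index of the extremum)
#'   and \code{runningSum}.
#' @examples
#' rk <- data.frame(gene = c("a", "b", "c", "d"), score = c(4, 3, 2, 1))
#' enrichmentScore(rk, c("a", "d"), weightExponent = 1)$es  # 0.8
#' @export
enrichmentScore <- function(ranked, members, weightExponent = 1) {
  hits <- ranked$gene %in% members
  N <- nrow(ranked)
  k <- sum(hits)
  if (k == 0L) .stopf("no members of the set occur in the ranked list")
  if (k == N) .stopf("every ranked gene is a member; ES undefined")
  w <- abs(ranked$score[hits])^weightExponent
  if (sum(w) == 0) w <- rep(1, k)  # all-zero scores: fall back to equal weights
  inc <- numeric(N)
  inc[hits] <- w / sum(w)
  inc[!hits] <- -1 / (N - k)
  rs <- cumsum(inc)
  mx <- max(rs); mn <- min(rs)
  # positive extremum wins unless the negative one is larger beyond
  # floating-point noise, so exact |max| = |min| ties resolve stably
  if (mx + mn >= -1e-12) {
    list(es = mx, position = which.max(rs), runningSum = rs)
  } else {
    list(es = mn, position = which.min(rs), runningSum = rs)
  }
}

# O(k) enrichment score from sorted hit positions; extrema of the running
# sum can only occur just after a hit (maximum candidates) or just before
# one (minimum candidates).
.esHits <- function(pos, absw, N) {
  k <- length(pos)
  if (sum(absw) == 0) absw <- rep(1, k)
  cw <- cumsum(absw / sum(absw))
  sq <- seq_len(k)
  top <- cw - (pos - sq) / (N - k)
  bot <- c(0, cw[-k]) - (pos - sq) / (N - k)
  mx <- max(top, 0); mn <- min(bot, 0)
  if (mx + mn >= -1e-12) mx else mn
}

#' Permutation null distribution of the enrichment score
#'
#' Enrichment scores of \code{nPerm} uniformly random member sets of the
#' given size drawn from the ranked list's genes; seeded and reproducible.
#'
#' @param ranked a [buildRankedList()] table.
#' @param setSize size of the random sets (1 <= setSize < N).
#' @param nPerm number of permutations (>= 100).
#' @param weightExponent as in [enrichmentScore()].
#' @param seed integer seed.
#' @return numeric vector of null enrichment scores.
#' @export
geneSetPermutationNull <- function(ranked, setSize, nPerm = 1000,
                                   weightExponent = 1, seed = 1) {
  N <- nrow(ranked)
  if (nPerm < 100L) .stopf("parameter error: nPerm must be >= 100")
  if (setSize < 1L || setSize >= N) {
    .stopf("parameter error: setSize must be in [1, N)")
  }
  aw <- abs(ranked$score)^weightExponent
  .withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      pos <- sort.int(sample.int(N, setSize))
      .esHits(pos, aw[pos], N)
    }, numeric(1))
  })
}

#' Normalize enrichment scores and estimate permutation FDR
#'
#' The normalized enrichment score divides each observed ES by the
#' absolute mean of its set's same-sign null scores. Null scores are
#' normalized the same way and pooled; the FDR q-value of a set with
#' \eqn{NES^* > 0} is the fraction of pooled null NES at least
#' \eqn{NES^*} divided by the fraction of observed NES at least
#' \eqn{NES^*}, clipped to [0, 1] (mirrored for negative scores), then
#' made monotone non-increasing in \eqn{|NES|} within each sign.
#'
#' @param observed named numeric vector of observed enrichment scores.
#' @param nulls named list of per-set null ES vectors (>= 100 each),
#'   aligned with \code{observed}.
#' @return data.frame with columns \code{nes} and \code{fdr_q} in input
#'   order; sets with no same-sign null values get \code{NA} and are
#'   reported via a message.
#' @export
normalizeAndFdr <- function(observed, nulls) {
  stopifnot(length(observed) == length(nulls))
  if (any(vapply(nulls, length, 1L) < 100L)) {
    .stopf("every set needs at least 100 null scores")
  }
  n <- length(observed)
  nes <- rep(NA_real_, n)
  nullNes <- vector("list", n)
  for (i in seq_len(n)) {
    nv <- nulls[[i]]
    mp <- mean(nv[nv > 0])
    mn <- abs(mean(nv[nv < 0]))
    es <- observed[[i]]
    nes[i] <- if (es > 0) {
      if (is.finite(mp) && mp > 0) es / mp else NA_real_
    } else if (es < 0) {
      if (is.finite(mn) && mn > 0) es / mn else NA_real_
    } else 0
    pos <- nv > 0; neg <- nv < 0
    scaled <- numeric(length(nv))
    scaled[pos] <- if (is.finite(mp) && mp > 0) nv[pos] / mp else NA_real_
    scaled[neg] <- if (is.finite(mn) && mn > 0) nv[neg] / mn else NA_real_
    nullNes[[i]] <- scaled[is.finite(scaled)]
  }
  if (anyNA(nes)) {
    message(sum(is.na(nes)),
            " set(s) lack same-sign null scores; excluded from NES/FDR")
  }
  pool <- unlist(nullNes, use.names = FALSE)
  obsOk <- nes[!is.na(nes)]
  q <- rep(NA_real_, n)
  for (i in which(!is.na(nes))) {
    z <- nes[i]
    if (z >= 0) {
      nullFrac <- mean(pool >= z)
      obsFrac <- mean(obsOk >= z)
    } else {
      nullFrac <- mean(pool <= z)
      obsFrac <- mean(obsOk <= z)
    }
    q[i] <- min(1, max(0, nullFrac / max(obsFrac, .Machine$double.eps)))
  }
  # enforce monotonicity: larger |NES| never gets a larger q within a sign
  for (sgn in c(1, -1)) {
    sel <- which(!is.na(nes) & sign(nes) == sgn)
    if (length(sel) > 1L) {
      ord <- sel[order(abs(nes[sel]))]
      q[ord] <- cummin(q[ord])
    }
  }
  data.frame(nes = nes, fdr_q = q, row.names = names(observed))
}

#' Run pre-ranked GSEA over a gene-set collection
#'
#' Ranks the genes (the DEG list by default; the full statistics universe
#' when \code{degList = NULL}), filters sets to those with
#' \code{minSize}--\code{maxSize} members present in the ranked list,
#' computes the weighted KS enrichment score per set, a gene-set
#' permutation null shared across sets of equal size, the normalized
#' score and the permutation FDR.
#'
#' @param degList a \code{"DEGList"} or \code{NULL} (rank the universe).
#' @param stats a [geneStatistics()] table.
#' @param sets a [GeneSetCollection-class].
#' @param method ranking metric source; see [buildRankedList()].
#' @param weightExponent weighting exponent (default 1).
#' @param nPerm permutations per set size (default 1000).
#' @param minSize,maxSize size filter on members present in the list.
#' @param fdrCutoff significance cutoff on the FDR q-value.
#' @param seed integer seed for the permutation null.
#' @return data.frame with one row per retained set: \code{set_id},
#'   \code{size}, \code{es}, \code{nes}, \code{fdr_q}, \code{direction}
#'   (\code{"pos"} iff \code{es > 0}), \code{significant}.
#' @export
runGsea <- function(degList = NULL, stats, sets, method = NULL,
                    weightExponent = 1, nPerm = 1000, minSize = 5,
                    maxSize = 500, fdrCutoff = 0.25, seed = 1) {
  stopifnot(is(sets, "GeneSetCollection"))
  ranked <- buildRankedList(degList, stats, method)
  N <- nrow(ranked)
  idx <- seq_len(N)
  names(idx) <- ranked$gene
  aw <- abs(ranked$score)^weightExponent

  positions <- lapply(geneSets(sets), function(m) {
    sort.int(unname(idx[m[m %in% ranked$gene]]))
  })
  sizes <- lengths(positions)
  keep <- sizes >= minSize & sizes <= maxSize & sizes < N
  dropped <- sum(!keep)
  if (dropped) {
    message(dropped, " set(s) outside the size filter [", minSize, ", ",
            maxSize, "] on the ranked list; skipped")
  }
  if (!any(keep)) .stopf("analysis error: no gene set passes the size filter")
  positions <- positions[keep]
  sizes <- sizes[keep]

  es <- vapply(positions, function(p) .esHits(p, aw[p], N), numeric(1))

  uniq <- sort(unique(sizes))
  nullsBySize <- .withSeed(seed, {
    out <- lapply(uniq, function(k) {
      vapply(seq_len(nPerm), function(i) {
        pos <- sort.int(sample.int(N, k))
        .esHits(pos, aw[pos], N)
      }, numeric(1))
    })
    names(out) <- as.character(uniq)
    out
  })
  nulls <- nullsBySize[as.character(sizes)]

  nf <- normalizeAndFdr(es, nulls)
  out <- data.frame(set_id = names(positions), size = unname(sizes),
                    es = unname(es), nes = nf$nes, fdr_q = nf$fdr_q,
                    direction = ifelse(es > 0, "pos", "neg"),
                    stringsAsFactors = FALSE, row.names = NULL)
  drop <- is.na(out$nes)
  if (any(drop)) out <- out[!drop, , drop = FALSE]
  out$significant <- out$fdr_q < fdrCutoff
  out
}
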
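#' Rank significant terms from an enrichment result
#'
#' Keeps terms passing the FDR criterion (strict \code{q < fdrCutoff}) and
#' orders them by q ascending. Ties are broken by a secondary key
#' (\code{|nes|} descending for GSEA, \code{wald_p} ascending for the
#' logistic engine) and finally by set id, so rankings are deterministic.
#' GSEA results yield one list per direction.
#'
#' @param result a [runGsea()] or [runLrpath()] table.
#' @param fdrCutoff FDR significance cutoff (default 0.25).
#' @return for a logistic result, a data.frame (\code{term}, \code{q})
#'   ordered by significance; for a GSEA result, a list with elements
#'   \code{pos} and \code{neg} of such data.frames.
#' @export
rankSignificantTerms <- function(result, fdrCutoff = 0.25) {
  if ("nes" %in% colnames(result)) {
    lapply(stats::setNames(c("pos", "neg"), c("pos", "neg")), function(d) {
      sub <- result[result$direction == d & !is.na(result$fdr_q) &
                      result$fdr_q < fdrCutoff, , drop = FALSE]
      ord <- order(sub$fdr_q, -abs(sub$nes), sub$set_id)
      data.frame(term = sub$set_id[ord], q = sub$fdr_q[ord],
                 stringsAsFactors = FALSE, row.names = NULL)
    })
  } else if ("bh_q" %in% colnames(result)) {
    sub <- result[!is.na(result$bh_q) & result$bh_q < fdrCutoff, ,
                  drop = FALSE]
    ord <- order(sub$bh_q, sub$wald_p, sub$set_id)
    data.frame(term = sub$set_id[ord], q = sub$bh_q[ord],
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    .stopf("unrecognized enrichment result")
  }
}

.termVec <- function(x) {
  if (is.data.frame(x)) as.character(x$term) else as.character(x)
}

#' Truncate two significant-term lists to a common length
#'
#' Both lists are cut to the length of the shorter one. A zero-length
#' match is reported as undefined (\code{N = 0}) rather than as zero
#' overlap.
#'
#' @param a,b ordered term lists (data.frames from
#'   [rankSignificantTerms()] or character vectors).
#' @return list with \code{a}, \code{b} (character, truncated) and
#'   \code{N}.
#' @export
matchLists <- function(a, b) {
  va <- .termVec(a); vb <- .termVec(b)
  N <- min(length(va), length(vb))
  if (N == 0L) {
    message("empty significant-term list; comparison undefined (NA)")
  }
  list(a = utils::head(va, N), b = utils::head(vb, N), N = N)
}

#' Combine directional GSEA term lists for comparison
#'
#' For each direction the two sides are truncated to the direction-wise
#' minimum length; each side's combined list is its truncated "pos" block
#' followed by its truncated "neg" block, preserving within-direction
#' order. \code{N} is the combined length.
#'
#' @param posA,negA,posB,negB ordered term lists per direction and side.
#' @return list with \code{a}, \code{b} (combined character vectors) and
#'   \code{N}; \code{N = 0} when both directions are empty on either side.
#' @export
combinePosNeg <- function(posA, negA, posB, negB) {
  pa <- .termVec(posA); na <- .termVec(negA)
  pb <- .termVec(posB); nb <- .termVec(negB)
  np <- min(length(pa), length(pb))
  nn <- min(length(na), length(nb))
  if (np + nn == 0L) {
    message("no matched terms in either direction; comparison undefined (NA)")
  }
  list(a = c(utils::head(pa, np), utils::head(na, nn)),
       b = c(utils::head(pb, np), utils::head(nb, nn)),
       N = np + nn)
}

#' Percentage of overlapping terms at one depth
#'
#' \eqn{POG_i = 100 \cdot O_i / T_i} where \eqn{O_i} is the size of the
#' intersection of the first \eqn{i} terms of each list and
#' \eqn{T_i = i}.
#'
#' @param a,b equal-length ordered term lists.
#' @param i depth, \code{1 <= i <= length}.
#' @return the overlap percentage at depth \code{i}.
#' @examples
#' overlapPercentage(c("w", "x", "y", "z"), c("x", "w", "z", "v"), 2)  # 100
#' @export
overlapPercentage <- function(a, b, i) {
  va <- .termVec(a); vb <- .termVec(b)
  N <- min(length(va), length(vb))
  if (i < 1L || i > N) .stopf("parameter error: depth %d outside [1, %d]",
                              i, N)
  100 * length(intersect(utils::head(va, i), utils::head(vb, i))) / i
}

#' Concordance curve of two significant-term lists
#'
#' Computes the overlap percentage at every depth \eqn{i = 1..N} after
#' matching the lists to the shorter length. The terminal value
#' \eqn{POG_N} summarizes the comparison when every term meeting the FDR
#' criterion is retained.
#'
#' @param a,b ordered term lists (matched or not; unequal lengths are
#'   truncated via [matchLists()]).
#' @return data.frame of class \code{"ConcordanceCurve"} with columns
#'   \code{depth}, \code{overlap} (\eqn{O_i}) and \code{pog}; attributes
#'   \code{"N"} and \code{"terminal"}. \code{NULL}-like \code{NA} result
#'   (zero rows, \code{N = 0}) when either list is empty.
#' @export
concordanceCurve <- function(a, b) {
  m <- matchLists(a, b)
  if (m$N == 0L) {
    out <- data.frame(depth = integer(0), overlap = integer(0),
                      pog = numeric(0))
    attr(out, "N") <- 0L
    attr(out, "terminal") <- NA_real_
    class(out) <- c("ConcordanceCurve", "data.frame")
    return(out)
  }
  # a pair (j, match position) contributes to O_i for all
  # i >= max(position in a, position in b)
  pos <- match(m$a, m$b)
  hit <- !is.na(pos)
  entry <- pmax(seq_len(m$N)[hit], pos[hit])
  O <- cumsum(tabulate(entry, nbins = m$N))
  out <- data.frame(depth = seq_len(m$N), overlap = O,
                    pog = 100 * O / seq_len(m$N))
  attr(out, "N") <- m$N
  attr(out, "terminal") <- out$pog[m$N]
  class(out) <- c("ConcordanceCurve", "data.frame")
  out
}

.pairPog <- function(entryA, entryB, engine) {
  m <- if (engine == "gsea") {
    combinePosNeg(entryA$pos, entryA$neg, entryB$pos, entryB$neg)
  } else {
    matchLists(entryA$all, entryB$all)
  }
  if (m$N == 0L) {
    list(N = 0L, pog = NA_real_)
  } else {
    list(N = m$N, pog = overlapPercentage(m$a, m$b, m$N))
  }
}

#' All pairwise concordance comparisons of a term catalog
#'
#' Emits the three comparison families of the study design:
#' \describe{
#'   \item{inter_site}{same platform and criterion, different test sites;}
#'   \item{intra_site}{same platform and site, different DEG criteria at a
#'     matched p cutoff;}
#'   \item{inter_platform}{same site and criterion, different platforms.}
#' }
#' GSEA entries are compared through their combined pos/neg lists,
#' logistic entries through their single list. Catalog combinations
#' missing from the expected grid are recorded in the \code{"exclusions"}
#' attribute and skipped.
#'
#' @param catalog data.frame with columns \code{engine}, \code{platform},
#'   \code{site}, \code{method}, \code{p_cutoff} and a list-column
#'   \code{terms}; each element of \code{terms} is a list with components
#'   \code{pos}/\code{neg} (GSEA) or \code{all} (logistic). Built by
#'   [runStudy()] or by hand.
#' @return data.frame with one row per comparison: \code{family},
#'   \code{engine}, \code{p_cutoff}, \code{platform_a}, \code{site_a},
#'   \code{method_a}, \code{platform_b}, \code{site_b}, \code{method_b},
#'   \code{n_matched}, \code{pog}; attribute \code{"exclusions"} lists
#'   expected-but-absent catalog entries.
#' @export
compareAll <- function(catalog) {
  stopifnot(is.data.frame(catalog), "terms" %in% colnames(catalog))
  key <- function(engine, platform, site, method, p) {
    paste(engine, platform, site, method, p, sep = "|")
  }
  catalog$.key <- key(catalog$engine, catalog$platform, catalog$site,
                      catalog$method, catalog$p_cutoff)
  lookup <- stats::setNames(seq_len(nrow(catalog)), catalog$.key)

  grid <- expand.grid(engine = unique(catalog$engine),
                      platform = unique(catalog$platform),
                      site = unique(catalog$site),
                      method = unique(catalog$method),
                      p_cutoff = unique(catalog$p_cutoff),
                      stringsAsFactors = FALSE)
  grid$.key <- key(grid$engine, grid$platform, grid$site, grid$method,
                   grid$p_cutoff)
  exclusions <- grid[!grid$.key %in% names(lookup), , drop = FALSE]
  exclusions$.key <- NULL

  rows <- list()
  emit <- function(family, engine, p, a, b) {
    ia <- lookup[key(engine, a["platform"], a["site"], a["method"], p)]
    ib <- lookup[key(engine, b["platform"], b["site"], b["method"], p)]
    if (is.na(ia) || is.na(ib)) return()
    r <- .pairPog(catalog$terms[[ia]], catalog$terms[[ib]], engine)
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, engine = engine, p_cutoff = as.numeric(p),
      platform_a = unname(a["platform"]), site_a = unname(a["site"]),
      method_a = unname(a["method"]),
      platform_b = unname(b["platform"]), site_b = unname(b["site"]),
      method_b = unname(b["method"]),
      n_matched = r$N, pog = r$pog, stringsAsFactors = FALSE)
  }

  engines <- unique(catalog$engine)
  platforms <- unique(catalog$platform)
  siteLabels <- unique(catalog$site)
  methodsAll <- unique(catalog$method)
  cutoffs <- unique(catalog$p_cutoff)

  for (e in engines) for (p in cutoffs) {
    # (i) inter-site within platform, same criterion
    for (pl in platforms) for (me in methodsAll) {
      if (length(siteLabels) > 1L) {
        cmb <- utils::combn(siteLabels, 2L)
        for (j in seq_len(ncol(cmb))) {
          emit("inter_site", e, p,
               c(platform = pl, site = cmb[1L, j], method = me),
               c(platform = pl, site = cmb[2L, j], method = me))
        }
      }
    }
    # (ii) intra-site criterion pairs at matched cutoff
    for (pl in platforms) for (st in siteLabels) {
      if (length(methodsAll) > 1L) {
        cmb <- utils::combn(methodsAll, 2L)
        for (j in seq_len(ncol(cmb))) {
          emit("intra_site", e, p,
               c(platform = pl, site = st, method = cmb[1L, j]),
               c(platform = pl, site = st, method = cmb[2L, j]))
        }
      }
    }
    # (iii) inter-platform at same site and criterion
    for (st in siteLabels) for (me in methodsAll) {
      if (length(platforms) > 1L) {
        cmb <- utils::combn(platforms, 2L)
        for (j in seq_len(ncol(cmb))) {
          emit("inter_platform", e, p,
               c(platform = cmb[1L, j], site = st, method = me),
               c(platform = cmb[2L, j], site = st, method = me))
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), engine = character(0),
               p_cutoff = numeric(0), platform_a = character(0),
               site_a = character(0), method_a = character(0),
               platform_b = character(0), site_b = character(0),
               method_b = character(0), n_matched = integer(0),
               pog = numeric(0))
  attr(out, "exclusions") <- exclusions
  out
}
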
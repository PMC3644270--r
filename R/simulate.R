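#' Generate a gene-set collection for a synthetic study
#'
#' Draws \code{nSets} sets with sizes uniform over \code{setSizeRange};
#' members are drawn without replacement within a set but independently
#' across sets, so sets may overlap. Deterministic given the design seed.
#'
#' @param design a [StudyDesign-class].
#' @param genes optional character vector of gene ids; defaults to the
#'   design's synthetic gene ids.
#' @return a [GeneSetCollection-class] whose universe is \code{genes}.
#' @export
generateGeneSets <- function(design, genes = NULL) {
  stopifnot(is(design, "StudyDesign"))
  if (is.null(genes)) genes <- .syntheticGeneIds(design@nGenes)
  if (design@setSizeRange[2L] > length(genes)) {
    .stopf("parameter error: maximum set size %d exceeds the %d genes",
           design@setSizeRange[2L], length(genes))
  }
  ids <- sprintf("S%0*d", nchar(design@nSets), seq_len(design@nSets))
  sets <- .withSeed(.substreamSeed(design@seed, "sets"), {
    sizes <- sample(seq(design@setSizeRange[1L], design@setSizeRange[2L]),
                    design@nSets, replace = TRUE)
    lapply(sizes, function(k) sample(genes, k))
  })
  names(sets) <- ids
  GeneSetCollection(sets, rep("synthetic gene set", length(sets)),
                    universe = genes)
}

.syntheticGeneIds <- function(n) sprintf("G%0*d", nchar(n), seq_len(n))

#' Simulate a MAQC-like multi-platform expression study
#'
#' Generates one [ExpressionStudy-class] per platform under an additive
#' Gaussian model on the log2 scale: per gene \eqn{g}, platform \eqn{q},
#' site \eqn{s}, condition \eqn{c} and replicate,
#' \deqn{x = \alpha_g + \lambda_{gq} + \nu_{gqs} + \delta_g 1[c = A] + \epsilon,}
#' with baseline \eqn{\alpha_g \sim N(8, 2^2)}, platform offsets
#' \eqn{\lambda \sim N(0, platformSd^2)}, site offsets
#' \eqn{\nu \sim N(0, siteSd^2)} and noise
#' \eqn{\epsilon \sim N(0, \sigma_g^2)} where
#' \eqn{\sigma_g \sim U(geneSdRange)}.
#'
#' Genes become differentially expressed with probability
#' \code{deFraction}, multiplied by \code{plantedDeEnrichment} (capped at
#' one) for members of planted sets. A DE gene's absolute effect is drawn
#' from \eqn{N(effectSizeLog2, effectSd^2)} truncated at zero and applied
#' to condition A. Each planted set carries one regulation direction
#' (a fair coin per set) inherited by DE genes recruited through it;
#' background DE genes get independent fair-coin signs. Each platform
#' measures a seeded random gene subset of proportion
#' \code{platformCoverage}; the cross-platform intersection is returned.
#'
#' All randomness derives from the design seed through per-component
#' substreams, so repeated calls are byte-identical and changing one
#' design field does not reshuffle unrelated draws.
#'
#' @param design a [StudyDesign-class].
#' @return a list with elements \code{studies} (named list of
#'   [ExpressionStudy-class], one per platform), \code{sets}
#'   (the [GeneSetCollection-class]), \code{truth}
#'   (a [GroundTruth-class]) and \code{commonGenes} (character).
#' @examples
#' sim <- generateStudy(studyDesign(nGenes = 300, platforms = "AFX",
#'                                  sitesPerPlatform = 1, nSets = 20,
#'                                  setSizeRange = c(5, 15),
#'                                  nPlantedSets = 2, seed = 7))
#' sim$studies$AFX
#' @export
generateStudy <- function(design) {
  stopifnot(is(design, "StudyDesign"))
  methods::validObject(design)
  nG <- design@nGenes
  genes <- .syntheticGeneIds(nG)

  sets <- generateGeneSets(design, genes)

  planted <- character(0)
  setDir <- numeric(0)
  if (design@nPlantedSets > 0L) {
    planted <- .withSeed(.substreamSeed(design@seed, "planted"), {
      sort(sample(setIds(sets), design@nPlantedSets))
    })
    setDir <- .withSeed(.substreamSeed(design@seed, "planted") + 500L, {
      stats::setNames(sample(c(-1, 1), length(planted), replace = TRUE),
                      planted)
    })
  }

  # per-gene DE probability, elevated inside planted sets
  pDE <- rep(design@deFraction, nG)
  names(pDE) <- genes
  if (length(planted)) {
    inPlanted <- unique(unlist(geneSets(sets)[planted], use.names = FALSE))
    pDE[inPlanted] <- pmin(1, design@deFraction * design@plantedDeEnrichment)
  }
  isDE <- .withSeed(.substreamSeed(design@seed, "de"),
                    stats::runif(nG) < pDE)

  # effect sizes: truncated-normal magnitudes with per-set coherent signs
  # for planted members, fair-coin signs elsewhere
  delta <- numeric(nG)
  names(delta) <- genes
  .withSeed(.substreamSeed(design@seed, "effect"), {
    nDE <- sum(isDE)
    mag <- stats::rnorm(nDE, design@effectSizeLog2, design@effectSd)
    while (any(mag <= 0)) {
      mag[mag <= 0] <- stats::rnorm(sum(mag <= 0), design@effectSizeLog2,
                                    design@effectSd)
    }
    sgn <- sample(c(-1, 1), nDE, replace = TRUE)
    if (length(planted)) {
      dirOf <- rep(NA_real_, nG)
      names(dirOf) <- genes
      for (sid in rev(planted)) dirOf[sets[[sid]]] <- setDir[[sid]]
      coherent <- !is.na(dirOf[genes[isDE]])
      sgn[coherent] <- dirOf[genes[isDE]][coherent]
    }
    delta[isDE] <- mag * sgn
  })

  alpha <- .withSeed(.substreamSeed(design@seed, "baseline"),
                     stats::rnorm(nG, 8, 2))
  sigma <- .withSeed(.substreamSeed(design@seed, "sigma"),
                     stats::runif(nG, design@geneSdRange[1L],
                                  design@geneSdRange[2L]))

  nP <- length(design@platforms)
  nS <- design@sitesPerPlatform
  lambda <- .withSeed(.substreamSeed(design@seed, "platformFx"),
                      matrix(stats::rnorm(nG * nP, 0, design@platformSd),
                             nG, nP))
  nu <- .withSeed(.substreamSeed(design@seed, "siteFx"),
                  array(stats::rnorm(nG * nP * nS, 0, design@siteSd),
                        c(nG, nP, nS)))

  nCov <- max(1L, round(design@platformCoverage * nG))
  covered <- .withSeed(.substreamSeed(design@seed, "coverage"), {
    lapply(seq_len(nP), function(q) {
      if (nCov >= nG) seq_len(nG) else sort(sample.int(nG, nCov))
    })
  })

  reps <- design@replicates
  nSamp <- nS * 2L * reps
  studies <- .withSeed(.substreamSeed(design@seed, "noise"), {
    out <- vector("list", nP)
    for (q in seq_len(nP)) {
      idx <- covered[[q]]
      plat <- design@platforms[q]
      cond <- rep(rep(c("A", "B"), each = reps), nS)
      site <- rep(as.character(seq_len(nS)), each = 2L * reps)
      repl <- rep(seq_len(reps), 2L * nS)
      sampleIds <- paste(plat, site, cond, repl, sep = "_")
      mu <- alpha[idx] + lambda[idx, q]
      vals <- matrix(0, length(idx), nSamp,
                     dimnames = list(genes[idx], sampleIds))
      for (j in seq_len(nSamp)) {
        m <- mu + nu[idx, q, as.integer(site[j])] +
          if (cond[j] == "A") delta[idx] else 0
        vals[, j] <- stats::rnorm(length(idx), m, sigma[idx])
      }
      des <- data.frame(sample_id = sampleIds, platform = plat,
                        site = site, condition = cond, replicate = repl,
                        stringsAsFactors = FALSE)
      out[[q]] <- ExpressionStudy(vals, des)
    }
    names(out) <- design@platforms
    out
  })

  truth <- new("GroundTruth",
               deGenes = data.frame(gene = genes[isDE],
                                    delta = unname(delta[isDE]),
                                    stringsAsFactors = FALSE),
               plantedSets = planted, setDirections = setDir)

  list(studies = studies, sets = sets, truth = truth,
       commonGenes = commonGenes(studies))
}

#' Intersect the gene lists of several studies
#'
#' Returns the genes measured by every platform, ordered as in the first
#' study; downstream analysis is restricted to this list, mirroring the
#' common-probe restriction of cross-platform microarray comparisons.
#'
#' @param studies a list of [ExpressionStudy-class] objects (or a single
#'   one).
#' @return character vector of common gene ids.
#' @export
commonGenes <- function(studies) {
  if (is(studies, "ExpressionStudy")) studies <- list(studies)
  if (!length(studies)) .stopf("need at least one study")
  lists <- lapply(studies, geneIds)
  common <- Reduce(intersect, lists)
  if (!length(common)) {
    .stopf("analysis error: studies share no genes")
  }
  lists[[1L]][lists[[1L]] %in% common]
}
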
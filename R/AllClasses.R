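#' ExpressionStudy: a log2 expression matrix with its sample design
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one
#' log2-scale intensity matrix (genes in rows, samples in columns) together
#' with the per-sample design labels of a MAQC-like two-condition study:
#' \code{platform}, \code{site}, \code{condition} (\code{"A"} or \code{"B"})
#' and \code{replicate}.
#'
#' Validity requires unique gene identifiers, finite values, complete design
#' labels for every sample, and at least two replicates in every
#' (platform, site, condition) cell so that two-sample statistics are
#' defined everywhere.
#'
#' All slots are inherited from \code{SummarizedExperiment}; the single
#' assay is named \code{"log2"}.
#'
#' @seealso [ExpressionStudy()], [readExpressionMatrix()], [generateStudy()]
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

.designCols <- c("platform", "site", "condition", "replicate")

setValidity("ExpressionStudy", function(object) {
  msgs <- character(0)
  vals <- SummarizedExperiment::assay(object)
  gn <- rownames(vals)
  if (is.null(gn) || anyNA(gn) || any(gn == "")) {
    msgs <- c(msgs, "gene identifiers (rownames) must be present and non-empty")
  } else if (anyDuplicated(gn)) {
    dup <- unique(gn[duplicated(gn)])
    msgs <- c(msgs, sprintf("duplicate gene id(s): %s",
                            paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (!all(is.finite(vals))) {
    msgs <- c(msgs, "expression values must all be finite")
  }
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(.designCols, colnames(cd))
  if (length(miss)) {
    msgs <- c(msgs, sprintf("design is missing column(s): %s",
                            paste(miss, collapse = ", ")))
  } else {
    for (cl in .designCols) {
      bad <- is.na(cd[[cl]])
      if (any(bad)) {
        msgs <- c(msgs, sprintf("sample(s) %s missing design label '%s'",
                                paste(rownames(cd)[bad], collapse = ", "), cl))
      }
    }
    if (!all(is.na(cd$condition)) && !all(cd$condition %in% c("A", "B"))) {
      msgs <- c(msgs, "condition labels must be 'A' or 'B'")
    }
    if (!length(msgs)) {
      cell <- table(paste(cd$platform, cd$site, cd$condition, sep = "|"))
      if (any(cell < 2L)) {
        msgs <- c(msgs, sprintf(
          "fewer than 2 replicates in cell(s): %s",
          paste(names(cell)[cell < 2L], collapse = ", ")))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionStudy
#'
#' @param values numeric matrix of log2 intensities, genes in rows (rownames
#'   are gene ids), samples in columns (colnames are sample ids).
#' @param design data.frame with one row per sample and columns
#'   \code{sample_id} (or rownames matching the matrix columns),
#'   \code{platform}, \code{site}, \code{condition}, \code{replicate}.
#'
#' @return a validated [ExpressionStudy-class] object.
#' @examples
#' vals <- matrix(rnorm(12, 8), 3, 4,
#'                dimnames = list(paste0("G", 1:3), paste0("s", 1:4)))
#' des <- data.frame(sample_id = paste0("s", 1:4), platform = "AFX",
#'                   site = "1", condition = rep(c("A", "B"), each = 2),
#'                   replicate = c(1, 2, 1, 2))
#' es <- ExpressionStudy(vals, des)
#' @export
ExpressionStudy <- function(values, design) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if ("sample_id" %in% colnames(design)) {
    rownames(design) <- design$sample_id
    design$sample_id <- NULL
  }
  if (is.null(colnames(values))) {
    .stopf("expression matrix must have sample ids as column names")
  }
  absent <- setdiff(colnames(values), rownames(design))
  if (length(absent)) {
    .stopf("sample(s) in matrix missing from design: %s",
           paste(absent, collapse = ", "))
  }
  design <- design[colnames(values), , drop = FALSE]
  design$site <- as.character(design$site)
  design$platform <- as.character(design$platform)
  design$condition <- as.character(design$condition)
  design$replicate <- as.integer(design$replicate)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values),
    colData = S4Vectors::DataFrame(design)
  )
  new("ExpressionStudy", se)
}

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionStudy", function(x, ...) rownames(x))

#' @rdname accessors
#' @export
setMethod("designInfo", "ExpressionStudy", function(x, ...) {
  as.data.frame(SummarizedExperiment::colData(x))
})

setMethod("show", "ExpressionStudy", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("ExpressionStudy:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  platforms:", paste(unique(cd$platform), collapse = ", "), "\n")
  cat("  sites:    ", paste(unique(cd$site), collapse = ", "), "\n")
  cat("  conditions:", paste(sort(unique(cd$condition)), collapse = "/"),
      "with", max(cd$replicate), "replicates\n")
})

#' GeneSetCollection: named gene sets standing in for GO terms
#'
#' Holds a list of uniquely named gene sets (deduplicated, non-empty
#' character vectors of gene ids), their free-text descriptions, and an
#' optional explicit gene universe.
#'
#' @slot sets named list of character vectors of member gene ids.
#' @slot descriptions character vector parallel to \code{sets}.
#' @slot universe character vector of gene ids (may be empty = unset).
#'
#' @seealso [GeneSetCollection()], [readGmt()], [generateGeneSets()]
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", descriptions = "character",
                        universe = "character"))

setValidity("GeneSetCollection", function(object) {
  msgs <- character(0)
  ids <- names(object@sets)
  if (is.null(ids) || any(ids == "") || anyNA(ids)) {
    msgs <- c(msgs, "all sets must be named")
  } else if (anyDuplicated(ids)) {
    msgs <- c(msgs, sprintf("duplicate set id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  sizes <- lengths(object@sets)
  if (any(sizes == 0L)) {
    msgs <- c(msgs, "gene sets must be non-empty")
  }
  if (any(vapply(object@sets, anyDuplicated, 1L) > 0L)) {
    msgs <- c(msgs, "set membership must be deduplicated")
  }
  if (length(object@descriptions) != length(object@sets)) {
    msgs <- c(msgs, "descriptions must parallel sets")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors (member gene ids).
#' @param descriptions optional character vector of set descriptions.
#' @param universe optional character vector: the explicit gene universe.
#' @return a validated [GeneSetCollection-class].
#' @examples
#' gsc <- GeneSetCollection(list(S1 = c("G1", "G2"), S2 = c("G2", "G3")))
#' setSizes(gsc)
#' @export
GeneSetCollection <- function(sets, descriptions = NULL, universe = character(0)) {
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  names(descriptions) <- names(sets)
  new("GeneSetCollection", sets = sets,
      descriptions = as.character(descriptions),
      universe = as.character(universe))
}

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x, ...) x@sets)

#' @rdname accessors
#' @export
setMethod("setIds", "GeneSetCollection", function(x, ...) names(x@sets))

#' @rdname accessors
#' @export
setMethod("setSizes", "GeneSetCollection", function(x, ...) {
  stats::setNames(lengths(x@sets), names(x@sets))
})

#' @rdname accessors
#' @export
setMethod("setDescriptions", "GeneSetCollection", function(x, ...) {
  stats::setNames(x@descriptions, names(x@sets))
})

#' @rdname accessors
#' @export
setMethod("universe", "GeneSetCollection", function(x, ...) x@universe)

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat("GeneSetCollection:", length(sz), "sets, sizes",
      min(sz), "-", max(sz), "\n")
  if (length(object@universe)) {
    cat("  universe:", length(object@universe), "genes\n")
  }
})

#' StudyDesign: parameters of the MAQC-like synthetic study generator
#'
#' Encodes the design of a simulated two-condition (A vs B) multi-platform,
#' multi-site expression study with planted differentially expressed genes
#' and planted enriched gene sets. Defaults are desk-scale analogues of the
#' MAQC reference design (three platforms, three test sites per platform,
#' five replicates per condition per site) with a reduced gene count.
#'
#' @slot nGenes number of genes in the simulated transcriptome.
#' @slot platforms platform labels.
#' @slot sitesPerPlatform number of independent test sites per platform.
#' @slot replicates replicates per condition per site.
#' @slot deFraction background probability that a gene is differentially
#'   expressed.
#' @slot effectSizeLog2 mean absolute log2 effect of a DE gene.
#' @slot effectSd standard deviation of the absolute effect.
#' @slot geneSdRange range of per-gene noise standard deviations.
#' @slot siteSd scale of per-site, per-gene offsets.
#' @slot platformSd scale of per-platform, per-gene offsets.
#' @slot platformCoverage proportion of genes each platform measures.
#' @slot nSets number of gene sets to generate.
#' @slot setSizeRange integer range of set sizes.
#' @slot nPlantedSets number of sets planted as enriched.
#' @slot plantedDeEnrichment multiplicative increase of the DE probability
#'   inside planted sets (capped at probability one).
#' @slot seed integer seed; expands to per-component substreams.
#'
#' @seealso [studyDesign()], [generateStudy()]
#' @export
setClass("StudyDesign",
         representation(nGenes = "integer", platforms = "character",
                        sitesPerPlatform = "integer", replicates = "integer",
                        deFraction = "numeric", effectSizeLog2 = "numeric",
                        effectSd = "numeric", geneSdRange = "numeric",
                        siteSd = "numeric", platformSd = "numeric",
                        platformCoverage = "numeric", nSets = "integer",
                        setSizeRange = "integer", nPlantedSets = "integer",
                        plantedDeEnrichment = "numeric", seed = "integer"))

setValidity("StudyDesign", function(object) {
  msgs <- character(0)
  if (object@nGenes < 1L) msgs <- c(msgs, "nGenes must be positive")
  if (!length(object@platforms) || anyDuplicated(object@platforms)) {
    msgs <- c(msgs, "platforms must be non-empty and unique")
  }
  if (object@sitesPerPlatform < 1L) msgs <- c(msgs, "sitesPerPlatform must be positive")
  if (object@replicates < 2L) msgs <- c(msgs, "replicates must be >= 2")
  if (object@deFraction < 0 || object@deFraction >= 1) {
    msgs <- c(msgs, "deFraction must be in [0, 1)")
  }
  if (object@effectSizeLog2 <= 0) msgs <- c(msgs, "effectSizeLog2 must be positive")
  if (object@effectSd < 0) msgs <- c(msgs, "effectSd must be nonnegative")
  if (length(object@geneSdRange) != 2L || any(object@geneSdRange <= 0) ||
      diff(object@geneSdRange) < 0) {
    msgs <- c(msgs, "geneSdRange must be an increasing positive pair")
  }
  if (object@siteSd < 0 || object@platformSd < 0) {
    msgs <- c(msgs, "siteSd and platformSd must be nonnegative")
  }
  if (object@platformCoverage <= 0 || object@platformCoverage > 1) {
    msgs <- c(msgs, "platformCoverage must be in (0, 1]")
  }
  if (object@nSets < 1L) msgs <- c(msgs, "nSets must be positive")
  if (length(object@setSizeRange) != 2L || object@setSizeRange[1] < 2L ||
      diff(object@setSizeRange) < 0) {
    msgs <- c(msgs, "setSizeRange must be an increasing pair with minimum >= 2")
  } else if (object@setSizeRange[2] > object@nGenes) {
    msgs <- c(msgs, "setSizeRange maximum exceeds nGenes")
  }
  if (object@nPlantedSets < 0L || object@nPlantedSets > object@nSets) {
    msgs <- c(msgs, "nPlantedSets must be between 0 and nSets")
  }
  if (object@plantedDeEnrichment < 1) {
    msgs <- c(msgs, "plantedDeEnrichment must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Create a synthetic study design
#'
#' @param nGenes,platforms,sitesPerPlatform,replicates study layout; see
#'   [StudyDesign-class].
#' @param deFraction,effectSizeLog2,effectSd differential-expression model.
#' @param geneSdRange,siteSd,platformSd noise model (log2 scale).
#' @param platformCoverage proportion of genes measured by each platform.
#' @param nSets,setSizeRange,nPlantedSets,plantedDeEnrichment gene-set
#'   collection and planted enrichment.
#' @param seed integer seed.
#' @return a validated [StudyDesign-class].
#' @examples
#' d <- studyDesign(nGenes = 500, platforms = "AFX", sitesPerPlatform = 1)
#' @export
studyDesign <- function(nGenes = 2000, platforms = c("AFX", "AG1", "ILM"),
                        sitesPerPlatform = 3, replicates = 5,
                        deFraction = 0.2, effectSizeLog2 = 1,
                        effectSd = 0.5, geneSdRange = c(0.1, 0.6),
                        siteSd = 0.15, platformSd = 0.25,
                        platformCoverage = 0.85, nSets = 150,
                        setSizeRange = c(15, 80), nPlantedSets = 10,
                        plantedDeEnrichment = 5, seed = 1) {
  new("StudyDesign", nGenes = as.integer(nGenes),
      platforms = as.character(platforms),
      sitesPerPlatform = as.integer(sitesPerPlatform),
      replicates = as.integer(replicates),
      deFraction = as.numeric(deFraction),
      effectSizeLog2 = as.numeric(effectSizeLog2),
      effectSd = as.numeric(effectSd),
      geneSdRange = as.numeric(geneSdRange),
      siteSd = as.numeric(siteSd), platformSd = as.numeric(platformSd),
      platformCoverage = as.numeric(platformCoverage),
      nSets = as.integer(nSets), setSizeRange = as.integer(setSizeRange),
      nPlantedSets = as.integer(nPlantedSets),
      plantedDeEnrichment = as.numeric(plantedDeEnrichment),
      seed = as.integer(seed))
}

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", object@nGenes, "genes;",
      length(object@platforms), "platform(s) x",
      object@sitesPerPlatform, "site(s) x 2 conditions x",
      object@replicates, "replicates\n")
  cat(sprintf("  DE: fraction %.3g, |effect| ~ N(%.2g, %.2g^2) log2\n",
              object@deFraction, object@effectSizeLog2, object@effectSd))
  cat(sprintf("  sets: %d (sizes %d-%d), %d planted at enrichment %.3g\n",
              object@nSets, object@setSizeRange[1], object@setSizeRange[2],
              object@nPlantedSets, object@plantedDeEnrichment))
})

#' GroundTruth: what the generator planted
#'
#' Records the genes made differentially expressed (with their true log2
#' A - B effect) and the gene sets planted as enriched, including the
#' per-set regulation direction used for their members.
#'
#' @slot deGenes data.frame with columns \code{gene} and \code{delta}.
#' @slot plantedSets character vector of planted set ids.
#' @slot setDirections named numeric (+1 / -1) per planted set.
#'
#' @export
setClass("GroundTruth",
         representation(deGenes = "data.frame", plantedSets = "character",
                        setDirections = "numeric"))

setValidity("GroundTruth", function(object) {
  msgs <- character(0)
  if (!all(c("gene", "delta") %in% colnames(object@deGenes))) {
    msgs <- c(msgs, "deGenes needs columns 'gene' and 'delta'")
  } else if (any(object@deGenes$delta == 0)) {
    msgs <- c(msgs, "deGenes must have nonzero effects")
  }
  if (length(object@setDirections) &&
      !all(object@setDirections %in% c(-1, 1))) {
    msgs <- c(msgs, "setDirections must be +1/-1")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname accessors
#' @export
setMethod("deGenes", "GroundTruth", function(x, ...) x@deGenes)

#' @rdname accessors
#' @export
setMethod("plantedSets", "GroundTruth", function(x, ...) x@plantedSets)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@deGenes), "DE genes;",
      length(object@plantedSets), "planted set(s)\n")
})
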
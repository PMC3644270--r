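#' Default pipeline configuration
#'
#' @return a nested list of the defaults [runStudy()] merges user
#'   configuration into.
#' @export
defaultConfig <- function() {
  list(
    mode = "simulate",
    design = list(),
    load = NULL,
    criteria = list(methods = c("FC", "SAM", "TTEST"),
                    pCutoffs = c(0.01, 0.05), fcCutoff = 1),
    gsea = list(enabled = TRUE, nPerm = 1000, weightExponent = 1,
                minSize = 5, maxSize = 500, fdrCutoff = 0.25),
    lrpath = list(enabled = TRUE, minSize = 5, maxSize = 500,
                  fdrCutoff = 0.25, restrictToDegList = FALSE),
    outputDir = NULL,
    writeInputs = FALSE,
    seed = 1
  )
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

.normalizeConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- .mergeConfig(defaultConfig(), config)
  if (!is(cfg$design, "StudyDesign")) {
    args <- cfg$design
    if (is.null(args$seed)) args$seed <- cfg$seed
    cfg$design <- do.call(studyDesign, args)
  }
  cfg$criteria$methods <- match.arg(cfg$criteria$methods,
                                    c("FC", "SAM", "TTEST"),
                                    several.ok = TRUE)
  cfg
}

.runSeed <- function(seed, i) (abs(as.integer(seed)) %% 214748L) * 10000L + i

# evidence source feeding the logistic engine, tied to the DEG criterion:
# each criterion contributes the per-gene quantity it ranks by
.pSourceFor <- function(method) {
  switch(method, SAM = "sam_p", FC = "log2fc", "t_p")
}

#' Run the full concordance study
#'
#' Orchestrates every stage: simulate (or load) the multi-platform study,
#' restrict to the cross-platform common genes, compute per-site gene
#' statistics, select DEG lists for each criterion and cutoff, run both
#' enrichment engines per combination, and compare all significant-term
#' lists. Deterministic given the configuration and seed; per-combination
#' failures are recorded in the manifest and downstream dependents
#' skipped.
#'
#' @param config a nested list (see [defaultConfig()]), or the path to a
#'   YAML file with the same structure. In \code{mode = "simulate"},
#'   \code{design} holds [studyDesign()] arguments (or a ready
#'   [StudyDesign-class]); in \code{mode = "load"}, \code{load} must give
#'   \code{matrices} (named per-platform paths), \code{design} (sidecar
#'   TSV) and \code{gmt}.
#' @return a list with \code{config}, \code{commonGenes}, \code{stats},
#'   \code{degLists}, \code{degCounts}, \code{enrichment},
#'   \code{catalog}, \code{concordance}, \code{truth} (simulate mode) and
#'   \code{manifest}. When \code{config$outputDir} is set, tables are
#'   also written there as TSV.
#' @examples
#' \donttest{
#' run <- runStudy(list(design = list(nGenes = 400, platforms = "AFX",
#'                                    sitesPerPlatform = 2, nSets = 30,
#'                                    setSizeRange = c(5, 20),
#'                                    nPlantedSets = 3),
#'                      gsea = list(nPerm = 200), seed = 42))
#' run$degCounts
#' }
#' @export
runStudy <- function(config = list()) {
  cfg <- .normalizeConfig(config)
  manifest <- list()
  note <- function(stage, combo, status, detail = "") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, combo = combo, status = status, detail = detail,
      stringsAsFactors = FALSE)
  }

  truth <- NULL
  if (cfg$mode == "simulate") {
    sim <- generateStudy(cfg$design)
    studies <- sim$studies
    sets <- sim$sets
    truth <- sim$truth
  } else if (cfg$mode == "load") {
    ld <- cfg$load
    paths <- c(unlist(ld$matrices), ld$design, ld$gmt)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      .stopf("validation error: missing input file(s): %s",
             paste(missing, collapse = ", "))
    }
    studies <- lapply(ld$matrices, readExpressionMatrix,
                      designPath = ld$design)
    names(studies) <- names(ld$matrices)
    sets <- readGmt(ld$gmt)
  } else {
    .stopf("unknown mode '%s'", cfg$mode)
  }
  common <- commonGenes(studies)
  note("input", "all", "completed",
       sprintf("%d platform(s), %d common genes", length(studies),
               length(common)))

  combos <- list()
  for (plName in names(studies)) {
    st <- studies[[plName]]
    for (site in unique(designInfo(st)$site)) {
      combos[[paste(plName, site, sep = "|")]] <-
        list(platform = plName, site = site)
    }
  }

  stats <- list()
  runIx <- 0L
  for (key in names(combos)) {
    cb <- combos[[key]]
    runIx <- runIx + 1L
    stats[[key]] <- geneStatistics(studies[[cb$platform]], cb$site,
                                   genes = common,
                                   seed = .runSeed(cfg$seed, runIx))
    note("stats", key, "completed",
         sprintf("s0 = %.4g", attr(stats[[key]], "s0")))
  }

  degLists <- list()
  for (key in names(combos)) {
    for (me in cfg$criteria$methods) for (p in cfg$criteria$pCutoffs) {
      crit <- degCriterion(me, p, cfg$criteria$fcCutoff)
      dk <- paste(key, me, p, sep = "|")
      degLists[[dk]] <- suppressMessages(selectDegs(stats[[key]], crit))
      note("degs", dk, "completed", sprintf("%d genes", nrow(degLists[[dk]])))
    }
  }
  degCounts <- degCountTable(degLists)

  enrichment <- list()
  catRows <- list()
  for (key in names(combos)) {
    cb <- combos[[key]]
    for (me in cfg$criteria$methods) for (p in cfg$criteria$pCutoffs) {
      dk <- paste(key, me, p, sep = "|")
      dl <- degLists[[dk]]
      if (!nrow(dl)) {
        note("enrich", dk, "skipped", "empty DEG list")
        next
      }
      if (isTRUE(cfg$gsea$enabled)) {
        runIx <- runIx + 1L
        ek <- paste("gsea", dk, sep = "|")
        res <- tryCatch(
          suppressMessages(runGsea(
            dl, stats[[key]], sets,
            weightExponent = cfg$gsea$weightExponent,
            nPerm = cfg$gsea$nPerm, minSize = cfg$gsea$minSize,
            maxSize = cfg$gsea$maxSize, fdrCutoff = cfg$gsea$fdrCutoff,
            seed = .runSeed(cfg$seed, runIx))),
          error = function(e) e)
        if (inherits(res, "error")) {
          note("gsea", dk, "failed", conditionMessage(res))
        } else {
          enrichment[[ek]] <- res
          terms <- rankSignificantTerms(res, cfg$gsea$fdrCutoff)
          catRows[[ek]] <- list(engine = "gsea", platform = cb$platform,
                                site = cb$site, method = me, p_cutoff = p,
                                terms = terms)
          note("gsea", dk, "completed",
               sprintf("%d significant", sum(res$significant)))
        }
      }
      if (isTRUE(cfg$lrpath$enabled)) {
        ek <- paste("lrpath", dk, sep = "|")
        restrict <- if (isTRUE(cfg$lrpath$restrictToDegList)) dl$gene
        res <- tryCatch(
          suppressMessages(runLrpath(
            stats[[key]], pSource = .pSourceFor(me), sets = sets,
            minSize = cfg$lrpath$minSize, maxSize = cfg$lrpath$maxSize,
            fdrCutoff = cfg$lrpath$fdrCutoff, restrict = restrict)),
          error = function(e) e)
        if (inherits(res, "error")) {
          note("lrpath", dk, "failed", conditionMessage(res))
        } else {
          enrichment[[ek]] <- res
          catRows[[ek]] <- list(
            engine = "lrpath", platform = cb$platform, site = cb$site,
            method = me, p_cutoff = p,
            terms = list(all = rankSignificantTerms(res, cfg$lrpath$fdrCutoff)))
          note("lrpath", dk, "completed",
               sprintf("%d significant", sum(res$significant)))
        }
      }
    }
  }

  catalog <- data.frame(
    engine = vapply(catRows, `[[`, character(1), "engine"),
    platform = vapply(catRows, `[[`, character(1), "platform"),
    site = vapply(catRows, `[[`, character(1), "site"),
    method = vapply(catRows, `[[`, character(1), "method"),
    p_cutoff = vapply(catRows, `[[`, numeric(1), "p_cutoff"),
    stringsAsFactors = FALSE, row.names = NULL)
  catalog$terms <- lapply(catRows, `[[`, "terms")

  concordance <- if (nrow(catalog)) suppressMessages(compareAll(catalog))
    else NULL
  note("concordance", "all",
       if (is.null(concordance)) "skipped" else "completed",
       if (is.null(concordance)) "no enrichment results"
       else sprintf("%d comparisons", nrow(concordance)))

  manifest <- do.call(rbind, manifest)
  out <- list(config = cfg, commonGenes = common, stats = stats,
              degLists = degLists, degCounts = degCounts,
              enrichment = enrichment, catalog = catalog,
              concordance = concordance, truth = truth,
              manifest = manifest)

  if (!is.null(cfg$outputDir)) .writeRunOutputs(out, cfg, studies, sets)
  out
}

.writeRunOutputs <- function(run, cfg, studies, sets) {
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  od <- cfg$outputDir
  counts <- data.frame(criterion = rownames(run$degCounts),
                       run$degCounts, check.names = FALSE)
  writeResultsTable(counts, file.path(od, "deg_counts.tsv"))
  if (!is.null(run$concordance)) {
    writeResultsTable(run$concordance, file.path(od, "concordance.tsv"))
  }
  for (ek in names(run$enrichment)) {
    fn <- paste0(gsub("[|]", "_", ek), ".tsv")
    writeResultsTable(run$enrichment[[ek]], file.path(od, fn))
  }
  writeResultsTable(run$manifest, file.path(od, "manifest.tsv"))
  if (isTRUE(cfg$writeInputs)) {
    for (plName in names(studies)) {
      writeExpressionStudy(studies[[plName]],
                           file.path(od, paste0(plName, "_matrix.tsv")),
                           file.path(od, paste0(plName, "_design.tsv")))
    }
    writeGmt(sets, file.path(od, "gene_sets.gmt"))
    if (!is.null(run$truth)) {
      writeResultsTable(deGenes(run$truth), file.path(od, "truth_de.tsv"))
    }
  }
  invisible(od)
}

#' Table of DEG counts per criterion and platform/site
#'
#' Rows follow the fixed criterion order (FC at p < 0.01, FC at p < 0.05,
#' SAM, then t-test); columns are \code{platform_site} labels.
#'
#' @param degLists named list of \code{"DEGList"} objects keyed
#'   \code{"platform|site|method|pCutoff"} (as built by [runStudy()]).
#' @return integer matrix of DEG counts.
#' @export
degCountTable <- function(degLists) {
  info <- do.call(rbind, lapply(names(degLists), function(k) {
    f <- strsplit(k, "|", fixed = TRUE)[[1L]]
    data.frame(platform = f[1L], site = f[2L], method = f[3L],
               p = as.numeric(f[4L]), n = nrow(degLists[[k]]),
               stringsAsFactors = FALSE)
  }))
  methodOrder <- c("FC", "SAM", "TTEST")
  rows <- unique(info[order(match(info$method, methodOrder), info$p),
                      c("method", "p")])
  cols <- unique(info[order(info$platform, info$site),
                      c("platform", "site")])
  rowLab <- sprintf("%s (p < %g)", rows$method, rows$p)
  colLab <- paste(cols$platform, cols$site, sep = "_")
  out <- matrix(0L, nrow(rows), nrow(cols),
                dimnames = list(rowLab, colLab))
  for (i in seq_len(nrow(info))) {
    r <- which(rows$method == info$method[i] & rows$p == info$p[i])
    cc <- which(cols$platform == info$platform[i] &
                  cols$site == info$site[i])
    out[r, cc] <- info$n[i]
  }
  out
}
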
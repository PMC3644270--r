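#' Read a log2 expression matrix with its design sidecar
#'
#' The matrix file is a TSV whose header row holds sample ids and whose
#' first column holds gene ids; the design file is a TSV keyed by
#' \code{sample_id} with columns \code{platform}, \code{site},
#' \code{condition} and \code{replicate}. Gene and sample order from the
#' files is preserved.
#'
#' @param path path to the expression matrix TSV.
#' @param designPath path to the design TSV.
#' @return an [ExpressionStudy-class].
#' @seealso [writeExpressionStudy()]
#' @export
readExpressionMatrix <- function(path, designPath) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) .stopf("format error in %s: no sample columns", path)
  genes <- raw[[1L]]
  if (anyDuplicated(genes)) {
    .stopf("format error in %s: duplicate gene id '%s'",
           path, genes[duplicated(genes)][1L])
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    .stopf("format error in %s: non-numeric cell at gene '%s', sample '%s'",
           path, genes[bad[1L]], colnames(vals)[bad[2L]])
  }
  rownames(num) <- genes
  design <- utils::read.delim(designPath, header = TRUE, sep = "\t",
                              check.names = FALSE,
                              colClasses = "character")
  if (!"sample_id" %in% colnames(design)) {
    .stopf("format error in %s: missing 'sample_id' column", designPath)
  }
  missingSamples <- setdiff(colnames(num), design$sample_id)
  if (length(missingSamples)) {
    .stopf("format error: sample(s) %s present in %s but missing from %s",
           paste(missingSamples, collapse = ", "), path, designPath)
  }
  missingCols <- setdiff(.designCols, colnames(design))
  if (length(missingCols)) {
    .stopf("format error in %s: missing design column(s) %s",
           designPath, paste(missingCols, collapse = ", "))
  }
  for (cl in .designCols) {
    bad <- is.na(design[[cl]]) | design[[cl]] == ""
    if (any(bad)) {
      .stopf("format error in %s: sample '%s' missing '%s'",
             designPath, design$sample_id[bad][1L], cl)
    }
  }
  ExpressionStudy(num, design)
}

#' Write an ExpressionStudy as matrix + design TSVs
#'
#' @param study an [ExpressionStudy-class].
#' @param path output path for the expression matrix TSV.
#' @param designPath output path for the design TSV.
#' @return invisibly, the two paths.
#' @export
writeExpressionStudy <- function(study, path, designPath) {
  vals <- SummarizedExperiment::assay(study)
  df <- data.frame(gene_id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  des <- designInfo(study)
  des <- data.frame(sample_id = rownames(des), des, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(des, designPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, designPath))
}

#' Read a GMT gene-set file
#'
#' One set per line: \code{set_id TAB description TAB member TAB member ...}
#' (the MSigDB dialect: tab-separated, no quoting, trailing tabs ignored).
#' Duplicate members within a line are removed with a warning; a duplicate
#' set id or a line with fewer than three fields is a format error.
#'
#' @param path path to the GMT file.
#' @return a [GeneSetCollection-class].
#' @seealso [writeGmt()]
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    while (length(fields) && fields[length(fields)] == "") {
      fields <- fields[-length(fields)]
    }
    if (length(fields) < 3L) {
      .stopf("format error in %s, line %d: fewer than 3 fields", path, i)
    }
    id <- fields[1L]
    if (id %in% names(sets)) {
      .stopf("format error in %s, line %d: duplicate set id '%s'",
             path, i, id)
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning(sprintf("set '%s': duplicate member(s) removed", id),
              call. = FALSE)
      members <- unique(members)
    }
    sets[[id]] <- members
    desc[id] <- fields[2L]
  }
  GeneSetCollection(sets, desc)
}

#' Write a GeneSetCollection as GMT
#'
#' @param collection a [GeneSetCollection-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGmt <- function(collection, path) {
  ids <- setIds(collection)
  desc <- setDescriptions(collection)
  desc[desc == ""] <- "na"
  lines <- vapply(ids, function(id) {
    paste(c(id, desc[[id]], collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a results table as TSV
#'
#' Writes a homogeneous data.frame with a header row; numeric columns keep
#' full double precision so a re-read reproduces values to at least six
#' significant digits.
#'
#' @param rows a data.frame.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @seealso [readResultsTable()]
#' @export
writeResultsTable <- function(rows, path) {
  rows <- as.data.frame(rows)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [writeResultsTable()]
#'
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
readResultsTable <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
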
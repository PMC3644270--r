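#' @title Accessor generics
#' @description Small accessor generics used across the package's S4 classes.
#' @param x an object
#' @param ... passed to methods
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("designInfo", function(x, ...) standardGeneric("designInfo"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x, ...) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("setIds", function(x, ...) standardGeneric("setIds"))

#' @rdname accessors
#' @export
setGeneric("setSizes", function(x, ...) standardGeneric("setSizes"))

#' @rdname accessors
#' @export
setGeneric("setDescriptions", function(x, ...) standardGeneric("setDescriptions"))

#' @rdname accessors
#' @export
setGeneric("universe", function(x, ...) standardGeneric("universe"))

#' @rdname accessors
#' @export
setGeneric("deGenes", function(x, ...) standardGeneric("deGenes"))

#' @rdname accessors
#' @export
setGeneric("plantedSets", function(x, ...) standardGeneric("plantedSets"))
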
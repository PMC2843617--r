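#' @import methods
NULL

#' Gene symbols of an object
#'
#' @param x a [GeneList], [InteractorTree], [BackgroundNetwork] or
#'   [Subnetwork].
#' @return character vector of normalized gene symbols.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Label of a gene list or library
#' @param x object carrying a name label.
#' @return length-one character.
#' @export
setGeneric("objectName", function(x) standardGeneric("objectName"))

#' Free-text description
#' @param x a [GeneList].
#' @return length-one character (possibly empty).
#' @export
setGeneric("objectDescription", function(x) standardGeneric("objectDescription"))

#' Convert an object's node collection to a GeneList
#'
#' The node set in deterministic (discovery or rank) order.
#'
#' @param x an [InteractorTree], [BackgroundNetwork] or [Subnetwork].
#' @param name optional label for the resulting list.
#' @return a [GeneList].
#' @export
setGeneric("asGeneList", function(x, name = NULL) standardGeneric("asGeneList"))

#' Write an object as a SIF (Simple Interaction Format) file
#'
#' One tab-delimited row per edge, `nodeA<TAB>relation<TAB>nodeB`, each
#' unordered edge written once with endpoints in lexicographic order, rows
#' sorted; nodes without any incident edge are written as single-field rows
#' (standard Cytoscape lone-node syntax).
#'
#' @param x a [BackgroundNetwork] or [Subnetwork].
#' @param path output file path.
#' @param ... method-specific arguments.
#' @return `path`, invisibly.
#' @export
setGeneric("writeSIF", function(x, path, ...) standardGeneric("writeSIF"))
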
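setOldClass("igraph")

## ---------------------------------------------------------------- GeneList

#' GeneList: a named, ordered, de-duplicated collection of gene symbols
#'
#' Symbols are stored in canonical form (trimmed, upper-cased, optionally
#' synonym-resolved; see [normalizeSymbol()]). Construction de-duplicates
#' while preserving first-occurrence order. Empty lists are representable.
#'
#' @slot name label of the list.
#' @slot description free text, may be empty.
#' @slot genes character vector of unique canonical symbols.
#'
#' @param name label string.
#' @param genes character vector of raw symbols; normalized and
#'   de-duplicated (first occurrence kept).
#' @param description free text.
#' @param synonyms optional synonym table (see [synonymTable()]) applied
#'   during normalization.
#' @return a `GeneList`.
#' @examples
#' gl <- GeneList("demo", c(" nanog ", "SOX2", "sox2"))
#' genes(gl)
#' @export GeneList
#' @exportClass GeneList
#' @aliases GeneList-class
GeneList <- setClass("GeneList",
  slots = c(name = "character", description = "character",
            genes = "character"))

setValidity("GeneList", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "'name' must be a single non-NA string")
  if (length(object@description) != 1L || is.na(object@description))
    msg <- c(msg, "'description' must be a single non-NA string")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate gene symbols after normalization")
  if (any(!nzchar(object@genes)) || anyNA(object@genes))
    msg <- c(msg, "empty or NA gene symbols are not allowed")
  if (any(grepl("[\t\n\r]", object@genes)))
    msg <- c(msg, "gene symbols must not contain tab or newline characters")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneList constructor (normalizes and de-duplicates `genes`).
GeneList <- function(name, genes = character(), description = "",
                     synonyms = NULL) {
  genes <- as.character(genes)
  if (length(genes))
    genes <- unique(normalizeSymbol(genes, synonyms = synonyms))
  new("GeneList", name = as.character(name),
      description = as.character(description), genes = genes)
}

#' @rdname genes
#' @export
setMethod("genes", "GeneList", function(x) x@genes)

#' @rdname objectName
#' @export
setMethod("objectName", "GeneList", function(x) x@name)

#' @rdname objectDescription
#' @export
setMethod("objectDescription", "GeneList", function(x) x@description)

#' @describeIn GeneList number of member genes.
#' @param x a `GeneList`.
#' @export
setMethod("length", "GeneList", function(x) length(x@genes))

setMethod("show", "GeneList", function(object) {
  cat(sprintf("GeneList '%s': %d gene%s%s\n", object@name,
              length(object@genes),
              if (length(object@genes) == 1L) "" else "s",
              if (length(object@genes) == 0L) " (empty)" else ""))
  if (length(object@genes)) {
    shown <- utils::head(object@genes, 6L)
    cat("  ", paste(shown, collapse = ", "),
        if (length(object@genes) > 6L) ", ..." else "", "\n", sep = "")
  }
})

## --------------------------------------------------------- GeneSetLibrary

#' GeneSetLibrary: an ordered collection of labeled gene lists (one GMT file)
#'
#' Set names are unique within a library; the background universe (union of
#' all member symbols) is derived at construction and cached.
#'
#' @slot name library label.
#' @slot sets list of [GeneList] objects, in file/insertion order.
#' @slot universe cached union of all member symbols.
#' @slot duplicatesDropped named integer: per set, how many within-row
#'   duplicate symbols were silently dropped at read time.
#'
#' @param name library label.
#' @param sets list of [GeneList] objects.
#' @param duplicatesDropped optional named integer counter (see slot).
#' @return a `GeneSetLibrary`.
#' @export GeneSetLibrary
#' @exportClass GeneSetLibrary
#' @aliases GeneSetLibrary-class
GeneSetLibrary <- setClass("GeneSetLibrary",
  slots = c(name = "character", sets = "list", universe = "character",
            duplicatesDropped = "integer"))

setValidity("GeneSetLibrary", function(object) {
  msg <- character()
  if (!all(vapply(object@sets, is, logical(1), "GeneList")))
    msg <- c(msg, "'sets' must be a list of GeneList objects")
  nm <- vapply(object@sets, objectName, character(1))
  if (anyDuplicated(nm))
    msg <- c(msg, sprintf("duplicate set name: '%s'",
                          nm[duplicated(nm)][1L]))
  expected <- unique(unlist(lapply(object@sets, genes), use.names = FALSE))
  if (!setequal(object@universe, expected))
    msg <- c(msg, "cached universe does not equal the union of member genes")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneSetLibrary constructor; derives and caches the universe.
GeneSetLibrary <- function(name, sets = list(),
                           duplicatesDropped = integer()) {
  universe <- unique(unlist(lapply(sets, genes), use.names = FALSE))
  if (is.null(universe)) universe <- character()
  new("GeneSetLibrary", name = as.character(name), sets = sets,
      universe = universe,
      duplicatesDropped = duplicatesDropped)
}

#' @rdname objectName
#' @export
setMethod("objectName", "GeneSetLibrary", function(x) x@name)

#' @describeIn GeneSetLibrary number of member sets.
#' @param x a `GeneSetLibrary`.
#' @export
setMethod("length", "GeneSetLibrary", function(x) length(x@sets))

#' Member gene sets of a library
#' @param lib a [GeneSetLibrary].
#' @return list of [GeneList] objects in library order.
#' @export
geneSets <- function(lib) {
  stopifnot(is(lib, "GeneSetLibrary"))
  lib@sets
}

#' Set labels of a library, in order
#' @param lib a [GeneSetLibrary].
#' @return character vector.
#' @export
setNames2 <- function(lib) {
  stopifnot(is(lib, "GeneSetLibrary"))
  vapply(lib@sets, objectName, character(1))
}

#' Background universe of a library
#'
#' The union of all member gene symbols, cached at construction.
#' @param lib a [GeneSetLibrary].
#' @return character vector of symbols.
#' @export
universe <- function(lib) {
  stopifnot(is(lib, "GeneSetLibrary"))
  lib@universe
}

#' Within-row duplicate counter from GMT reading
#' @param lib a [GeneSetLibrary].
#' @return named integer, one entry per set read with duplicates dropped.
#' @export
duplicatesDropped <- function(lib) {
  stopifnot(is(lib, "GeneSetLibrary"))
  lib@duplicatesDropped
}

#' @describeIn GeneSetLibrary extract one member set by index or name.
#' @param i numeric index or set name.
#' @export
setMethod("[[", "GeneSetLibrary", function(x, i) {
  if (is.character(i)) {
    hit <- match(i, setNames2(x))
    if (is.na(hit)) stop(sprintf("no gene set named '%s'", i))
    i <- hit
  }
  x@sets[[i]]
})

setMethod("show", "GeneSetLibrary", function(object) {
  cat(sprintf("GeneSetLibrary '%s': %d set%s, universe of %d genes\n",
              object@name, length(object@sets),
              if (length(object@sets) == 1L) "" else "s",
              length(object@universe)))
})

## ------------------------------------------------------ BackgroundNetwork

#' BackgroundNetwork: a simple undirected graph over gene symbols
#'
#' Wraps an igraph object; construction normalizes symbols, merges duplicate
#' and reversed-duplicate edges (keeping the maximum weight, first relation
#' string) and drops self-loops, keeping a counter of loops dropped.
#'
#' @slot graph the underlying undirected simple igraph.
#' @slot kind one of `"ppi"`, `"coexpression"`, `"coannotation"`, `"custom"`.
#' @slot selfLoopsDropped number of self-loop rows dropped at construction.
#'
#' @param edges two-column character matrix or data.frame of endpoints
#'   (raw symbols; normalized here).
#' @param kind network kind tag.
#' @param weight optional numeric edge weights, recycled rules not applied
#'   (must match `nrow(edges)`).
#' @param relation optional character relation strings (SIF column 2).
#' @param nodes optional additional (possibly isolated) node symbols.
#' @param synonyms optional synonym table used in normalization.
#' @return a `BackgroundNetwork`.
#' @export BackgroundNetwork
#' @exportClass BackgroundNetwork
#' @aliases BackgroundNetwork-class
BackgroundNetwork <- setClass("BackgroundNetwork",
  slots = c(graph = "igraph", kind = "character",
            selfLoopsDropped = "integer"))

setValidity("BackgroundNetwork", function(object) {
  msg <- character()
  if (!object@kind %in% c("ppi", "coexpression", "coannotation", "custom"))
    msg <- c(msg, "unknown network kind")
  if (igraph::is_directed(object@graph))
    msg <- c(msg, "graph must be undirected")
  if (igraph::any_multiple(object@graph) ||
      any(igraph::which_loop(object@graph)))
    msg <- c(msg, "graph must be simple (no parallel edges or self-loops)")
  if (length(msg)) msg else TRUE
})

#' @describeIn BackgroundNetwork constructor from an edge table.
BackgroundNetwork <- function(edges, kind = "custom", weight = NULL,
                              relation = NULL, nodes = character(),
                              synonyms = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L)
    stop("'edges' must have two columns")
  a <- if (nrow(edges)) normalizeSymbol(edges[, 1L], synonyms) else character()
  b <- if (nrow(edges)) normalizeSymbol(edges[, 2L], synonyms) else character()
  nodes <- if (length(nodes)) normalizeSymbol(nodes, synonyms) else character()
  loops <- a == b
  nLoops <- sum(loops)
  if (nLoops) {
    nodes <- c(nodes, a[loops])   # a self-loop still names its node
    a <- a[!loops]; b <- b[!loops]
    if (!is.null(weight)) weight <- weight[!loops]
    if (!is.null(relation)) relation <- relation[!loops]
  }
  df <- data.frame(from = pmin(a, b), to = pmax(a, b),
                   stringsAsFactors = FALSE)
  if (!is.null(weight)) df$weight <- as.numeric(weight)
  if (!is.null(relation)) df$relation <- as.character(relation)
  if (nrow(df)) {
    key <- paste(df$from, df$to, sep = "\r")
    ord <- order(key)
    df <- df[ord, , drop = FALSE]
    key <- key[ord]
    first <- !duplicated(key)
    if (!is.null(weight)) {  # merge rule: keep maximum weight
      mx <- tapply(df$weight, key, max)
      df$weight[first] <- as.numeric(mx[unique(key)])
    }
    df <- df[first, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    df, directed = FALSE,
    vertices = data.frame(name = unique(c(df$from, df$to, nodes)),
                          stringsAsFactors = FALSE))
  new("BackgroundNetwork", graph = g, kind = kind,
      selfLoopsDropped = as.integer(nLoops))
}

#' @rdname genes
#' @export
setMethod("genes", "BackgroundNetwork",
          function(x) igraph::V(x@graph)$name)

#' @describeIn BackgroundNetwork number of nodes.
#' @param x a `BackgroundNetwork`.
#' @export
setMethod("length", "BackgroundNetwork",
          function(x) igraph::vcount(x@graph))

#' Kind tag of a background network
#' @param net a [BackgroundNetwork].
#' @return one of `"ppi"`, `"coexpression"`, `"coannotation"`, `"custom"`.
#' @export
networkKind <- function(net) {
  stopifnot(is(net, "BackgroundNetwork"))
  net@kind
}

#' Self-loop counter from network construction
#' @param net a [BackgroundNetwork].
#' @return integer count of dropped self-loop rows.
#' @export
selfLoopsDropped <- function(net) {
  stopifnot(is(net, "BackgroundNetwork"))
  net@selfLoopsDropped
}

#' Edge table of a background network
#'
#' @param net a [BackgroundNetwork].
#' @return data.frame with columns `from`, `to` (endpoints in lexicographic
#'   order per edge) and, when present, `weight` and `relation`.
#' @export
edgeTable <- function(net) {
  stopifnot(is(net, "BackgroundNetwork"))
  el <- igraph::as_edgelist(net@graph)
  df <- data.frame(from = pmin(el[, 1L], el[, 2L]),
                   to = pmax(el[, 1L], el[, 2L]),
                   stringsAsFactors = FALSE)
  if (!is.null(igraph::edge_attr(net@graph, "weight")))
    df$weight <- igraph::E(net@graph)$weight
  if (!is.null(igraph::edge_attr(net@graph, "relation")))
    df$relation <- igraph::E(net@graph)$relation
  df[order(df$from, df$to), , drop = FALSE]
}

#' Node degrees of a background network
#' @param net a [BackgroundNetwork].
#' @param v optional symbols to restrict to.
#' @return named integer vector.
#' @export
nodeDegree <- function(net, v = NULL) {
  stopifnot(is(net, "BackgroundNetwork"))
  d <- igraph::degree(net@graph)
  storage.mode(d) <- "integer"
  if (!is.null(v)) d <- d[v]
  d
}

setMethod("show", "BackgroundNetwork", function(object) {
  cat(sprintf("BackgroundNetwork (%s): %d nodes, %d edges\n", object@kind,
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
})

## ---------------------------------------------------------- InteractorTree

#' InteractorTree: recursive direct-interactor expansion around one gene
#'
#' Produced by [interactorTree()]. Rows are discovery events in BFS order;
#' a node already displayed earlier is marked `revisit = TRUE` and is not
#' expanded further.
#'
#' @slot root the query gene.
#' @slot table data.frame with columns `node`, `parent`, `level`, `degree`,
#'   `revisit`.
#' @export
#' @aliases InteractorTree-class
setClass("InteractorTree",
  slots = c(root = "character", table = "data.frame"))

#' @rdname genes
#' @export
setMethod("genes", "InteractorTree",
          function(x) unique(c(x@root, x@table$node[!x@table$revisit])))

setMethod("show", "InteractorTree", function(object) {
  cat(sprintf("InteractorTree rooted at %s: %d node%s\n", object@root,
              length(genes(object)),
              if (length(genes(object)) == 1L) "" else "s"))
})

## ------------------------------------------------------------ OverlapTest

#' OverlapTest: one Fisher-exact overlap between a user list and a gene set
#'
#' @slot k overlap count.
#' @slot a user-list size within the universe.
#' @slot b library-set size within the universe.
#' @slot N universe size.
#' @slot pRaw one-sided hypergeometric upper-tail p-value in (0, 1].
#' @slot overlapGenes the k shared symbols.
#' @slot degenerate TRUE when either list is empty after universe
#'   restriction (then k = 0, pRaw = 1).
#' @export
#' @aliases OverlapTest-class
setClass("OverlapTest",
  slots = c(k = "integer", a = "integer", b = "integer", N = "integer",
            pRaw = "numeric", overlapGenes = "character",
            degenerate = "logical"))

setValidity("OverlapTest", function(object) {
  msg <- character()
  if (object@k > min(object@a, object@b) || object@k < 0L)
    msg <- c(msg, "k must satisfy 0 <= k <= min(a, b)")
  if (object@a > object@N || object@b > object@N)
    msg <- c(msg, "a and b must not exceed N")
  if (object@pRaw <= 0 || object@pRaw > 1)
    msg <- c(msg, "pRaw must lie in (0, 1]")
  if (length(object@overlapGenes) != object@k)
    msg <- c(msg, "overlapGenes must contain exactly k symbols")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OverlapTest", function(object) {
  cat(sprintf("OverlapTest: k=%d (a=%d, b=%d, N=%d), p=%.4g%s\n",
              object@k, object@a, object@b, object@N, object@pRaw,
              if (object@degenerate) " [degenerate]" else ""))
})

## ---------------------------------------------------------- OverlapMatrix

#' OverlapMatrix: Fisher-exact overlaps of user lists against a library
#'
#' Rows are library sets, columns are user lists; every cell shares the
#' same universe size N. Corrected p-values (Bonferroni and
#' Benjamini-Hochberg) are computed per user-list column over the library's
#' sets by default, or matrix-wide on request.
#'
#' @slot k integer matrix of overlap counts (sets x lists).
#' @slot pRaw raw one-sided p-values.
#' @slot pBonferroni Bonferroni-adjusted p-values.
#' @slot pBH Benjamini-Hochberg-adjusted p-values.
#' @slot listSizes per-column user-list size a (after universe restriction).
#' @slot setSizes per-row library-set size b (after universe restriction).
#' @slot universeSize N.
#' @slot overlapGenes list (one per column) of lists (one per row) of
#'   shared-symbol vectors.
#' @slot droppedGenes named list: per user list, its symbols absent from
#'   the universe (dropped from a, not added to N).
#' @slot correction `"column"` or `"matrix"`.
#' @export
#' @aliases OverlapMatrix-class
setClass("OverlapMatrix",
  slots = c(k = "matrix", pRaw = "matrix", pBonferroni = "matrix",
            pBH = "matrix", listSizes = "integer", setSizes = "integer",
            universeSize = "integer", overlapGenes = "list",
            droppedGenes = "list", correction = "character"))

setValidity("OverlapMatrix", function(object) {
  msg <- character()
  d <- dim(object@pRaw)
  if (!identical(dim(object@k), d) || !identical(dim(object@pBonferroni), d)
      || !identical(dim(object@pBH), d))
    msg <- c(msg, "all matrices must share one shape")
  if (any(object@pBonferroni < object@pRaw - 1e-12) ||
      any(object@pBH < object@pRaw - 1e-12))
    msg <- c(msg, "corrected p-values must be >= raw p-values")
  if (any(object@pBonferroni > 1) || any(object@pBH > 1))
    msg <- c(msg, "corrected p-values must be <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OverlapMatrix", function(object) {
  cat(sprintf(
    "OverlapMatrix: %d library sets x %d user lists (N = %d, %s-wise correction)\n",
    nrow(object@pRaw), ncol(object@pRaw), object@universeSize,
    object@correction))
})

#' Dimensions of an overlap matrix
#' @param x an [OverlapMatrix].
#' @export
setMethod("dim", "OverlapMatrix", function(x) dim(x@pRaw))

#' Raw p-value matrix
#' @param om an [OverlapMatrix].
#' @return numeric matrix (library sets x user lists).
#' @export
pRaw <- function(om) { stopifnot(is(om, "OverlapMatrix")); om@pRaw }

#' Bonferroni-adjusted p-value matrix
#' @inheritParams pRaw
#' @export
pBonferroni <- function(om) {
  stopifnot(is(om, "OverlapMatrix")); om@pBonferroni
}

#' Benjamini-Hochberg-adjusted p-value matrix
#' @inheritParams pRaw
#' @export
pBH <- function(om) { stopifnot(is(om, "OverlapMatrix")); om@pBH }

#' Overlap-count matrix
#' @inheritParams pRaw
#' @export
overlapCounts <- function(om) { stopifnot(is(om, "OverlapMatrix")); om@k }

#' Universe size N shared by all cells
#' @inheritParams pRaw
#' @export
universeSize <- function(om) {
  stopifnot(is(om, "OverlapMatrix")); om@universeSize
}

## ------------------------------------------------------------- Subnetwork

#' Subnetwork: seed nodes connected through admitted intermediates
#'
#' Result of [expand()]. Edges are the union of all admitted shortest
#' seed-pair paths plus every background edge between two seeds
#' (path-union, not induced-subgraph, semantics).
#'
#' @slot name label (seed-list name).
#' @slot seeds seed symbols present in the background network, input order.
#' @slot missingSeeds seed symbols absent from the background network.
#' @slot intermediates data.frame: `node`, `specificity`, `seedLinks`,
#'   `subnetworkLinks`, `degree`, `ratio`, `rank` (rank order: descending
#'   subnetworkLinks/degree, ties by descending subnetworkLinks, then label).
#' @slot edges two-column character matrix, endpoints lexicographic, rows
#'   unique and sorted.
#' @slot params list with `maxSteps` and `specificityCutoff` used.
#' @export
#' @aliases Subnetwork-class
setClass("Subnetwork",
  slots = c(name = "character", seeds = "character",
            missingSeeds = "character", intermediates = "data.frame",
            edges = "matrix", params = "list"))

setValidity("Subnetwork", function(object) {
  msg <- character()
  it <- object@intermediates
  need <- c("node", "specificity", "seedLinks", "subnetworkLinks",
            "degree", "ratio", "rank")
  if (!all(need %in% names(it)))
    msg <- c(msg, "intermediates table is missing required columns")
  else {
    if (nrow(it) && (any(it$specificity <= 0) || any(it$specificity > 1)))
      msg <- c(msg, "specificity must lie in (0, 1]")
    if (nrow(it) && !setequal(it$rank, seq_len(nrow(it))))
      msg <- c(msg, "ranks must be a permutation of 1..n")
  }
  if (length(object@edges) && ncol(object@edges) != 2L)
    msg <- c(msg, "edges must have two columns")
  if (length(msg)) msg else TRUE
})

#' @rdname genes
#' @export
setMethod("genes", "Subnetwork", function(x)
  unique(c(x@seeds, x@intermediates$node[order(x@intermediates$rank)],
           x@missingSeeds)))

setMethod("show", "Subnetwork", function(object) {
  cat(sprintf(
    "Subnetwork '%s': %d seeds (%d missing), %d intermediates, %d edges\n",
    object@name, length(object@seeds), length(object@missingSeeds),
    nrow(object@intermediates), nrow(object@edges)))
})

#' Seed symbols of a subnetwork present in the background network
#' @param sub a [Subnetwork].
#' @export
seedGenes <- function(sub) { stopifnot(is(sub, "Subnetwork")); sub@seeds }

#' Seed symbols that were absent from the background network
#' @inheritParams seedGenes
#' @export
missingSeeds <- function(sub) {
  stopifnot(is(sub, "Subnetwork")); sub@missingSeeds
}

#' Edge matrix of a subnetwork
#' @inheritParams seedGenes
#' @return two-column character matrix, canonical order.
#' @export
subnetworkEdges <- function(sub) {
  stopifnot(is(sub, "Subnetwork")); sub@edges
}

## ----------------------------------------------------------- ListsNetwork

#' ListsNetwork: the network of lists
#'
#' Nodes are user (input) lists and library sets; edges mark statistically
#' significant overlap after Bonferroni correction at level `alpha`.
#' Library-set nodes are classed `single_overlap` (edges to exactly one
#' input list) or `multi_overlap` (two or more); sets with no significant
#' edge are absent.
#'
#' @slot nodes data.frame: `label`, `class` in
#'   \{`input`, `single_overlap`, `multi_overlap`\}.
#' @slot edges data.frame: `from`, `to`, `k`, `pRaw`, `pAdjusted`, `type`
#'   (`user_library` or `user_user`).
#' @slot alpha significance level used.
#' @export
#' @aliases ListsNetwork-class
setClass("ListsNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame", alpha = "numeric"))

setValidity("ListsNetwork", function(object) {
  msg <- character()
  if (!all(object@nodes$class %in%
           c("input", "single_overlap", "multi_overlap")))
    msg <- c(msg, "unknown node class")
  if (anyDuplicated(object@nodes$label))
    msg <- c(msg, "node labels must be unique")
  if (nrow(object@edges) && any(object@edges$pAdjusted >= object@alpha))
    msg <- c(msg, "every edge must satisfy corrected p < alpha")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ListsNetwork", function(object) {
  tab <- table(factor(object@nodes$class,
                      c("input", "single_overlap", "multi_overlap")))
  cat(sprintf(
    "ListsNetwork (alpha = %g): %d nodes (%d input, %d single, %d multi), %d edges\n",
    object@alpha, nrow(object@nodes), tab[["input"]],
    tab[["single_overlap"]], tab[["multi_overlap"]], nrow(object@edges)))
})

#' Node table of a lists network
#' @param ln a [ListsNetwork].
#' @export
listsNetworkNodes <- function(ln) {
  stopifnot(is(ln, "ListsNetwork")); ln@nodes
}

#' Edge table of a lists network
#' @inheritParams listsNetworkNodes
#' @export
listsNetworkEdges <- function(ln) {
  stopifnot(is(ln, "ListsNetwork")); ln@edges
}
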
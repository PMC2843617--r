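## Background-network builders (SIF / weighted-pair readers, co-expression
## thresholding, co-annotation graphs) and the recursive interactor browser.

#' Read a background network from a SIF or weighted-pair file
#'
#' SIF dialect: tab-delimited rows `nodeA<TAB>relation<TAB>nodeB`; a
#' single-field row names an isolated node (standard Cytoscape lone-node
#' syntax). Weighted dialect: rows `nodeA<TAB>nodeB<TAB>weight` with an
#' optional header (auto-detected by a non-numeric third field in row 1).
#' Symbols are normalized; duplicate and reversed-duplicate edges are
#' merged (maximum weight kept); self-loops are dropped and counted
#' (see [selfLoopsDropped()]).
#'
#' @param path input file.
#' @param dialect `"sif"` or `"tsv"` (weighted pairs).
#' @param kind network kind tag; defaults to `"custom"` (`"coexpression"`
#'   is typical for the weighted dialect).
#' @param synonyms optional synonym table.
#' @return a [BackgroundNetwork].
#' @export
readNetwork <- function(path, dialect = c("sif", "tsv"), kind = "custom",
                        synonyms = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLinesNormalized(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "sif") {
    bad <- which(!lengths(fields) %in% c(1L, 3L))
    if (length(bad))
      stop(sprintf("row %d: expected 3 tab-delimited fields (or 1 for a lone node)",
                   bad[1L]))
    lone <- lengths(fields) == 1L
    nodes <- unlist(fields[lone], use.names = FALSE)
    m <- do.call(rbind, fields[!lone])
    if (is.null(m)) m <- matrix(character(), 0L, 3L)
    BackgroundNetwork(m[, c(1L, 3L), drop = FALSE], kind = kind,
                      relation = m[, 2L], nodes = nodes,
                      synonyms = synonyms)
  } else {
    bad <- which(lengths(fields) != 3L)
    if (length(bad))
      stop(sprintf("row %d: expected 3 fields", bad[1L]))
    m <- do.call(rbind, fields)
    if (is.null(m)) m <- matrix(character(), 0L, 3L)
    if (nrow(m) && is.na(suppressWarnings(as.numeric(m[1L, 3L]))))
      m <- m[-1L, , drop = FALSE]   # header row
    w <- suppressWarnings(as.numeric(m[, 3L]))
    if (anyNA(w))
      stop(sprintf("row %d: non-numeric weight '%s'",
                   which(is.na(w))[1L], m[which(is.na(w))[1L], 3L]))
    BackgroundNetwork(m[, 1:2, drop = FALSE], kind = kind, weight = w,
                      synonyms = synonyms)
  }
}

#' @describeIn writeSIF write a background network; edge relation strings
#'   are preserved (default `"pp"`).
#' @export
setMethod("writeSIF", "BackgroundNetwork", function(x, path, ...) {
  et <- edgeTable(x)
  rel <- if (!is.null(et$relation)) et$relation else
    rep("pp", nrow(et))
  rel[is.na(rel) | !nzchar(rel)] <- "pp"
  rows <- if (nrow(et)) sprintf("%s\t%s\t%s", et$from, rel, et$to)
          else character()
  isolated <- sort(names(which(nodeDegree(x) == 0L)))
  writeLines(c(sort(rows), isolated), path)
  invisible(path)
})

#' Build a co-expression network by thresholding a weighted pair table
#'
#' An edge is kept iff its weight is at least `cutoff` (inclusive).
#' Duplicate pairs are merged keeping the maximum weight *before*
#' thresholding.
#'
#' @param pairs data.frame/matrix with columns (geneA, geneB, weight), or a
#'   path to a 3-column TSV (header auto-detected).
#' @param cutoff minimum weight to keep an edge.
#' @return a [BackgroundNetwork] of kind `"coexpression"`.
#' @export
buildCoexpressionNetwork <- function(pairs, cutoff) {
  if (is.character(pairs) && length(pairs) == 1L) {
    net <- readNetwork(pairs, dialect = "tsv", kind = "coexpression")
    et <- edgeTable(net)
    pairs <- et[, c("from", "to", "weight")]
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) != 3L) stop("'pairs' must have 3 columns")
  w <- suppressWarnings(as.numeric(pairs[[3L]]))
  if (anyNA(w) && nrow(pairs))
    stop(sprintf("non-numeric weight in row %d", which(is.na(w))[1L]))
  ## merge duplicates (max weight) happens in the constructor; threshold after
  full <- BackgroundNetwork(cbind(as.character(pairs[[1L]]),
                                  as.character(pairs[[2L]])),
                            kind = "coexpression", weight = w)
  et <- edgeTable(full)
  keep <- et$weight >= cutoff
  BackgroundNetwork(cbind(et$from[keep], et$to[keep]),
                    kind = "coexpression", weight = et$weight[keep])
}

## genes x sets logical incidence matrix of a library
membershipMatrix <- function(lib) {
  genes <- universe(lib)
  sets <- geneSets(lib)
  m <- matrix(FALSE, length(genes), length(sets),
              dimnames = list(genes, setNames2(lib)))
  for (j in seq_along(sets)) m[genes(sets[[j]]), j] <- TRUE
  m
}

#' Co-annotation score of a gene pair within a library
#'
#' Measures co-appearance across a library's gene sets as the Jaccard
#' index over set membership: sets containing both genes divided by sets
#' containing either. 1 when both genes are annotated to exactly the same
#' (at least one) sets; 0 when they share no set or neither is annotated.
#' Symmetric. The corresponding distance is `1 - score`.
#'
#' @param u,v gene symbols (normalized here).
#' @param lib a non-empty [GeneSetLibrary].
#' @return numeric score in \[0, 1\].
#' @export
coannotationScore <- function(u, v, lib) {
  stopifnot(is(lib, "GeneSetLibrary"))
  if (length(lib) == 0L) stop("library must be non-empty")
  u <- normalizeSymbol(u); v <- normalizeSymbol(v)
  inU <- vapply(geneSets(lib), function(s) u %in% genes(s), logical(1))
  inV <- vapply(geneSets(lib), function(s) v %in% genes(s), logical(1))
  either <- sum(inU | inV)
  if (either == 0L) return(0)
  sum(inU & inV) / either
}

#' Build a co-annotation network from a gene-set library
#'
#' Connects every gene pair whose [coannotationScore()] is at least
#' `cutoff` (inclusive, so `cutoff = 1` keeps identical-membership pairs).
#' Edge weights carry the scores.
#'
#' @param lib a [GeneSetLibrary].
#' @param cutoff minimum score in \[0, 1\].
#' @return a [BackgroundNetwork] of kind `"coannotation"` over the
#'   library's universe (genes with no qualifying partner are isolated
#'   nodes).
#' @export
buildCoannotationNetwork <- function(lib, cutoff) {
  stopifnot(is(lib, "GeneSetLibrary"), cutoff >= 0, cutoff <= 1)
  if (length(lib) == 0L || length(universe(lib)) == 0L)
    return(BackgroundNetwork(matrix(character(), 0L, 2L),
                             kind = "coannotation"))
  m <- membershipMatrix(lib) * 1L
  both <- tcrossprod(m)                     # |sets containing both|
  nSets <- rowSums(m)
  either <- outer(nSets, nSets, "+") - both # |sets containing either|
  score <- ifelse(either > 0, both / either, 0)
  score[lower.tri(score, diag = TRUE)] <- -1
  hit <- which(score >= cutoff, arr.ind = TRUE)
  g <- rownames(m)
  BackgroundNetwork(cbind(g[hit[, 1L]], g[hit[, 2L]]),
                    kind = "coannotation",
                    weight = score[hit], nodes = g)
}

#' Recursive direct-interactor tree around one gene
#'
#' Breadth-limited expansion: level 1 holds the gene's direct interactors,
#' level d the interactors of level d-1 nodes, up to `depth`. Each row is
#' annotated with the node's background degree; a node already listed
#' earlier is marked `revisit = TRUE` and is not expanded again.
#'
#' @param gene query symbol (must be in the network).
#' @param net a [BackgroundNetwork].
#' @param depth positive integer number of levels.
#' @return an [InteractorTree].
#' @export
interactorTree <- function(gene, net, depth = 1L) {
  stopifnot(is(net, "BackgroundNetwork"), depth >= 1L)
  gene <- normalizeSymbol(gene)
  if (!gene %in% genes(net))
    stop(sprintf("gene '%s' is not in the network", gene))
  deg <- nodeDegree(net)
  rows <- list()
  visited <- gene
  frontier <- gene
  for (lev in seq_len(depth)) {
    nxt <- character()
    for (v in frontier) {
      nb <- sort(igraph::neighbors(net@graph, v)$name)
      for (w in nb) {
        seen <- w %in% visited
        rows[[length(rows) + 1L]] <-
          data.frame(node = w, parent = v, level = lev,
                     degree = unname(deg[w]), revisit = seen,
                     stringsAsFactors = FALSE)
        if (!seen) {
          visited <- c(visited, w)
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = character(), parent = character(),
               level = integer(), degree = integer(),
               revisit = logical(), stringsAsFactors = FALSE)
  new("InteractorTree", root = gene, table = tab)
}

#' @rdname asGeneList
#' @export
setMethod("asGeneList", "InteractorTree", function(x, name = NULL) {
  if (is.null(name)) name <- paste0(x@root, "_interactors")
  new("GeneList", name = name, description = "", genes = genes(x))
})

#' @rdname asGeneList
#' @export
setMethod("asGeneList", "BackgroundNetwork", function(x, name = NULL) {
  if (is.null(name)) name <- paste0(x@kind, "_nodes")
  ## deterministic BFS discovery order from the lexicographically first
  ## node of each component
  g <- x@graph
  out <- character()
  remaining <- sort(genes(x))
  while (length(remaining)) {
    queue <- remaining[1L]
    seen <- queue
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      out <- c(out, v)
      fresh <- setdiff(sort(igraph::neighbors(g, v)$name), seen)
      seen <- c(seen, fresh)
      queue <- c(queue, fresh)
    }
    remaining <- setdiff(remaining, seen)
  }
  new("GeneList", name = name, description = "", genes = out)
})

#' @rdname asGeneList
#' @export
setMethod("asGeneList", "Subnetwork", function(x, name = NULL) {
  subnetworkToList(x, name = name)
})
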
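## Seed-list expansion into a connecting subnetwork: all shortest paths
## between seed pairs, specificity filtering of intermediates, ranking,
## and SIF export.

#' Specificity of a node with respect to a seed set
#'
#' The proportion of a node's background-network links that go to seed
#' nodes: `|neighbors(v) ∩ seeds| / degree(v)`. High specificity means the
#' node interacts preferentially with the input list.
#'
#' @param v a gene symbol present in the network with degree >= 1.
#' @param seeds character vector of seed symbols.
#' @param net a [BackgroundNetwork].
#' @return numeric in \[0, 1\].
#' @export
specificity <- function(v, seeds, net) {
  stopifnot(is(net, "BackgroundNetwork"))
  v <- normalizeSymbol(v)
  if (!v %in% genes(net))
    stop(sprintf("node '%s' is not in the network", v))
  nb <- igraph::neighbors(net@graph, v)$name
  if (!length(nb))
    stop(sprintf("specificity is undefined for isolated node '%s'", v))
  sum(nb %in% seeds) / length(nb)
}

canonicalEdges <- function(a, b) {
  if (!length(a))
    return(matrix(character(), 0L, 2L,
                  dimnames = list(NULL, c("from", "to"))))
  m <- cbind(from = pmin(a, b), to = pmax(a, b))
  m <- unique(m)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Expand a seed gene list into a connecting subnetwork
#'
#' For every unordered pair of seeds whose background shortest-path
#' distance d satisfies 2 <= d <= `maxSteps`, ALL shortest paths of length
#' d are enumerated; their interior nodes are candidate intermediates.
#' Candidate specificity is computed against the original background
#' network; candidates below `specificityCutoff` are removed together with
#' every path that traverses them (paths are not re-grown). Direct
#' seed-seed edges are always included. Seed pairs farther apart than
#' `maxSteps` are left unconnected. Seeds absent from the network are
#' reported (warning), excluded from path finding, but retained by
#' [subnetworkToList()]. Output is deterministic for fixed input.
#'
#' @param seedList a [GeneList] of seed genes.
#' @param net a [BackgroundNetwork].
#' @param maxSteps maximum shortest-path length in links (>= 1).
#' @param specificityCutoff minimum specificity in \[0, 1\] for admitting
#'   an intermediate.
#' @return a [Subnetwork].
#' @examples
#' net <- BackgroundNetwork(rbind(c("A","X"), c("X","B"), c("A","Y"),
#'                                c("Y","C"), c("X","Z")))
#' sub <- expand(GeneList("seeds", c("A","B","C")), net, maxSteps = 2)
#' rankIntermediates(sub)
#' @export
expand <- function(seedList, net, maxSteps = 2L, specificityCutoff = 0) {
  stopifnot(is(seedList, "GeneList"), is(net, "BackgroundNetwork"),
            maxSteps >= 1L,
            specificityCutoff >= 0, specificityCutoff <= 1)
  seeds0 <- genes(seedList)
  inNet <- seeds0 %in% genes(net)
  if (length(seeds0) && !any(inNet))
    stop(sprintf("no seed present in the network; missing: %s",
                 paste(seeds0, collapse = ", ")))
  if (any(!inNet))
    warning(sprintf("%d seed(s) absent from the network: %s",
                    sum(!inNet), paste(seeds0[!inNet], collapse = ", ")))
  seeds <- seeds0[inNet]
  g <- net@graph
  deg <- nodeDegree(net)

  ## background edges among seeds (covers all distance-1 pairs)
  seedEdges <- canonicalEdges(character(), character())
  if (length(seeds) >= 1L) {
    sg <- igraph::induced_subgraph(g, seeds)
    el <- igraph::as_edgelist(sg)
    seedEdges <- canonicalEdges(el[, 1L], el[, 2L])
  }

  paths <- list()
  if (length(seeds) >= 2L && maxSteps >= 2L) {
    ## hop counts, never edge weights (co-expression nets carry weights)
    dmat <- igraph::distances(g, v = seeds, to = seeds, weights = NA)
    pairs <- utils::combn(seq_along(seeds), 2L)
    for (q in seq_len(ncol(pairs))) {
      u <- seeds[pairs[1L, q]]; v <- seeds[pairs[2L, q]]
      d <- dmat[pairs[1L, q], pairs[2L, q]]
      if (!is.finite(d) || d < 2 || d > maxSteps) next
      r <- igraph::all_shortest_paths(g, from = u, to = v, weights = NA)
      asp <- if (!is.null(r$vpaths)) r$vpaths else r$res
      paths <- c(paths, lapply(asp, function(p) p$name))
    }
  }

  candidates <- sort(unique(unlist(lapply(paths, function(p)
    p[-c(1L, length(p))]), use.names = FALSE)))
  specs <- vapply(candidates, function(v) specificity(v, seeds, net),
                  numeric(1))
  failing <- candidates[specs < specificityCutoff]
  admitted <- Filter(function(p) !any(p[-c(1L, length(p))] %in% failing),
                     paths)

  pathEdges <- if (length(admitted)) {
    a <- unlist(lapply(admitted, function(p) p[-length(p)]))
    b <- unlist(lapply(admitted, function(p) p[-1L]))
    canonicalEdges(a, b)
  } else canonicalEdges(character(), character())
  edges <- canonicalEdges(c(seedEdges[, 1L], pathEdges[, 1L]),
                          c(seedEdges[, 2L], pathEdges[, 2L]))

  inter <- sort(unique(unlist(lapply(admitted, function(p)
    p[-c(1L, length(p))]), use.names = FALSE)))
  if (length(inter)) {
    subLinks <- vapply(inter, function(v)
      sum(edges[, 1L] == v | edges[, 2L] == v), integer(1))
    seedLinks <- vapply(inter, function(v)
      sum(igraph::neighbors(g, v)$name %in% seeds), integer(1))
    spec <- specs[match(inter, candidates)]
    ratio <- subLinks / deg[inter]
    ord <- order(-ratio, -subLinks, inter)
    it <- data.frame(node = inter, specificity = unname(spec),
                     seedLinks = unname(seedLinks),
                     subnetworkLinks = unname(subLinks),
                     degree = unname(deg[inter]),
                     ratio = unname(ratio),
                     rank = NA_integer_, stringsAsFactors = FALSE)
    it$rank[ord] <- seq_along(ord)
  } else {
    it <- data.frame(node = character(), specificity = numeric(),
                     seedLinks = integer(), subnetworkLinks = integer(),
                     degree = integer(), ratio = numeric(),
                     rank = integer(), stringsAsFactors = FALSE)
  }

  new("Subnetwork", name = objectName(seedList), seeds = seeds,
      missingSeeds = seeds0[!inNet], intermediates = it, edges = edges,
      params = list(maxSteps = as.integer(maxSteps),
                    specificityCutoff = specificityCutoff))
}

#' Ranked intermediate table of a subnetwork
#'
#' Intermediates sorted by descending subnetwork-link / background-degree
#' ratio; ties broken by descending subnetwork-link count, then label.
#'
#' @param sub a [Subnetwork].
#' @param net ignored; accepted for symmetry with [expand()] signatures.
#' @return data.frame with columns `node`, `specificity`, `seedLinks`,
#'   `subnetworkLinks`, `degree`, `ratio`, `rank`, in rank order.
#' @export
rankIntermediates <- function(sub, net = NULL) {
  stopifnot(is(sub, "Subnetwork"))
  it <- sub@intermediates
  it[order(it$rank), , drop = FALSE]
}

#' Convert a subnetwork back into a gene list
#'
#' Seeds first (input order, including seeds that were missing from the
#' background network, appended last and noted in the description), then
#' intermediates in rank order; the name gains an `"_expanded"` suffix.
#'
#' @param sub a [Subnetwork].
#' @param name optional name override.
#' @return a [GeneList].
#' @export
subnetworkToList <- function(sub, name = NULL) {
  stopifnot(is(sub, "Subnetwork"))
  if (is.null(name)) name <- paste0(sub@name, "_expanded")
  desc <- if (length(sub@missingSeeds))
    paste0("seeds absent from background network: ",
           paste(sub@missingSeeds, collapse = ";"))
  else ""
  ord <- sub@intermediates$node[order(sub@intermediates$rank)]
  new("GeneList", name = name, description = desc,
      genes = unique(c(sub@seeds, ord, sub@missingSeeds)))
}

#' @describeIn writeSIF write a subnetwork plus a node-attribute sidecar
#'   table (`node`, `role` in \{seed, intermediate\}, `specificity`,
#'   `rank`); `attrPath` defaults to the SIF path with a `_nodes.tsv`
#'   suffix.
#' @param attrPath sidecar node-attribute table path (Subnetwork method).
#' @export
setMethod("writeSIF", "Subnetwork", function(x, path, attrPath = NULL, ...) {
  if (is.null(attrPath))
    attrPath <- paste0(sub("\\.sif$", "", path), "_nodes.tsv")
  rows <- if (nrow(x@edges))
    sprintf("%s\tpp\t%s", x@edges[, 1L], x@edges[, 2L]) else character()
  connected <- unique(as.vector(x@edges))
  isolated <- sort(setdiff(x@seeds, connected))
  writeLines(c(sort(rows), isolated), path)
  it <- x@intermediates
  attrs <- rbind(
    data.frame(node = x@seeds, role = rep("seed", length(x@seeds)),
               specificity = rep(NA_real_, length(x@seeds)),
               rank = rep(NA_integer_, length(x@seeds)),
               stringsAsFactors = FALSE),
    data.frame(node = it$node, role = rep("intermediate", nrow(it)),
               specificity = it$specificity, rank = it$rank,
               stringsAsFactors = FALSE))
  utils::write.table(attrs, attrPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
})
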
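## The network of lists: nodes are user lists and library sets, edges mark
## statistically significant overlap after Bonferroni correction.

#' Build the network of lists
#'
#' Computes the overlap matrix of the user lists against the library,
#' applies the Bonferroni correction per user-list column, and connects a
#' user list to a library set when the corrected p-value is strictly below
#' `alpha`. With `includeUserUserEdges = TRUE` (default) every pair of
#' user lists is likewise tested, Bonferroni-corrected over the number of
#' user-list pairs, and connected when significant. Library-set nodes are
#' classed `single_overlap` (one significant input edge) or
#' `multi_overlap` (two or more); sets with no significant edge are left
#' out; input lists are always class `input`.
#'
#' @param users a [GeneList] or list of [GeneList] objects.
#' @param library a [GeneSetLibrary].
#' @param alpha significance level in (0, 1); edges require corrected
#'   p < alpha (strict).
#' @param includeUserUserEdges test and connect overlapping user-list
#'   pairs as well.
#' @param universe universe policy, as in [overlapMatrix()].
#' @return a [ListsNetwork].
#' @export
buildListsNetwork <- function(users, library, alpha = 0.05,
                              includeUserUserEdges = TRUE,
                              universe = "library") {
  if (is(users, "GeneList")) users <- list(users)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  om <- overlapMatrix(users, library, universe = universe)
  uNames <- colnames(om@pRaw)
  tNames <- rownames(om@pRaw)

  edges <- data.frame(from = character(), to = character(), k = integer(),
                      pRaw = numeric(), pAdjusted = numeric(),
                      type = character(), stringsAsFactors = FALSE)
  sig <- which(om@pBonferroni < alpha, arr.ind = TRUE)
  if (nrow(sig)) {
    edges <- data.frame(
      from = uNames[sig[, 2L]], to = tNames[sig[, 1L]],
      k = om@k[sig], pRaw = om@pRaw[sig], pAdjusted = om@pBonferroni[sig],
      type = "user_library", stringsAsFactors = FALSE)
  }

  if (includeUserUserEdges && length(users) >= 2L) {
    bg <- resolveUniverse(users, library, universe)
    pairs <- utils::combn(seq_along(users), 2L)
    nTests <- ncol(pairs)
    uu <- lapply(seq_len(nTests), function(q) {
      ot <- fisherOverlap(users[[pairs[1L, q]]], users[[pairs[2L, q]]], bg)
      data.frame(from = uNames[pairs[1L, q]], to = uNames[pairs[2L, q]],
                 k = ot@k, pRaw = ot@pRaw,
                 pAdjusted = min(1, ot@pRaw * nTests),
                 type = "user_user", stringsAsFactors = FALSE)
    })
    uu <- do.call(rbind, uu)
    edges <- rbind(edges, uu[uu$pAdjusted < alpha, , drop = FALSE])
  }
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  libEdges <- edges[edges$type == "user_library", , drop = FALSE]
  perSet <- table(libEdges$to)
  setNodes <- names(perSet)
  nodes <- rbind(
    data.frame(label = uNames, class = "input", stringsAsFactors = FALSE),
    data.frame(label = setNodes,
               class = ifelse(perSet >= 2L, "multi_overlap",
                              "single_overlap"),
               stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  new("ListsNetwork", nodes = nodes, edges = edges, alpha = alpha)
}

#' Export a lists network to GraphML or SIF
#'
#' GraphML carries the node `class` and edge statistics (`k`, `pRaw`,
#' `pAdjusted`, `type`) as attributes. The SIF variant writes edges with
#' relation `"overlaps"` plus a sidecar attribute table
#' (`<path>_attributes.tsv`: one row per node with its class, then one per
#' edge with its statistics). Row order is deterministic.
#'
#' @param netl a [ListsNetwork].
#' @param path output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
exportListsNetwork <- function(netl, path, format = c("graphml", "sif")) {
  stopifnot(is(netl, "ListsNetwork"))
  format <- match.arg(format)
  nodes <- netl@nodes[order(netl@nodes$label), , drop = FALSE]
  edges <- netl@edges
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      edges[, c("from", "to", "k", "pRaw", "pAdjusted", "type")],
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    rows <- if (nrow(edges))
      sort(sprintf("%s\toverlaps\t%s", pmin(edges$from, edges$to),
                   pmax(edges$from, edges$to))) else character()
    lone <- sort(setdiff(nodes$label, c(edges$from, edges$to)))
    writeLines(c(rows, lone), path)
    attrPath <- paste0(sub("\\.sif$", "", path), "_attributes.tsv")
    at <- rbind(
      data.frame(element = "node", id = nodes$label, class = nodes$class,
                 k = NA_integer_, pRaw = NA_real_, pAdjusted = NA_real_,
                 stringsAsFactors = FALSE),
      if (nrow(edges)) data.frame(
        element = "edge", id = paste(edges$from, edges$to, sep = "|"),
        class = edges$type, k = edges$k, pRaw = edges$pRaw,
        pAdjusted = edges$pAdjusted, stringsAsFactors = FALSE))
    utils::write.table(at, attrPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
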
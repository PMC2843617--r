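# Random-case generators for property-style tests. All callers seed
# explicitly; these functions only consume the current RNG stream.

# sample one element of a vector (safe for length-1 vectors, where
# base::sample would treat the value as a range)
sampleOne <- function(v) v[sample.int(length(v), 1)]

randomSymbols <- function(n) {
  paste0(replicate(n, paste(sample(LETTERS, sample(2:6, 1), replace = TRUE),
                            collapse = "")),
         sample(0:99, n, replace = TRUE))
}

randomGeneList <- function(name = "L", poolSize = 40, maxLen = 15) {
  pool <- sprintf("G%03d", seq_len(poolSize))
  GeneList(name, sample(pool, sample(0:maxLen, 1)))
}

randomLibrary <- function(nSets = NULL) {
  if (is.null(nSets)) nSets <- sample(1:8, 1)
  pool <- randomSymbols(60)
  sets <- lapply(seq_len(nSets), function(i)
    GeneList(sprintf("S%02d_%d", i, sample(1e4, 1)),
             sample(pool, sample(1:20, 1)),
             description = sample(c("", "some description", "x y z"), 1)))
  GeneSetLibrary("random_lib", sets)
}

# random connected undirected simple graph as a 2-column edge matrix over
# named nodes: random spanning tree plus extra random edges
randomConnectedGraph <- function(nNodes, extraEdges = NULL) {
  nodes <- sprintf("N%02d", seq_len(nNodes))
  edges <- NULL
  if (nNodes >= 2) {
    for (i in 2:nNodes)
      edges <- rbind(edges, c(nodes[sample(i - 1, 1)], nodes[i]))
    if (is.null(extraEdges)) extraEdges <- sample(0:nNodes, 1)
    for (e in seq_len(extraEdges)) {
      pair <- sample(nodes, 2)
      edges <- rbind(edges, pair)
    }
  }
  list(nodes = nodes,
       edges = if (is.null(edges)) matrix(character(), 0, 2) else edges)
}

edgeKeys <- function(edgeMat) {
  if (!nrow(edgeMat)) return(character())
  sort(unique(paste(pmin(edgeMat[, 1], edgeMat[, 2]),
                    pmax(edgeMat[, 1], edgeMat[, 2]))))
}
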
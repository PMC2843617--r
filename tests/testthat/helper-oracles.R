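# Independent reference implementations used to check the package. They
# deliberately share no code with R/: plain loops, adjacency lists, and
# recursive path enumeration.

# Benjamini-Hochberg step-up, coded directly from the definition:
# sort ascending, q_i = p_i * n / i, running minimum from the largest rank
# down, cap at 1, restore input order.
refBH <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- ps * n / seq_len(n)
  for (i in rev(seq_len(n - 1))) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

# hypergeometric upper tail via the recurrence
# f(i+1)/f(i) = (b-i)(a-i) / ((i+1)(N-b-a+i+1)), exact ratios in doubles;
# independent of lchoose.
refHyperTail <- function(k, a, b, N) {
  if (k <= 0) return(1)
  lo <- max(0, a + b - N)
  f <- exp(lchoose(b, lo) + lchoose(N - b, a - lo) - lchoose(N, a))
  # walk the pmf from the lower support end with the ratio recurrence
  total <- 0
  fi <- f
  for (i in lo:min(a, b)) {
    if (i >= k) total <- total + fi
    fi <- fi * (b - i) * (a - i) / ((i + 1) * (N - b - a + i + 1))
  }
  min(1, total)
}

# adjacency list of a 2-column edge matrix
adjList <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

# single-source BFS hop distances over an adjacency list
bfsDistances <- function(adj, from) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!is.finite(d[w])) {
      d[w] <- d[v] + 1
      queue <- c(queue, w)
    }
  }
  d
}

# all simple paths from u to v of exactly `len` edges (DFS with depth bound)
enumeratePaths <- function(adj, u, v, len) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (length(path) - 1 == len) {
      if (last == v) out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (w in adj[[last]]) if (!w %in% path) walk(c(path, w))
  }
  walk(u)
  out
}

# Brute-force expansion oracle: enumerate every shortest seed-pair path of
# length 2..maxSteps, compute specificity of each interior node against the
# full background, drop paths traversing a below-cutoff node, and collect
# surviving interiors and edges (plus direct seed-seed edges).
refExpand <- function(edges, nodes, seeds, maxSteps, cutoff) {
  adj <- adjList(edges, nodes)
  seeds <- seeds[seeds %in% nodes]
  spec <- function(v) {
    nb <- adj[[v]]
    sum(nb %in% seeds) / length(nb)
  }
  paths <- list()
  if (length(seeds) >= 2) {
    for (i in seq_along(seeds)) {
      d <- bfsDistances(adj, seeds[i])
      for (j in seq_along(seeds)) {
        if (j <= i) next
        dij <- d[seeds[j]]
        if (is.finite(dij) && dij >= 2 && dij <= maxSteps)
          paths <- c(paths, enumeratePaths(adj, seeds[i], seeds[j], dij))
      }
    }
  }
  keep <- Filter(function(p) {
    interior <- p[-c(1, length(p))]
    all(vapply(interior, spec, numeric(1)) >= cutoff)
  }, paths)
  intermediates <- sort(unique(unlist(lapply(keep, function(p)
    p[-c(1, length(p))]))))
  pe <- lapply(keep, function(p) cbind(p[-length(p)], p[-1]))
  seedPairs <- edges[edges[, 1] %in% seeds & edges[, 2] %in% seeds, ,
                     drop = FALSE]
  em <- do.call(rbind, c(pe, list(seedPairs)))
  edgeKeys <- if (is.null(em) || !nrow(em)) character() else
    unique(paste(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2])))
  list(intermediates = if (is.null(intermediates)) character()
                       else intermediates,
       edgeKeys = sort(edgeKeys))
}
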
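## Seeded synthetic fixtures: gene universes, libraries with planted
## enrichment, and background graphs. Pure functions of a FixtureSpec —
## identical specs give byte-identical files. The generators drive their
## own RNG stream and restore the caller's random state.

#' Describe a synthetic fixture
#'
#' A single integer seed drives one documented pseudo-random stream; the
#' global random state of the caller is saved and restored around every
#' generator call, so fixtures never leak randomness.
#'
#' @param seed integer seed.
#' @param universeSize number of genes in the universe.
#' @param nSets number of library sets.
#' @param setSizeRange length-2 integer vector (min, max) of set sizes.
#' @param planted optional `list(userSize =, overlapFraction =)`: one
#'   designated set will share exactly
#'   `round(overlapFraction * userSize)` genes with a generated user list
#'   whose remaining genes are drawn outside that set.
#' @param graph `list(model =, ...)` with model one of
#'   `"preferential_attachment"` (parameter `m`), `"erdos_renyi"`
#'   (parameter `p`), `"chain"`, `"star"`; `n` defaults to `universeSize`.
#' @return a `fixtureSpec` list.
#' @export
fixtureSpec <- function(seed = 1L, universeSize = 2000L, nSets = 50L,
                        setSizeRange = pmin(c(50L, 300L), universeSize),
                        planted = NULL,
                        graph = list(model = "preferential_attachment",
                                     m = 2L)) {
  if (universeSize < 1L) stop("universeSize must be >= 1")
  if (nSets < 0L) stop("nSets must be >= 0")
  if (length(setSizeRange) != 2L || setSizeRange[1L] > setSizeRange[2L] ||
      setSizeRange[2L] > universeSize)
    stop("setSizeRange must be (min, max) with max <= universeSize")
  structure(list(seed = as.integer(seed),
                 universeSize = as.integer(universeSize),
                 nSets = as.integer(nSets),
                 setSizeRange = as.integer(setSizeRange),
                 planted = planted, graph = graph),
            class = "fixtureSpec")
}

## evaluate expr under a private RNG stream, restoring the caller's state
withFixtureSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a deterministic gene universe
#'
#' Symbols `G000001`, `G000002`, ... — a pure function of the size.
#'
#' @param spec a [fixtureSpec()] (or an integer size).
#' @return character vector of symbols.
#' @export
makeUniverse <- function(spec) {
  n <- if (inherits(spec, "fixtureSpec")) spec$universeSize
       else as.integer(spec)
  if (is.na(n) || n < 1L) stop("universe size must be >= 1")
  sprintf("G%06d", seq_len(n))
}

#' Generate a random gene-set library, optionally with planted enrichment
#'
#' Each of `nSets` sets samples its size uniformly from `setSizeRange` and
#' its genes uniformly without replacement from the universe. When
#' `planted` is given, one designated set (chosen at random) is built to
#' share exactly `round(overlapFraction * userSize)` genes with a returned
#' user list; the user list's remaining genes are drawn outside that set.
#' The designated set's size is clamped up to the shared count when the
#' sampled size would be too small to hold it.
#'
#' @param spec a [fixtureSpec()].
#' @return `list(library = GeneSetLibrary, userList = GeneList or NULL,
#'   plantedName = character or NA)`.
#' @export
makeLibrary <- function(spec) {
  stopifnot(inherits(spec, "fixtureSpec"))
  withFixtureSeed(spec$seed, {
    uni <- makeUniverse(spec)
    sizes <- if (spec$nSets)
      sample(spec$setSizeRange[1L]:spec$setSizeRange[2L], spec$nSets,
             replace = TRUE) else integer()
    plantedIdx <- NA_integer_
    userList <- NULL
    if (!is.null(spec$planted) && spec$nSets >= 1L) {
      uSize <- as.integer(spec$planted$userSize)
      shared <- as.integer(round(spec$planted$overlapFraction * uSize))
      if (shared > uSize || shared > spec$universeSize)
        stop("infeasible planted overlap request")
      plantedIdx <- sample.int(spec$nSets, 1L)
      sizes[plantedIdx] <- max(sizes[plantedIdx], shared)
      if (uSize - shared > spec$universeSize - sizes[plantedIdx])
        stop("infeasible planted overlap request")
    }
    sets <- vector("list", spec$nSets)
    for (i in seq_len(spec$nSets)) {
      gs <- sample(uni, sizes[i])
      sets[[i]] <- new("GeneList", name = sprintf("SET%03d", i),
                       description = if (identical(i, plantedIdx))
                         "planted" else "decoy",
                       genes = sort(gs))
    }
    if (!is.na(plantedIdx)) {
      uSize <- as.integer(spec$planted$userSize)
      shared <- as.integer(round(spec$planted$overlapFraction * uSize))
      inPlanted <- sample(genes(sets[[plantedIdx]]), shared)
      outside <- sample(setdiff(uni, genes(sets[[plantedIdx]])),
                        uSize - shared)
      userList <- new("GeneList", name = "USERLIST",
                      description = "synthetic planted user list",
                      genes = sample(c(inPlanted, outside)))
    }
    list(library = GeneSetLibrary("synthetic_library", sets),
         userList = userList,
         plantedName = if (is.na(plantedIdx)) NA_character_
                       else sprintf("SET%03d", plantedIdx))
  })
}

#' Generate a synthetic background network
#'
#' Models: `chain` (path graph; exact deterministic topology),
#' `star` (node 1 is the hub), `erdos_renyi` (G(n, p)), and
#' `preferential_attachment` (Barabasi-Albert, `m` edges per new node).
#' Nodes are named from [makeUniverse()].
#'
#' @param spec a [fixtureSpec()].
#' @return a [BackgroundNetwork] of kind `"custom"`.
#' @export
makeNetwork <- function(spec) {
  stopifnot(inherits(spec, "fixtureSpec"))
  model <- spec$graph$model
  n <- as.integer(if (!is.null(spec$graph$n)) spec$graph$n
                  else spec$universeSize)
  if (is.na(n) || n < 1L) stop("graph size must be >= 1")
  nodes <- sprintf("G%06d", seq_len(n))
  withFixtureSeed(spec$seed, {
    g <- switch(model,
      chain = igraph::make_ring(n, circular = FALSE),
      star = igraph::make_star(n, mode = "undirected", center = 1L),
      erdos_renyi = {
        p <- spec$graph$p
        if (is.null(p) || p < 0 || p > 1)
          stop("erdos_renyi requires a probability 'p' in [0, 1]")
        igraph::sample_gnp(n, p)
      },
      preferential_attachment = {
        m <- spec$graph$m
        if (is.null(m) || m < 1L)
          stop("preferential_attachment requires 'm' >= 1")
        igraph::sample_pa(n, m = m, directed = FALSE)
      },
      stop(sprintf("unknown graph model '%s'", model)))
    igraph::V(g)$name <- nodes
    el <- igraph::as_edgelist(g)
    BackgroundNetwork(el, kind = "custom", nodes = nodes)
  })
}

#' Write a complete fixture set to a directory
#'
#' Emits the library as GMT, the network as SIF, and (when planted) the
#' user list as a plain text list — the same dialects the package's
#' readers accept. Identical specs yield byte-identical files.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return named character vector of files written, invisibly.
#' @export
writeFixtures <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lib <- makeLibrary(spec)
  net <- makeNetwork(spec)
  files <- c(gmt = file.path(dir, "library.gmt"),
             sif = file.path(dir, "network.sif"))
  writeGMT(lib$library, files[["gmt"]])
  writeSIF(net, files[["sif"]])
  if (!is.null(lib$userList)) {
    files <- c(files, list = file.path(dir, "user_list.txt"))
    writeGeneList(lib$userList, files[["list"]])
  }
  invisible(files)
}
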
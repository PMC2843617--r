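test_that("SIF reading merges duplicate edges and drops self-loops", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "B\tpp\tA", "A\tpp\tA"), f)
  net <- readNetwork(f, dialect = "sif")
  expect_identical(nrow(edgeTable(net)), 1L)
  expect_identical(selfLoopsDropped(net), 1L)
  expect_setequal(genes(net), c("A", "B"))

  writeLines(c("A\tpp\tB", "B\tpp\tC"), f)
  chain <- readNetwork(f)
  expect_identical(length(chain), 3L)
  expect_identical(nrow(edgeTable(chain)), 2L)

  writeLines(c("A\tpp\tB", "C\tD"), f)
  expect_error(readNetwork(f), "row 2")
})

test_that("lone-node SIF rows are read as isolated nodes", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "LONER"), f)
  net <- readNetwork(f)
  expect_setequal(genes(net), c("A", "B", "LONER"))
  expect_identical(unname(nodeDegree(net, "LONER")), 0L)
})

test_that("weighted dialect validates fields and auto-detects headers", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("geneA\tgeneB\tweight", "A\tB\t0.9", "A\tC\t0.2"), f)
  net <- readNetwork(f, dialect = "tsv", kind = "coexpression")
  expect_identical(nrow(edgeTable(net)), 2L)
  writeLines(c("A\tB"), f)
  expect_error(readNetwork(f, dialect = "tsv"), "row 1: expected 3 fields")
  writeLines(c("A\tB\t0.5", "A\tC\toops"), f)
  expect_error(readNetwork(f, dialect = "tsv"), "row 2: non-numeric weight")
})

test_that("co-expression thresholding keeps max weight of duplicate pairs", {
  pairs <- data.frame(a = c("A", "A", "B", "A"),
                      b = c("B", "C", "A", "B"),
                      w = c(0.9, 0.2, 0.4, 0.1))
  net <- buildCoexpressionNetwork(pairs, 0.5)
  et <- edgeTable(net)
  expect_identical(nrow(et), 1L)           # only A-B survives, via max(0.9,...)
  expect_identical(et$from, "A"); expect_identical(et$to, "B")
  expect_equal(et$weight, 0.9)
  expect_identical(networkKind(net), "coexpression")
  all <- buildCoexpressionNetwork(pairs, -Inf)
  expect_identical(nrow(edgeTable(all)), 2L)  # every distinct pair kept
})

test_that("co-annotation score is the Jaccard index over set membership", {
  lib <- GeneSetLibrary("L", list(
    GeneList("S1", c("U", "Q")), GeneList("S2", c("U", "V")),
    GeneList("S3", c("V", "Q"))))
  expect_equal(coannotationScore("U", "V", lib), 1 / 3)
  same <- GeneSetLibrary("L2", list(GeneList("S1", c("U", "V"))))
  expect_equal(coannotationScore("U", "V", same), 1)
  expect_equal(coannotationScore("U", "ZZ", lib), 0)
  expect_error(coannotationScore("U", "V", GeneSetLibrary("e", list())),
               "non-empty")
})

test_that("co-annotation scores are symmetric and bounded", {
  set.seed(23)
  for (rep in 1:20) {
    lib <- randomLibrary()
    pair <- sample(universe(lib), 2)
    s <- coannotationScore(pair[1], pair[2], lib)
    expect_identical(s, coannotationScore(pair[2], pair[1], lib))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("co-annotation networks threshold inclusively and shrink monotonically", {
  tri <- GeneSetLibrary("L", list(GeneList("S1", c("A", "B", "C"))))
  net <- buildCoannotationNetwork(tri, 0.5)
  expect_identical(nrow(edgeTable(net)), 3L)   # triangle, all scores 1
  expect_identical(nrow(edgeTable(buildCoannotationNetwork(tri, 1.0))), 3L)
  empty <- buildCoannotationNetwork(GeneSetLibrary("e", list()), 0.5)
  expect_identical(length(empty), 0L)

  set.seed(5)
  for (rep in 1:10) {
    lib <- randomLibrary()
    cuts <- sort(runif(3))
    eds <- lapply(cuts, function(ct)
      edgeKeys(as.matrix(edgeTable(buildCoannotationNetwork(lib, ct))[, 1:2])))
    expect_true(all(eds[[2]] %in% eds[[1]]))
    expect_true(all(eds[[3]] %in% eds[[2]]))
  }
})

test_that("co-annotation network edge weights equal pairwise scores", {
  set.seed(31)
  lib <- randomLibrary(4)
  net <- buildCoannotationNetwork(lib, 0.2)
  et <- edgeTable(net)
  for (r in seq_len(min(nrow(et), 10)))
    expect_equal(et$weight[r],
                 coannotationScore(et$from[r], et$to[r], lib))
})

test_that("the interactor tree is breadth-limited and marks revisits", {
  net <- BackgroundNetwork(rbind(c("A", "B"), c("B", "C")))
  t1 <- interactorTree("A", net, depth = 1)
  expect_identical(t1@table$node, "B")
  t2 <- interactorTree("A", net, depth = 2)
  expect_identical(genes(t2), c("A", "B", "C"))
  expect_identical(t2@table$parent[t2@table$node == "C"], "B")
  # revisit marking: the root reappears as B's neighbor but is not expanded
  expect_true(t2@table$revisit[t2@table$node == "A"])
  expect_error(interactorTree("ZZ", net), "not in the network")
  iso <- BackgroundNetwork(matrix(character(), 0, 2), nodes = "X")
  expect_identical(nrow(interactorTree("X", iso)@table), 0L)
})

test_that("tree depth-d node sets equal distance<=d balls (BFS oracle)", {
  set.seed(13)
  for (rep in 1:30) {
    g <- randomConnectedGraph(sample(4:15, 1))
    net <- BackgroundNetwork(g$edges)
    root <- sample(genes(net), 1)
    d <- sample(1:3, 1)
    tree <- interactorTree(root, net, depth = d)
    dist <- bfsDistances(adjList(g$edges, g$nodes), root)
    dist <- dist[genes(net)]
    expect_setequal(genes(tree), names(dist)[dist <= d])
    # per-node annotated degree matches the background
    deg <- nodeDegree(net)
    expect_identical(tree@table$degree,
                     unname(deg[tree@table$node]))
  }
})

test_that("asGeneList collects nodes deterministically", {
  net <- BackgroundNetwork(rbind(c("B", "C"), c("A", "B")))
  gl <- asGeneList(net)
  expect_identical(genes(gl), c("A", "B", "C"))   # BFS from lexicographic min
  tree <- interactorTree("A", net, depth = 2)
  expect_identical(genes(asGeneList(tree)), c("A", "B", "C"))
  empty <- BackgroundNetwork(matrix(character(), 0, 2))
  expect_identical(length(asGeneList(empty)), 0L)
})

test_that("SIF write/read is the identity on nodes and edges", {
  set.seed(37)
  f <- withr::local_tempfile(fileext = ".sif")
  for (rep in 1:15) {
    g <- randomConnectedGraph(sample(2:12, 1))
    net <- BackgroundNetwork(g$edges, nodes = "ISOLATED1")
    writeSIF(net, f)
    back <- readNetwork(f)
    expect_setequal(genes(back), genes(net))
    expect_identical(edgeKeys(as.matrix(edgeTable(back)[, 1:2])),
                     edgeKeys(as.matrix(edgeTable(net)[, 1:2])))
  }
})
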
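test_that("fisherOverlap reproduces closed-form tail values", {
  uni20 <- sprintf("G%02d", 1:20)
  u <- GeneList("u", uni20[1:5]); s <- GeneList("s", uni20[1:5])
  expect_equal(fisherOverlap(u, s, uni20)@pRaw, 1 / choose(20, 5),
               tolerance = 1e-12)
  uni10 <- sprintf("G%02d", 1:10)
  p <- fisherOverlap(GeneList("u", uni10[1:4]), GeneList("s", uni10[1:5]),
                     uni10)@pRaw
  expect_equal(p, 5 / 210, tolerance = 1e-12)
  # zero overlap: upper tail from 0 sums to 1 exactly
  p0 <- fisherOverlap(GeneList("u", uni10[1:3]), GeneList("s", uni10[8:10]),
                      uni10)
  expect_identical(p0@k, 0L)
  expect_identical(p0@pRaw, 1)
})

test_that("fisherOverlap restricts to the universe and flags degeneracy", {
  uni <- sprintf("G%02d", 1:10)
  u <- GeneList("u", c(uni[1:3], "OFFUNIVERSE"))
  s <- GeneList("s", uni[2:4])
  ot <- fisherOverlap(u, s, uni)
  expect_identical(ot@a, 3L)          # off-universe gene dropped from a
  expect_identical(ot@N, 10L)
  expect_identical(sort(ot@overlapGenes), c("G02", "G03"))
  deg <- fisherOverlap(GeneList("u", "OFFUNIVERSE"), s, uni)
  expect_true(deg@degenerate)
  expect_identical(deg@pRaw, 1)
  expect_identical(deg@k, 0L)
  expect_error(fisherOverlap(u, s, character()), "non-empty")
})

test_that("fisherOverlap matches independent references on a small grid", {
  # dual route: stats::phyper and a ratio-recurrence oracle
  set.seed(3)
  for (rep in 1:300) {
    N <- sample(5:60, 1)
    a <- sample(1:N, 1); b <- sample(1:N, 1)
    lo <- max(0, a + b - N)
    k <- sampleOne(lo:min(a, b))
    uni <- sprintf("U%03d", 1:N)
    # deterministic placement: shared block, then disjoint tails
    # (a + b - k <= N is guaranteed by k >= max(0, a + b - N))
    uGenes <- uni[seq_len(a)]
    bGenes <- c(uni[seq_len(k)], uni[a + seq_len(b - k)])
    ot <- fisherOverlap(GeneList("u", uGenes), GeneList("s", bGenes), uni)
    expect_identical(ot@k, as.integer(k))
    pPhyper <- stats::phyper(k - 1, b, N - b, a, lower.tail = FALSE)
    expect_equal(ot@pRaw, pPhyper, tolerance = 1e-10)
    expect_equal(ot@pRaw, refHyperTail(k, a, b, N), tolerance = 1e-9)
  }
})

test_that("the tail p-value is non-increasing in k for fixed (a, b, N)", {
  for (N in c(15, 40)) for (a in c(4, 10)) for (b in c(6, 12)) {
    p <- vapply(0:min(a, b), function(k)
      ListNet:::hyperUpperTail(k, a, b, N), numeric(1))
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("corrections match closed forms and validate their input", {
  expect_equal(bonferroni(c(0.01, 0.30)), c(0.02, 0.60))
  expect_equal(bonferroni(c(0.70, 0.90)), c(1, 1))
  expect_equal(bonferroni(0.05), 0.05)
  expect_equal(benjaminiHochberg(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.0267, 0.04), tolerance = 1e-2)
  expect_equal(benjaminiHochberg(0.5), 0.5)
  expect_equal(benjaminiHochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bonferroni(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(benjaminiHochberg(1.2), "\\(0, 1\\]")
})

test_that("BH is bounded by Bonferroni, dominates raw p, and is order-equivariant", {
  set.seed(19)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    bh <- benjaminiHochberg(p)
    expect_true(all(bh >= p - 1e-12))
    expect_true(all(bh <= bonferroni(p) + 1e-12))
    expect_equal(bh, refBH(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(benjaminiHochberg(p[perm]), bh[perm], tolerance = 1e-12)
  }
})

makeToyMatrix <- function() {
  uni <- sprintf("G%02d", 1:30)
  lib <- GeneSetLibrary("lib", list(
    GeneList("T1", uni[1:6]), GeneList("T2", uni[7:12]),
    GeneList("T3", uni[13:30])))
  users <- list(GeneList("U1", uni[1:6]), GeneList("U2", uni[25:30]))
  overlapMatrix(users, lib)
}

test_that("overlapMatrix has the contracted shape and shared N", {
  om <- makeToyMatrix()
  expect_identical(dim(om), c(3L, 2L))
  expect_identical(universeSize(om), 30L)
  expect_true(all(pBonferroni(om) >= pRaw(om) - 1e-12))
  expect_true(all(pBH(om) <= pBonferroni(om) + 1e-12))
  # U1 identical to T1: cell has k = a = b and the column minimum p
  expect_identical(overlapCounts(om)["T1", "U1"], 6L)
  expect_equal(min(pRaw(om)[, "U1"]), pRaw(om)["T1", "U1"])
  # U2 subset of T3 only: other rows have k = 0 hence p = 1
  expect_identical(pRaw(om)["T1", "U2"], 1)
  expect_identical(pRaw(om)["T2", "U2"], 1)
})

test_that("matrix-wide correction uses one family across all cells", {
  uni <- sprintf("G%02d", 1:30)
  lib <- GeneSetLibrary("lib", list(GeneList("T1", uni[1:6]),
                                    GeneList("T2", uni[7:12])))
  users <- list(GeneList("U1", uni[1:6]), GeneList("U2", uni[7:12]))
  omCol <- overlapMatrix(users, lib, correction = "column")
  omAll <- overlapMatrix(users, lib, correction = "matrix")
  expect_equal(pBonferroni(omCol)["T1", "U1"],
               min(1, pRaw(omCol)["T1", "U1"] * 2))
  expect_equal(pBonferroni(omAll)["T1", "U1"],
               min(1, pRaw(omAll)["T1", "U1"] * 4))
})

test_that("universe policies change N as documented", {
  uni <- sprintf("G%02d", 1:12)
  lib <- GeneSetLibrary("lib", list(GeneList("T1", uni[1:8])))
  user <- GeneList("U1", c(uni[1:4], "EXTRA1", "EXTRA2"))
  omLib <- overlapMatrix(user, lib)                      # N = |library universe|
  omUnion <- overlapMatrix(user, lib, universe = "union")
  omExpl <- overlapMatrix(user, lib, universe = c(uni, "EXTRA1", "EXTRA2",
                                                  "PAD1", "PAD2"))
  expect_identical(universeSize(omLib), 8L)
  expect_identical(universeSize(omUnion), 10L)
  expect_identical(universeSize(omExpl), 16L)
  expect_identical(omLib@droppedGenes$U1, c("EXTRA1", "EXTRA2"))
})

test_that("rankTerms sorts by p, then descending k, then label", {
  om <- makeToyMatrix()
  tab <- rankTerms(om, "U1")
  expect_identical(tab$term[1], "T1")
  expect_true(!is.unsorted(tab$pRaw))
  expect_error(rankTerms(om, "NOPE"), "unknown user-list column")
  # tie-break: equal p (both k = 0 -> p = 1) ordered by label
  ties <- tab[tab$pRaw == 1, ]
  expect_identical(ties$term, sort(ties$term))
})

test_that("enrichment reports round-trip through their TSV contract", {
  om <- makeToyMatrix()
  d <- withr::local_tempdir()
  files <- writeEnrichmentReports(om, d)
  tab <- read.delim(file.path(d, "enrichment_U1.tsv"))
  expect_identical(names(tab),
                   c("term", "overlap_k", "list_size", "term_size",
                     "universe", "p_raw", "p_bonferroni", "p_bh",
                     "overlap_genes"))
  expect_identical(tab$term[1], "T1")
  expect_identical(tab$overlap_k[1], 6L)
  mat <- read.delim(file.path(d, "enrichment_praw_matrix.tsv"),
                    check.names = FALSE)
  expect_identical(dim(mat), c(3L, 3L))  # term column + 2 user lists
})
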
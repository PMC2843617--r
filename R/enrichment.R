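## Fisher-exact overlap statistics, multiple-testing correction, the
## sortable overlap matrix, and ranked enrichment tables.

## One-sided (over-representation) hypergeometric upper tail:
##   P(K >= k) = sum_{i=k..min(a,b)} C(b,i) C(N-b,a-i) / C(N,a).
## Computed in log space (lchoose + log-sum-exp) so N up to tens of
## thousands of genes cannot overflow; deterministic.
hyperUpperTail <- function(k, a, b, N) {
  if (k <= 0L) return(1)
  hi <- min(a, b)
  if (k > hi) stop("k exceeds min(a, b)")
  i <- k:hi
  lt <- lchoose(b, i) + lchoose(N - b, a - i) - lchoose(N, a)
  m <- max(lt)
  min(1, exp(m) * sum(exp(lt - m)))
}

#' Fisher-exact overlap between a user list and a library set
#'
#' Tests over-representation of the overlap under the hypergeometric null:
#' both lists are first restricted to the background universe, then the
#' one-sided upper-tail p-value
#' \deqn{P = \sum_{i=k}^{\min(a,b)} \binom{b}{i}\binom{N-b}{a-i} \Big/ \binom{N}{a}}
#' is computed exactly in log space, where `k` is the overlap, `a` and `b`
#' the restricted list sizes and `N` the universe size. Equivalent to the
#' one-sided Fisher exact test on the 2x2 membership table.
#'
#' @param user a [GeneList] (the experimental list).
#' @param libset a [GeneList] (one library set).
#' @param universe character vector of background symbols (non-empty).
#' @return an [OverlapTest]; degenerate (k = 0, p = 1, flagged) when either
#'   list is empty after universe restriction.
#' @examples
#' u <- GeneList("u", sprintf("G%02d", 1:5))
#' s <- GeneList("s", sprintf("G%02d", 1:5))
#' fisherOverlap(u, s, sprintf("G%02d", 1:20))  # p = 1/choose(20,5)
#' @export
fisherOverlap <- function(user, libset, universe) {
  stopifnot(is(user, "GeneList"), is(libset, "GeneList"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty")
  ua <- user@genes[user@genes %in% universe]
  lb <- libset@genes[libset@genes %in% universe]
  shared <- ua[ua %in% lb]
  a <- length(ua); b <- length(lb); k <- length(shared)
  N <- length(universe)
  degenerate <- a == 0L || b == 0L
  p <- if (degenerate) 1 else hyperUpperTail(k, a, b, N)
  new("OverlapTest", k = k, a = a, b = b, N = N, pRaw = p,
      overlapGenes = shared, degenerate = degenerate)
}

checkPValues <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p
}

#' Bonferroni family-wise correction
#'
#' Each p-value is multiplied by the family size and capped at 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same order.
#' @export
bonferroni <- function(p) {
  p <- checkPValues(p)
  stats::p.adjust(p, method = "bonferroni")
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up adjustment: with p sorted ascending, q_i = p_i * n / i,
#' made monotone from the largest rank down, capped at 1, and returned in
#' the original input order.
#'
#' @inheritParams bonferroni
#' @return adjusted p-values, same order.
#' @export
benjaminiHochberg <- function(p) {
  p <- checkPValues(p)
  stats::p.adjust(p, method = "BH")
}

resolveUniverse <- function(users, library, universe) {
  if (is.character(universe) && length(universe) > 1L)
    return(unique(normalizeSymbol(universe)))
  policy <- match.arg(universe, c("library", "union"))
  u <- universe(library)
  if (policy == "union")
    u <- unique(c(u, unlist(lapply(users, genes), use.names = FALSE)))
  u
}

#' Overlap matrix of user lists against a gene-set library
#'
#' One [OverlapTest] per (library set, user list) pair, all sharing one
#' universe size N. The background universe defaults to the library's own
#' universe; `universe = "union"` adds all user-list genes, and an explicit
#' character vector may be supplied. Under the default policy, user-list
#' genes absent from the universe are dropped from `a` (and reported via
#' the `droppedGenes` slot), not added to N. Corrected p-values are
#' computed per user-list column over the library's sets
#' (`correction = "column"`) or over all cells at once
#' (`correction = "matrix"`).
#'
#' @param users a [GeneList] or list of [GeneList] objects with unique names.
#' @param library a non-empty [GeneSetLibrary].
#' @param universe `"library"` (default), `"union"`, or an explicit symbol
#'   vector.
#' @param correction `"column"` (default) or `"matrix"`.
#' @return an [OverlapMatrix].
#' @export
overlapMatrix <- function(users, library, universe = "library",
                          correction = c("column", "matrix")) {
  if (is(users, "GeneList")) users <- list(users)
  stopifnot(length(users) >= 1L,
            all(vapply(users, is, logical(1), "GeneList")),
            is(library, "GeneSetLibrary"), length(library) >= 1L)
  correction <- match.arg(correction)
  uNames <- vapply(users, objectName, character(1))
  if (anyDuplicated(uNames)) stop("user list names must be unique")
  bg <- resolveUniverse(users, library, universe)
  if (!length(bg)) stop("background universe is empty under this policy")
  tNames <- setNames2(library)
  nT <- length(tNames); nU <- length(uNames)
  k <- matrix(0L, nT, nU, dimnames = list(tNames, uNames))
  p <- matrix(1, nT, nU, dimnames = list(tNames, uNames))
  ogenes <- vector("list", nU); names(ogenes) <- uNames
  dropped <- vector("list", nU); names(dropped) <- uNames
  aSizes <- integer(nU); names(aSizes) <- uNames
  bSizes <- integer(nT); names(bSizes) <- tNames
  for (j in seq_len(nU)) {
    col <- vector("list", nT)
    dropped[[j]] <- setdiff(genes(users[[j]]), bg)
    for (i in seq_len(nT)) {
      ot <- fisherOverlap(users[[j]], library[[i]], bg)
      k[i, j] <- ot@k; p[i, j] <- ot@pRaw
      col[[i]] <- ot@overlapGenes
      bSizes[i] <- ot@b
      aSizes[j] <- ot@a
    }
    names(col) <- tNames
    ogenes[[j]] <- col
  }
  if (correction == "column") {
    pb <- apply(p, 2L, bonferroni)
    ph <- apply(p, 2L, benjaminiHochberg)
    if (nT == 1L) {  # apply() drops to a vector for single-row matrices
      pb <- matrix(pb, 1L); ph <- matrix(ph, 1L)
    }
  } else {
    pb <- matrix(bonferroni(as.vector(p)), nT, nU)
    ph <- matrix(benjaminiHochberg(as.vector(p)), nT, nU)
  }
  dimnames(pb) <- dimnames(ph) <- dimnames(p)
  new("OverlapMatrix", k = k, pRaw = p, pBonferroni = pb, pBH = ph,
      listSizes = aSizes, setSizes = bSizes, universeSize = length(bg),
      overlapGenes = ogenes, droppedGenes = dropped,
      correction = correction)
}

#' Ranked enrichment table for one user list
#'
#' Rows (library sets) sorted by ascending raw p-value; ties broken by
#' descending overlap count, then set label.
#'
#' @param om an [OverlapMatrix].
#' @param column user-list label (or column index).
#' @return data.frame with columns `term`, `k`, `a`, `b`, `N`, `pRaw`,
#'   `pBonferroni`, `pBH`, `overlapGenes` (semicolon-joined).
#' @export
rankTerms <- function(om, column) {
  stopifnot(is(om, "OverlapMatrix"))
  if (is.character(column)) {
    j <- match(column, colnames(om@pRaw))
    if (is.na(j)) stop(sprintf("unknown user-list column '%s'", column))
  } else j <- as.integer(column)
  terms <- rownames(om@pRaw)
  df <- data.frame(
    term = terms,
    k = om@k[, j],
    a = rep(om@listSizes[j], length(terms)),
    b = om@setSizes,
    N = rep(om@universeSize, length(terms)),
    pRaw = om@pRaw[, j],
    pBonferroni = om@pBonferroni[, j],
    pBH = om@pBH[, j],
    overlapGenes = vapply(om@overlapGenes[[j]], paste, character(1),
                          collapse = ";"),
    row.names = NULL, stringsAsFactors = FALSE)
  df[order(df$pRaw, -df$k, df$term), , drop = FALSE]
}

#' Write per-list enrichment reports and the combined p-value matrix
#'
#' One tab-delimited file per user list with columns `term`, `overlap_k`,
#' `list_size`, `term_size`, `universe`, `p_raw`, `p_bonferroni`, `p_bh`,
#' `overlap_genes` (semicolon-joined), rows in rank order; plus one
#' combined file of raw p-values (terms x lists).
#'
#' @param om an [OverlapMatrix].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of files written, invisibly.
#' @export
writeEnrichmentReports <- function(om, dir, prefix = "enrichment") {
  stopifnot(is(om, "OverlapMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (col in colnames(om@pRaw)) {
    tab <- rankTerms(om, col)
    out <- data.frame(term = tab$term, overlap_k = tab$k,
                      list_size = tab$a, term_size = tab$b,
                      universe = tab$N, p_raw = tab$pRaw,
                      p_bonferroni = tab$pBonferroni, p_bh = tab$pBH,
                      overlap_genes = tab$overlapGenes,
                      stringsAsFactors = FALSE)
    f <- file.path(dir, paste0(prefix, "_", col, ".tsv"))
    utils::write.table(out, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  fm <- file.path(dir, paste0(prefix, "_praw_matrix.tsv"))
  mat <- data.frame(term = rownames(om@pRaw), om@pRaw, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(mat, fm, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, fm))
}
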
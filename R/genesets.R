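## Gene-symbol normalization, GMT / plain-list I/O, set algebra.

#' Normalize raw gene symbols
#'
#' Canonical form: surrounding whitespace stripped, upper-cased, then an
#' optional synonym table applied (alias -> canonical, looked up once; the
#' mapping is acyclic by construction so a single pass suffices).
#' Normalization is idempotent.
#'
#' @param raw character vector of raw symbols.
#' @param synonyms optional synonym table from [synonymTable()] or
#'   [readSynonymTable()].
#' @return character vector of canonical symbols, same length as `raw`.
#' @examples
#' normalizeSymbol(c("  nanog ", "Sox2"))
#' normalizeSymbol("p53", synonymTable("P53", "TP53"))
#' @export
normalizeSymbol <- function(raw, synonyms = NULL) {
  out <- toupper(trimws(as.character(raw)))
  bad <- which(!nzchar(out) | is.na(out))
  if (length(bad))
    stop(sprintf("empty gene symbol at position %d ('%s')",
                 bad[1L], raw[bad[1L]]))
  if (any(grepl("[\t\n\r]", out)))
    stop("gene symbols must not contain tab or newline characters")
  if (!is.null(synonyms) && length(synonyms)) {
    hit <- match(out, names(synonyms))
    out[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  out
}

#' Build a synonym table
#'
#' A pluggable alias-to-canonical mapping applied at normalization time.
#' Both columns are themselves normalized (trim + upper-case). The mapping
#' must be flat: a canonical symbol may map only to itself, never onward to
#' a third symbol, so no chains or cycles can arise.
#'
#' @param alias character vector of alias symbols.
#' @param canonical character vector of canonical symbols, same length.
#' @return named character vector (names = aliases, values = canonicals)
#'   with self-mappings removed.
#' @export
synonymTable <- function(alias, canonical) {
  if (length(alias) != length(canonical))
    stop("'alias' and 'canonical' must have equal length")
  alias <- toupper(trimws(alias))
  canonical <- toupper(trimws(canonical))
  keep <- alias != canonical
  map <- stats::setNames(canonical[keep], alias[keep])
  if (anyDuplicated(names(map)))
    stop(sprintf("alias '%s' maps to more than one canonical symbol",
                 names(map)[duplicated(names(map))][1L]))
  chained <- names(map)[map %in% names(map)]
  if (length(chained))
    stop(sprintf(
      "synonym table contains a chain: alias '%s' maps to '%s', itself an alias",
      chained[1L], map[chained[1L]]))
  map
}

#' Read a synonym table from a two-column tab-delimited file
#'
#' @param path file with rows `alias<TAB>canonical`; `#` comment lines and
#'   blank lines are ignored.
#' @return a synonym table as from [synonymTable()].
#' @export
readSynonymTable <- function(path) {
  lines <- readLinesNormalized(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(synonymTable(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop(sprintf("row %d: expected 2 tab-delimited fields", bad[1L]))
  m <- do.call(rbind, fields)
  synonymTable(m[, 1L], m[, 2L])
}

## readLines with Windows line endings tolerated
readLinesNormalized <- function(path) {
  sub("\r$", "", readLines(path, warn = FALSE))
}

#' Read a gene-set library from a GMT file
#'
#' Gene Matrix Transposed format: one gene set per tab-delimited row; column
#' 1 is the set name, column 2 a free-text description, the remaining cells
#' are gene symbols. Symbols are normalized and de-duplicated (first
#' occurrence kept, drop counts exposed via [duplicatesDropped()]); empty
#' trailing cells are dropped; row order is preserved. UTF-8, Unix or
#' Windows line endings.
#'
#' @param path GMT file path.
#' @param name library label; defaults to the file name.
#' @param synonyms optional synonym table.
#' @return a [GeneSetLibrary].
#' @export
readGMT <- function(path, name = basename(path), synonyms = NULL) {
  lines <- readLinesNormalized(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  drops <- integer()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L)
      stop(sprintf("row %d: fewer than 2 columns", i))
    raw <- fields[-(1:2)]
    raw <- raw[nzchar(trimws(raw))]
    norm <- if (length(raw)) normalizeSymbol(raw, synonyms) else character()
    nDup <- sum(duplicated(norm))
    gl <- new("GeneList", name = fields[1L], description = fields[2L],
              genes = unique(norm))
    sets[[i]] <- gl
    if (nDup > 0L) drops[fields[1L]] <- nDup
  }
  nm <- vapply(sets, objectName, character(1))
  if (anyDuplicated(nm))
    stop(sprintf("duplicate set name: '%s'", nm[duplicated(nm)][1L]))
  GeneSetLibrary(name, sets, duplicatesDropped = drops)
}

#' Write a gene-set library to a GMT file
#'
#' Round-trip identity: `readGMT(writeGMT(lib, path))` reproduces names,
#' descriptions and gene collections exactly. Unix line endings.
#'
#' @param lib a [GeneSetLibrary].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(lib, path) {
  stopifnot(is(lib, "GeneSetLibrary"))
  validObject(lib)
  rows <- vapply(lib@sets, function(s) {
    if (grepl("\t", s@name) || grepl("\t", s@description))
      stop(sprintf("set '%s': name or description contains a tab", s@name))
    paste(c(s@name, s@description, s@genes), collapse = "\t")
  }, character(1))
  writeLines(rows, path, sep = "\n")
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#'
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path text file path.
#' @param name list label; defaults to the file name without extension.
#' @param synonyms optional synonym table.
#' @return a [GeneList].
#' @export
readGeneList <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                         synonyms = NULL) {
  lines <- readLinesNormalized(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  GeneList(name, lines, synonyms = synonyms)
}

#' Write a plain gene list (one symbol per line)
#'
#' @param x a [GeneList].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneList <- function(x, path) {
  stopifnot(is(x, "GeneList"))
  writeLines(x@genes, path)
  invisible(path)
}

## ----------------------------------------------------------- set algebra

opName <- function(a, b, op) paste0(a@name, "_", op, "_", b@name)

#' Set algebra on gene lists
#'
#' Standard set semantics on the symbol sets; the result name is generated
#' from the operand names and the operator. `setUnion` keeps operand-a
#' order first, then operand-b novelties; `setIntersection` and
#' `setSubtract` keep operand-a order. Empty operands are legal.
#'
#' @param a,b [GeneList] objects (already normalized by construction).
#' @return a [GeneList].
#' @examples
#' a <- GeneList("A", c("X", "Y", "Z")); b <- GeneList("B", c("Y", "Z", "W"))
#' genes(setIntersection(a, b))
#' genes(setSubtract(a, b))
#' @export
setUnion <- function(a, b) {
  stopifnot(is(a, "GeneList"), is(b, "GeneList"))
  new("GeneList", name = opName(a, b, "OR"), description = "",
      genes = c(a@genes, setdiff(b@genes, a@genes)))
}

#' @rdname setUnion
#' @export
setIntersection <- function(a, b) {
  stopifnot(is(a, "GeneList"), is(b, "GeneList"))
  new("GeneList", name = opName(a, b, "AND"), description = "",
      genes = a@genes[a@genes %in% b@genes])
}

#' @rdname setUnion
#' @export
setSubtract <- function(a, b) {
  stopifnot(is(a, "GeneList"), is(b, "GeneList"))
  new("GeneList", name = opName(a, b, "NOT"), description = "",
      genes = a@genes[!a@genes %in% b@genes])
}
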
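#' Read a coded species-by-trait table
#'
#' Reads a delimited table whose header row gives trait ids and whose first
#' column gives species ids.  Cells use the growth codes of taxonomic trait
#' compendia: growth `+`, no growth `-`, variable `v`, no data `n`
#' (synonyms configurable via `codes`).
#'
#' @param path file path (TSV or CSV, UTF-8).
#' @param sep field separator; `NULL` autodetects `\t` vs `,` from the
#'   header line.
#' @param codes named list of accepted tokens for `present`, `absent`,
#'   `variable` and `missing` cells.
#' @return A [TraitMatrix-class] with `coding = "raw"`.
#' @export
readTraitTable <- function(path, sep = NULL,
    codes = list(present = c("+", "1"), absent = c("-", "−", "0"),
      variable = c("v", "V"), missing = c("n", "N", "NA", ""))) {
  if (is.null(sep)) sep <- .sniffSep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
    colClasses = "character", check.names = FALSE, quote = "\"",
    comment.char = "", stringsAsFactors = FALSE)
  sp <- tab[[1L]]
  if (anyDuplicated(sp))
    stop("duplicated species id(s): ",
      paste(unique(sp[duplicated(sp)]), collapse = ", "))
  tr <- colnames(tab)[-1L]
  if (anyDuplicated(tr))
    stop("duplicated trait id(s): ",
      paste(unique(tr[duplicated(tr)]), collapse = ", "))
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  coded <- matrix(NA_integer_, nrow(cells), ncol(cells),
    dimnames = list(sp, tr))
  map <- c(
    stats::setNames(rep(.CODE_PRESENT, length(codes$present)), codes$present),
    stats::setNames(rep(.CODE_ABSENT, length(codes$absent)), codes$absent),
    stats::setNames(rep(.CODE_VARIABLE, length(codes$variable)), codes$variable))
  known_missing <- codes$missing
  for (j in seq_len(ncol(cells))) {
    v <- trimws(cells[, j])
    bad <- !(v %in% c(names(map), known_missing)) & !is.na(v)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("unrecognized cell token '%s' at species '%s', trait '%s'",
        v[i], sp[i], tr[j]))
    }
    coded[, j] <- ifelse(v %in% known_missing | is.na(v), NA_integer_,
      map[v])
  }
  TraitMatrix(coded, coding = "raw")
}

.sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write a coded trait table
#'
#' Inverse of [readTraitTable()]; raw codes are written as `+`, `-`, `v`,
#' `n` and binary codings as `1`, `0`, `n`.
#'
#' @param x a [TraitMatrix-class].
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeTraitTable <- function(x, path, sep = "\t") {
  d <- as.matrix(x)
  if (coding(x) == "raw") {
    out <- matrix("n", nrow(d), ncol(d))
    out[which(d == .CODE_PRESENT)] <- "+"
    out[which(d == .CODE_ABSENT)] <- "-"
    out[which(d == .CODE_VARIABLE)] <- "v"
  } else {
    out <- matrix("n", nrow(d), ncol(d))
    out[which(d == 1L)] <- "1"
    out[which(d == 0L)] <- "0"
  }
  df <- data.frame(species = rownames(d), out, check.names = FALSE,
    stringsAsFactors = FALSE)
  colnames(df) <- c("species", colnames(d))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score variable traits as present
#'
#' Traits scored as variable among strains reflect growth in at least some
#' strains of the type material, so they are scored positive: variable -> 1,
#' present -> 1, absent -> 0; unavailable cells stay missing.
#'
#' @param x a raw-coded [TraitMatrix-class].
#' @return A binary [TraitMatrix-class] (0/1/NA).
#' @export
applyVariableRule <- function(x) {
  stopifnot(is(x, "TraitMatrix"))
  if (coding(x) != "raw")
    return(x)
  d <- as.matrix(x)
  d[which(d == .CODE_VARIABLE)] <- 1L
  TraitMatrix(d, coding = "binary")
}

#' Remove poorly observed traits and species
#'
#' Drops traits whose growth was evaluated in fewer than `traitMin` of the
#' species, then species with data for fewer than `speciesMin` of the
#' remaining traits.  Retained cell values are never altered; dropped ids
#' are messaged and attached as attributes `droppedTraits` /
#' `droppedSpecies`.
#'
#' @param x a binary [TraitMatrix-class] (may contain NA).
#' @param traitMin minimum fraction of species with data for a trait to be
#'   kept (default 0.8).
#' @param speciesMin minimum fraction of retained traits with data for a
#'   species to be kept (default 0.2).
#' @return The filtered [TraitMatrix-class].
#' @export
filterByCoverage <- function(x, traitMin = 0.8, speciesMin = 0.2) {
  stopifnot(is(x, "TraitMatrix"), traitMin > 0, traitMin <= 1,
    speciesMin > 0, speciesMin <= 1)
  d <- as.matrix(x)
  traitCov <- colMeans(!is.na(d))
  dropT <- colnames(d)[traitCov < traitMin]
  d <- d[, traitCov >= traitMin, drop = FALSE]
  spCov <- rowMeans(!is.na(d))
  dropS <- rownames(d)[spCov < speciesMin]
  d <- d[spCov >= speciesMin, , drop = FALSE]
  if (nrow(d) == 0L || ncol(d) == 0L)
    stop("coverage filtering removed every species or trait")
  if (length(dropT))
    message("dropped ", length(dropT), " trait(s): ",
      paste(dropT, collapse = ", "))
  if (length(dropS))
    message("dropped ", length(dropS), " species")
  out <- TraitMatrix(d, coding = "binary")
  attr(out, "droppedTraits") <- dropT
  attr(out, "droppedSpecies") <- dropS
  out
}

#' Read a binary species table (environments, genes, growth)
#'
#' Reads a delimited binary table with a header row of column ids and a
#' first column of species ids.  Cells must be 0 or 1.
#'
#' @param path file path.
#' @param sep field separator; `NULL` autodetects.
#' @return integer matrix with species rownames.
#' @export
readBinaryTable <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .sniffSep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
    colClasses = "character", check.names = FALSE, quote = "\"",
    comment.char = "", stringsAsFactors = FALSE)
  sp <- tab[[1L]]
  if (anyDuplicated(sp))
    stop("duplicated species id(s): ",
      paste(unique(sp[duplicated(sp)]), collapse = ", "))
  cells <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- matrix(!(trimws(cells) %in% c("0", "1")), nrow(cells))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary cell '%s' at species '%s', column '%s'",
      cells[idx[1L], idx[2L]], sp[idx[1L]], colnames(cells)[idx[2L]]))
  }
  out <- matrix(as.integer(cells), nrow(cells), ncol(cells),
    dimnames = list(sp, colnames(cells)))
  out
}

#' Read a species-by-environment table
#'
#' Environments with fewer than 4 member species are too small for the
#' association tests and are flagged; all-zero environments draw a warning.
#'
#' @param path file path to a binary table (see [readBinaryTable()]).
#' @param sep field separator; `NULL` autodetects.
#' @param minSpecies eligibility threshold (default 4 member species).
#' @return An [EnvironmentMatrix-class]; attribute `eligible` holds the
#'   logical eligibility flags.
#' @export
readEnvironmentTable <- function(path, sep = NULL, minSpecies = 4L) {
  m <- readBinaryTable(path, sep)
  env <- EnvironmentMatrix(m)
  sizes <- colSums(m)
  if (any(sizes == 0L))
    warning("all-zero environment column(s): ",
      paste(colnames(m)[sizes == 0L], collapse = ", "))
  attr(env, "eligible") <- eligibleEnvironments(env, minSpecies)
  env
}

#' Environment eligibility for association testing
#'
#' @param env an [EnvironmentMatrix-class].
#' @param minSpecies minimum member species (default 4).
#' @return Named logical vector, TRUE for testable environments.
#' @export
eligibleEnvironments <- function(env, minSpecies = 4L) {
  colSums(as.matrix(env)) >= minSpecies
}

#' Read a rooted phylogeny
#'
#' Thin wrapper over [ape::read.tree()] that enforces the requirements of
#' the downstream analyses: rooted topology and branch lengths (needed for
#' the threshold-Brownian null).
#'
#' @param path newick file.
#' @return An [ape::phylo] tree.
#' @export
readPhylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree))
    stop("could not parse newick file: ", path)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (!ape::is.rooted(tree))
    stop("tree must be rooted")
  tree
}

#' Match tree tips to trait-matrix species
#'
#' Normalizes labels (whitespace to underscore, configurable) on both
#' sides, prunes the tree to the shared species, and reports how many
#' species were dropped from each side.
#'
#' @param tree an `ape::phylo`.
#' @param x a [TraitMatrix-class].
#' @param normalize if TRUE, collapse runs of whitespace/underscores to a
#'   single underscore before matching.
#' @return list with elements `tree` (pruned), `x` (subset, reordered to
#'   the tree's tips), `droppedFromTree`, `droppedFromMatrix`.
#' @export
matchTreeToTraits <- function(tree, x, normalize = TRUE) {
  norm <- function(s) if (normalize) gsub("[ _]+", "_", trimws(s)) else s
  tips <- norm(tree$tip.label)
  sp <- norm(speciesIds(x))
  shared <- intersect(tips, sp)
  if (!length(shared))
    stop("no species shared between tree and trait matrix")
  dropTree <- setdiff(tips, shared)
  dropMat <- setdiff(sp, shared)
  tree2 <- tree
  tree2$tip.label <- tips
  tree2 <- ape::drop.tip(tree2, dropTree)
  xs <- x[match(tree2$tip.label, sp), ]
  d <- as.matrix(xs)
  rownames(d) <- tree2$tip.label  # normalized ids on both sides
  xs <- TraitMatrix(d, coding = coding(xs))
  if (length(dropTree) || length(dropMat))
    message(length(dropTree), " tip(s) dropped from tree, ",
      length(dropMat), " species dropped from matrix")
  list(tree = tree2, x = xs, droppedFromTree = dropTree,
    droppedFromMatrix = dropMat)
}
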
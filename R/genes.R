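#' Gene presence vs growth chi-squared tests
#'
#' For each (gene, carbon source) pair: `same` counts species where the
#' gene is present and the species grows; `different` counts gene-absent
#' growth plus gene-present no-growth.  The test statistic is the
#' chi-squared of the full 2x2 presence x growth table without continuity
#' correction (the Same/Different columns are summaries of that table, not
#' the test's entire input).  p-values are Benjamini-Hochberg corrected
#' across all tested pairs.
#'
#' @param genes binary matrix, species x genes.
#' @param growth binary matrix, species x carbon sources (same species,
#'   same order).
#' @param pairs optional data.frame with columns `gene`, `carbon`;
#'   default all combinations.
#' @return data.frame: gene, carbon, same, different, chi2, p, q.
#'   Constant columns make a pair untestable; it is kept with NA
#'   statistics and a note.
#' @export
geneGrowthChi2 <- function(genes, growth, pairs = NULL) {
  stopifnot(identical(rownames(genes), rownames(growth)))
  if (is.null(pairs))
    pairs <- expand.grid(gene = colnames(genes), carbon = colnames(growth),
      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    g <- genes[, pairs$gene[k]]
    w <- growth[, pairs$carbon[k]]
    same <- sum(g == 1L & w == 1L)
    diff <- sum(g == 0L & w == 1L) + sum(g == 1L & w == 0L)
    if (length(unique(g)) < 2L || length(unique(w)) < 2L)
      return(data.frame(gene = pairs$gene[k], carbon = pairs$carbon[k],
        same = same, different = diff, chi2 = NA_real_, p = NA_real_))
    tab <- table(factor(g, 0:1), factor(w, 0:1))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(gene = pairs$gene[k], carbon = pairs$carbon[k],
      same = same, different = diff,
      chi2 = unname(ct$statistic), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  nskip <- sum(is.na(out$p))
  if (nskip)
    message(nskip, " pair(s) with a constant column were not testable")
  out$q <- NA_real_
  out$q[!is.na(out$p)] <- bhAdjust(out$p[!is.na(out$p)])
  out
}

#' Within- vs between-community gene co-occurrence
#'
#' Compares how often two genes are both present in a species when the
#' genes belong to the same trait community versus different communities.
#' Within-pairs are all unordered gene pairs inside `group1` plus inside
#' `group2`; between-pairs cross the groups.  Co-occurrence events (both
#' present) are pooled over species x pairs and the two pooled proportions
#' compared with an equal-proportions chi-squared test (Yates-corrected by
#' default); `pooled = FALSE` averages frequencies per pair instead.
#'
#' @param genes binary matrix, species x genes.
#' @param group1,group2 disjoint character vectors of gene ids.
#' @param correct apply Yates continuity correction (default TRUE).
#' @param pooled pool events over species x pairs (default) or average
#'   per-pair frequencies.
#' @return list: `within_freq`, `between_freq`, `chi2`, `p`, and the
#'   event/total counts.
#' @export
coOccurrenceTest <- function(genes, group1, group2, correct = TRUE,
    pooled = TRUE) {
  if (!length(group1) || !length(group2))
    stop("both gene groups must be non-empty")
  if (length(intersect(group1, group2)))
    stop("gene groups must be disjoint")
  miss <- setdiff(c(group1, group2), colnames(genes))
  if (length(miss))
    stop("gene(s) absent from table: ", paste(miss, collapse = ", "))
  pairsWithin <- rbind(
    if (length(group1) > 1L) t(utils::combn(group1, 2L)) else NULL,
    if (length(group2) > 1L) t(utils::combn(group2, 2L)) else NULL)
  pairsBetween <- as.matrix(expand.grid(group1, group2,
    stringsAsFactors = FALSE))
  countPair <- function(p) sum(genes[, p[1L]] == 1L & genes[, p[2L]] == 1L)
  n <- nrow(genes)
  xW <- apply(pairsWithin, 1L, countPair)
  xB <- apply(pairsBetween, 1L, countPair)
  if (pooled) {
    ew <- sum(xW); nw <- n * nrow(pairsWithin)
    eb <- sum(xB); nb <- n * nrow(pairsBetween)
  } else {
    # per-pair averaging: rescale mean frequency to an effective n of one
    # pair's worth of species
    ew <- mean(xW); nw <- n
    eb <- mean(xB); nb <- n
  }
  pt <- suppressWarnings(stats::prop.test(c(ew, eb), c(nw, nb),
    correct = correct))
  list(within_freq = ew / nw, between_freq = eb / nb,
    chi2 = unname(pt$statistic), p = pt$p.value,
    within_events = ew, within_total = nw,
    between_events = eb, between_total = nb)
}
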
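#' Observed-minus-expected deviation within an isolation environment
#'
#' Restricts the trait matrix to one environment's member species, builds
#' a fresh fixed-margin swap ensemble on the submatrix (restricting global
#' permutations would not preserve the subset's margins), and for each
#' evaluated trait pair computes the deviation of the observed count from
#' the null mean: the co-occurrence count for positive-direction pairs and
#' the single-presence count for negative-direction ones.  Deviations near
#' zero mean the associations within the environment look just as the
#' margin-conditioned null predicts.
#'
#' @param m binary matrix or imputed binary [TraitMatrix-class].
#' @param env an [EnvironmentMatrix-class] (same species, same order), or
#'   `NULL` when `species` is given directly.
#' @param environmentId environment to evaluate (needs >= `minSpecies`
#'   members).
#' @param pairs data.frame of evaluated pairs with columns `item_a`,
#'   `item_b`, `direction` — typically [significantPairs()] of the global
#'   association table.
#' @param nPerm,nSwaps,swapMode ensemble parameters (defaults 1000, 1000,
#'   `"attempts"`).
#' @param minSpecies eligibility threshold (default 4).
#' @param species optional character vector of species ids, overriding
#'   `env`/`environmentId` (used by the random-draw control so both code
#'   paths are identical apart from species selection).
#' @return data.frame with one row per association direction:
#'   `environment_id`, `direction`, `n_species`, `n_pairs`,
#'   `mean_deviation`, `sd_deviation`.  Pairs whose columns are constant
#'   in the submatrix are skipped (messaged).
#' @export
environmentDeviation <- function(m, env = NULL, environmentId = NULL,
    pairs, nPerm = 1000L, nSwaps = 1000L,
    swapMode = c("attempts", "successful"), minSpecies = 4L,
    species = NULL) {
  mm <- .asBinaryMatrix(m)
  if (is.null(species)) {
    stopifnot(is(env, "EnvironmentMatrix"), !is.null(environmentId))
    ed <- as.matrix(env)
    if (!identical(rownames(mm), rownames(ed)))
      stop("trait and environment matrices must share species order")
    members <- rownames(ed)[ed[, environmentId] == 1L]
    if (length(members) < minSpecies)
      stop("environment '", environmentId, "' has fewer than ", minSpecies,
        " member species")
    label <- environmentId
  } else {
    members <- species
    label <- sprintf("random:%d", length(species))
  }
  sub <- mm[members, , drop = FALSE]
  usable <- vapply(seq_len(nrow(pairs)), function(k) {
    a <- sub[, pairs$item_a[k]]
    b <- sub[, pairs$item_b[k]]
    length(unique(a)) > 1L && length(unique(b)) > 1L
  }, logical(1L))
  if (any(!usable))
    message(sum(!usable), " pair(s) with a constant column skipped in '",
      label, "'")
  pairs <- pairs[usable, , drop = FALSE]
  if (!nrow(pairs))
    return(data.frame(environment_id = label,
      direction = c("positive", "negative"),
      n_species = length(members), n_pairs = 0L,
      mean_deviation = NA_real_, sd_deviation = NA_real_))
  ens <- buildEnsemble(sub,
    pairs = data.frame(item_a = pairs$item_a, item_b = pairs$item_b,
      b_fixed = FALSE),
    nPerm = nPerm, nSwaps = nSwaps, swapMode = match.arg(swapMode))
  devPos <- ens@posObs - ens@posMean
  devNeg <- ens@negObs - ens@negMean
  dev <- ifelse(pairs$direction == "negative", devNeg, devPos)
  out <- lapply(c("positive", "negative"), function(dir) {
    v <- dev[pairs$direction == dir]
    data.frame(environment_id = label, direction = dir,
      n_species = length(members), n_pairs = length(v),
      mean_deviation = if (length(v)) mean(v) else NA_real_,
      sd_deviation = if (length(v) > 1L) stats::sd(v) else NA_real_)
  })
  do.call(rbind, out)
}

#' Random-draw control for environment deviations
#'
#' Removes the effect of the environment by drawing species at random
#' (ignoring their isolation records) at each sample size of the control
#' grid and running the identical deviation computation on every draw.
#'
#' @param m binary matrix or imputed binary [TraitMatrix-class].
#' @param pairs evaluated pairs, as in [environmentDeviation()].
#' @param sizes sample sizes (default the control grid 4, 11, 26, 47, 76,
#'   147, 217).
#' @param reps random draws per size (default 1000).
#' @param nPerm,nSwaps,swapMode per-draw ensemble parameters.
#' @return data.frame with one row per size and direction: mean deviation
#'   averaged over draws and its sampling sd across draws.
#' @export
randomSamplingControl <- function(m, pairs,
    sizes = c(4L, 11L, 26L, 47L, 76L, 147L, 217L), reps = 1000L,
    nPerm = 1000L, nSwaps = 1000L,
    swapMode = c("attempts", "successful")) {
  mm <- .asBinaryMatrix(m)
  swapMode <- match.arg(swapMode)
  stopifnot(all(sizes <= nrow(mm)))
  res <- list()
  for (n in sizes) {
    draws <- lapply(seq_len(reps), function(r) {
      sp <- sample(rownames(mm), n)
      suppressMessages(environmentDeviation(mm, pairs = pairs,
        species = sp, nPerm = nPerm, nSwaps = nSwaps, swapMode = swapMode))
    })
    tab <- do.call(rbind, draws)
    for (dir in c("positive", "negative")) {
      v <- tab$mean_deviation[tab$direction == dir]
      v <- v[!is.na(v)]
      res[[length(res) + 1L]] <- data.frame(
        environment_id = sprintf("random:%d", n), direction = dir,
        n_species = n, reps = length(v),
        mean_deviation = mean(v), sd_deviation = stats::sd(v))
    }
  }
  do.call(rbind, res)
}
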
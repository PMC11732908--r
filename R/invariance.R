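#' Permutation test of item-parameter invariance
#'
#' Estimates the noise ceiling of cross-sample difficulty correlations: how
#' high could the correlation between two groups' item calibrations be if
#' group membership carried no information, given the groups' sizes? Each
#' iteration reassigns every person to a pseudo-group multinomially with
#' probabilities proportional to `size_ratio` (so sample sizes vary across
#' iterations), calibrates each pseudo-group with [fit_1pl()], and correlates
#' each pseudo-group's difficulties against the reference pseudo-group's.
#' The mean, SD and percentile 95\% interval over iterations summarise the
#' ceiling; an observed between-group correlation below the interval for the
#' matching group size indicates real parameter non-invariance rather than
#' sampling noise.
#'
#' @param x A [response_matrix()]. When it carries group labels, observed
#'   between-group correlations (first label level as reference) are computed
#'   alongside the permutation distribution.
#' @param size_ratio Positive counts (or proportions) per pseudo-group; the
#'   first entry is the reference group.
#' @param n_iter Number of permutation iterations (default 50).
#' @param seed Optional RNG seed.
#' @param subset Item subset passed to [difficulty_correlation()].
#' @param categories Optional item categories for subsets.
#' @param min_group Iterations leaving any pseudo-group below this size are
#'   resampled (logged); after 10 consecutive failures an error is raised.
#' @param ... Additional arguments passed to [fit_1pl()].
#' @return An object of class `"invariance_result"`: `observed_r` (named per
#'   group pair, or `NULL`), `permuted` (iteration x pair matrix),
#'   `permuted_mean`, `permuted_sd`, `ci95` (percentile, per pair), `n_iter`,
#'   `n_resampled`.
#' @export
permutation_invariance <- function(x, size_ratio, n_iter = 50L, seed = NULL,
                                   subset = "all", categories = NULL,
                                   min_group = 10L, ...) {
  rm <- as_response_matrix(x)
  if (n_iter < 1L) stop("n_iter must be at least 1", call. = FALSE)
  if (any(size_ratio <= 0)) stop("size_ratio entries must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  G <- length(size_ratio)
  prob <- size_ratio / sum(size_ratio)
  N <- nrow(rm$resp)
  pair_names <- paste0("g1_vs_g", seq_len(G)[-1])

  fit_group <- function(rows) {
    em_fit_1pl(rm$resp[rows, , drop = FALSE], ...)
  }
  cor_pairs <- function(fits) {
    vapply(seq_len(G)[-1], function(g)
      difficulty_correlation(structure(fits[[1]], class = "irt1pl"),
                             structure(fits[[g]], class = "irt1pl"),
                             subset = subset, categories = categories),
      numeric(1))
  }

  perm <- matrix(NA_real_, n_iter, G - 1L, dimnames = list(NULL, pair_names))
  n_resampled <- 0L
  for (it in seq_len(n_iter)) {
    fails <- 0L
    repeat {
      assign <- sample.int(G, N, replace = TRUE, prob = prob)
      if (min(tabulate(assign, G)) >= min_group) break
      fails <- fails + 1L; n_resampled <- n_resampled + 1L
      message("iteration ", it, ": a pseudo-group fell below ", min_group,
              " persons; resampling")
      if (fails >= 10L)
        stop("permutation assignment failed 10 times; size_ratio too extreme ",
             "for this cohort", call. = FALSE)
    }
    fits <- lapply(seq_len(G), function(g) fit_group(assign == g))
    perm[it, ] <- cor_pairs(fits)
  }

  observed <- NULL
  if (!is.null(rm$group) && length(unique(rm$group)) >= 2L) {
    lev <- unique(rm$group)
    fits <- lapply(lev, function(g) fit_group(rm$group == g))
    obs <- vapply(seq_along(lev)[-1], function(g)
      difficulty_correlation(structure(fits[[1]], class = "irt1pl"),
                             structure(fits[[g]], class = "irt1pl"),
                             subset = subset, categories = categories),
      numeric(1))
    observed <- stats::setNames(obs, paste0(lev[1], "_vs_", lev[-1]))
  }

  ci <- apply(perm, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  psd <- if (n_iter == 1L) stats::setNames(rep(0, G - 1L), pair_names)
         else apply(perm, 2L, stats::sd)
  structure(list(observed_r = observed, permuted = perm,
                 permuted_mean = colMeans(perm),
                 permuted_sd = psd,
                 ci95 = ci, n_iter = n_iter, size_ratio = size_ratio,
                 n_resampled = n_resampled, subset = subset),
            class = "invariance_result")
}

#' @export
print.invariance_result <- function(x, ...) {
  cat(sprintf("Parameter-invariance permutation test (%d iteration(s), ratio %s)\n",
              x$n_iter, paste(x$size_ratio, collapse = ":")))
  for (j in seq_along(x$permuted_mean)) {
    cat(sprintf("  %s: permuted mean r = %.3f (SD %.3f), 95%% CI [%.3f, %.3f]\n",
                names(x$permuted_mean)[j], x$permuted_mean[j], x$permuted_sd[j],
                x$ci95[1, j], x$ci95[2, j]))
  }
  if (!is.null(x$observed_r)) {
    cat("  observed between-group correlations:\n")
    for (j in seq_along(x$observed_r))
      cat(sprintf("    %s: r = %.3f\n", names(x$observed_r)[j], x$observed_r[j]))
  }
  invisible(x)
}
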
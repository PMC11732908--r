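#' Generate a synthetic item bank
#'
#' Seeded generator emulating the structure of a lexical decision item bank:
#' an exact real/pseudoword split, pronounceable placeholder CVC stimuli, and
#' difficulties drawn from a normal distribution truncated to \[-6, 6\]. The
#' default normal(-1, 1.5^2) reproduces a pool that consists primarily of
#' easier items relative to a mean-zero cohort (appropriate for a screener)
#' while still covering the screening range.
#'
#' @param n_items Total items.
#' @param n_real,n_pseudo Category split; must sum to `n_items`.
#' @param difficulty_mean,difficulty_sd Normal difficulty distribution.
#' @param clip Truncation range for difficulties.
#' @param calibrated Calibrated flag applied to all items.
#' @param seed RNG seed; the bank is a pure function of seed and spec.
#' @return An [item_bank()].
#' @export
gen_bank <- function(n_items = 246L, n_real = 123L, n_pseudo = 123L,
                     difficulty_mean = -1, difficulty_sd = 1.5,
                     clip = c(-6, 6), calibrated = TRUE, seed = 1L) {
  if (n_real + n_pseudo != n_items)
    stop("category counts must sum to n_items", call. = FALSE)
  set.seed(seed)
  d <- stats::rnorm(n_items, difficulty_mean, difficulty_sd)
  while (any(bad <- d < clip[1] | d > clip[2]))
    d[bad] <- stats::rnorm(sum(bad), difficulty_mean, difficulty_sd)
  category <- c(rep("real", n_real), rep("pseudo", n_pseudo))
  item_bank(item_id = sprintf("itm%04d", seq_len(n_items)),
            stimulus = cvc_stimuli(n_items, category),
            category = category, difficulty = d, calibrated = calibrated,
            provenance = sprintf("synthetic bank (seed %d)", seed))
}

# Placeholder pronounceable consonant-vowel-consonant strings; pseudo items
# get a doubled final consonant so the two pools are visually distinct.
cvc_stimuli <- function(n, category) {
  cons <- c("b", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r", "s", "t", "v", "w", "z")
  vow <- c("a", "e", "i", "o", "u")
  s <- paste0(sample(cons, n, TRUE), sample(vow, n, TRUE),
              sample(cons, n, TRUE), sample(vow, n, TRUE), sample(cons, n, TRUE))
  ifelse(category == "pseudo", paste0(s, substr(s, 5, 5)), s)
}

#' Generate a multi-group synthetic cohort with responses and RTs
#'
#' Draws each group's abilities from its normal distribution, generates
#' responses to the whole bank under the fixed-guessing 1PL, and attaches
#' lognormal response times (milliseconds) with optional rapid-guesser
#' contamination: a random fraction of persons whose log-RTs centre on a
#' much faster mean, emulating non-compliant responding. True thetas are
#' returned alongside for parameter-recovery tests.
#'
#' @param bank An [item_bank()].
#' @param groups Data frame with columns `label`, `n`, `theta_mean`,
#'   `theta_sd` (one row per group).
#' @param rt List with `log_mean`, `log_sd` (log-ms scale),
#'   `rapid_frac` in \[0, 1\] and `rapid_log_mean`; `NULL` for no RTs.
#' @param shift Optional non-invariance injection: a list
#'   `(label, frac, delta)` making the named group respond to a random
#'   `frac` of items as if their difficulty were `delta` logits higher
#'   (used to probe the sensitivity of the permutation invariance test).
#' @param seed RNG seed.
#' @return List with `responses` (a [response_matrix()] carrying group labels
#'   and RTs), `theta` (named true abilities), `rapid` (named logical:
#'   contaminated persons) and `shifted_items` (ids affected by `shift`).
#' @export
gen_cohort <- function(bank, groups, rt = list(log_mean = 6.7, log_sd = 0.3,
                                               rapid_frac = 0,
                                               rapid_log_mean = 5.0),
                       shift = NULL, seed = 1L) {
  stopifnot(all(c("label", "n", "theta_mean", "theta_sd") %in% names(groups)))
  if (any(groups$n < 1L) || any(groups$theta_sd <= 0))
    stop("each group needs n >= 1 and theta_sd > 0", call. = FALSE)
  set.seed(seed)
  N <- sum(groups$n)
  glab <- rep(groups$label, groups$n)
  theta <- stats::rnorm(N, rep(groups$theta_mean, groups$n),
                        rep(groups$theta_sd, groups$n))
  names(theta) <- sprintf("p%04d", seq_len(N))
  P <- outer(theta, bank$difficulty, prob_correct)
  shifted_items <- character()
  if (!is.null(shift)) {
    ix <- sample.int(nrow(bank), round(shift$frac * nrow(bank)))
    shifted_items <- bank$item_id[ix]
    rows <- glab == shift$label
    P[rows, ix] <- outer(theta[rows], bank$difficulty[ix] + shift$delta,
                         prob_correct)
  }
  resp <- (matrix(stats::runif(length(P)), nrow(P)) < P) + 0
  dimnames(resp) <- list(names(theta), bank$item_id)
  rtm <- NULL; rapid <- stats::setNames(rep(FALSE, N), names(theta))
  if (!is.null(rt)) {
    rapid[] <- stats::runif(N) < rt$rapid_frac
    mu <- ifelse(rapid, rt$rapid_log_mean, rt$log_mean)
    rtm <- exp(matrix(stats::rnorm(length(P), mean = rep(mu, ncol(P)),
                                   sd = rt$log_sd), nrow(P)))
    dimnames(rtm) <- dimnames(resp)
  }
  list(responses = response_matrix(resp, group = glab, rt = rtm),
       theta = theta, rapid = rapid, shifted_items = shifted_items)
}

#' Packaged efficiency-comparison scenario
#'
#' A ready-made Monte Carlo scenario matching the validation-study setting:
#' a 246-item bank (123 real / 123 pseudo, mostly-easy difficulty spread),
#' 472 simulated persons with abilities drawn from the pooled cohort moments
#' (mean -0.9, SD 1.55 — a weighted blend of the two arm-level moments
#' M = -0.73/SD = 1.48 and M = -1.07/SD = 1.61), full-length administration
#' with MFI selection, counterbalancing and theta bounds (-4, 4), averaged
#' over 5 iterations.
#'
#' @param seed Master seed for the scenario (bank, thetas and all session
#'   RNG derive from it).
#' @param n_persons Cohort size (default 472).
#' @param n_iter Iterations (default 5).
#' @param theta_mean,theta_sd Pooled cohort moments.
#' @return A [sim_scenario()].
#' @export
gen_study2_scenario <- function(seed = 1L, n_persons = 472L, n_iter = 5L,
                                theta_mean = -0.9, theta_sd = 1.55) {
  bank <- gen_bank(seed = derive_seed(seed, 1L))
  set.seed(derive_seed(seed, 2L))
  thetas <- stats::rnorm(n_persons, theta_mean, theta_sd)
  config <- cat_config(selector = "mfi", bounds = theta_bounds(-4, 4),
                       counterbalance = TRUE, test_length = nrow(bank),
                       initial_theta = 0)
  sim_scenario(bank, thetas, config, n_iter = n_iter, master_seed = seed)
}
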
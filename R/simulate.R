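#' Simulate full-bank responses for one person
#'
#' Independent Bernoulli draws per item with success probability
#' [prob_correct()] at the person's ability: the generating model of the
#' Monte Carlo harness. Accuracy never falls below the 0.5 guessing floor in
#' expectation, whatever the ability.
#'
#' @param theta Ability in logits (scalar).
#' @param bank An [item_bank()]; all items must be calibrated.
#' @return Integer 0/1 vector, one response per bank row.
#' @export
simulate_responses <- function(theta, bank) {
  if (!all(bank$calibrated))
    stop("bank must be fully calibrated for response simulation", call. = FALSE)
  p <- prob_correct(theta, bank$difficulty)
  as.integer(stats::runif(nrow(bank)) < p)
}

#' Randomly assign persons to the adaptive and random-order arms
#'
#' Independent fair coin per person. Degenerate draws leaving an arm empty
#' are redrawn (logged via `message()`), so both arms are always non-empty.
#'
#' @param n_persons Number of persons (>= 2).
#' @return Character vector of `"cat"` / `"random"` labels.
#' @export
assign_arms <- function(n_persons) {
  if (n_persons < 2L) stop("at least 2 persons are required", call. = FALSE)
  repeat {
    arms <- ifelse(stats::runif(n_persons) < 0.5, "cat", "random")
    if (length(unique(arms)) == 2L) return(arms)
    message("degenerate arm assignment (one arm empty); redrawing")
  }
}

#' Bundle a Monte Carlo scenario
#'
#' @param bank An [item_bank()].
#' @param theta_sample Ability values of the simulated cohort.
#' @param config A [cat_config()] used by the adaptive arm; the random arm
#'   uses the same scaffolding with `selector = "random"`.
#' @param n_iter Iterations to average over (default 5).
#' @param master_seed Master seed; per-iteration and per-person sub-seeds
#'   are derived from it (see [derive_seed()]).
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(bank, theta_sample, config, n_iter = 5L,
                         master_seed = 1L) {
  if (length(theta_sample) < 2L)
    stop("theta_sample must contain at least 2 persons", call. = FALSE)
  if (n_iter < 1L) stop("n_iter must be at least 1", call. = FALSE)
  structure(list(bank = bank, theta_sample = as.numeric(theta_sample),
                 config = config, n_iter = as.integer(n_iter),
                 master_seed = as.integer(master_seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Monte Carlo scenario: %d persons, %d-item bank, %d iteration(s), master seed %d\n",
              length(x$theta_sample), nrow(x$bank), x$n_iter, x$master_seed))
  invisible(x)
}

#' Derive a reproducible sub-seed
#'
#' Splitting scheme for nested simulation seeds: sub-seeds are a fixed
#' integer hash of the master seed and the index path (iteration, person),
#' kept within the 31-bit range R accepts. Deterministic, so any iteration
#' or person can be re-run in isolation.
#'
#' @param master Master seed (integer).
#' @param ... Integer indices (e.g. iteration, person).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  h <- as.double(master) %% 2147483647
  for (ix in c(...)) h <- (h * 48271 + as.double(ix)) %% 2147483647
  as.integer(h)
}

#' Run the Monte Carlo comparison of adaptive versus random ordering
#'
#' For each iteration: full-bank response patterns are generated for every
#' person from their theta under the model, persons are randomly split into
#' the adaptive ("cat") and random-order ("random") arms, each person's
#' responses are replayed under their arm's ordering policy, and the
#' per-test-length metric curves are computed against the generating thetas.
#' Arm assignment is redrawn each iteration. The reported curves are the
#' across-iteration means; per-iteration curves are retained.
#'
#' @param scenario A [sim_scenario()].
#' @return Object of class `"mc_result"`: `$mean` (named list of
#'   `"metric_curve"`s per arm), `$per_iteration` (list of the same per
#'   iteration), `$scenario`.
#' @export
run_monte_carlo <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  bank <- scenario$bank
  thetas <- scenario$theta_sample
  n <- length(thetas)
  per_iter <- vector("list", scenario$n_iter)
  for (it in seq_len(scenario$n_iter)) {
    set.seed(derive_seed(scenario$master_seed, it))
    resp <- vapply(thetas, simulate_responses, integer(nrow(bank)), bank = bank)
    arms <- assign_arms(n)
    sessions <- vector("list", n)
    for (j in seq_len(n)) {
      cfg <- scenario$config
      cfg$selector <- if (arms[j] == "cat") scenario$config$selector else "random"
      cfg$seed <- derive_seed(scenario$master_seed, it, j)
      sessions[[j]] <- run_session(bank, cfg, resp[, j])
    }
    per_iter[[it]] <- lapply(c(cat = "cat", random = "random"), function(a) {
      ix <- which(arms == a)
      curves_by_length(sessions[ix], thetas[ix])
    })
  }
  mean_curves <- lapply(c(cat = "cat", random = "random"), function(a) {
    mats <- lapply(per_iter, `[[`, a)
    out <- mats[[1]]
    for (col in c("reliability", "mse", "bias", "mean_sem", "n"))
      out[[col]] <- rowMeans(vapply(mats, `[[`, numeric(nrow(out)), col))
    out
  })
  structure(list(mean = mean_curves, per_iteration = per_iter,
                 scenario = scenario),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo result: %d iteration(s) averaged, arms cat/random\n",
              x$scenario$n_iter))
  for (a in names(x$mean)) {
    cur <- x$mean[[a]]
    t90 <- items_to_threshold(cur, "reliability", 0.9, "above")
    cat(sprintf("  %-6s final reliability %.3f; reaches 0.90 at %s items\n",
                a, cur$reliability[nrow(cur)],
                if (is.na(t90)) "no" else t90))
  }
  invisible(x)
}

#' Post hoc replay of observed full-bank responses under a CAT policy
#'
#' Replays each person's complete observed response row under adaptive (or
#' random) ordering: the "responder" simply returns the person's recorded
#' response to whichever item the policy selects. Because the full-data
#' likelihood does not depend on administration order, the full-length theta
#' estimate equals the full-bank MLE regardless of ordering; intermediate
#' trajectories reveal how quickly each policy approaches it. Persons with
#' incomplete rows are skipped with a warning.
#'
#' @param x A [response_matrix()] covering every bank item.
#' @param bank An [item_bank()].
#' @param config A [cat_config()].
#' @return List of class `"replay_result"`: `$sessions` (per person),
#'   `$truths` (full-bank MLE per replayed person), `$skipped`.
#' @export
posthoc_replay <- function(x, bank, config) {
  rm <- as_response_matrix(x)
  if (!all(bank$item_id %in% colnames(rm$resp)))
    stop("response matrix does not cover every bank item", call. = FALSE)
  resp <- rm$resp[, bank$item_id, drop = FALSE]
  complete <- !apply(resp, 1L, anyNA)
  if (any(!complete))
    warning(sum(!complete), " person(s) with incomplete rows skipped",
            call. = FALSE)
  persons <- rownames(resp)[complete]
  sessions <- vector("list", length(persons)); names(sessions) <- persons
  truths <- numeric(length(persons)); names(truths) <- persons
  for (k in seq_along(persons)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed %||% 0L, k)
    sessions[[k]] <- run_session(bank, cfg, resp[persons[k], ])
    truths[k] <- estimate_mle(resp[persons[k], ], bank$difficulty,
                              config$bounds)$theta
  }
  structure(list(sessions = sessions, truths = truths,
                 skipped = rownames(resp)[!complete]),
            class = "replay_result")
}
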
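#' Configure an adaptive testing session
#'
#' @param selector Item selection rule: `"mfi"` (maximum Fisher information),
#'   `"closest_difficulty"`, or `"random"` (the random-ordering comparison arm
#'   uses the same scaffolding with this selector).
#' @param bounds Theta estimation limits, a [theta_bounds()].
#' @param counterbalance Keep real/pseudoword presentations near 50/50 by
#'   flipping a fair coin for the category before every selection (default
#'   `TRUE`).
#' @param test_length Number of scored trials.
#' @param initial_theta Starting ability estimate (default 0).
#' @param seed Optional integer seed for the session RNG.
#' @param validation_schedule Optional list `(n_scored, every, n_new)`
#'   interleaving unscored, uncalibrated validation items: one new item after
#'   each block of `every` scored items (see [validation_layout()]). When
#'   present it overrides `test_length` with `n_scored`.
#' @param block_sizes Optional presentation block sizes (e.g. `c(33, 33, 34)`
#'   for short breaks). Presentation metadata only: blocks never alter
#'   selection or estimation.
#' @return An object of class `"cat_config"`.
#' @export
cat_config <- function(selector = c("mfi", "closest_difficulty", "random"),
                       bounds = theta_bounds(), counterbalance = TRUE,
                       test_length = NULL, initial_theta = 0, seed = NULL,
                       validation_schedule = NULL, block_sizes = NULL) {
  selector <- match.arg(selector)
  bounds <- as_theta_bounds(bounds)
  if (!is.null(validation_schedule)) {
    vs <- validation_schedule
    stopifnot(all(c("n_scored", "every", "n_new") %in% names(vs)))
    test_length <- vs$n_scored
  }
  if (is.null(test_length) || test_length < 1L)
    stop("test_length must be at least 1", call. = FALSE)
  cfg <- structure(list(selector = selector, bounds = bounds,
                        counterbalance = isTRUE(counterbalance),
                        test_length = as.integer(test_length),
                        initial_theta = initial_theta, seed = seed,
                        validation_schedule = validation_schedule,
                        block_sizes = block_sizes),
                   class = "cat_config")
  sched <- session_schedule(cfg)
  if (!is.null(block_sizes) && sum(block_sizes) != length(sched))
    stop("block_sizes must sum to the total trial count (", length(sched), ")",
         call. = FALSE)
  cfg
}

#' @export
print.cat_config <- function(x, ...) {
  cat(sprintf("CAT config: selector = %s, bounds = (%g, %g), counterbalance = %s\n",
              x$selector, x$bounds$lo, x$bounds$hi, x$counterbalance))
  cat(sprintf("  %d scored trial(s)", x$test_length))
  if (!is.null(x$validation_schedule))
    cat(sprintf(" + %d interleaved validation trial(s)",
                x$validation_schedule$n_new))
  cat("\n")
  invisible(x)
}

selector_code <- function(selector) {
  match(selector, c("mfi", "closest_difficulty", "random")) - 1L
}

session_schedule <- function(config) {
  vs <- config$validation_schedule
  if (is.null(vs)) rep(TRUE, config$test_length)
  else validation_layout(vs$n_scored, vs$every, vs$n_new)
}

#' Interleaving schedule for uncalibrated validation items
#'
#' Builds a trial schedule of length `n_scored + n_new` in which an unscored
#' validation slot follows every block of `every` scored adaptive trials,
#' until `n_new` slots have been placed; any remaining trials are scored.
#' With 84 scored items, a new item after each five, and 16 new items, this
#' yields a 100-trial layout with unscored slots at positions 6, 12, ..., 96.
#'
#' @param n_scored Number of scored adaptive trials.
#' @param every Scored-trial block length preceding each validation slot.
#' @param n_new Number of validation slots; must satisfy
#'   `n_new <= floor(n_scored / every)`.
#' @return Logical vector, `TRUE` for scored slots.
#' @export
validation_layout <- function(n_scored, every, n_new) {
  if (every < 1L || n_scored < 1L || n_new < 0L)
    stop("n_scored and every must be positive; n_new nonnegative", call. = FALSE)
  if (n_new > floor(n_scored / every))
    stop("infeasible schedule: n_new exceeds floor(n_scored / every)", call. = FALSE)
  head <- rep(c(rep(TRUE, every), FALSE), n_new)
  c(head, rep(TRUE, n_scored - every * n_new))
}

#' Draw the category for the next item
#'
#' Fair coin from the current session RNG: "real" or "pseudo" with equal
#' probability. The draw precedes selection on every trial (including the
#' first) when counterbalancing is enabled.
#'
#' @return `"real"` or `"pseudo"`.
#' @export
choose_category <- function() {
  if (stats::runif(1) < 0.5) "real" else "pseudo"
}

#' First item of a session
#'
#' The median-difficulty calibrated item of the requested category pool
#' (lower of the two middle items for even counts, for deterministic starts).
#'
#' @param bank An [item_bank()].
#' @param category `"real"`, `"pseudo"`, or `NULL` for the merged pool.
#' @return One bank row.
#' @export
first_item <- function(bank, category = NULL) {
  pool <- bank[bank$calibrated, , drop = FALSE]
  if (!is.null(category)) pool <- pool[pool$category == category, , drop = FALSE]
  if (nrow(pool) == 0L)
    stop("category pool is exhausted: no calibrated items available", call. = FALSE)
  ord <- order(pool$difficulty)
  pool[ord[(length(ord) - 1L) %/% 2L + 1L], , drop = FALSE]
}

#' Select the next item
#'
#' Stateless selection among unadministered calibrated items of a category
#' pool: `"mfi"` maximises [item_information()] at the current theta
#' estimate, `"closest_difficulty"` minimises `|theta - b|`, `"random"`
#' draws uniformly. Ties are broken uniformly at random from the session RNG
#' to avoid item-order bias in the bank file. If the requested category is
#' exhausted the other category is used.
#'
#' @param bank An [item_bank()].
#' @param theta Current ability estimate.
#' @param selector Selection rule.
#' @param exclude Item ids already administered.
#' @param category Category pool, or `NULL` for the merged pool.
#' @return One bank row.
#' @export
select_next <- function(bank, theta,
                        selector = c("mfi", "closest_difficulty", "random"),
                        exclude = character(), category = NULL) {
  selector <- match.arg(selector)
  pool <- bank[bank$calibrated & !bank$item_id %in% exclude, , drop = FALSE]
  if (nrow(pool) == 0L)
    stop("session complete: no unadministered calibrated items remain", call. = FALSE)
  if (!is.null(category)) {
    sub <- pool[pool$category == category, , drop = FALSE]
    if (nrow(sub) > 0L) pool <- sub  # silent fallback on exhausted category
  }
  crit <- switch(selector,
    mfi = item_information(theta, pool$difficulty),
    closest_difficulty = -abs(theta - pool$difficulty),
    random = NULL)
  if (is.null(crit)) {
    idx <- floor(stats::runif(1) * nrow(pool)) + 1L
    return(pool[min(idx, nrow(pool)), , drop = FALSE])
  }
  ties <- which(crit > max(crit) - 1e-12)
  idx <- if (length(ties) == 1L) ties
         else ties[min(floor(stats::runif(1) * length(ties)) + 1L, length(ties))]
  pool[idx, , drop = FALSE]
}

#' Begin / step a session by hand
#'
#' A functional state machine for trial-by-trial administration:
#' [cat_begin()] initialises the state, [cat_next()] selects the next item
#' (advancing the session RNG exactly as [run_session()] does), and
#' [cat_update()] records the response and refits theta by MLE over the
#' scored responses so far. Unscored validation trials leave theta and SEM
#' untouched.
#'
#' @param bank An [item_bank()].
#' @param config A [cat_config()].
#' @return `cat_begin` returns a state list; `cat_next` the state with
#'   `$current_item` set; `cat_update` the state with the trial appended to
#'   `$trials`.
#' @export
cat_begin <- function(bank, config) {
  validate_bank(bank)
  sched <- session_schedule(config)
  check_bank_capacity(bank, sched)
  if (!is.null(config$seed)) set.seed(config$seed)
  list(bank = bank, config = config, schedule = sched, trial = 1L,
       administered = character(), correct = numeric(), b = numeric(),
       theta = config$initial_theta, sem = NA_real_,
       current_item = NULL, trials = list(), first_scored = TRUE)
}

#' @rdname cat_begin
#' @param state A session state.
#' @export
cat_next <- function(state) {
  if (state$trial > length(state$schedule))
    stop("session complete: all trials administered", call. = FALSE)
  bank <- state$bank
  if (state$schedule[state$trial]) {
    category <- NULL
    if (state$config$counterbalance) {
      category <- choose_category()
      avail <- bank$calibrated & !bank$item_id %in% state$administered
      if (!any(avail & bank$category == category)) category <- setdiff(c("real", "pseudo"), category)
    }
    if (state$first_scored) {
      pool <- bank[bank$calibrated & !bank$item_id %in% state$administered, , drop = FALSE]
      if (!is.null(category)) pool <- pool[pool$category == category, , drop = FALSE]
      ord <- order(pool$difficulty)
      item <- pool[ord[(length(ord) - 1L) %/% 2L + 1L], , drop = FALSE]
    } else {
      item <- select_next(bank, state$theta, state$config$selector,
                          exclude = state$administered, category = category)
    }
  } else {
    pool <- bank[!bank$calibrated & !bank$item_id %in% state$administered, , drop = FALSE]
    if (nrow(pool) == 0L)
      stop("no unadministered uncalibrated items remain", call. = FALSE)
    idx <- min(floor(stats::runif(1) * nrow(pool)) + 1L, nrow(pool))
    item <- pool[idx, , drop = FALSE]
  }
  state$current_item <- item
  state
}

#' @rdname cat_begin
#' @param correct Response to the currently selected item, 0 or 1.
#' @export
cat_update <- function(state, correct) {
  item <- state$current_item
  if (is.null(item)) stop("call cat_next() before cat_update()", call. = FALSE)
  if (item$item_id %in% state$administered)
    stop("item ", item$item_id, " was already administered", call. = FALSE)
  correct <- check_binary(correct, "correct")
  scored <- state$schedule[state$trial]
  state$administered <- c(state$administered, item$item_id)
  if (scored) {
    if (!item$calibrated)
      stop("scored trials must use calibrated items", call. = FALSE)
    state$correct <- c(state$correct, correct)
    state$b <- c(state$b, item$difficulty)
    est <- estimate_mle(state$correct, state$b, state$config$bounds)
    state$theta <- est$theta
    state$sem <- est$sem
    state$first_scored <- FALSE
  }
  state$trials[[state$trial]] <- data.frame(
    trial = state$trial, item_id = item$item_id, category = item$category,
    scored = scored, response = as.integer(correct),
    theta_after = state$theta, sem_after = state$sem,
    stringsAsFactors = FALSE)
  state$trial <- state$trial + 1L
  state$current_item <- NULL
  state
}

check_bank_capacity <- function(bank, sched) {
  if (sum(sched) > sum(bank$calibrated))
    stop("bank has too few calibrated items for the scored schedule", call. = FALSE)
  if (sum(!sched) > sum(!bank$calibrated))
    stop("bank has too few uncalibrated items for the validation schedule",
         call. = FALSE)
  invisible(TRUE)
}

#' Run a full adaptive session
#'
#' Executes the session loop: a fair category coin (when counterbalancing),
#' the median-difficulty first item, then configured selection and an MLE
#' theta update after every scored trial, for the whole schedule. Unscored
#' validation trials draw uniformly from the uncalibrated pool and never
#' touch the ability estimate.
#'
#' @param bank An [item_bank()].
#' @param config A [cat_config()]. If `config$seed` is set the session RNG is
#'   seeded, making the trajectory exactly reproducible.
#' @param responder Either a 0/1 vector over all bank rows (the fixed
#'   response a simulated or replayed person gives to each item) or a
#'   function of one bank row returning 0 or 1.
#' @return An object of class `"cat_session"`: `$trials` (one row per trial
#'   with `trial`, `item_id`, `category`, `scored`, `response`,
#'   `theta_after`, `sem_after`), `$estimate` (final [estimate_mle()] result)
#'   and `$incomplete` (`TRUE` when the responder failed mid-session and the
#'   log is partial).
#' @export
run_session <- function(bank, config, responder) {
  validate_bank(bank)
  sched <- session_schedule(config)
  check_bank_capacity(bank, sched)
  if (!is.null(config$seed)) set.seed(config$seed)

  progress <- new.env(parent = emptyenv())
  progress$item <- integer(); progress$resp <- integer()
  if (is.function(responder)) {
    user_fn <- responder
    cb <- function(ix) {
      r <- user_fn(bank[ix, , drop = FALSE])
      progress$item <- c(progress$item, ix)
      progress$resp <- c(progress$resp, as.integer(r))
      as.integer(r)
    }
    raw <- tryCatch(
      run_cat_cpp(bank$difficulty, as.integer(bank$category == "pseudo"),
                  bank$calibrated, sched, selector_code(config$selector),
                  config$counterbalance, config$bounds$lo, config$bounds$hi,
                  config$initial_theta, cb),
      error = function(e) e)
    if (inherits(raw, "error"))
      return(partial_session(bank, config, sched, progress, conditionMessage(raw)))
  } else {
    if (length(responder) != nrow(bank))
      stop("responder vector must have one entry per bank item", call. = FALSE)
    raw <- run_cat_cpp(bank$difficulty, as.integer(bank$category == "pseudo"),
                       bank$calibrated, sched, selector_code(config$selector),
                       config$counterbalance, config$bounds$lo, config$bounds$hi,
                       config$initial_theta, as.numeric(responder))
  }
  trials <- data.frame(trial = seq_along(raw$item),
                       item_id = bank$item_id[raw$item],
                       category = bank$category[raw$item],
                       scored = sched,
                       response = raw$response,
                       theta_after = raw$theta_after,
                       sem_after = raw$sem_after,
                       stringsAsFactors = FALSE)
  last <- max(which(sched))
  est <- new_ability_estimate(raw$theta_after[last], raw$sem_after[last],
                              "mle", sum(sched))
  structure(list(trials = trials, estimate = est, config = config,
                 n_fallback = raw$n_fallback, incomplete = FALSE),
            class = "cat_session")
}

# Rebuild a partial log after a responder failure; theta trajectory is
# refit per prefix so the partial record is still internally consistent.
partial_session <- function(bank, config, sched, progress, msg) {
  warning("responder failed (", msg, "); returning partial session log",
          call. = FALSE)
  k <- length(progress$resp)
  theta <- rep(config$initial_theta, k); sem <- rep(NA_real_, k)
  xs <- integer(); bs <- numeric()
  for (t in seq_len(k)) {
    if (sched[t]) {
      xs <- c(xs, progress$resp[t]); bs <- c(bs, bank$difficulty[progress$item[t]])
      est <- estimate_mle(xs, bs, config$bounds)
      theta[t] <- est$theta; sem[t] <- est$sem
    } else if (t > 1L) { theta[t] <- theta[t - 1L]; sem[t] <- sem[t - 1L] }
  }
  trials <- data.frame(trial = seq_len(k),
                       item_id = bank$item_id[progress$item],
                       category = bank$category[progress$item],
                       scored = sched[seq_len(k)], response = progress$resp,
                       theta_after = theta, sem_after = sem,
                       stringsAsFactors = FALSE)
  est <- if (length(xs)) new_ability_estimate(theta[k], sem[k], "mle", length(xs))
         else new_ability_estimate(config$initial_theta, NA_real_, "mle", 0L)
  structure(list(trials = trials, estimate = est, config = config,
                 n_fallback = NA_integer_, incomplete = TRUE),
            class = "cat_session")
}

#' @export
print.cat_session <- function(x, ...) {
  cat(sprintf("CAT session: %d trial(s), %d scored%s\n", nrow(x$trials),
              sum(x$trials$scored),
              if (isTRUE(x$incomplete)) " [INCOMPLETE]" else ""))
  print(x$estimate)
  invisible(x)
}

#' @export
plot.cat_session <- function(x, ...) {
  tr <- x$trials[x$trials$scored, ]
  n <- seq_len(nrow(tr))
  graphics::plot(n, tr$theta_after, type = "l", xlab = "scored items",
                 ylab = expression(hat(theta)), ...)
  ok <- is.finite(tr$sem_after)
  graphics::lines(n[ok], (tr$theta_after + tr$sem_after)[ok], lty = 2)
  graphics::lines(n[ok], (tr$theta_after - tr$sem_after)[ok], lty = 2)
  invisible(x)
}
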
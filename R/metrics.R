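#' Empirical reliability of a cohort of ability estimates
#'
#' \eqn{R_{emp} = \mathrm{Var}(\hat\theta) / (\mathrm{Var}(\hat\theta) +
#' \overline{SEM^2})}: the share of observed score variance attributable to
#' true ability differences rather than measurement error. The variance is
#' the population (1/N) form around the cohort mean, and the error term is
#' the mean of the per-person squared SEMs.
#'
#' @param theta_hats Ability estimates, length >= 2.
#' @param sems Per-person SEMs, same length.
#' @return Reliability in \[0, 1).
#' @export
empirical_reliability <- function(theta_hats, sems) {
  n <- length(theta_hats)
  if (n < 2L || length(sems) != n)
    stop("theta_hats and sems must have equal length >= 2", call. = FALSE)
  v <- mean((theta_hats - mean(theta_hats))^2)
  v / (v + mean(sems^2))
}

#' Mean squared error and bias of ability estimates
#'
#' `MSE = mean((theta_hat - theta)^2)` and `bias = mean(theta_hat - theta)`
#' against ground-truth abilities (the generating theta in Monte Carlo mode,
#' or the full-bank estimate in post hoc replay). `MSE >= bias^2` always
#' (variance decomposition).
#'
#' @param theta_hats Ability estimates.
#' @param truths Ground-truth abilities, same length.
#' @return Named numeric vector `c(mse = , bias = )`.
#' @export
mse_and_bias <- function(theta_hats, truths) {
  if (length(theta_hats) != length(truths) || length(truths) < 1L)
    stop("theta_hats and truths must have equal length >= 1", call. = FALSE)
  d <- theta_hats - truths
  c(mse = mean(d^2), bias = mean(d))
}

#' Per-test-length metric curves over a cohort of sessions
#'
#' At each scored-trial count t, gathers every person's theta and SEM after
#' their t-th scored trial and computes empirical reliability, MSE, bias and
#' mean SEM, producing the curve that compares measurement quality as a
#' function of test length. With a single person the reliability column is
#' `NA` (undefined); MSE and bias are still computed.
#'
#' @param sessions List of `"cat_session"` objects sharing the same number of
#'   scored trials.
#' @param truths Named vector of ground-truth thetas covering all persons
#'   (names matching `names(sessions)`), or an unnamed vector in session
#'   order.
#' @return A data frame of class `"metric_curve"`: `length`, `reliability`,
#'   `mse`, `bias`, `mean_sem`, `n`.
#' @export
curves_by_length <- function(sessions, truths) {
  stopifnot(length(sessions) >= 1L)
  if (!is.null(names(sessions)) && !is.null(names(truths))) {
    missing <- setdiff(names(sessions), names(truths))
    if (length(missing))
      stop("truths missing for person(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    truths <- truths[names(sessions)]
  } else if (length(truths) != length(sessions)) {
    stop("truths must cover every session", call. = FALSE)
  }
  traj <- lapply(sessions, function(s) s$trials[s$trials$scored, , drop = FALSE])
  lens <- vapply(traj, nrow, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all sessions must share the same scored length", call. = FALSE)
  Tmax <- lens[[1]]
  Theta <- vapply(traj, function(d) d$theta_after, numeric(Tmax))
  Sem <- vapply(traj, function(d) d$sem_after, numeric(Tmax))
  if (Tmax == 1L) { Theta <- matrix(Theta, 1L); Sem <- matrix(Sem, 1L) }
  n <- length(sessions)
  out <- data.frame(length = seq_len(Tmax),
                    reliability = NA_real_, mse = NA_real_, bias = NA_real_,
                    mean_sem = NA_real_, n = n)
  for (t in seq_len(Tmax)) {
    if (n >= 2L) out$reliability[t] <- empirical_reliability(Theta[t, ], Sem[t, ])
    mb <- mse_and_bias(Theta[t, ], truths)
    out$mse[t] <- mb[["mse"]]; out$bias[t] <- mb[["bias"]]
    out$mean_sem[t] <- mean(Sem[t, ])
  }
  structure(out, class = c("metric_curve", "data.frame"))
}

#' Quintile bins of ground-truth ability
#'
#' Partitions persons into Q1 (lowest) ... Q5 (highest) at the 20/40/60/80th
#' percentiles of their ground-truth theta. Persons exactly at a cutoff go to
#' the lower bin (deterministic, matching half-open interval reporting).
#'
#' @param truths Theta values for at least 5 persons.
#' @return List with `cutoffs` (the four interior percentiles) and `bin`
#'   (factor Q1..Q5 per person).
#' @export
quintile_bins <- function(truths) {
  if (length(truths) < 5L) stop("at least 5 persons are required", call. = FALSE)
  cutoffs <- stats::quantile(truths, probs = c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  bin <- cut(truths, breaks = c(-Inf, cutoffs, Inf),
             labels = paste0("Q", 1:5), right = TRUE)
  list(cutoffs = cutoffs, bin = bin)
}

#' Flag rapid-guessing participants from block-level response times
#'
#' For each presentation block, computes the cohort mean and SD of per-person
#' median log RTs and flags any person whose median in any block falls more
#' than `k` standard deviations below that block's mean (strict inequality,
#' so a degenerate cohort with SD 0 flags nobody). Persons with a missing
#' block median are reported as unevaluable, distinct from flagged.
#'
#' @param block_medians Numeric matrix of per-person (rows), per-block
#'   (columns) median log RTs.
#' @param k SD multiplier (default 3).
#' @return Data frame `person`, `flagged`, `unevaluable`.
#' @export
flag_rapid_guessers <- function(block_medians, k = 3) {
  m <- as.matrix(block_medians)
  if (is.null(rownames(m))) rownames(m) <- paste0("p", seq_len(nrow(m)))
  complete <- stats::complete.cases(m)
  if (sum(complete) < 3L)
    stop("at least 3 persons with complete block data are required", call. = FALSE)
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- apply(m, 2L, stats::sd, na.rm = TRUE)
  thr <- mu - k * sdv
  below <- sweep(m, 2L, thr, "<")
  flagged <- apply(below, 1L, function(r) any(r, na.rm = TRUE))
  data.frame(person = rownames(m), flagged = unname(flagged),
             unevaluable = !complete, stringsAsFactors = FALSE)
}

#' Percentage-bend robust correlation with bootstrap CI
#'
#' Robust alternative to Pearson's r that downweights marginal outliers via
#' the percentage-bend estimator (bend constant `beta = 0.2`), with a
#' seeded percentile-bootstrap 95\% confidence interval.
#'
#' @param x,y Numeric vectors, equal length >= 10, no missing values.
#' @param beta Bend constant in (0, 0.5).
#' @param n_boot Bootstrap resamples for the percentile CI (default 2000).
#' @return List with `r`, `ci95` (length-2 vector) and `n`.
#' @export
robust_correlation <- function(x, y, beta = 0.2, n_boot = 2000L) {
  n <- length(x)
  if (n < 10L || length(y) != n)
    stop("x and y must have equal length >= 10", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  r <- pbcor(x, y, beta)
  boots <- vapply(seq_len(n_boot), function(i) {
    ix <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[ix]) == 0 || stats::sd(y[ix]) == 0) return(NA_real_)
    pbcor(x[ix], y[ix], beta)
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(r = r, ci95 = ci, n = n)
}

# Percentage-bend correlation (Wilcox-style): winsorise standardised
# deviations from the percentage-bend location at +/- 1 and correlate.
pbcor <- function(x, y, beta = 0.2) {
  a <- pb_scores(x, beta)
  b <- pb_scores(y, beta)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

pb_scores <- function(x, beta) {
  n <- length(x)
  w <- sort(abs(x - stats::median(x)))
  omega <- w[max(1L, floor((1 - beta) * n + 0.5))]
  if (omega == 0) omega <- .Machine$double.eps
  psi <- (x - pb_location(x, omega)) / omega
  pmax(-1, pmin(1, psi))
}

pb_location <- function(x, omega) {
  psi <- (x - stats::median(x)) / omega
  i1 <- sum(psi < -1); i2 <- sum(psi > 1)
  sx <- ifelse(psi < -1, 0, ifelse(psi > 1, 0, x))
  (sum(sx) + omega * (i2 - i1)) / (length(x) - i1 - i2)
}

#' First test length at which a metric crosses a threshold
#'
#' Scans a metric curve for the smallest test length whose metric value
#' first crosses `threshold` in the stated direction (no smoothing:
#' first-crossing semantics).
#'
#' @param curve A `"metric_curve"` data frame from [curves_by_length()].
#' @param metric One of `"reliability"`, `"mse"`, `"bias"`, `"mean_sem"`.
#' @param threshold Crossing level.
#' @param direction `"above"` (metric >= threshold) or `"below"`
#'   (metric <= threshold).
#' @return The test length (integer), or `NA` if the threshold is never
#'   reached.
#' @export
items_to_threshold <- function(curve, metric, threshold,
                               direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (!metric %in% c("reliability", "mse", "bias", "mean_sem"))
    stop("unknown metric: ", metric, call. = FALSE)
  v <- curve[[metric]]
  hit <- if (direction == "above") v >= threshold else v <= threshold
  ix <- which(hit)[1]
  if (is.na(ix)) NA_integer_ else curve$length[ix]
}

#' @export
plot.metric_curve <- function(x, metric = "reliability", ...) {
  graphics::plot(x$length, x[[metric]], type = "l", xlab = "test length (items)",
                 ylab = metric, ...)
  invisible(x)
}
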
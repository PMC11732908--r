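#' Calibrate item difficulties under the fixed-guessing 1PL
#'
#' Fits the one-parameter logistic model with discrimination fixed at 1 and
#' lower asymptote fixed at 0.5 to a person-by-item 0/1 matrix by marginal
#' maximum likelihood (EM), integrating ability over a standard-normal prior
#' on 61 equally spaced quadrature nodes spanning \[-6, 6\]. The prior mean
#' of 0 identifies the scale: the mean ability of the calibration sample is
#' 0 by assumption, so a lower-ability sample yields relatively higher
#' difficulty values for the same items. Difficulties are clamped to
#' \[-6, 6\]; items driven to a bound (including items answered all-correct
#' or with at-or-below-chance accuracy, whose likelihood is monotone in `b`)
#' are flagged divergent.
#'
#' @param x A [response_matrix()] or plain 0/1 matrix (persons x items,
#'   `NA` allowed and ignored).
#' @param group Optional label describing the sample, carried through to
#'   results.
#' @param categories Optional named character vector mapping item ids to
#'   `"real"`/`"pseudo"`; enables category subsets in
#'   [difficulty_correlation()].
#' @param n_nodes,node_range Quadrature grid (61 nodes on \[-6, 6\]).
#' @param prior_mean,prior_sd Normal ability prior.
#' @param tol Convergence: stop when `max(abs(diff(b)))` falls below `tol`.
#' @param max_cycles EM cycle cap.
#' @param keep_data Store the response matrix in the fit (needed by
#'   [residuals.irt1pl()]).
#' @return An object of class `"irt1pl"` with methods `print`, `summary`,
#'   `coef` (named difficulty vector), `logLik`, `predict`, `plot`,
#'   `simulate` and `residuals`. Fields include `difficulty`, `se`
#'   (quadrature approximation to the observed-information standard error),
#'   `flag` (divergent items), `loglik`, `converged`, `n_cycles`.
#' @examples
#' bank <- gen_bank(n_items = 20, n_real = 10, n_pseudo = 10, seed = 1)
#' cohort <- gen_cohort(bank, groups = data.frame(label = "g", n = 80,
#'                      theta_mean = 0, theta_sd = 1), seed = 2)
#' fit <- fit_1pl(cohort$responses)
#' head(coef(fit))
#' @export
fit_1pl <- function(x, group = NULL, categories = NULL,
                    n_nodes = 61L, node_range = c(-6, 6),
                    prior_mean = 0, prior_sd = 1,
                    tol = 1e-4, max_cycles = 500L, keep_data = TRUE) {
  rm <- as_response_matrix(x)
  fit <- em_fit_1pl(rm$resp, n_nodes, node_range, prior_mean, prior_sd,
                    tol, max_cycles)
  structure(c(fit, list(group = group, categories = categories,
                        prior = c(mean = prior_mean, sd = prior_sd),
                        node_range = node_range, n_nodes = n_nodes,
                        n_persons = nrow(rm$resp), n_items = ncol(rm$resp),
                        data = if (keep_data) rm else NULL,
                        call = match.call())),
            class = "irt1pl")
}

# EM engine; X is an N x I matrix of 0/1/NA.
em_fit_1pl <- function(X, n_nodes = 61L, node_range = c(-6, 6),
                       prior_mean = 0, prior_sd = 1,
                       tol = 1e-4, max_cycles = 500L) {
  X <- as.matrix(X)
  M <- !is.na(X); storage.mode(M) <- "double"
  Xz <- X; Xz[is.na(Xz)] <- 0; storage.mode(Xz) <- "double"
  nobs <- colSums(M)
  if (any(nobs == 0))
    stop("item(s) with no observed responses: ",
         paste(colnames(X)[nobs == 0], collapse = ", "), call. = FALSE)
  q <- seq(node_range[1], node_range[2], length.out = n_nodes)
  wq <- stats::dnorm(q, prior_mean, prior_sd); wq <- wq / sum(wq)
  lo <- node_range[1]; hi <- node_range[2]

  # moment start from above-chance accuracy
  p <- pmin(pmax((colSums(Xz) / nobs - 0.5) / 0.5, 0.01), 0.99)
  b <- pmin(pmax(-stats::qlogis(p), lo), hi)

  loglik <- NA_real_; converged <- FALSE; cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    s <- stats::plogis(outer(-b, q, "+"))            # I x Q
    LL <- Xz %*% log(0.5 * (1 + s)) + (M - Xz) %*% log(0.5 * (1 - s))
    A <- sweep(LL, 2L, log(wq), "+")
    amax <- apply(A, 1L, max)
    E <- exp(A - amax)
    rs <- rowSums(E)
    loglik <- sum(amax + log(rs))
    post <- E / rs                                   # N x Q posterior weights
    r_iq <- crossprod(Xz, post)                      # expected correct counts
    n_iq <- crossprod(M, post)                       # expected trial counts
    bnew <- mstep_difficulty(r_iq, n_iq, q, lo, hi)
    delta <- max(abs(bnew - b))
    b <- bnew
    if (delta < tol) { converged <- TRUE; break }
    if (cycle >= max_cycles) break
  }
  flag <- b <= lo + 1e-6 | b >= hi - 1e-6
  # SE from the quadrature-expected information at the converged solution
  info <- rowSums(n_iq * item_information(matrix(q, nrow = length(b),
                                                 ncol = length(q), byrow = TRUE), b))
  names(b) <- names(flag) <- colnames(X)
  se <- 1 / sqrt(info); names(se) <- colnames(X)
  list(difficulty = b, se = se, flag = flag, loglik = loglik,
       converged = converged, n_cycles = cycle)
}

# Solve the marginal score equation per item by vectorised bisection on
# [lo, hi]; the item log-likelihood is unimodal in b so the score crosses
# zero at most once.
mstep_difficulty <- function(r_iq, n_iq, q, lo, hi) {
  score <- function(b) {
    s <- stats::plogis(outer(-b, q, "+"))
    P <- 0.5 * (1 + s)
    rowSums((n_iq - r_iq) * s - 0.5 * r_iq * s * (1 - s) / P)
  }
  I <- nrow(r_iq)
  a <- rep(lo, I); c <- rep(hi, I)
  at_lo <- score(a) <= 0        # likelihood decreasing everywhere: clamp low
  at_hi <- score(c) >= 0        # at-or-below-chance item: clamp high
  for (k in seq_len(40L)) {
    mid <- 0.5 * (a + c)
    pos <- score(mid) > 0
    a[pos] <- mid[pos]; c[!pos] <- mid[!pos]
  }
  out <- 0.5 * (a + c)
  out[at_lo] <- lo; out[at_hi] <- hi
  out
}

#' @export
print.irt1pl <- function(x, ...) {
  cat(sprintf("1PL fit (fixed guessing 0.5)%s: %d items, %d persons\n",
              if (!is.null(x$group)) paste0(" [", x$group, "]") else "",
              x$n_items, x$n_persons))
  cat(sprintf("  marginal logLik %.2f after %d EM cycle(s)%s; %d item(s) flagged divergent\n",
              x$loglik, x$n_cycles,
              if (x$converged) "" else " (NOT converged)", sum(x$flag)))
  invisible(x)
}

#' @export
coef.irt1pl <- function(object, ...) object$difficulty

#' @export
logLik.irt1pl <- function(object, ...) {
  structure(object$loglik, df = object$n_items, nobs = object$n_persons,
            class = "logLik")
}

#' @export
summary.irt1pl <- function(object, ...) {
  tab <- data.frame(item_id = names(object$difficulty),
                    difficulty = unname(object$difficulty),
                    se = unname(object$se),
                    flag = unname(object$flag),
                    stringsAsFactors = FALSE)
  if (!is.null(object$categories))
    tab$category <- unname(object$categories[tab$item_id])
  structure(list(items = tab, loglik = object$loglik,
                 converged = object$converged, n_cycles = object$n_cycles,
                 group = object$group, n_persons = object$n_persons),
            class = "summary.irt1pl")
}

#' @export
print.summary.irt1pl <- function(x, ...) {
  cat(sprintf("1PL calibration%s: %d persons, %d items (%d flagged)\n",
              if (!is.null(x$group)) paste0(" [", x$group, "]") else "",
              x$n_persons, nrow(x$items), sum(x$items$flag)))
  cat(sprintf("logLik %.2f, %d EM cycles, converged: %s\n",
              x$loglik, x$n_cycles, x$converged))
  print(utils::head(x$items, 10))
  if (nrow(x$items) > 10) cat("...", nrow(x$items) - 10, "more item(s)\n")
  invisible(x)
}

#' @export
#' @param theta Ability values at which to evaluate response probabilities.
#' @param items Item ids (default: all calibrated items in the fit).
#' @rdname fit_1pl
predict.irt1pl <- function(object, theta, items = NULL, ...) {
  b <- object$difficulty
  if (!is.null(items)) b <- b[items]
  out <- outer(theta, b, prob_correct)
  rownames(out) <- names(theta)
  out
}

#' @export
plot.irt1pl <- function(x, ...) {
  b <- sort(x$difficulty)
  col <- if (!is.null(x$categories)) {
    ifelse(x$categories[names(b)] == "pseudo", "firebrick", "steelblue")
  } else "steelblue"
  graphics::plot(seq_along(b), b, col = col, pch = 16, cex = 0.6,
                 xlab = "item rank", ylab = "difficulty (logits)", ...)
  invisible(x)
}

#' @export
simulate.irt1pl <- function(object, nsim = 1, seed = NULL, theta = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  b <- object$difficulty
  if (is.null(theta))
    theta <- stats::rnorm(object$n_persons, object$prior["mean"], object$prior["sd"])
  P <- outer(theta, b, prob_correct)
  lapply(seq_len(nsim), function(k) {
    m <- (matrix(stats::runif(length(P)), nrow(P)) < P) + 0
    dimnames(m) <- list(paste0("p", seq_len(nrow(P))), names(b))
    m
  })
}

#' @export
residuals.irt1pl <- function(object, ...) {
  if (is.null(object$data))
    stop("fit was made with keep_data = FALSE; residuals need the data",
         call. = FALSE)
  X <- object$data$resp
  q <- seq(object$node_range[1], object$node_range[2],
           length.out = object$n_nodes)
  wq <- stats::dnorm(q, object$prior["mean"], object$prior["sd"])
  wq <- wq / sum(wq)
  M <- !is.na(X); storage.mode(M) <- "double"
  Xz <- X; Xz[is.na(Xz)] <- 0; storage.mode(Xz) <- "double"
  s <- stats::plogis(outer(-object$difficulty, q, "+"))
  A <- sweep(Xz %*% log(0.5 * (1 + s)) + (M - Xz) %*% log(0.5 * (1 - s)),
             2L, log(wq), "+")
  E <- exp(A - apply(A, 1L, max))
  theta_hat <- rowSums(E * rep(q, each = nrow(E))) / rowSums(E)  # per-person EAP
  fitted <- outer(theta_hat, object$difficulty, prob_correct)
  X - fitted
}

#' Pearson correlation of difficulty estimates across two calibrations
#'
#' Measures parameter invariance: items calibrated in different samples
#' should keep their relative difficulty ordering even when the samples
#' differ in ability (the scale origin shifts, but a linear association is
#' preserved). Flagged-divergent items are excluded by default.
#'
#' @param a,b Two `"irt1pl"` fits sharing (some) items.
#' @param subset `"all"`, `"real"` or `"pseudo"` (category subsets need
#'   `categories` stored in the fits or supplied here).
#' @param categories Optional named vector of item categories.
#' @param include_flagged Keep divergent items (default `FALSE`).
#' @return Pearson correlation over the shared, unflagged item set.
#' @export
difficulty_correlation <- function(a, b, subset = c("all", "real", "pseudo"),
                                   categories = NULL, include_flagged = FALSE) {
  subset <- match.arg(subset)
  ids <- intersect(names(a$difficulty), names(b$difficulty))
  if (!include_flagged)
    ids <- ids[!(a$flag[ids] | b$flag[ids])]
  if (subset != "all") {
    categories <- categories %||% a$categories %||% b$categories
    if (is.null(categories))
      stop("category subsets need item categories", call. = FALSE)
    ids <- ids[categories[ids] == subset]
  }
  if (length(ids) < 3L)
    stop("fewer than 3 shared unflagged items", call. = FALSE)
  stats::cor(a$difficulty[ids], b$difficulty[ids])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Trimmed mean log response time per item
#'
#' Drops implausibly fast or slow trials (below `lower` or above `upper`
#' milliseconds, the convention in lexical decision research) and returns
#' the mean log RT per item. Natural log by default; the base is
#' configurable.
#'
#' @param x A [response_matrix()] carrying `rt`.
#' @param lower,upper Trimming window in milliseconds (defaults 200 / 5000).
#' @param base Logarithm base (default `exp(1)`).
#' @return Data frame `item_id`, `mean_log_rt`, `n_used` with attributes
#'   `excluded_fraction` and `items_all_trimmed` (items whose trials were all
#'   trimmed; their mean is `NA`).
#' @export
rt_item_means <- function(x, lower = 200, upper = 5000, base = exp(1)) {
  rm <- as_response_matrix(x)
  if (is.null(rm$rt)) stop("response matrix has no RTs", call. = FALSE)
  rt <- rm$rt
  present <- !is.na(rt)
  keep <- present & rt >= lower & rt <= upper
  logrt <- log(rt, base = base)
  logrt[!keep] <- NA
  mlog <- colMeans(logrt, na.rm = TRUE)
  n_used <- as.integer(colSums(keep))
  mlog[n_used == 0] <- NA
  out <- data.frame(item_id = colnames(rt), mean_log_rt = unname(mlog),
                    n_used = unname(n_used), stringsAsFactors = FALSE)
  attr(out, "excluded_fraction") <- 1 - sum(keep) / sum(present)
  attr(out, "items_all_trimmed") <- colnames(rt)[n_used == 0 & colSums(present) > 0]
  out
}
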
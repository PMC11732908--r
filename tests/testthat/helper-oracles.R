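# Independent oracles and small fixtures shared across test files.

# Exhaustive grid-search MLE oracle (step 1e-4), independent of the
# package's optimiser.
mle_grid_oracle <- function(x, b, lo = -4, hi = 4, step = 1e-4) {
  g <- seq(lo, hi, by = step)
  s <- plogis(outer(g, b, "-"))
  ll <- log(0.5 * (1 + s)) %*% x + log(0.5 * (1 - s)) %*% (1 - x)
  g[which.max(ll)]
}

# Dense-quadrature EAP oracle (2001 equally spaced nodes).
eap_dense_oracle <- function(x, b, prior_mean = 0, prior_sd = 1,
                             lo = -4, hi = 4, n_nodes = 2001L) {
  g <- seq(lo, hi, length.out = n_nodes)
  s <- plogis(outer(g, b, "-"))
  ll <- log(0.5 * (1 + s)) %*% x + log(0.5 * (1 - s)) %*% (1 - x)
  w <- exp(dnorm(g, prior_mean, prior_sd, log = TRUE) + as.vector(ll) -
             max(ll))
  sum(w * g) / sum(w)
}

small_bank <- function(n = 20, seed = 1, ...) {
  gen_bank(n_items = n, n_real = ceiling(n / 2), n_pseudo = floor(n / 2),
           seed = seed, ...)
}

# 252-item bank (126 real / 126 pseudo) containing the six canonically
# removed stimuli under their own ids.
bank_252 <- function(seed = 3) {
  set.seed(seed)
  real_ids <- c("an", "potent", "garment", sprintf("real%03d", 1:123))
  pseudo_ids <- c("rackle", "bads", "streat", sprintf("pseu%03d", 1:123))
  item_bank(item_id = c(real_ids, pseudo_ids),
            stimulus = c(real_ids, pseudo_ids),
            category = rep(c("real", "pseudo"), each = 126),
            difficulty = rnorm(252, -1, 1.5))
}

# Bank with an uncalibrated pool for validation-item interleaving.
bank_with_new_items <- function(n_cal = 100, n_new = 30, seed = 5) {
  cal <- gen_bank(n_items = n_cal, n_real = n_cal / 2, n_pseudo = n_cal / 2,
                  seed = seed)
  set.seed(seed + 1)
  new <- item_bank(sprintf("new%03d", seq_len(n_new)),
                   sprintf("new%03d", seq_len(n_new)),
                   rep(c("real", "pseudo"), length.out = n_new),
                   rnorm(n_new, -1, 1.5), calibrated = FALSE)
  item_bank(c(cal$item_id, new$item_id), c(cal$stimulus, new$stimulus),
            c(cal$category, new$category), c(cal$difficulty, new$difficulty),
            c(cal$calibrated, new$calibrated))
}
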
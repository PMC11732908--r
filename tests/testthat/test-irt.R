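test_that("response probability has the guessing floor and logistic shape", {
  expect_identical(prob_correct(0, 0), 0.75)
  expect_equal(prob_correct(1, 0), 0.5 + 0.5 * plogis(1), tolerance = 1e-12)
  expect_equal(prob_correct(1, 0), 0.8655293, tolerance = 1e-6)
  # lower asymptote
  expect_lt(prob_correct(-40, 0) - 0.5, 1e-12)
  expect_gt(prob_correct(-40, 0), 0.5 - 1e-15)
  # range and monotonicity on randomised grids
  set.seed(1)
  for (k in 1:20) {
    th <- sort(runif(50, -8, 8)); b <- runif(1, -4, 4)
    p <- prob_correct(th, b)
    expect_true(all(p > 0.5 & p < 1))
    expect_true(all(diff(p) > 0))
    p2 <- prob_correct(th[1], sort(runif(50, -4, 4)))
    expect_true(all(diff(p2) < 0))
  }
  expect_error(prob_correct(NA, 0), "finite")
  expect_error(prob_correct(0, Inf), "finite")
})

test_that("item information follows the closed form and peaks above difficulty", {
  expect_equal(item_information(0, 0), 1 / 12, tolerance = 1e-12)
  # agreement with 4*(Q/P)*(P-0.5)^2
  set.seed(2)
  th <- runif(100, -6, 6); b <- runif(100, -4, 4)
  P <- prob_correct(th, b)
  expect_equal(item_information(th, b), 4 * ((1 - P) / P) * (P - 0.5)^2,
               tolerance = 1e-12)
  expect_true(all(item_information(th, b) >= 0))
  # vanishes at the asymptotes
  expect_lt(item_information(35, 0), 1e-12)
  expect_lt(item_information(-35, 0), 1e-10)
  # unique maximum at theta - b = log((1 + sqrt(5)) / 2)
  g <- seq(-2, 3, by = 1e-4)
  im <- item_information(g, 0)
  expect_equal(g[which.max(im)], log((1 + sqrt(5)) / 2), tolerance = 1e-3)
  expect_equal(max(im), 0.0901699, tolerance = 1e-5)
})

test_that("test information is additive and SEM is its inverse root", {
  expect_equal(test_information(0, 0), 1 / 12, tolerance = 1e-12)
  expect_equal(test_information(1.3, rep(1.3, 7)), 7 / 12, tolerance = 1e-12)
  set.seed(3)
  for (k in 1:20) {
    th <- runif(1, -3, 3); b <- runif(5, -4, 4)
    expect_equal(test_information(th, b),
                 sum(vapply(b, function(bi) item_information(th, bi), 0)),
                 tolerance = 1e-12)
    expect_equal(sem_of(th, b), 1 / sqrt(test_information(th, b)),
                 tolerance = 1e-15)
  }
  expect_equal(sem_of(0, 0), sqrt(12), tolerance = 1e-12)
  expect_error(test_information(0, numeric()), "at least one")
  expect_error(sem_of(0, 900), class = "adaptlex_degenerate_information")
})

test_that("MLE clamps monotone patterns at the bounds and matches the grid oracle", {
  b <- c(-1, 0, 1)
  expect_identical(estimate_mle(c(1, 1, 1), b)$theta, 4)
  expect_identical(estimate_mle(c(0, 0, 0), b)$theta, -4)
  bounds <- theta_bounds(-6, 6)
  expect_identical(estimate_mle(rep(1, 5), runif(5), bounds)$theta, 6)
  est <- estimate_mle(c(1, 1, 0), b)
  expect_lt(abs(est$theta - mle_grid_oracle(c(1, 1, 0), b)), 1e-3)
  expect_equal(est$sem, 1 / sqrt(test_information(est$theta, b)),
               tolerance = 1e-12)
  expect_identical(est$n_items, 3L)
  set.seed(4)
  for (k in 1:40) {
    n <- sample(3:12, 1)
    bb <- runif(n, -3.5, 3.5)
    x <- rbinom(n, 1, prob_correct(runif(1, -2.5, 2.5), bb))
    est <- estimate_mle(x, bb)
    oracle <- if (all(x == 1)) 4 else if (all(x == 0)) -4
              else mle_grid_oracle(x, bb)
    expect_lt(abs(est$theta - oracle), 1e-3)
  }
  expect_error(estimate_mle(numeric(), numeric()), "at least one")
  expect_error(estimate_mle(c(1, 0), c(0, 1), calibrated = c(TRUE, FALSE)),
               "uncalibrated")
  expect_error(estimate_mle(c(1, 2), c(0, 1)), "0 and 1")
})

test_that("EAP shrinks toward the prior and matches the dense-quadrature oracle", {
  expect_identical(estimate_eap(numeric(), numeric(), prior_mean = 0.3)$theta, 0.3)
  est <- estimate_eap(rep(1, 6), rep(0, 6))
  expect_gt(est$theta, 0)
  expect_lt(est$theta, 4)
  set.seed(5)
  for (k in 1:40) {
    n <- sample(2:15, 1)
    b <- runif(n, -3, 3)
    x <- rbinom(n, 1, 0.6)
    expect_lt(abs(estimate_eap(x, b)$theta - eap_dense_oracle(x, b)), 1e-3)
  }
  # diffuse prior converges to the MLE on interior solutions (long enough
  # tests for the posterior to be approximately symmetric around its mode)
  for (k in 1:10) {
    n <- 300
    b <- runif(n, -2, 2)
    x <- rbinom(n, 1, prob_correct(runif(1, -1.5, 1.5), b))
    mle <- estimate_mle(x, b)$theta
    if (abs(mle) >= 3.5) next
    eap <- estimate_eap(x, b, prior_sd = 100)$theta
    expect_lt(abs(eap - mle), 0.05)
  }
  expect_error(estimate_eap(c(1), c(0), prior_sd = 0), "positive")
})
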
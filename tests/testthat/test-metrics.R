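test_that("empirical reliability follows its defining identity", {
  th <- c(-1, 0, 1, 2)
  expect_identical(empirical_reliability(th, rep(0, 4)), 1)
  # Var(theta) equals mean squared SEM -> exactly 0.5
  v <- mean((th - mean(th))^2)
  expect_equal(empirical_reliability(th, rep(sqrt(v), 4)), 0.5, tolerance = 1e-12)
  set.seed(51)
  for (k in 1:25) {
    n <- sample(2:40, 1)
    t <- rnorm(n); s <- abs(rnorm(n)) + 0.01
    r <- empirical_reliability(t, s)
    expect_equal(r, mean((t - mean(t))^2) /
                   (mean((t - mean(t))^2) + mean(s^2)), tolerance = 1e-12)
    expect_true(r >= 0 && r < 1)
  }
  expect_error(empirical_reliability(1, 1), "length")
})

test_that("MSE and bias obey the variance decomposition", {
  expect_identical(unname(mse_and_bias(1:5, 1:5)), c(0, 0))
  mb <- mse_and_bias(1:4 + 0.5, 1:4)
  expect_equal(unname(mb), c(0.25, 0.5))
  set.seed(52)
  for (k in 1:25) {
    n <- sample(1:30, 1)
    est <- rnorm(n); tru <- rnorm(n)
    mb <- mse_and_bias(est, tru)
    expect_gte(mb[["mse"]], mb[["bias"]]^2 - 1e-12)
  }
  expect_error(mse_and_bias(1:3, 1:4), "length")
})

test_that("metric curves equal per-length recomputation and handle edge cohorts", {
  mk_session <- function(theta_traj, sem_traj) {
    structure(list(trials = data.frame(
      trial = seq_along(theta_traj), item_id = paste0("i", seq_along(theta_traj)),
      category = "real", scored = TRUE, response = 1L,
      theta_after = theta_traj, sem_after = sem_traj)), class = "cat_session")
  }
  set.seed(53)
  n <- 6; Tmax <- 8
  sessions <- lapply(1:n, function(i)
    mk_session(cumsum(rnorm(Tmax, 0, 0.3)), abs(rnorm(Tmax)) + 0.1))
  names(sessions) <- paste0("p", 1:n)
  truths <- setNames(rnorm(n), names(sessions))
  cur <- curves_by_length(sessions, truths)
  expect_identical(nrow(cur), as.integer(Tmax))
  for (t in c(1, 4, 8)) {
    th <- vapply(sessions, function(s) s$trials$theta_after[t], 0)
    se <- vapply(sessions, function(s) s$trials$sem_after[t], 0)
    expect_equal(cur$reliability[t], empirical_reliability(th, se))
    expect_equal(cur$mse[t], mse_and_bias(th, truths)[["mse"]])
    expect_equal(cur$bias[t], mse_and_bias(th, truths)[["bias"]])
    expect_equal(cur$mean_sem[t], mean(se))
  }
  # permutation invariance in person order
  perm <- sample(n)
  cur2 <- curves_by_length(sessions[perm], truths[perm])
  expect_equal(cur2, cur)
  # single person: reliability undefined, MSE/bias still there
  cur1 <- curves_by_length(sessions[1], truths[1])
  expect_true(all(is.na(cur1$reliability)))
  expect_false(anyNA(cur1$mse))
  expect_error(curves_by_length(sessions, truths[-1]), "missing")
})

test_that("quintile bins partition at the 20/40/60/80th percentiles with ties down", {
  qb <- quintile_bins(1:100)
  expect_identical(as.integer(table(qb$bin)), rep(20L, 5))
  expect_identical(levels(qb$bin), paste0("Q", 1:5))
  # a value exactly at a cutoff lands in the lower bin
  tr <- c(1, 2, 3, 4, 5, 5, 5, 8, 9, 10)
  qb2 <- quintile_bins(tr)
  at_cut <- which(tr == qb2$cutoffs[2])
  if (length(at_cut)) expect_true(all(qb2$bin[at_cut] <= "Q2"))
  set.seed(54)
  x <- rnorm(100)
  sizes <- table(quintile_bins(x)$bin)
  expect_lte(diff(range(sizes)), 1)
  expect_error(quintile_bins(1:4), "at least 5")
})

test_that("rapid guessers are flagged per block with strict 3-SD rule", {
  set.seed(55)
  m <- matrix(rnorm(30 * 3, 6.7, 0.1), 30, 3,
              dimnames = list(paste0("p", 1:30), NULL))
  m[7, 2] <- 5.0
  fl <- flag_rapid_guessers(m)
  expect_identical(fl$person[fl$flagged], "p7")
  # identical medians: SD = 0, strict inequality flags nobody
  same <- matrix(6.7, 10, 3, dimnames = list(paste0("p", 1:10), NULL))
  expect_false(any(flag_rapid_guessers(same)$flagged))
  # invariant to person ordering
  perm <- sample(30)
  fl2 <- flag_rapid_guessers(m[perm, ])
  expect_identical(fl2$flagged[match(fl$person, fl2$person)], fl$flagged)
  # missing block -> unevaluable, not flagged
  m[3, 1] <- NA
  fl3 <- flag_rapid_guessers(m)
  expect_true(fl3$unevaluable[fl3$person == "p3"])
})

test_that("percentage-bend correlation is exact on affine relations and covers rho", {
  set.seed(56)
  x <- rnorm(40)
  r1 <- robust_correlation(x, x, n_boot = 50)
  expect_equal(r1$r, 1.0, tolerance = 1e-12)
  expect_equal(robust_correlation(x, -x, n_boot = 50)$r, -1.0, tolerance = 1e-12)
  expect_error(robust_correlation(x, rep(1, 40), n_boot = 10), "constant")
  expect_error(robust_correlation(1:5, 1:5), "length")
  # coverage of a known rho = 0.8 at n = 200
  rho <- 0.8; hits <- 0; reps <- 50
  set.seed(57)
  for (k in seq_len(reps)) {
    z <- rnorm(200); e <- rnorm(200)
    xx <- z; yy <- rho * z + sqrt(1 - rho^2) * e
    ci <- robust_correlation(xx, yy, n_boot = 400)$ci95
    if (ci[1] <= rho && rho <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("threshold crossing uses first-crossing semantics", {
  cur <- structure(data.frame(length = 1:50,
                              reliability = pmin(0.99, 1:50 / 45),
                              mse = seq(2, 0.1, length.out = 50),
                              bias = 0, mean_sem = 1, n = 10),
                   class = c("metric_curve", "data.frame"))
  expect_identical(items_to_threshold(cur, "reliability", 42 / 45, "above"), 42L)
  expect_identical(items_to_threshold(cur, "reliability", 1.01, "above"),
                   NA_integer_)
  expect_error(items_to_threshold(cur, "accuracy", 0.5), "unknown metric")
  # noisy curve: first crossing, no smoothing
  set.seed(58)
  noisy <- cur
  noisy$mse <- 1 + cumsum(rnorm(50, -0.05, 0.1))
  scan <- which(noisy$mse <= 0.5)[1]
  expect_identical(items_to_threshold(noisy, "mse", 0.5, "below"),
                   if (is.na(scan)) NA_integer_ else noisy$length[scan])
})
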
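test_that("EM calibration recovers generating difficulties", {
  set.seed(101)
  b <- runif(50, -3, 3)
  bank <- item_bank(sprintf("i%02d", 1:50), sprintf("i%02d", 1:50),
                    rep(c("real", "pseudo"), 25), b)
  co <- gen_cohort(bank, groups = data.frame(label = "g", n = 500,
                                             theta_mean = 0, theta_sd = 1),
                   rt = NULL, seed = 102)
  fit <- fit_1pl(co$responses)
  expect_true(fit$converged)
  expect_gt(cor(coef(fit), b), 0.95)
  expect_lt(sqrt(mean((coef(fit) - b)^2)), 0.4)
  expect_true(all(fit$se > 0))
  # model-object surface
  expect_s3_class(fit, "irt1pl")
  expect_identical(length(coef(fit)), 50L)
  expect_identical(attr(logLik(fit), "df"), 50L)
  sm <- summary(fit)
  expect_identical(nrow(sm$items), 50L)
  p <- predict(fit, theta = c(-1, 0, 1), items = c("i01", "i02"))
  expect_identical(dim(p), c(3L, 2L))
  expect_true(all(p > 0.5 & p < 1))
  r <- residuals(fit)
  expect_identical(dim(r), dim(co$responses$resp))
  expect_lt(max(abs(colMeans(r))), 0.1)
  sims <- simulate(fit, nsim = 2, seed = 1, theta = co$theta)
  expect_length(sims, 2L)
  expect_true(all(sims[[1]] %in% 0:1))
})

test_that("degenerate items are clamped and flagged; duplication leaves estimates unchanged", {
  set.seed(103)
  X <- matrix(rbinom(200 * 10, 1, 0.8), 200, 10,
              dimnames = list(paste0("p", 1:200), paste0("i", 1:10)))
  X[, 1] <- 1                         # answered correctly by everyone
  X[, 2] <- rbinom(200, 1, 0.45)      # below the 0.5 chance floor
  fit <- fit_1pl(X)
  expect_identical(unname(coef(fit)[1]), -6)
  expect_true(fit$flag[1])
  expect_identical(unname(coef(fit)[2]), 6)
  expect_true(fit$flag[2])
  expect_false(any(fit$flag[3:10]))
  # replicating every person is a no-op for the likelihood
  fit2 <- fit_1pl(rbind(X, X))
  expect_equal(unname(coef(fit2)), unname(coef(fit)), tolerance = 1e-6)
  # all-missing item is rejected by name
  Xm <- X; Xm[, 4] <- NA
  expect_error(fit_1pl(Xm), "i4")
})

test_that("difficulty correlations respect subsets, flags and the shared-item floor", {
  set.seed(104)
  b <- rnorm(30)
  cats <- setNames(rep(c("real", "pseudo"), 15), paste0("i", 1:30))
  mk <- function(bv, flag = rep(FALSE, 30)) {
    structure(list(difficulty = setNames(bv, names(cats)),
                   flag = setNames(flag, names(cats)),
                   categories = cats), class = "irt1pl")
  }
  a <- mk(b)
  expect_equal(difficulty_correlation(a, a), 1.0, tolerance = 1e-12)
  expect_equal(difficulty_correlation(a, mk(-b)), -1.0, tolerance = 1e-12)
  # flagged items are excluded: corrupt one b wildly but flag it
  bad <- b; bad[1] <- 50
  expect_equal(difficulty_correlation(a, mk(bad, flag = c(TRUE, rep(FALSE, 29)))),
               1.0, tolerance = 1e-12)
  r_real <- difficulty_correlation(a, mk(b + rnorm(30, 0, 0.1)), subset = "real")
  expect_true(r_real >= -1 && r_real <= 1)
  few <- structure(list(difficulty = c(x = 1, y = 2), flag = c(x = FALSE, y = FALSE),
                        categories = NULL), class = "irt1pl")
  expect_error(difficulty_correlation(few, few), "fewer than 3")
})

test_that("shifting the generating abilities moves only the scale origin", {
  set.seed(105)
  b <- runif(40, -3, 3)
  n <- 5000
  theta <- rnorm(n)
  U <- matrix(runif(n * 40), n)
  mk <- function(th) {
    m <- (U < outer(th, b, prob_correct)) + 0
    dimnames(m) <- list(paste0("p", 1:n), paste0("i", 1:40))
    m
  }
  f0 <- fit_1pl(mk(theta), keep_data = FALSE)
  f1 <- fit_1pl(mk(theta + 0.5), keep_data = FALSE)
  shift <- mean(coef(f1) - coef(f0))
  expect_equal(shift, -0.5, tolerance = 0.1)
  # sampling noise at n = 5000 dominates the per-item comparison; the
  # tight 0.05 bound is checked at n = 30000 in the acceptance suite
  centred <- function(x) x - mean(x)
  expect_lt(max(abs(centred(coef(f1)) - centred(coef(f0)))), 0.25)
})

test_that("RT trimming drops implausible trials and is idempotent", {
  resp <- matrix(1, 3, 3, dimnames = list(paste0("p", 1:3), paste0("i", 1:3)))
  rt <- matrix(c(150, 1000, 1200,
                 6000, 1000, 800,
                 300, 1000, 40), 3, 3, byrow = TRUE,
               dimnames = dimnames(resp))
  x <- response_matrix(resp, rt = rt)
  out <- rt_item_means(x)
  # column i1 keeps only 300; i2 all 1000; i3 keeps 1200, 800
  expect_equal(out$mean_log_rt[out$item_id == "i1"], log(300))
  expect_equal(out$mean_log_rt[out$item_id == "i2"], log(1000), tolerance = 1e-12)
  expect_equal(out$mean_log_rt[out$item_id == "i3"], mean(log(c(1200, 800))))
  expect_equal(attr(out, "excluded_fraction"), 3 / 9)
  expect_identical(out$n_used, c(1L, 3L, 2L))
  # boundary values 200 and 5000 are kept ("below"/"above" rule)
  rt2 <- rt; rt2[1, 1] <- 200; rt2[2, 1] <- 5000
  out2 <- rt_item_means(response_matrix(resp, rt = rt2))
  expect_identical(out2$n_used[1], 3L)
  # idempotence: feeding back only the kept trials changes nothing
  rt3 <- rt; rt3[rt < 200 | rt > 5000] <- NA
  out3 <- rt_item_means(response_matrix(resp, rt = rt3))
  expect_equal(out3$mean_log_rt, out$mean_log_rt)
  # an item losing every trial is reported missing and listed
  rt4 <- rt; rt4[, 2] <- 100
  out4 <- rt_item_means(response_matrix(resp, rt = rt4))
  expect_true(is.na(out4$mean_log_rt[out4$item_id == "i2"]))
  expect_identical(attr(out4, "items_all_trimmed"), "i2")
})
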
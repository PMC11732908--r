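test_that("validation layout interleaves one new item after each scored block", {
  sched <- validation_layout(84, 5, 16)
  expect_length(sched, 100L)
  expect_identical(sum(sched), 84L)
  expect_identical(which(!sched), 6L * (1:16))
  expect_identical(validation_layout(5, 5, 0), rep(TRUE, 5))
  expect_error(validation_layout(84, 5, 17), "infeasible")
})

test_that("category coin is fair, seeded, and reproducible", {
  set.seed(11); a <- replicate(50, choose_category())
  set.seed(11); b <- replicate(50, choose_category())
  expect_identical(a, b)
  set.seed(12)
  draws <- replicate(10000, choose_category())
  frac <- mean(draws == "real")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("first item is the median-difficulty item of its category pool", {
  mk <- function(b) item_bank(paste0("i", seq_along(b)), paste0("i", seq_along(b)),
                              rep("real", length(b)), b)
  b5 <- c(2, -1, 0, 1, -2)  # sorted: -2 -1 0 1 2 -> median 0
  expect_identical(first_item(mk(b5), "real")$difficulty, 0)
  b4 <- c(3, 1, 2, 4)       # lower middle of 1 2 3 4 -> 2
  expect_identical(first_item(mk(b4), "real")$difficulty, 2)
  expect_identical(first_item(mk(7), "real")$difficulty, 7)
  expect_error(first_item(mk(1), "pseudo"), "exhausted")
})

test_that("selection rules pick the advertised item", {
  bank <- item_bank(c("a", "b", "c", "d"), c("a", "b", "c", "d"),
                    c("real", "real", "real", "pseudo"), c(-1, 0, 1, 0.5))
  # at theta 0, information is maximised by b = 0 (1/12 vs 0.08297 at b = -1)
  expect_identical(select_next(bank, 0, "mfi", category = "real")$item_id, "b")
  expect_gt(item_information(0, 0), item_information(0, -1))
  expect_identical(select_next(bank, 0.6, "closest_difficulty",
                               category = "real")$item_id, "c")
  # exhausted category falls back to the other pool
  expect_identical(select_next(bank, 0, "mfi", exclude = c("a", "b", "c"),
                               category = "real")$item_id, "d")
  expect_error(select_next(bank, 0, "mfi", exclude = bank$item_id),
               "session complete")
})

test_that("a full-bank session administers every item exactly once with equal categories", {
  bank <- small_bank(n = 40, seed = 21)
  cfg <- cat_config(selector = "mfi", test_length = 40, seed = 31)
  set.seed(99); resp <- simulate_responses(-0.4, bank)
  s <- run_session(bank, cfg, resp)
  expect_identical(sort(s$trials$item_id), sort(bank$item_id))
  expect_identical(anyDuplicated(s$trials$item_id), 0L)
  expect_identical(unname(table(s$trials$category)["real"]),
                   unname(table(s$trials$category)["pseudo"]))
  expect_identical(s$estimate$n_items, 40L)
  # seeded determinism: bit-identical re-run
  s2 <- run_session(bank, cfg, resp)
  expect_identical(s$trials, s2$trials)
})

test_that("trajectory is prefix-consistent with a from-scratch MLE", {
  bank <- small_bank(n = 60, seed = 22)
  cfg <- cat_config(selector = "mfi", test_length = 60, seed = 32)
  set.seed(7); resp <- simulate_responses(0.8, bank)
  s <- run_session(bank, cfg, resp)
  b_admin <- bank$difficulty[match(s$trials$item_id, bank$item_id)]
  for (t in c(1, 2, 7, 23, 41, 60)) {
    est <- estimate_mle(s$trials$response[1:t], b_admin[1:t], cfg$bounds)
    expect_equal(s$trials$theta_after[t], est$theta, tolerance = 1e-6)
    expect_equal(s$trials$sem_after[t], est$sem, tolerance = 1e-6)
  }
})

test_that("MFI selection dominates every other unadministered item in its category", {
  bank <- small_bank(n = 50, seed = 23)
  cfg <- cat_config(selector = "mfi", test_length = 50, seed = 33)
  set.seed(8); resp <- simulate_responses(-1, bank)
  s <- run_session(bank, cfg, resp)
  tr <- s$trials
  for (t in 2:nrow(tr)) {
    theta_prev <- tr$theta_after[t - 1]
    cat_t <- tr$category[t]
    pool <- bank[bank$category == cat_t &
                   !bank$item_id %in% tr$item_id[seq_len(t - 1)], ]
    chosen_info <- item_information(theta_prev,
                                    bank$difficulty[bank$item_id == tr$item_id[t]])
    expect_gte(chosen_info, max(item_information(theta_prev, pool$difficulty)) - 1e-9)
  }
})

test_that("stepwise R administration reproduces the compiled session exactly", {
  bank <- small_bank(n = 24, seed = 24)
  cfg <- cat_config(selector = "mfi", test_length = 24, seed = 34)
  set.seed(5); resp <- simulate_responses(0.2, bank)
  s <- run_session(bank, cfg, resp)
  st <- cat_begin(bank, cfg)
  for (t in 1:24) {
    st <- cat_next(st)
    st <- cat_update(st, resp[match(st$current_item$item_id, bank$item_id)])
  }
  manual <- do.call(rbind, st$trials)
  expect_identical(manual$item_id, s$trials$item_id)
  expect_identical(manual$response, s$trials$response)
  expect_equal(manual$theta_after, s$trials$theta_after, tolerance = 1e-9)
  expect_equal(manual$sem_after, s$trials$sem_after, tolerance = 1e-9)
})

test_that("scored updates clamp at the bound and validation trials leave theta alone", {
  bank <- bank_with_new_items(n_cal = 20, n_new = 6, seed = 25)
  cfg <- cat_config(selector = "mfi",
                    validation_schedule = list(n_scored = 15, every = 5, n_new = 3),
                    seed = 35)
  st <- cat_begin(bank, cfg)
  st <- cat_next(st)
  st <- cat_update(st, 1)            # first response correct -> theta at hi
  expect_identical(st$trials[[1]]$theta_after, 4)
  resp_all <- rep(1, nrow(bank))
  s <- run_session(bank, cfg, resp_all)
  expect_identical(which(!s$trials$scored), 6L * (1:3))
  for (t in which(!s$trials$scored)) {
    expect_identical(s$trials$theta_after[t], s$trials$theta_after[t - 1])
    expect_identical(s$trials$sem_after[t], s$trials$sem_after[t - 1])
    expect_false(bank$calibrated[match(s$trials$item_id[t], bank$item_id)])
  }
  expect_true(all(bank$calibrated[match(s$trials$item_id[s$trials$scored],
                                        bank$item_id)]))
  # duplicate administration is a contract violation
  st2 <- cat_begin(bank, cat_config(test_length = 5, seed = 36))
  st2 <- cat_next(st2)
  first <- st2$current_item
  st2 <- cat_update(st2, 1)
  st2$current_item <- first
  expect_error(cat_update(st2, 0), "already administered")
})

test_that("a deterministic threshold responder recovers interior ability", {
  bank <- gen_bank(n_items = 246, seed = 26, difficulty_mean = 0,
                   difficulty_sd = 2)
  theta_true <- 0.5
  for (rep in 1:5) {
    cfg <- cat_config(selector = "mfi", test_length = 120, seed = 100 + rep)
    s <- run_session(bank, cfg, function(item)
      as.integer(item$difficulty < theta_true))
    expect_lt(abs(s$estimate$theta - theta_true), 0.5)
  }
})

test_that("a failing responder aborts with a partial log flagged incomplete", {
  bank <- small_bank(n = 20, seed = 27)
  cfg <- cat_config(selector = "mfi", test_length = 20, seed = 37)
  count <- 0
  flaky <- function(item) {
    count <<- count + 1
    if (count > 5) stop("respondent walked away")
    1L
  }
  expect_warning(s <- run_session(bank, cfg, flaky), "partial")
  expect_true(s$incomplete)
  expect_identical(nrow(s$trials), 5L)
  expect_identical(s$trials$theta_after[5], 4)  # five correct answers
})
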
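test_that("strategy-selection probability matches the logistic form", {
  expect_equal(p_memory_retrieval(0, 0), 0.5)
  expect_equal(p_memory_retrieval(1, 0), 0.7310586, tolerance = 1e-6)
  # complementarity holds exactly, including extreme arguments
  for (ri in c(-800, -3, 0, 2.5, 800)) {
    for (rk in c(-700, 0, 1, 650)) {
      expect_equal(p_memory_retrieval(ri, rk) +
                     (1 - p_memory_retrieval(ri, rk)), 1)
      expect_true(is.finite(p_memory_retrieval(ri, rk)))
    }
  }
})

test_that("memory drift rate decreases in item difficulty, bounded by delta_m", {
  expect_equal(memory_drift_rate(1, 0), 0.5)
  expect_equal(memory_drift_rate(2, 1), 0.537883, tolerance = 1e-6)
  rk <- seq(-5, 5, by = 0.5)
  v <- memory_drift_rate(1.7, rk)
  expect_true(all(diff(v) < 0))
  expect_true(all(v < 1.7))
  expect_lt(memory_drift_rate(1, 50), 1e-20)
  expect_error(memory_drift_rate(-1, 0), "positive")
})

test_that("counting drift rate is delta_c over count steps", {
  expect_equal(counting_drift_rate(3, 3), 1)
  expect_equal(counting_drift_rate(2, 1), 2)
  expect_true(all(diff(counting_drift_rate(2, 1:8)) < 0))
  expect_error(counting_drift_rate(2, 0), "n_k")
})

test_that("mixture likelihood reduces to one strategy in the degenerate case", {
  tr <- one_trials(rt = 1.1)
  it <- one_items(rho_k = 0)
  # rho_i - rho_k very large: pure memory
  p_mem <- one_params(rho_i = 50)
  lik <- trial_likelihood(tr, p_mem, it)$likelihood
  direct <- wiener_density(1.1, "correct", alpha = 1.5,
                           drift = memory_drift_rate(1.2, 0), tau = 0.3)
  expect_equal(lik, direct, tolerance = 1e-12)
})

test_that("counting contributes nothing below its non-decision floor", {
  # tau = 0.3, tau_switch = 0.4: an RT of 0.5 is impossible for counting
  tr <- one_trials(rt = 0.5)
  p <- one_params(rho_i = 0, tau = 0.3, tau_switch = 0.4)
  it <- one_items()
  out <- trial_likelihood(tr, p, it)
  expect_equal(out$lik_counting, 0)
  expect_gt(out$lik_memory, 0)
  resp <- strategy_responsibility(tr, p, it)
  expect_equal(resp$responsibility, 1)
})

test_that("responsibilities normalise and missing RTs are flagged", {
  tr <- one_trials(rt = c(1.2, NA))
  p <- one_params()
  it <- one_items()
  out <- strategy_responsibility(tr, p, it)
  expect_true(out$responsibility[1] >= 0 && out$responsibility[1] <= 1)
  expect_true(is.na(out$responsibility[2]))
  lik <- trial_likelihood(tr, p, it)
  expect_true(is.na(lik$likelihood[2]))
})

test_that("responsibilities separate true strategies on labelled simulations", {
  set.seed(71)
  sim <- simulate_mixture(2000, rho_i = 0.2, rho_k = 0, delta_m = 1.5,
                          delta_c = 1.2, n_k = 4, alpha = 1.5, tau = 0.3,
                          tau_switch = 0.45)
  tr <- tibble::tibble(participant_id = "P01", session = "pre",
                       item_id = "4+5", response_correct =
                         sim$boundary == "correct", rt = sim$rt)
  p <- one_params(rho_i = 0.2, delta_m = 1.5, delta_c = 1.2, alpha = 1.5,
                  tau = 0.3, tau_switch = 0.45)
  it <- one_items(rho_k = 0, n_k = 4, item_id = "4+5")
  resp <- strategy_responsibility(tr, p, it)$responsibility
  expect_gt(mean(resp[sim$memory], na.rm = TRUE),
            mean(resp[!sim$memory], na.rm = TRUE))
  acc <- mean((resp > 0.5) == sim$memory, na.rm = TRUE)
  expect_gt(acc, max(mean(sim$memory), 1 - mean(sim$memory)) * 0 + 0.5)
})

test_that("retrieval-use summary hits its extremes and both conventions work", {
  tr <- one_trials(rt = c(0.5, 0.55, 0.6))  # all below the counting floor
  p <- one_params(tau = 0.3, tau_switch = 0.4)
  it <- one_items()
  use <- retrieval_use_summary(tr, p, it)
  expect_equal(use$retrieval_use, 1)
  use_cl <- retrieval_use_summary(tr, p, it, method = "classify")
  expect_equal(use_cl$retrieval_use, 1)
  # pure counting: rho_i - rho_k strongly negative and slow RTs
  p2 <- one_params(rho_i = -50)
  tr2 <- one_trials(rt = c(2.5, 3, 4))
  expect_equal(retrieval_use_summary(tr2, p2, it)$retrieval_use, 0)
})

test_that("preprocessing applies the anticipation and validity rules", {
  tr <- tibble::tibble(participant_id = "P01", session = "pre",
                       item_id = "3+4", response_correct = TRUE,
                       rt = c(0.25, 0.300, 1.4, 9.6, NA))
  out <- preprocess_trials(tr, quiet = TRUE)
  expect_equal(nrow(out), 4)            # the 9.6 s record is invalid
  expect_true(is.na(out$rt[1]))         # 0.25 s marked missing
  expect_equal(out$rt[2], 0.300)        # boundary retained (strict <)
  expect_equal(attr(out, "exclusions"), c(too_slow = 1L, too_fast = 1L))
  empty <- preprocess_trials(tr[0, ], quiet = TRUE)
  expect_equal(nrow(empty), 0)
  expect_equal(sum(attr(empty, "exclusions")), 0)
  bad <- tr; bad$rt[3] <- -1
  expect_error(preprocess_trials(bad, quiet = TRUE), "row")
})

test_that("trial tables round-trip through CSV with empty-field missing RTs", {
  path <- tempfile(fileext = ".csv")
  tr <- tibble::tibble(participant_id = "P01",
                       session = factor(c("pre", "post"),
                                        levels = c("pre", "post")),
                       item_id = "3+4", addend_a = 3L, addend_b = 4L,
                       equation_valid = c(TRUE, FALSE),
                       response_correct = c(TRUE, NA),
                       rt = c(1.25, NA))
  write_trials(tr, path)
  expect_true(any(grepl(",$", readLines(path))))  # empty field for NA
  back <- read_trials(path)
  expect_equal(back$rt, tr$rt)
  expect_equal(as.character(back$session), as.character(tr$session))
})
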
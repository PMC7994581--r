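test_that("item bank enumerates all unordered operand pairs", {
  spec <- cohort_spec(seed = 5)
  items <- generate_item_bank(spec)
  expect_equal(nrow(items), 36)               # 8 ties + choose(8, 2)
  expect_true(all(items$addend_a >= 2 & items$addend_b <= 9))
  expect_false(any(items$addend_a %in% c(0, 1) |
                     items$addend_b %in% c(0, 1)))
  expect_equal(items$n_k, pmin(items$addend_a, items$addend_b))
  expect_equal(items$n_k[items$item_id == "3+4"], 3)
  # deterministic given the spec
  expect_identical(items, generate_item_bank(spec))
})

test_that("population draws respect positivity and planted shifts", {
  spec <- cohort_spec(seed = 8)
  params <- sample_population(spec)
  expect_true(all(params$delta_m > 0))
  expect_true(all(params$delta_c > 0))
  expect_true(all(params$alpha > 0))
  expect_true(all(params$tau > 0))
  expect_true(all(params$tau_switch >= 0))
  # positive planted mean change in memory efficiency shows up pre -> post
  wide <- tidyr::pivot_wider(params[, c("participant_id", "session",
                                        "delta_m")],
                             names_from = "session",
                             values_from = "delta_m")
  expect_gt(mean(wide$post - wide$pre), 0)
  expect_identical(params, sample_population(spec))
})

test_that("zero change-variance and zero change-mean reproduce pre exactly", {
  spec <- cohort_spec(seed = 9)
  spec$population$d_rho <- c(0, 1e-12)
  spec$population$d_delta_m <- c(0, 1e-12)
  spec$population$d_delta_c <- c(0, 1e-12)
  spec$population$d_alpha <- c(0, 1e-12)
  spec$population$d_tau_switch <- c(0, 1e-12)
  params <- sample_population(spec)
  wide <- tidyr::pivot_wider(params, names_from = "session",
                             values_from = c("rho_i", "delta_m", "delta_c",
                                             "alpha", "tau", "tau_switch"))
  expect_equal(wide$rho_i_pre, wide$rho_i_post, tolerance = 1e-9)
  expect_equal(wide$delta_m_pre, wide$delta_m_post, tolerance = 1e-9)
  expect_equal(wide$tau_switch_pre, wide$tau_switch_post, tolerance = 1e-9)
})

test_that("infeasible truncation is rejected", {
  spec <- cohort_spec(seed = 10)
  spec$population$delta_m <- c(-50, 1)
  expect_error(sample_population(spec), "truncation")
})

test_that("simulated behaviour honours strategy labels and timing floors", {
  spec <- cohort_spec(n_participants = 5, trials_per_session = 40, seed = 12)
  items <- generate_item_bank(spec)
  params <- sample_population(spec)
  trials <- simulate_behavior(params, items, spec)
  expect_equal(nrow(trials), 5 * 40 * 2)
  # counting trials can never beat the switching floor
  joined <- dplyr::inner_join(trials, params,
                              by = c("participant_id", "session"))
  cnt <- joined[joined$true_strategy == "counting" & !is.na(joined$rt), ]
  expect_true(all(cnt$rt >= cnt$tau + cnt$tau_switch))
  expect_true(all(is.na(trials$rt) | trials$rt <= spec$max_rt))
  # forcing retrieval propensity to extremes forces the labels
  spec2 <- spec
  spec2$population$rho <- c(50, 0.01)
  spec2$population$d_rho <- c(0, 0.01)
  trials2 <- simulate_behavior(sample_population(spec2), items, spec2)
  expect_true(all(trials2$true_strategy == "memory"))
})

test_that("simulated mixture RTs match the analytic mixture distribution", {
  # one moderate parameter set; the full multi-set comparison runs in the
  # acceptance suite
  set.seed(21)
  n <- 20000
  sim <- simulate_mixture(n, rho_i = 0.4, rho_k = 0.2, delta_m = 1.4,
                          delta_c = 1.1, n_k = 3, alpha = 1.4, tau = 0.3,
                          tau_switch = 0.4)
  for (b in c("correct", "error")) {
    rts <- sort(sim$rt[sim$boundary == b & !is.na(sim$rt)])
    Fa <- mixture_cdf(rts, b, 0.4, 0.2, 1.4, 1.1, 3, 1.4, 0.3, 0.4)
    Femp <- seq_along(rts) / length(rts)
    expect_lt(max(abs(Fa - Femp)), 0.02)
  }
})

test_that("planted networks are symmetric, zero-diagonal, and coupled", {
  spec <- cohort_spec(n_participants = 20, seed = 14)
  params <- sample_population(spec)
  changes <- attr(params, "changes")
  nets <- simulate_networks(spec, changes)
  W <- nets$matrices[[1]]$pre
  expect_equal(W, t(W))
  expect_true(all(diag(W) == 0))
  expect_equal(dim(W), c(30, 30))
  # planted negative coupling between efficiency change and diversity change
  truth <- nets$truth
  r <- cor(changes$d_delta_m, truth$d_diversity)
  expect_lt(r, -0.5)
  # mean designated-node diversity decreases (planted shift)
  expect_lt(mean(truth$d_diversity), 0)
})

test_that("ROI time-series generator balances the task indicator", {
  sim <- simulate_roi_timeseries(4, 600, block_length = 30, seed = 3)
  expect_equal(sum(sim$task == 1), sum(sim$task == -1))
  expect_equal(dim(sim$timeseries), c(600, 4))
  # zero coupling: interaction weights centred at zero
  W <- ppi_edge_weights(sim$timeseries, sim$task)
  expect_lt(max(abs(W)), 0.2)
})
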
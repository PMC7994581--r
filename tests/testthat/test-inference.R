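test_that("Savage-Dickey matches closed-form conjugate-normal oracles", {
  # posterior identical to the prior: BF = 1
  set.seed(20)
  s0 <- rnorm(2e5)
  bf0 <- savage_dickey_bf(s0)
  expect_equal(bf0$bf, 1, tolerance = 0.05)
  # posterior N(1, 1): BF = exp(0.5)
  s1 <- rnorm(2e5, 1, 1)
  bf1 <- savage_dickey_bf(s1)
  oracle1 <- dnorm(0, 0, 1) / dnorm(0, 1, 1)
  expect_equal(oracle1, exp(0.5))
  expect_equal(bf1$bf, oracle1, tolerance = 0.05 * oracle1)
  expect_equal(bf1$bf_normal, oracle1, tolerance = 0.02 * oracle1)
  # posterior N(2, 0.5): BF ~ 1490.4
  s2 <- rnorm(2e5, 2, 0.5)
  bf2 <- savage_dickey_bf(s2)
  oracle2 <- dnorm(0, 0, 1) / dnorm(0, 2, 0.5)
  expect_equal(oracle2, 1490.479, tolerance = 1e-3)
  expect_equal(bf2$bf_normal, oracle2, tolerance = 0.05 * oracle2)
  # far-tail KDE estimates are flagged as what they are
  expect_true(bf2$bf > 3)
  expect_equal(bf2$evidence, "moderate evidence for H1")
  # evidence categories at the stated thresholds
  expect_equal(savage_dickey_bf(rnorm(5e4, 3, 0.6))$evidence,
               "moderate evidence for H1")
  expect_equal(savage_dickey_bf(rnorm(5e4, 0, 0.2))$evidence,
               "evidence of absence")
  expect_warning(savage_dickey_bf(rnorm(50, 1, 1)), "unstable")
})

test_that("split-Rhat behaves at its reference points", {
  # identical chains copied: Rhat = 1 exactly
  set.seed(22)
  x <- rnorm(400)
  draws <- array(NA_real_, c(3, 400, 1),
                 dimnames = list(NULL, NULL, parameter = "theta"))
  for (ch in 1:3) draws[ch, , 1] <- x
  d <- convergence_diagnostics(draws)
  # split-Rhat of copied chains: no between-chain variance beyond the
  # within-chain split, so the statistic sits at 1 up to the finite-n
  # correction
  expect_equal(d$rhat, 1, tolerance = 0.01)
  # chains from the same distribution: Rhat near 1
  for (ch in 1:3) draws[ch, , 1] <- rnorm(400)
  d2 <- convergence_diagnostics(draws)
  expect_lt(d2$rhat, 1.05)
  expect_gt(d2$ess, 100)
  # disjoint supports: Rhat far above 1.1
  draws[1, , 1] <- rnorm(400, -10)
  draws[2, , 1] <- rnorm(400, 0)
  draws[3, , 1] <- rnorm(400, 10)
  d3 <- convergence_diagnostics(draws)
  expect_gt(d3$rhat, 2)
  expect_false(d3$ok)
  # single chain: ESS only
  d4 <- convergence_diagnostics(draws[1, , , drop = FALSE])
  expect_true(is.na(d4$rhat))
  expect_false(is.na(d4$ess))
})

test_that("identical seed and config reproduce identical draws", {
  co <- small_cohort(n_participants = 4, trials = 30)
  cfg <- fit_config(n_chains = 2, n_samples = 150, burn_in = 80, seed = 5)
  f1 <- suppressWarnings(fit_hierarchical(co$trials, config = cfg,
                                          compute_waic = FALSE))
  f2 <- suppressWarnings(fit_hierarchical(co$trials, config = cfg,
                                          compute_waic = FALSE))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_hierarchical(co$trials,
                                          config = fit_config(
                                            n_chains = 2, n_samples = 150,
                                            burn_in = 80, seed = 6),
                                          compute_waic = FALSE))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the fit exposes every declared parameter exactly once", {
  co <- small_cohort(n_participants = 3, trials = 25)
  cfg <- fit_config(n_chains = 2, n_samples = 120, burn_in = 60, seed = 2)
  fit <- suppressWarnings(fit_hierarchical(co$trials, config = cfg,
                                           compute_waic = FALSE))
  pn <- dimnames(fit$draws)[[3]]
  expect_false(any(duplicated(pn)))
  # 11 per participant + items + 2 x 8 hypers + 2 item hypers
  expect_equal(length(pn),
               11 * 3 + nrow(fit$items) + 16 + 2)
  expect_equal(dim(fit$draws)[2], 60)
  # draw counts respect thinning
  cfg2 <- fit_config(n_chains = 2, n_samples = 120, burn_in = 60,
                     thinning = 3, seed = 2)
  fit2 <- suppressWarnings(fit_hierarchical(co$trials, config = cfg2,
                                            compute_waic = FALSE))
  expect_equal(dim(fit2$draws)[2], 20)
})

test_that("a participant with pure-retrieval behaviour is inferred as such", {
  spec <- cohort_spec(n_participants = 4, trials_per_session = 80,
                      seed = 33)
  spec$population$rho <- c(6, 0.2)       # retrieval essentially always
  spec$population$d_rho <- c(0.2, 0.1)
  items <- generate_item_bank(spec)
  params <- sample_population(spec)
  trials <- preprocess_trials(simulate_behavior(params, items, spec),
                              quiet = TRUE)
  cfg <- fit_config(n_chains = 2, n_samples = 500, burn_in = 250, seed = 4)
  fit <- suppressWarnings(fit_hierarchical(trials, config = cfg,
                                           compute_waic = FALSE))
  pp <- participant_params(fit)
  it <- item_params(fit)
  pm <- p_memory_retrieval(pp$rho_i, mean(it$rho_k))
  expect_gt(mean(pm), 0.85)
})

test_that("posterior predictive reproduces observed summaries from model data", {
  co <- small_cohort(n_participants = 6, trials = 80, seed = 55)
  cfg <- fit_config(n_chains = 2, n_samples = 500, burn_in = 250, seed = 9)
  fit <- suppressWarnings(fit_hierarchical(co$trials, config = cfg,
                                           compute_waic = FALSE))
  pp <- posterior_predictive(fit, n_rep = 40, seed = 2)
  cov <- attr(pp, "coverage")
  # data were generated by the model: intervals should cover most
  # participant-session error rates and mean RTs
  expect_gte(cov[["error_rate"]], 0.7)
  expect_gte(cov[["rt"]], 0.7)
  expect_equal(nrow(pp), 12)
  # predictions track observations
  expect_gt(cor(pp$obs_mean_rt, pp$pred_mean_rt), 0.7)
})

test_that("missing modularity scores exclude participants from the joint fit", {
  co <- small_cohort(n_participants = 4, trials = 30, seed = 77)
  dm <- tibble::tibble(participant_id = unique(co$trials$participant_id)[1:3],
                       d_diversity = c(-0.1, 0, 0.1))
  cfg <- fit_config(n_chains = 2, n_samples = 150, burn_in = 80, seed = 3)
  expect_message(
    fit <- suppressWarnings(
      fit_joint_brain_model(co$trials, dm, config = cfg)),
    "excluding")
  expect_equal(length(fit$participants), 3)
  expect_true(all(beta_names <- grepl("^beta\\[",
                                      dimnames(fit$draws)[[3]]) |> sum() == 5))
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("a constant brain score concentrates all slopes at zero", {
  co <- small_cohort(n_participants = 6, trials = 40, seed = 88)
  dm <- tibble::tibble(participant_id = unique(co$trials$participant_id),
                       d_diversity = rep(-0.2, 6))
  cfg <- fit_config(n_chains = 2, n_samples = 400, burn_in = 200, seed = 3)
  fit <- suppressWarnings(fit_joint_brain_model(co$trials, dm, config = cfg))
  b <- tidy(fit)
  expect_true(all(abs(b$median) < 0.6))
  expect_true(all(b$q2.5 < 0 & b$q97.5 > 0))
})

test_that("posterior export writes tabular CSV and JSON summaries", {
  co <- small_cohort(n_participants = 3, trials = 20, seed = 91)
  cfg <- fit_config(n_chains = 2, n_samples = 100, burn_in = 50, seed = 2)
  fit <- suppressWarnings(fit_hierarchical(co$trials, config = cfg,
                                           compute_waic = FALSE))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  export_posterior(fit, csv, js)
  long <- readr::read_csv(csv, show_col_types = FALSE)
  expect_setequal(names(long), c("chain", "draw", "parameter", "value"))
  expect_equal(nrow(long), 2 * 50 * dim(fit$draws)[3])
  summ <- jsonlite::read_json(js)
  expect_true(length(summ) == dim(fit$draws)[3])
})
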
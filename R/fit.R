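#' MCMC configuration
#'
#' Chain and sample counts for the hierarchical fit. The `"full"`
#' profile mirrors a production fit (3 chains of 10,000 samples, 5,000
#' burn-in, thinning 1); the `"ci"` profile is a reduced setting for
#' fast checks (3 chains of 1,000 with 500 burn-in).
#'
#' @param n_chains number of chains (>= 2 for split-Rhat).
#' @param n_samples MCMC iterations per chain (including burn-in).
#' @param burn_in discarded initial iterations per chain.
#' @param thinning keep every `thinning`-th retained draw.
#' @param seed integer seed; chain c uses `seed + 1000 * c`.
#' @param profile `"full"` or `"ci"`; overrides the counts above.
#' @export
fit_config <- function(n_chains = 3, n_samples = 10000, burn_in = 5000,
                       thinning = 1, seed = 1,
                       profile = c("full", "ci")) {
  profile <- match.arg(profile)
  if (profile == "ci") {
    n_samples <- 1000
    burn_in <- 500
  }
  if (burn_in >= n_samples) abort("burn_in must be smaller than n_samples")
  structure(list(n_chains = n_chains, n_samples = n_samples,
                 burn_in = burn_in, thinning = thinning, seed = seed,
                 profile = profile),
            class = "fit_config")
}

#' Prior specification
#'
#' Hierarchical normal priors (truncated to the positivity region where
#' needed) on retrieval propensity, both efficiencies and the decision
#' threshold, at pre-training level and on their pre-to-post changes;
#' uniform priors on the non-decision and switching times; a hierarchical
#' normal prior on item difficulty. Hyperpriors are normal on the
#' locations and uniform on the scales.
#'
#' @param mu0_sd sd of the normal hyperprior on location hyperparameters.
#' @param sd_lo,sd_hi support of the uniform prior on scale parameters.
#' @param tau_lo,tau_hi support of the uniform prior on non-decision
#'   time, seconds.
#' @param tc_hi upper bound of the uniform prior on switching time.
#' @param beta_prior_sd sd of the N(0, sd) prior on the joint-model
#'   regression slopes (the Savage-Dickey reference prior).
#' @export
prior_spec <- function(mu0_sd = 2, sd_lo = 0.01, sd_hi = 5,
                       tau_lo = 0.05, tau_hi = 1, tc_hi = 2.5,
                       beta_prior_sd = 1) {
  structure(list(mu0_sd = mu0_sd, sd_lo = sd_lo, sd_hi = sd_hi,
                 tau_lo = tau_lo, tau_hi = tau_hi, tc_hi = tc_hi,
                 beta_prior_sd = beta_prior_sd),
            class = "prior_spec")
}

model_par_cols <- function(type) {
  if (type == 2)
    c("rho_pre", "rho_change", "delta_m_pre", "delta_m_change",
      "delta_c_pre", "delta_c_change", "alpha_pre", "alpha_change",
      "tau", "tau_switch_pre", "tau_switch_post")
  else
    c("drift_pre", "drift_change", "alpha_pre", "alpha_change", "tau")
}

beta_par_names <- function() {
  c("beta[rho_change]", "beta[delta_m_change]", "beta[delta_c_change]",
    "beta[alpha_change]", "beta[tau_switch_change]")
}

# initial state for one chain; jittered deterministically via the
# caller's RNG state
init_theta <- function(type, pids, trials, prior) {
  P <- length(pids)
  nppar <- if (type == 2) 11 else 5
  th <- matrix(0, P, nppar)
  min_rt <- tapply(trials$rt, trials$participant_id, min)[pids]
  tau0 <- pmin(pmax(0.6 * min_rt, prior$tau_lo + 0.02), 0.6)
  jit <- function(x, s = 0.05) x + rnorm(length(x), 0, s)
  if (type == 2) {
    th[, 1] <- jit(rep(0, P), 0.3)        # rho_pre
    th[, 2] <- jit(rep(0.3, P), 0.2)      # rho_change
    th[, 3] <- pmax(jit(rep(1.0, P), 0.15), 0.2)
    th[, 4] <- jit(rep(0.3, P), 0.1)
    th[, 5] <- pmax(jit(rep(1.2, P), 0.15), 0.2)
    th[, 6] <- jit(rep(0, P), 0.1)
    th[, 7] <- pmax(jit(rep(1.5, P), 0.15), 0.4)
    th[, 8] <- jit(rep(0, P), 0.1)
    th[, 9] <- pmin(pmax(jit(tau0), prior$tau_lo + 0.01),
                    prior$tau_hi - 0.01)
    th[, 10] <- pmin(pmax(jit(rep(0.4, P)), 0.01), prior$tc_hi - 0.01)
    th[, 11] <- pmin(pmax(jit(rep(0.4, P)), 0.01), prior$tc_hi - 0.01)
    th[, 4] <- pmax(th[, 4], -th[, 3] + 0.1)
    th[, 6] <- pmax(th[, 6], -th[, 5] + 0.1)
    th[, 8] <- pmax(th[, 8], -th[, 7] + 0.2)
  } else {
    th[, 1] <- pmax(jit(rep(1.0, P), 0.15), 0.2)
    th[, 2] <- jit(rep(0.2, P), 0.1)
    th[, 3] <- pmax(jit(rep(1.5, P), 0.15), 0.4)
    th[, 4] <- jit(rep(0, P), 0.1)
    th[, 5] <- pmin(pmax(jit(tau0), prior$tau_lo + 0.01),
                    prior$tau_hi - 0.01)
    th[, 2] <- pmax(th[, 2], -th[, 1] + 0.1)
    th[, 4] <- pmax(th[, 4], -th[, 3] + 0.2)
  }
  th
}

#' Fit the hierarchical strategy-mixture model
#'
#' Hierarchical Bayesian estimation of all individual, item and
#' hyper-parameters of the two-strategy mixture drift-diffusion model
#' (or of a control model) by adaptive random-walk
#' Metropolis-within-Gibbs with a Navarro-Fuss Wiener likelihood.
#' Pre-training levels and pre-to-post changes are estimated for
#' retrieval propensity, both efficiencies and the decision threshold;
#' non-decision time and item difficulty are shared across sessions; the
#' switching time is estimated per session. Missing reaction times are
#' excluded from the likelihood. When `delta_modularity` is supplied the
#' model is extended with a latent regression of the brain-change score
#' on the (cohort-centered) change parameters, fitted jointly.
#'
#' @param trials preprocessed trial tibble (see [preprocess_trials()]);
#'   must contain `addend_a`/`addend_b` (or be accompanied by `items`).
#' @param config a [fit_config()].
#' @param prior a [prior_spec()].
#' @param model `"mixture"` (full model), `"single"` (one strategy with
#'   item difficulty) or `"simple"` (plain drift-diffusion).
#' @param delta_modularity optional tibble `participant_id`,
#'   `d_diversity`: one brain-network change score per participant.
#'   Participants without a score are excluded (with a message).
#' @param items optional item table with `item_id`, `n_k`.
#' @param compute_waic accumulate pointwise log-likelihood for WAIC?
#' @return object of class `strategy_fit`: posterior draws
#'   (chain x draw x parameter), convergence diagnostics, WAIC, and the
#'   data bookkeeping needed by downstream summaries.
#' @export
fit_hierarchical <- function(trials, config = fit_config(),
                             prior = prior_spec(),
                             model = c("mixture", "single", "simple"),
                             delta_modularity = NULL, items = NULL,
                             compute_waic = TRUE) {
  model <- match.arg(model)
  type <- c(simple = 0L, single = 1L, mixture = 2L)[[model]]
  trials <- dplyr::filter(trials, !is.na(.data$rt))
  if (nrow(trials) == 0) abort("no trials with valid reaction times")
  if (any(trials$rt <= prior$tau_lo))
    abort("some reaction times are at or below the non-decision lower bound")

  if (!is.null(delta_modularity)) {
    have <- unique(trials$participant_id) %in%
      delta_modularity$participant_id[!is.na(delta_modularity$d_diversity)]
    if (!all(have)) {
      dropped <- unique(trials$participant_id)[!have]
      inform(paste0("excluding participants without modularity values: ",
                    paste(dropped, collapse = ", ")))
      trials <- dplyr::filter(trials,
                              !.data$participant_id %in% dropped)
    }
  }

  pids <- sort(unique(trials$participant_id))
  P <- length(pids)
  if (is.null(items)) {
    if (!all(c("addend_a", "addend_b") %in% names(trials)))
      abort("supply `items` or include addend_a/addend_b in `trials`")
    items <- trials |>
      dplyr::distinct(.data$item_id, .data$addend_a, .data$addend_b) |>
      mutate(n_k = pmin(.data$addend_a, .data$addend_b)) |>
      dplyr::arrange(.data$item_id)
  }
  item_ids <- items$item_id
  K <- length(item_ids)

  part <- match(trials$participant_id, pids) - 1L
  sess <- as.integer(trials$session == "post")
  item <- match(trials$item_id, item_ids) - 1L
  up <- as.integer(trials$response_correct)
  nk <- as.integer(items$n_k)

  ddiv <- numeric(0)
  if (!is.null(delta_modularity)) {
    dd <- delta_modularity[match(pids, delta_modularity$participant_id), ]
    ddiv <- dd$d_diversity
  }

  ctrl <- unclass(prior)
  cols <- model_par_cols(type)
  par_names <- c(
    as.vector(t(outer(pids, cols, function(p, c) paste0(c, "[", p, "]")))),
    if (type >= 1) paste0("rho_item[", item_ids, "]"),
    as.vector(rbind(paste0("mu_", cols[seq_len(if (type == 2) 8 else 4)]),
                    paste0("sd_", cols[seq_len(if (type == 2) 8 else 4)]))),
    if (type >= 1) c("mu_rho_item", "sd_rho_item"),
    if (length(ddiv) > 0) c("beta0", beta_par_names(), "sigma_div")
  )
  # participant-block names come out column-major from outer; rebuild
  par_names_part <- unlist(lapply(pids, function(p) paste0(cols, "[", p, "]")))
  par_names[seq_along(par_names_part)] <- par_names_part

  chains <- vector("list", config$n_chains)
  waic_acc <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 1000L * ch)
    th0 <- init_theta(type, pids, trials, prior)
    rk0 <- rnorm(max(K, 1), 0, 0.1)
    res <- fit_chain_cpp(part, sess, item, trials$rt, up, nk, P, K, type,
                         th0, rk0, config$n_samples, config$burn_in,
                         config$thinning, ctrl, ddiv, compute_waic)
    colnames(res$draws) <- par_names
    chains[[ch]] <- res$draws
    if (compute_waic)
      waic_acc[[ch]] <- res[c("waic_lse", "waic_mean", "waic_m2",
                              "waic_count")]
  }
  n_keep <- nrow(chains[[1]])
  draws <- array(NA_real_, dim = c(config$n_chains, n_keep,
                                   length(par_names)),
                 dimnames = list(chain = NULL, draw = NULL,
                                 parameter = par_names))
  for (ch in seq_len(config$n_chains)) draws[ch, , ] <- chains[[ch]]

  waic <- if (compute_waic) combine_waic(waic_acc) else NULL

  fit <- structure(list(
    draws = draws, model = model, type = type, config = config,
    prior = prior, participants = pids, items = items,
    trials = trials, joint = length(ddiv) > 0,
    delta_modularity = if (length(ddiv) > 0)
      tibble(participant_id = pids, d_diversity = ddiv) else NULL,
    waic = waic
  ), class = if (length(ddiv) > 0) c("joint_fit", "strategy_fit")
     else "strategy_fit")
  fit$diagnostics <- convergence_diagnostics(fit)
  fit$converged <- all(fit$diagnostics$rhat < 1.1, na.rm = TRUE)
  if (!fit$converged)
    warn(sprintf("convergence not reached: max split-Rhat = %.3f",
                 max(fit$diagnostics$rhat, na.rm = TRUE)))
  fit
}

combine_waic <- function(acc) {
  S <- sum(vapply(acc, function(a) a$waic_count, numeric(1)))
  lse <- do.call(cbind, lapply(acc, function(a) a$waic_lse))
  lse_tot <- apply(lse, 1, function(v) {
    m <- max(v); m + log(sum(exp(v - m)))
  })
  # pool Welford accumulators across chains
  means <- do.call(cbind, lapply(acc, function(a) a$waic_mean))
  m2 <- do.call(cbind, lapply(acc, function(a) a$waic_m2))
  ns <- vapply(acc, function(a) a$waic_count, numeric(1))
  gm <- as.vector(means %*% ns) / S
  tss <- rowSums(m2) + (means - gm)^2 %*% ns
  var_t <- as.vector(tss) / (S - 1)
  lppd_t <- lse_tot - log(S)
  elpd_t <- lppd_t - var_t
  list(waic = -2 * sum(elpd_t), lppd = sum(lppd_t),
       p_waic = sum(var_t), se = 2 * sqrt(length(elpd_t) * var(elpd_t)),
       pointwise = tibble(lppd = lppd_t, p_waic = var_t))
}

split_rhat <- function(mat) {
  # mat: chains x draws for one parameter
  n <- ncol(mat)
  half <- floor(n / 2)
  sub <- rbind(mat[, seq_len(half), drop = FALSE],
               mat[, (n - half + 1):n, drop = FALSE])
  m <- nrow(sub); nn <- ncol(sub)
  mu <- rowMeans(sub)
  W <- mean(apply(sub, 1, var))
  B <- nn * var(mu)
  if (W == 0) return(ifelse(B == 0, 1, Inf))
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_basic <- function(mat) {
  # combined effective sample size via Geyer initial positive sequence
  m <- nrow(mat); n <- ncol(mat)
  if (n < 4) return(NA_real_)
  W <- mean(apply(mat, 1, var))
  if (W == 0) return(NA_real_)
  max_lag <- min(n - 2, 500)
  rho <- rep(0, max_lag + 1)
  acs <- lapply(seq_len(m), function(c)
    acf(mat[c, ], lag.max = max_lag, plot = FALSE,
        demean = TRUE)$acf[, 1, 1] * var(mat[c, ]))
  varplus <- split_var_plus(mat, W)
  for (l in 0:max_lag)
    rho[l + 1] <- 1 - (W - mean(vapply(acs, `[`, numeric(1), l + 1))) /
      varplus
  # Geyer: sum consecutive pairs while positive
  s <- 0; t <- 1
  while (t + 1 <= max_lag + 1) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  tau_int <- max(-1 + 2 * s, 1 / (m * n))
  min(m * n / tau_int, m * n)
}

split_var_plus <- function(mat, W) {
  n <- ncol(mat)
  if (nrow(mat) < 2) return(W)
  mu <- rowMeans(mat)
  B <- n * var(mu)
  (n - 1) / n * W + B / n
}

#' Convergence diagnostics
#'
#' Split-Rhat and effective sample size per parameter, with a pass flag
#' at Rhat < 1.1. With a single chain Rhat is unavailable and only ESS
#' is reported.
#'
#' @param fit a `strategy_fit`, or a chains x draws x parameters array.
#' @return tibble with `parameter`, `rhat`, `ess`, `ok`.
#' @export
convergence_diagnostics <- function(fit) {
  draws <- if (inherits(fit, "strategy_fit")) fit$draws else fit
  pn <- dimnames(draws)[[3]]
  single <- dim(draws)[1] < 2
  out <- purrr::map(seq_along(pn), function(j) {
    mat <- draws[, , j, drop = FALSE]
    dim(mat) <- dim(draws)[1:2]
    tibble(parameter = pn[j],
           rhat = if (single) NA_real_ else split_rhat(mat),
           ess = ess_basic(mat))
  }) |> dplyr::bind_rows()
  out$ok <- is.na(out$rhat) | out$rhat < 1.1
  out
}

#' @export
print.strategy_fit <- function(x, ...) {
  cat("Hierarchical strategy-mixture fit (model:", x$model, ")\n")
  cat(sprintf("  %d participants, %d trials, %d items\n",
              length(x$participants), nrow(x$trials), nrow(x$items)))
  cat(sprintf("  %d chains x %d retained draws; converged: %s\n",
              dim(x$draws)[1], dim(x$draws)[2], x$converged))
  if (!is.null(x$waic))
    cat(sprintf("  WAIC: %.1f (p_waic %.1f)\n", x$waic$waic, x$waic$p_waic))
  invisible(x)
}

#' @rdname tidy
#' @param parameters optional regular expression to select parameters.
#' @export
tidy.strategy_fit <- function(x, parameters = NULL, ...) {
  pn <- dimnames(x$draws)[[3]]
  keep <- if (is.null(parameters)) seq_along(pn) else grep(parameters, pn)
  purrr::map(keep, function(j) {
    v <- as.vector(x$draws[, , j])
    tibble(parameter = pn[j], median = median(v), mean = mean(v),
           sd = sd(v), q2.5 = quantile(v, 0.025),
           q97.5 = quantile(v, 0.975))
  }) |>
    dplyr::bind_rows() |>
    dplyr::left_join(x$diagnostics, by = "parameter")
}

#' @rdname glance
#' @export
glance.strategy_fit <- function(x, ...) {
  tibble(model = x$model, n_participants = length(x$participants),
         n_trials = nrow(x$trials), n_chains = dim(x$draws)[1],
         n_draws = dim(x$draws)[2],
         max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
         min_ess = min(x$diagnostics$ess, na.rm = TRUE),
         converged = x$converged,
         waic = if (is.null(x$waic)) NA_real_ else x$waic$waic)
}

posterior_median <- function(fit, name) {
  median(fit$draws[, , name])
}

#' Posterior-median individual parameters
#'
#' Extracts the per-participant, per-session posterior medians in the
#' long parameter format consumed by [trial_likelihood()] and
#' [strategy_responsibility()].
#'
#' @param fit a fitted `strategy_fit` with `model = "mixture"`.
#' @return long tibble `participant_id`, `session`, `rho_i`, `delta_m`,
#'   `delta_c`, `alpha`, `tau`, `tau_switch`.
#' @export
participant_params <- function(fit) {
  if (fit$model != "mixture")
    abort("participant_params needs the full mixture model")
  med <- function(nm) vapply(fit$participants, function(p)
    posterior_median(fit, paste0(nm, "[", p, "]")), numeric(1))
  pre <- tibble(participant_id = fit$participants, session = "pre",
                rho_i = med("rho_pre"), delta_m = med("delta_m_pre"),
                delta_c = med("delta_c_pre"), alpha = med("alpha_pre"),
                tau = med("tau"), tau_switch = med("tau_switch_pre"))
  post <- tibble(participant_id = fit$participants, session = "post",
                 rho_i = med("rho_pre") + med("rho_change"),
                 delta_m = med("delta_m_pre") + med("delta_m_change"),
                 delta_c = med("delta_c_pre") + med("delta_c_change"),
                 alpha = med("alpha_pre") + med("alpha_change"),
                 tau = med("tau"), tau_switch = med("tau_switch_post"))
  dplyr::bind_rows(pre, post) |>
    mutate(session = factor(.data$session, levels = c("pre", "post")))
}

#' Item parameter posterior medians
#'
#' @param fit a fitted `strategy_fit` with item effects.
#' @return the fit's item table with a `rho_k` column of posterior
#'   medians.
#' @export
item_params <- function(fit) {
  if (fit$type < 1) abort("this model has no item parameters")
  fit$items |>
    mutate(rho_k = vapply(.data$item_id, function(k)
      posterior_median(fit, paste0("rho_item[", k, "]")), numeric(1)))
}

#' Posterior-predictive check
#'
#' Simulates replicate datasets from randomly selected posterior draws
#' (strategy selection followed by Euler-Maruyama diffusion) and compares
#' per participant-session predicted mean reaction time and error rate
#' with the observed values, including a coverage summary of the
#' predictive intervals.
#'
#' @param fit a fitted mixture `strategy_fit`.
#' @param n_rep number of replicate datasets.
#' @param dt simulation step, seconds.
#' @param seed RNG seed.
#' @param level interval coverage level.
#' @return tibble per participant-session with observed and predicted
#'   summaries; coverage proportions in attribute `"coverage"`.
#' @export
posterior_predictive <- function(fit, n_rep = 50, dt = 1e-3, seed = 1,
                                 level = 0.95) {
  if (fit$model != "mixture")
    abort("posterior_predictive is implemented for the mixture model")
  set.seed(seed)
  trials <- fit$trials
  items <- item_params(fit)
  n_chain <- dim(fit$draws)[1]; n_draw <- dim(fit$draws)[2]
  pick_ch <- sample.int(n_chain, n_rep, replace = TRUE)
  pick_dr <- sample.int(n_draw, n_rep, replace = TRUE)
  lo <- (1 - level) / 2

  sims <- purrr::map(seq_len(n_rep), function(r) {
    g <- function(nm) fit$draws[pick_ch[r], pick_dr[r],
                                paste0(nm, "[", fit$participants, "]")]
    pars <- dplyr::bind_rows(
      tibble(participant_id = fit$participants, session = "pre",
             rho_i = g("rho_pre"), delta_m = g("delta_m_pre"),
             delta_c = g("delta_c_pre"), alpha = g("alpha_pre"),
             tau = g("tau"), tau_switch = g("tau_switch_pre")),
      tibble(participant_id = fit$participants, session = "post",
             rho_i = g("rho_pre") + g("rho_change"),
             delta_m = g("delta_m_pre") + g("delta_m_change"),
             delta_c = g("delta_c_pre") + g("delta_c_change"),
             alpha = g("alpha_pre") + g("alpha_change"),
             tau = g("tau"), tau_switch = g("tau_switch_post")))
    rk <- fit$draws[pick_ch[r], pick_dr[r],
                    paste0("rho_item[", items$item_id, "]")]
    it <- mutate(items, rho_k = unname(rk))
    df <- trials |>
      dplyr::select("participant_id", "session", "item_id") |>
      dplyr::inner_join(pars, by = c("participant_id", "session")) |>
      dplyr::inner_join(it, by = "item_id") |>
      mutate(
        p_memory = p_memory_retrieval(.data$rho_i, .data$rho_k),
        mem = runif(dplyr::n()) < .data$p_memory,
        drift = ifelse(.data$mem,
                       memory_drift_rate(.data$delta_m, .data$rho_k),
                       counting_drift_rate(.data$delta_c, .data$n_k)),
        t0 = .data$tau + ifelse(.data$mem, 0, .data$tau_switch))
    sim <- rwiener_em_cpp(df$alpha, df$drift, df$t0,
                          rep(0.5, nrow(df)), dt, 12)
    df |>
      mutate(rt = sim$rt, correct = sim$upper == 1L, rep = r) |>
      group_by(.data$participant_id, .data$session) |>
      summarise(mean_rt = mean(.data$rt, na.rm = TRUE),
                error_rate = mean(!.data$correct, na.rm = TRUE),
                rep = r, .groups = "drop")
  }) |> dplyr::bind_rows()

  pred <- sims |>
    group_by(.data$participant_id, .data$session) |>
    summarise(pred_mean_rt = mean(.data$mean_rt),
              rt_lo = quantile(.data$mean_rt, lo),
              rt_hi = quantile(.data$mean_rt, 1 - lo),
              pred_error_rate = mean(.data$error_rate),
              er_lo = quantile(.data$error_rate, lo),
              er_hi = quantile(.data$error_rate, 1 - lo),
              .groups = "drop")
  obs <- trials |>
    group_by(.data$participant_id, .data$session) |>
    summarise(obs_mean_rt = mean(.data$rt),
              obs_error_rate = mean(!.data$response_correct),
              .groups = "drop")
  out <- dplyr::inner_join(obs, pred, by = c("participant_id", "session"))
  attr(out, "coverage") <- c(
    rt = mean(out$obs_mean_rt >= out$rt_lo & out$obs_mean_rt <= out$rt_hi),
    error_rate = mean(out$obs_error_rate >= out$er_lo &
                        out$obs_error_rate <= out$er_hi))
  class(out) <- c("posterior_predictive", class(out))
  out
}

#' Compare the mixture model against control models
#'
#' Fits the full strategy-dissociation model, a single-strategy model
#' with item difficulty, and a simple drift-diffusion model, and ranks
#' them by WAIC (computed from the pointwise log-likelihood of the
#' posterior draws).
#'
#' @param trials preprocessed trial tibble.
#' @param config a [fit_config()].
#' @param prior a [prior_spec()].
#' @return tibble `model`, `waic`, `p_waic`, `se`, `rank`, `converged`,
#'   of class `model_comparison`.
#' @export
compare_models <- function(trials, config = fit_config(profile = "ci"),
                           prior = prior_spec()) {
  trials <- dplyr::filter(trials, !is.na(.data$rt))
  if (nrow(trials) < 10)
    abort("too few valid trials for model comparison")
  fits <- purrr::map(c("simple", "single", "mixture"), function(m)
    suppressWarnings(
      fit_hierarchical(trials, config = config, prior = prior, model = m)))
  out <- purrr::map(fits, function(f)
    tibble(model = f$model, waic = f$waic$waic, p_waic = f$waic$p_waic,
           se = f$waic$se, converged = f$converged)) |>
    dplyr::bind_rows() |>
    mutate(rank = rank(.data$waic, ties.method = "first")) |>
    dplyr::arrange(.data$rank)
  class(out) <- c("model_comparison", class(out))
  out
}

#' Joint brain-behaviour latent-regression model
#'
#' Extends the hierarchical mixture model with a latent regression of a
#' per-participant brain-network change score (e.g. the change in the
#' right rostral hippocampus diversity coefficient) on the cohort-
#' centered changes in all individual model parameters, fitted jointly.
#' Savage-Dickey Bayes factors are computed for each slope against the
#' point null of zero.
#'
#' @inheritParams fit_hierarchical
#' @param delta_modularity tibble `participant_id`, `d_diversity`.
#' @return a `joint_fit` (a `strategy_fit` with a `betas` summary).
#' @export
fit_joint_brain_model <- function(trials, delta_modularity,
                                  config = fit_config(),
                                  prior = prior_spec()) {
  fit <- fit_hierarchical(trials, config = config, prior = prior,
                          model = "mixture",
                          delta_modularity = delta_modularity)
  fit$betas <- joint_beta_summary(fit)
  fit
}

joint_beta_summary <- function(fit) {
  purrr::map(beta_par_names(), function(nm) {
    v <- as.vector(fit$draws[, , nm])
    sd_res <- savage_dickey_bf(v, prior_sd = fit$prior$beta_prior_sd)
    tibble(parameter = sub("^beta\\[(.*)\\]$", "\\1", nm),
           median = median(v), q2.5 = quantile(v, 0.025),
           q97.5 = quantile(v, 0.975), bf = sd_res$bf,
           bf_normal = sd_res$bf_normal, evidence = sd_res$evidence)
  }) |> dplyr::bind_rows()
}

#' @rdname tidy
#' @export
tidy.joint_fit <- function(x, parameters = NULL, ...) {
  if (is.null(parameters)) x$betas %||% joint_beta_summary(x)
  else NextMethod()
}

#' Savage-Dickey Bayes factor for a point null at zero
#'
#' BF10 = prior density at zero over posterior density at zero. The
#' posterior density is estimated from the MCMC draws by Gaussian kernel
#' density with Sheather-Jones plug-in bandwidth; a normal approximation
#' (moments of the draws) is always computed as a cross-check and both
#' are reported when they disagree by more than 20%. Evidence labels:
#' BF > 3 moderate evidence for the alternative; 1/3 to 3 insufficient;
#' below 1/3 evidence of absence.
#'
#' @param samples posterior draws of the parameter.
#' @param prior_mean,prior_sd the (normal) prior, whose density at zero
#'   is known in closed form.
#' @return list: `bf` (KDE estimate), `bf_normal`, `evidence`,
#'   `method`, `unstable`.
#' @export
savage_dickey_bf <- function(samples, prior_mean = 0, prior_sd = 1) {
  samples <- samples[is.finite(samples)]
  unstable <- FALSE
  if (length(samples) < 100) {
    warn("few posterior samples: Savage-Dickey density estimate unstable")
    unstable <- TRUE
  }
  prior_at_0 <- dnorm(0, prior_mean, prior_sd)
  bw <- tryCatch(bw.SJ(samples), error = function(e) bw.nrd0(samples))
  dens <- density(samples, bw = bw, n = 1024,
                  from = min(samples, 0) - 3 * bw,
                  to = max(samples, 0) + 3 * bw)
  post_at_0 <- stats::approx(dens$x, dens$y, xout = 0)$y
  if (0 < min(samples) || 0 > max(samples)) {
    warn("zero lies outside the posterior sample range; BF unstable")
    unstable <- TRUE
  }
  post_norm <- dnorm(0, mean(samples), sd(samples))
  bf <- prior_at_0 / post_at_0
  bf_normal <- prior_at_0 / post_norm
  disagree <- is.finite(bf) && is.finite(bf_normal) &&
    abs(log(bf / bf_normal)) > log(1.2)
  evid <- function(b) {
    if (!is.finite(b)) "unstable"
    else if (b > 3) "moderate evidence for H1"
    else if (b < 1 / 3) "evidence of absence"
    else "insufficient evidence"
  }
  list(bf = bf, bf_normal = bf_normal, evidence = evid(bf),
       method = if (disagree) "kde (normal approximation disagrees)"
       else "kde", unstable = unstable)
}

#' Export posterior draws and summaries
#'
#' Draws go to tabular CSV (`chain`, `draw`, `parameter`, `value`);
#' summaries (medians, 95% intervals, Rhat, ESS) to JSON.
#'
#' @param fit a `strategy_fit`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @export
export_posterior <- function(fit, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    pn <- dimnames(fit$draws)[[3]]
    long <- purrr::map(seq_len(dim(fit$draws)[1]), function(ch) {
      m <- fit$draws[ch, , ]
      tibble(chain = ch, draw = rep(seq_len(nrow(m)), times = ncol(m)),
             parameter = rep(pn, each = nrow(m)), value = as.vector(m))
    }) |> dplyr::bind_rows()
    readr::write_csv(long, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(tidy(fit), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(fit)
}
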
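# shared oracles and fixtures, built in code at test time

# enumerate all set partitions of n elements (Bell(n) of them)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (k in seq_len(max(p) + 1L)) out <- c(out, list(c(p, as.integer(k))))
  }
  out
}

# analytic conditional CDF of the strategy mixture at one boundary
mixture_cdf <- function(t, boundary, rho_i, rho_k, delta_m, delta_c, n_k,
                        alpha, tau, tau_switch) {
  p_m <- p_memory_retrieval(rho_i, rho_k)
  vm <- memory_drift_rate(delta_m, rho_k)
  vc <- counting_drift_rate(delta_c, n_k)
  num <- p_m * wiener_cdf(t, boundary, alpha, vm, tau) +
    (1 - p_m) * wiener_cdf(t, boundary, alpha, vc, tau + tau_switch)
  mass <- p_m * wiener_boundary_mass(alpha, vm)$mass[
    c(correct = 1, error = 2)[boundary]] +
    (1 - p_m) * wiener_boundary_mass(alpha, vc)$mass[
      c(correct = 1, error = 2)[boundary]]
  num / mass
}

# simulate the generative two-step process (Bernoulli strategy draw, then
# Euler-Maruyama diffusion) for a single parameter set
simulate_mixture <- function(n, rho_i, rho_k, delta_m, delta_c, n_k,
                             alpha, tau, tau_switch, dt = 1e-4) {
  p_m <- p_memory_retrieval(rho_i, rho_k)
  mem <- runif(n) < p_m
  drift <- ifelse(mem, memory_drift_rate(delta_m, rho_k),
                  counting_drift_rate(delta_c, n_k))
  t0 <- tau + ifelse(mem, 0, tau_switch)
  sim <- retrievalmix:::rwiener_em_cpp(rep(alpha, n), drift, t0,
                                       rep(0.5, n), dt, 30)
  data.frame(rt = sim$rt,
             boundary = ifelse(sim$upper == 1L, "correct", "error"),
             memory = mem)
}

# a small behavioural cohort for fast fitting tests
small_cohort <- function(n_participants = 6, trials = 60, seed = 301) {
  spec <- cohort_spec(n_participants = n_participants,
                      trials_per_session = trials, seed = seed)
  items <- generate_item_bank(spec)
  params <- sample_population(spec)
  trials_df <- preprocess_trials(simulate_behavior(params, items, spec),
                                 quiet = TRUE)
  list(spec = spec, items = items, params = params, trials = trials_df)
}

# long individual-parameter tibble for a single participant-session
one_params <- function(rho_i = 1, delta_m = 1.2, delta_c = 1.5,
                       alpha = 1.5, tau = 0.3, tau_switch = 0.4) {
  tibble::tibble(participant_id = "P01", session = "pre", rho_i = rho_i,
                 delta_m = delta_m, delta_c = delta_c, alpha = alpha,
                 tau = tau, tau_switch = tau_switch)
}

one_trials <- function(rt, correct = TRUE, item_id = "3+4") {
  tibble::tibble(participant_id = "P01", session = "pre",
                 item_id = item_id, response_correct = correct, rt = rt)
}

one_items <- function(rho_k = 0, n_k = 3, item_id = "3+4") {
  tibble::tibble(item_id = item_id, n_k = n_k, rho_k = rho_k)
}
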
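#' Specification of a synthetic pre/post training cohort
#'
#' Bundles every constant of the synthetic study: cohort size, the item
#' bank, the hierarchical population distributions of the individual
#' parameters and their training-related changes, the planted modular
#' structure of the connectivity networks, and the planted coupling
#' between memory-efficiency change and the diversity change of a
#' designated (hippocampal) node.
#'
#' Defaults emulate a 35-child cohort verifying single-digit additions
#' (operands 2-9, response window 9.5 s, 24 scanned trials per session),
#' with training shifts whose standardized sizes match a strong
#' retrieval-efficiency gain, and 30-node signed networks with 2 planted
#' modules before and 3 after training.
#'
#' @param n_participants cohort size.
#' @param trials_per_session trials per participant and session (24 in
#'   the scanner task; recovery studies typically use 200).
#' @param addend_range inclusive operand range of the item bank.
#' @param population named list of `c(mean, sd)` pairs for the pre-level
#'   parameters (`rho`, `delta_m`, `delta_c`, `alpha`, `tau`,
#'   `tau_switch`) and their pre-to-post changes (`d_*`).
#' @param item_mean,item_sd item difficulty distribution.
#' @param network list: `n_nodes`, planted `modules_pre` / `modules_post`
#'   affiliation vectors, `within_mean`, `between_mean`, `noise_sd`, and
#'   `flip_prob` -- the per-node probability that a participant's own
#'   module membership deviates from the group template, which makes the
#'   pre-to-post reorganization distance vary across participants.
#' @param coupling list: `node` (designated node label), `beta` (slope of
#'   diversity change on cohort-centered memory-efficiency change),
#'   `residual_sd`, `div_change_mean` (mean diversity shift of the node).
#' @param max_rt censoring point of the response window, seconds.
#' @param seed integer seed; every generator is deterministic given the
#'   spec (which includes this seed).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 35,
                        trials_per_session = 24,
                        addend_range = c(2, 9),
                        population = list(
                          rho        = c(-0.5, 1.0),
                          d_rho      = c(0.9, 1.0),
                          delta_m    = c(1.2, 0.3),
                          d_delta_m  = c(0.8, 0.33),
                          delta_c    = c(1.5, 0.3),
                          d_delta_c  = c(0.1, 0.2),
                          alpha      = c(1.6, 0.3),
                          d_alpha    = c(-0.1, 0.15),
                          tau        = c(0.30, 0.05),
                          tau_switch = c(0.45, 0.10),
                          d_tau_switch = c(-0.05, 0.10)
                        ),
                        item_mean = 0, item_sd = 1,
                        network = list(
                          n_nodes = 30,
                          modules_pre = rep(c(1, 2), c(18, 12)),
                          modules_post = rep(c(1, 2, 3), c(12, 10, 8)),
                          within_mean = 0.6,
                          between_mean = -0.2,
                          noise_sd = 0.15,
                          flip_prob = 0.08
                        ),
                        coupling = list(
                          node = "R_rHipp",
                          beta = -0.8,
                          residual_sd = 0.1,
                          div_change_mean = -0.15
                        ),
                        max_rt = 9.5,
                        seed = 1) {
  for (nm in names(population))
    if (population[[nm]][2] <= 0)
      abort(sprintf("population sd for `%s` must be positive", nm))
  if (network$noise_sd <= 0) abort("network noise_sd must be positive")
  if (length(network$modules_pre) != network$n_nodes ||
      length(network$modules_post) != network$n_nodes)
    abort("planted partitions must cover all nodes")
  structure(list(n_participants = n_participants,
                 trials_per_session = trials_per_session,
                 addend_range = addend_range, population = population,
                 item_mean = item_mean, item_sd = item_sd,
                 network = network, coupling = coupling,
                 max_rt = max_rt, seed = seed),
            class = "cohort_spec")
}

# default node labels for a 30-node network: 18 cortical + 12 MTL
default_node_labels <- function(n = 30) {
  cortical <- c("L_SPL", "R_SPL", "L_IPS", "R_IPS", "L_AI", "R_AI",
                "L_IFG", "R_IFG", "DMPFC", "L_FEF", "R_FEF", "R_MFG",
                "L_ITG", "R_ITG", "L_LOC", "R_LOC", "L_FG", "R_FG")
  mtl <- c("L_rHipp", "R_rHipp", "L_cHipp", "R_cHipp", "L_EC", "R_EC",
           "L_cPHG", "R_cPHG", "L_mpPHG", "R_mpPHG", "L_lpPHG", "R_lpPHG")
  labs <- c(cortical, mtl)
  if (n <= length(labs)) labs[seq_len(n)] else
    c(labs, paste0("node", seq_len(n - length(labs))))
}

#' Generate the addition item bank
#'
#' All unique unordered addend pairs in the configured range (36 pairs
#' for operands 2-9, ties included), with the count-step number
#' `n_k = min(addend_a, addend_b)` and a group-level retrieval
#' difficulty `rho_k` drawn from the item-level normal distribution.
#'
#' @param spec a [cohort_spec()].
#' @return tibble `item_id`, `addend_a`, `addend_b`, `n_k`, `rho_k`.
#' @export
generate_item_bank <- function(spec) {
  set.seed(spec$seed + 101L)
  rng <- seq(spec$addend_range[1], spec$addend_range[2])
  grid <- expand.grid(addend_a = rng, addend_b = rng)
  grid <- grid[grid$addend_a <= grid$addend_b, ]
  tibble(
    item_id = paste0(grid$addend_a, "+", grid$addend_b),
    addend_a = grid$addend_a, addend_b = grid$addend_b,
    n_k = pmin(grid$addend_a, grid$addend_b),
    rho_k = rnorm(nrow(grid), spec$item_mean, spec$item_sd)
  )
}

rtruncnorm1 <- function(n, mean, sd, lower = -Inf) {
  if (is.finite(lower)) {
    plo <- pnorm(lower, mean, sd)
    if (any(plo > 0.999))
      abort("infeasible truncation: essentially no mass above the bound")
    qnorm(plo + runif(n) * (1 - plo), mean, sd)
  } else rnorm(n, mean, sd)
}

#' Draw ground-truth individual parameters for the cohort
#'
#' Pre-level parameters and pre-to-post changes are drawn from the
#' configured population distributions, with truncation enforcing
#' positivity of efficiencies, threshold and timing parameters (at both
#' sessions).
#'
#' @param spec a [cohort_spec()].
#' @return tibble in long participant-session format with columns
#'   `participant_id`, `session`, `rho_i`, `delta_m`, `delta_c`, `alpha`,
#'   `tau`, `tau_switch`; the per-participant change table is attached as
#'   attribute `"changes"`.
#' @export
sample_population <- function(spec) {
  set.seed(spec$seed + 202L)
  P <- spec$n_participants
  pop <- spec$population
  draw <- function(nm, lower = -Inf) rtruncnorm1(P, pop[[nm]][1], pop[[nm]][2], lower)
  rho0 <- draw("rho")
  drho <- draw("d_rho")
  dm0 <- draw("delta_m", 0); dc0 <- draw("delta_c", 0)
  a0 <- draw("alpha", 0)
  # changes truncated so post-training values stay positive
  dmd <- pmax(draw("d_delta_m"), -dm0 + 0.05)
  dcd <- pmax(draw("d_delta_c"), -dc0 + 0.05)
  ad <- pmax(draw("d_alpha"), -a0 + 0.1)
  tau <- pmax(draw("tau", 0), 0.12)
  tc0 <- draw("tau_switch", 0)
  dtc <- pmax(draw("d_tau_switch"), -tc0)
  ids <- sprintf("P%02d", seq_len(P))
  changes <- tibble(participant_id = ids, d_rho = drho, d_delta_m = dmd,
                    d_delta_c = dcd, d_alpha = ad, d_tau_switch = dtc)
  long <- dplyr::bind_rows(
    tibble(participant_id = ids, session = "pre", rho_i = rho0,
           delta_m = dm0, delta_c = dc0, alpha = a0, tau = tau,
           tau_switch = tc0),
    tibble(participant_id = ids, session = "post", rho_i = rho0 + drho,
           delta_m = dm0 + dmd, delta_c = dc0 + dcd, alpha = a0 + ad,
           tau = tau, tau_switch = tc0 + dtc)
  ) |>
    mutate(session = factor(.data$session, levels = c("pre", "post")))
  attr(long, "changes") <- changes
  long
}

#' Simulate verification trials from the generative two-step process
#'
#' For each trial a strategy is drawn (Bernoulli with the logistic
#' retrieval probability) and the reaction time and boundary are then
#' simulated from the corresponding diffusion by Euler-Maruyama
#' simulation -- deliberately independent of the analytic density used
#' for inference. Counting trials start after the additional switching
#' time. Reaction times are censored at the response window.
#'
#' @param params long participant-session parameter tibble
#'   (see [sample_population()]).
#' @param items item bank from [generate_item_bank()].
#' @param spec a [cohort_spec()].
#' @param dt Euler-Maruyama step, seconds.
#' @return trial tibble with the observed columns (`participant_id`,
#'   `session`, `item_id`, `addend_a`, `addend_b`, `equation_valid`,
#'   `response_correct`, `rt`) plus ground-truth `true_strategy` and a
#'   `censored` flag.
#' @export
simulate_behavior <- function(params, items, spec, dt = 1e-4) {
  set.seed(spec$seed + 303L)
  n_tr <- spec$trials_per_session
  df <- params |>
    dplyr::reframe(item_id = sample(items$item_id, n_tr, replace = TRUE),
                   .by = c("participant_id", "session")) |>
    dplyr::inner_join(params, by = c("participant_id", "session")) |>
    dplyr::inner_join(items, by = "item_id") |>
    mutate(
      equation_valid = runif(dplyr::n()) < 0.5,
      p_memory = p_memory_retrieval(.data$rho_i, .data$rho_k),
      true_strategy = ifelse(runif(dplyr::n()) < .data$p_memory,
                             "memory", "counting"),
      drift = ifelse(.data$true_strategy == "memory",
                     memory_drift_rate(.data$delta_m, .data$rho_k),
                     counting_drift_rate(.data$delta_c, .data$n_k)),
      t0 = .data$tau + ifelse(.data$true_strategy == "counting",
                              .data$tau_switch, 0)
    )
  sim <- rwiener_em_cpp(df$alpha, df$drift, df$t0, rep(0.5, nrow(df)),
                        dt, spec$max_rt + 1)
  df |>
    mutate(
      rt = sim$rt,
      response_correct = sim$upper == 1L,
      censored = is.na(.data$rt) | .data$rt > spec$max_rt,
      rt = ifelse(.data$censored, NA_real_, .data$rt),
      response_correct = ifelse(.data$censored, NA, .data$response_correct)
    ) |>
    dplyr::select("participant_id", "session", "item_id", "addend_a",
                  "addend_b", "equation_valid", "response_correct", "rt",
                  "true_strategy", "censored")
}

# diversity of one node (positive channel) given weights to all nodes
node_diversity_from_weights <- function(w, affiliation) {
  wp <- pmax(w, 0)
  s <- tapply(wp, affiliation, sum)
  tot <- sum(s)
  m <- length(unique(affiliation))
  if (tot <= 0 || m < 2) return(0)
  p <- s / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(m)
}

#' Simulate pre/post signed connectivity matrices with planted structure
#'
#' Block-structured signed matrices (2 planted modules before training, 3
#' after), Gaussian edge noise, symmetrized with zero diagonal. The
#' designated node (default the right rostral hippocampus) has mildly
#' positive between-module edges, and its post-training between-module
#' strength is rescaled so that its diversity-coefficient change equals
#' `div_change_mean + beta * centered(d_delta_m) + residual noise` --
#' the planted brain-behaviour coupling.
#'
#' @param spec a [cohort_spec()].
#' @param changes per-participant change table (attribute of
#'   [sample_population()]); needs `participant_id` and `d_delta_m`.
#' @return list with `matrices` (named list `participant_id` ->
#'   list(pre, post) of matrices), `truth` (tibble of planted diversity
#'   values/changes per participant), and planted partitions.
#' @export
simulate_networks <- function(spec, changes) {
  set.seed(spec$seed + 404L)
  net <- spec$network
  n <- net$n_nodes
  labels <- default_node_labels(n)
  node_idx <- match(spec$coupling$node, labels)
  if (is.na(node_idx)) abort("coupling node not among node labels")
  pre_aff <- net$modules_pre
  post_aff <- net$modules_post
  flip <- net$flip_prob %||% 0.08
  # participant-level deviation from the group partition template; the
  # designated node keeps its template membership so the planted
  # diversity coupling stays well defined
  jitter_aff <- function(aff) {
    mods <- unique(aff)
    repeat {
      a <- aff
      for (v in seq_along(a)) {
        if (v == node_idx) next
        if (runif(1) < flip) a[v] <- sample(setdiff(mods, a[v]), 1)
      }
      if (length(unique(a)) == length(mods)) return(a)
    }
  }
  dM <- changes$d_delta_m
  dM_c <- dM - mean(dM)
  target_change <- spec$coupling$div_change_mean +
    spec$coupling$beta * dM_c +
    rnorm(length(dM), 0, spec$coupling$residual_sd)

  block_matrix <- function(aff) {
    W <- matrix(0, n, n)
    same <- outer(aff, aff, "==")
    mu <- ifelse(same, net$within_mean, net$between_mean)
    # designated node: mildly positive diverse between-module edges
    mu[node_idx, ] <- ifelse(same[node_idx, ], net$within_mean, 0.09)
    mu[, node_idx] <- mu[node_idx, ]
    up <- upper.tri(W)
    W[up] <- mu[up] + rnorm(sum(up), 0, net$noise_sd)
    W <- W + t(W)
    diag(W) <- 0
    dimnames(W) <- list(labels, labels)
    W
  }

  mats <- list()
  part_i <- list()
  truth <- vector("list", nrow(changes))
  for (i in seq_len(nrow(changes))) {
    pre_aff_i <- jitter_aff(pre_aff)
    post_aff_i <- jitter_aff(post_aff)
    Wpre <- block_matrix(pre_aff_i)
    Wpost <- block_matrix(post_aff_i)
    div_pre <- node_diversity_from_weights(Wpre[node_idx, ], pre_aff_i)
    tgt <- div_pre + target_change[i]
    clipped <- FALSE
    if (tgt < 0 || tgt > 1) {
      warn("requested diversity change outside [0, 1]; clipped")
      tgt <- min(max(tgt, 0.001), 0.999)
      clipped <- TRUE
    }
    # Rescale the node's between-module edges to hit the target diversity
    # under the planted post partition. Diversity first rises with the
    # scale factor, peaks, then falls towards the between-module-only
    # entropy, so the root is taken on the rising branch below the peak.
    between <- post_aff_i != post_aff_i[node_idx]
    h_of <- function(logc) {
      w <- Wpost[node_idx, ]
      w[between] <- w[between] * exp(logc)
      node_diversity_from_weights(w, post_aff_i)
    }
    peak <- stats::optimize(h_of, c(-8, 8), maximum = TRUE)
    if (tgt > peak$objective) {
      warn("target diversity unreachable by rescaling; clipped to the maximum")
      tgt <- peak$objective - 1e-3
      clipped <- TRUE
    }
    lo_val <- h_of(-8)
    if (tgt < lo_val) {
      warn("target diversity unreachable by rescaling; clipped to the minimum")
      tgt <- lo_val + 1e-3
      clipped <- TRUE
    }
    logc <- uniroot(function(z) h_of(z) - tgt, c(-8, peak$maximum),
                    tol = 1e-10)$root
    Wpost[node_idx, between] <- Wpost[node_idx, between] * exp(logc)
    Wpost[between, node_idx] <- Wpost[node_idx, between]
    div_post <- node_diversity_from_weights(Wpost[node_idx, ], post_aff_i)
    id <- changes$participant_id[i]
    mats[[id]] <- list(pre = Wpre, post = Wpost)
    part_i[[id]] <- list(pre = pre_aff_i, post = post_aff_i)
    truth[[i]] <- tibble(participant_id = id, div_pre = div_pre,
                         div_post = div_post,
                         d_diversity = div_post - div_pre,
                         target_change = target_change[i],
                         clipped = clipped)
  }
  list(matrices = mats, truth = dplyr::bind_rows(truth),
       partition_pre = pre_aff, partition_post = post_aff,
       participant_partitions = part_i,
       node_labels = labels, coupling_node = spec$coupling$node)
}

#' Simulate ROI time series with task-gated coupling
#'
#' Autocorrelated (AR(1)) node noise plus, for each coupled node pair, a
#' task-modulated linear influence `g * task_t * seed_t` of the seed on
#' the target, the planted interaction weight that the PPI regression
#' should recover. The task indicator alternates +1 (task) / -1
#' (control) blocks separated by rest (0) samples.
#'
#' @param n_nodes number of regions.
#' @param n_time number of time points.
#' @param block_length samples per task block.
#' @param couplings tibble with `seed`, `target`, `g` (planted
#'   interaction weights); may be empty.
#' @param ar autoregressive coefficient of the node noise.
#' @param rest_length rest samples between blocks.
#' @param seed RNG seed.
#' @return list with `timeseries` (time x node matrix) and
#'   `task` (indicator vector).
#' @export
simulate_roi_timeseries <- function(n_nodes, n_time, block_length = 20,
                                    couplings = NULL, ar = 0.3,
                                    rest_length = 0, seed = 1) {
  set.seed(seed)
  cycle <- c(rep(1, block_length), rep(0, rest_length),
             rep(-1, block_length), rep(0, rest_length))
  task <- rep_len(cycle, n_time)
  X <- matrix(0, n_time, n_nodes)
  for (j in seq_len(n_nodes)) {
    e <- rnorm(n_time)
    X[, j] <- as.numeric(stats::filter(e, ar, method = "recursive"))
  }
  if (!is.null(couplings) && nrow(couplings) > 0) {
    for (r in seq_len(nrow(couplings)))
      X[, couplings$target[r]] <- X[, couplings$target[r]] +
        couplings$g[r] * task * X[, couplings$seed[r]]
  }
  colnames(X) <- default_node_labels(n_nodes)
  list(timeseries = X, task = task)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running the behavioural and network generators in
#' sequence with a shared spec.
#'
#' @param spec a [cohort_spec()].
#' @return list with `items`, `params` (ground truth), `changes`,
#'   `trials`, and `networks`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  items <- generate_item_bank(spec)
  params <- sample_population(spec)
  changes <- attr(params, "changes")
  trials <- simulate_behavior(params, items, spec)
  networks <- simulate_networks(spec, changes)
  list(spec = spec, items = items, params = params, changes = changes,
       trials = trials, networks = networks)
}
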
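#' Probability of selecting the memory-retrieval strategy
#'
#' Logistic strategy-selection probability for an individual with
#' retrieval propensity `rho_i` facing an item with retrieval difficulty
#' `rho_k`. The counting probability is its complement.
#'
#' @param rho_i individual retrieval propensity.
#' @param rho_k item retrieval difficulty.
#' @return probability in \[0, 1\]; vectorised.
#' @examples
#' p_memory_retrieval(0, 0)    # 0.5
#' p_memory_retrieval(1, 0)    # 0.731...
#' @export
p_memory_retrieval <- function(rho_i, rho_k) {
  stopifnot(is.numeric(rho_i), is.numeric(rho_k))
  stats::plogis(rho_i - rho_k)
}

#' Item-level memory-retrieval drift rate
#'
#' The individual's retrieval efficiency attenuated by the item's
#' retrieval difficulty: `delta_m / (1 + exp(rho_k))`. Strictly
#' decreasing in `rho_k` and bounded above by `delta_m`.
#'
#' @param delta_m individual memory-retrieval efficiency (> 0).
#' @param rho_k item retrieval difficulty.
#' @export
memory_drift_rate <- function(delta_m, rho_k) {
  if (any(delta_m <= 0)) abort("`delta_m` must be positive.")
  delta_m * stats::plogis(-rho_k)
}

#' Item-level counting drift rate
#'
#' Min-counting: counting starts from the larger addend and counts up the
#' smaller addend `n_k` steps, so the counting drift is `delta_c / n_k`.
#'
#' @param delta_c individual counting efficiency (> 0).
#' @param n_k number of count steps (the smaller addend, >= 1).
#' @export
counting_drift_rate <- function(delta_c, n_k) {
  if (any(delta_c <= 0)) abort("`delta_c` must be positive.")
  if (any(n_k < 1)) abort("`n_k` must be >= 1.")
  delta_c / n_k
}

# join trials with individual and item parameters and compute the
# per-trial mixture components; internal workhorse
mixture_components <- function(trials, params, items) {
  need <- c("participant_id", "session", "item_id", "response_correct", "rt")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0)
    abort(paste0("`trials` is missing columns: ", paste(miss, collapse = ", ")))
  if (!"bias" %in% names(params)) params$bias <- 0.5
  df <- trials |>
    dplyr::inner_join(params, by = c("participant_id", "session")) |>
    dplyr::inner_join(dplyr::select(items, "item_id", "n_k", "rho_k"),
                      by = "item_id")
  if (nrow(df) < nrow(trials))
    warn("some trials had no matching parameters or item and were dropped")
  df |>
    mutate(
      p_memory = p_memory_retrieval(.data$rho_i, .data$rho_k),
      drift_memory = memory_drift_rate(.data$delta_m, .data$rho_k),
      drift_counting = counting_drift_rate(.data$delta_c, .data$n_k),
      lik_memory = ifelse(
        is.na(.data$rt), NA_real_,
        mapply(function(rt, ok, a, v, t0, w)
          wiener_pdf_cpp(rt, a, v, t0, w, as.integer(ok), 1e-10),
          .data$rt, .data$response_correct, .data$alpha,
          .data$drift_memory, .data$tau, .data$bias)),
      lik_counting = ifelse(
        is.na(.data$rt), NA_real_,
        mapply(function(rt, ok, a, v, t0, w)
          wiener_pdf_cpp(rt, a, v, t0, w, as.integer(ok), 1e-10),
          .data$rt, .data$response_correct, .data$alpha,
          .data$drift_counting, .data$tau + .data$tau_switch, .data$bias))
    )
}

#' Per-trial mixture likelihood
#'
#' Likelihood of each trial's (correctness, reaction time) pair under the
#' two-strategy mixture: the strategy-selection probability times the
#' Wiener density of the corresponding diffusion, summed over strategies.
#' The counting diffusion starts after the additional strategy-switching
#' time, so its non-decision time is `tau + tau_switch`.
#'
#' @param trials tibble with columns `participant_id`, `session`,
#'   `item_id`, `response_correct` (logical), `rt` (seconds; `NA` =
#'   missing, excluded from the likelihood).
#' @param params tibble of individual parameters per participant-session:
#'   `participant_id`, `session`, `rho_i`, `delta_m`, `delta_c`, `alpha`,
#'   `tau`, `tau_switch` (and optionally `bias`, default 0.5).
#' @param items tibble with `item_id`, `n_k`, `rho_k`.
#' @param log return log-likelihoods?
#' @return the trials tibble with a `likelihood` column (`NA` for
#'   missing-RT trials) plus the mixture components.
#' @export
trial_likelihood <- function(trials, params, items, log = FALSE) {
  df <- mixture_components(trials, params, items) |>
    mutate(likelihood = .data$p_memory * .data$lik_memory +
             (1 - .data$p_memory) * .data$lik_counting)
  if (log) df$likelihood <- base::log(df$likelihood)
  df |>
    dplyr::select(dplyr::all_of(names(trials)), "p_memory",
                  "lik_memory", "lik_counting", "likelihood")
}

#' Posterior probability that a trial used memory retrieval
#'
#' Trial-level strategy responsibility: the memory component of the
#' mixture likelihood normalised by the total. Trials faster than the
#' counting non-decision floor (`tau + tau_switch`) are necessarily
#' retrieval trials (responsibility 1).
#'
#' @inheritParams trial_likelihood
#' @return the trials tibble with a `responsibility` column in \[0, 1\]
#'   (`NA` with a warning where both components have zero likelihood, and
#'   for missing-RT trials).
#' @export
strategy_responsibility <- function(trials, params, items) {
  df <- mixture_components(trials, params, items) |>
    mutate(
      num = .data$p_memory * .data$lik_memory,
      den = .data$num + (1 - .data$p_memory) * .data$lik_counting,
      responsibility = ifelse(.data$den > 0, .data$num / .data$den, NA_real_)
    )
  bad <- !is.na(df$rt) & !is.na(df$den) & df$den == 0
  if (any(bad))
    warn(sprintf("%d trial(s) had zero likelihood under both strategies; responsibility set to NA",
                 sum(bad)))
  df |>
    dplyr::select(dplyr::all_of(names(trials)), "p_memory", "responsibility")
}

#' Participant-level summary of memory-retrieval strategy use
#'
#' Summarises trial-level responsibilities into one retrieval-use value
#' per participant and session: either the mean responsibility over valid
#' trials (default, continuous) or the fraction of trials classified as
#' retrieval at a 0.5 cutoff.
#'
#' @inheritParams trial_likelihood
#' @param method `"mean"` (mean responsibility) or `"classify"`
#'   (proportion with responsibility > 0.5).
#' @return tibble with `participant_id`, `session`, `retrieval_use`,
#'   `n_trials` (valid trials used; `retrieval_use` is `NA` when none).
#' @export
retrieval_use_summary <- function(trials, params, items,
                                  method = c("mean", "classify")) {
  method <- match.arg(method)
  strategy_responsibility(trials, params, items) |>
    group_by(.data$participant_id, .data$session) |>
    summarise(
      n_trials = sum(!is.na(.data$responsibility)),
      retrieval_use = if (method == "mean")
        mean(.data$responsibility, na.rm = TRUE)
      else mean(.data$responsibility > 0.5, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(retrieval_use = ifelse(.data$n_trials == 0, NA_real_,
                                  .data$retrieval_use))
}

#' Preprocess raw verification trials
#'
#' Applies the task's validity rules: reaction times above `max_rt`
#' seconds are invalid records and are removed; reaction times strictly
#' below `min_rt` are anticipations and are set to missing (they stay in
#' the table but are excluded from model likelihoods). Exclusion counts
#' are attached as the `"exclusions"` attribute and reported.
#'
#' @param trials raw trial tibble (see [trial_likelihood()] for columns).
#' @param min_rt anticipation threshold, seconds (default 0.300; strict
#'   inequality, an RT of exactly `min_rt` is retained).
#' @param max_rt maximum valid reaction time, seconds (default 9.5).
#' @param quiet suppress the exclusion summary message?
#' @export
preprocess_trials <- function(trials, min_rt = 0.3, max_rt = 9.5,
                              quiet = FALSE) {
  trials <- as_tibble(trials)
  if (nrow(trials) == 0) {
    attr(trials, "exclusions") <- c(too_slow = 0L, too_fast = 0L)
    return(trials)
  }
  bad_row <- !is.na(trials$rt) & (!is.finite(trials$rt) | trials$rt <= 0)
  if (any(bad_row))
    abort(paste0("malformed rt in row(s): ",
                 paste(which(bad_row), collapse = ", ")))
  too_slow <- !is.na(trials$rt) & trials$rt > max_rt
  out <- trials[!too_slow, , drop = FALSE]
  too_fast <- !is.na(out$rt) & out$rt < min_rt
  out$rt[too_fast] <- NA_real_
  attr(out, "exclusions") <- c(too_slow = sum(too_slow),
                               too_fast = sum(too_fast))
  if (!quiet)
    inform(sprintf("preprocess_trials: %d invalid (> %.1f s) removed, %d anticipations (< %d ms) set missing",
                   sum(too_slow), max_rt, sum(too_fast),
                   round(min_rt * 1000)))
  out
}

#' Read / write trial tables
#'
#' Delimited-text interface for verification-trial tables. Missing
#' reaction times are encoded as empty fields; the RT column on disk is
#' `rt_seconds`.
#'
#' @param path file path.
#' @return `read_trials()` returns a trial tibble with an `rt` column.
#' @export
read_trials <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if ("rt_seconds" %in% names(df)) df <- dplyr::rename(df, rt = "rt_seconds")
  df |>
    mutate(session = factor(.data$session, levels = c("pre", "post")),
           response_correct = as.logical(.data$response_correct))
}

#' @rdname read_trials
#' @param trials trial tibble.
#' @export
write_trials <- function(trials, path) {
  trials |>
    dplyr::rename(rt_seconds = "rt") |>
    readr::write_csv(path, na = "")
  invisible(path)
}
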
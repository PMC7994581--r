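#' First-passage-time density of a two-boundary Wiener diffusion
#'
#' Defective density of the reaction time at the named boundary for a
#' constant-drift diffusion between two absorbing boundaries. The density
#' is zero for `rt <= tau`. Evaluation uses the adaptive small-time /
#' large-time series representation, truncated to absolute tolerance `err`.
#'
#' @param rt vector of reaction times in seconds.
#' @param boundary `"correct"` (upper boundary) or `"error"` (lower).
#' @param alpha boundary separation (> 0), the decision threshold.
#' @param drift drift rate; positive values favour the correct boundary.
#' @param tau non-decision time in seconds (>= 0).
#' @param bias relative start point in (0, 1); 0.5 is unbiased.
#' @param log return the log density?
#' @param err absolute tolerance of the series truncation.
#' @return numeric vector of (log) densities, per second.
#' @examples
#' wiener_density(0.8, "correct", alpha = 1, drift = 1, tau = 0.3)
#' @export
wiener_density <- function(rt, boundary = c("correct", "error"),
                           alpha, drift, tau, bias = 0.5,
                           log = FALSE, err = 1e-10) {
  boundary <- match.arg(boundary)
  check_wiener_params(alpha, drift, tau, bias)
  d <- wiener_pdf_cpp(as.numeric(rt), alpha, drift, tau, bias,
                      as.integer(boundary == "correct"), err)
  if (log) base::log(d) else d
}

#' Total probability mass at each boundary
#'
#' Closed-form absorption probabilities of the diffusion; the two masses
#' sum to one.
#'
#' @inheritParams wiener_density
#' @return tibble with columns `boundary` and `mass`.
#' @export
wiener_boundary_mass <- function(alpha, drift, bias = 0.5) {
  check_wiener_params(alpha, drift, 0, bias)
  pu <- wiener_p_upper_cpp(alpha, drift, bias)
  tibble(boundary = c("correct", "error"), mass = c(pu, 1 - pu))
}

#' Cumulative first-passage distribution at a boundary
#'
#' Numerical integration (cumulative trapezoid on a fine grid) of
#' [wiener_density()]. Returns the defective CDF, i.e. it tends to the
#' boundary mass, not to one.
#'
#' @inheritParams wiener_density
#' @param grid_dt grid resolution of the integration, seconds.
#' @export
wiener_cdf <- function(rt, boundary = c("correct", "error"),
                       alpha, drift, tau, bias = 0.5, grid_dt = 5e-4) {
  boundary <- match.arg(boundary)
  check_wiener_params(alpha, drift, tau, bias)
  hi <- max(rt, tau + 1) + grid_dt
  grid <- seq(tau, hi, by = grid_dt)
  dens <- wiener_pdf_cpp(grid, alpha, drift, tau, bias,
                         as.integer(boundary == "correct"), 1e-10)
  cum <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2) * grid_dt)
  out <- stats::approx(grid, cum, xout = pmin(pmax(rt, tau), hi),
                       rule = 2)$y
  out[rt <= tau] <- 0
  out
}

#' Simulate reaction times from the Wiener diffusion
#'
#' Euler-Maruyama path simulation with a Brownian-bridge crossing
#' correction inside each step. Used as the model-independent simulation
#' oracle for the analytic density, and by the synthetic-behaviour
#' generator.
#'
#' @inheritParams wiener_density
#' @param n number of trials.
#' @param dt simulation step in seconds.
#' @param t_max give up (censor) after this much decision time.
#' @return tibble with columns `rt` and `boundary` (`"correct"`/`"error"`;
#'   `NA` if no boundary was reached before `t_max`).
#' @export
simulate_wiener <- function(n, alpha, drift, tau, bias = 0.5,
                            dt = 1e-4, t_max = 20) {
  check_wiener_params(alpha, drift, tau, bias)
  sim <- rwiener_em_cpp(rep(alpha, n), rep(drift, n), rep(tau, n),
                        rep(bias, n), dt, t_max)
  tibble(rt = sim$rt,
         boundary = dplyr::if_else(sim$upper == 1L, "correct", "error"))
}

check_wiener_params <- function(alpha, drift, tau, bias) {
  if (!is.numeric(alpha) || any(alpha <= 0))
    abort("`alpha` (decision threshold) must be positive.")
  if (!is.numeric(drift) || any(!is.finite(drift)))
    abort("`drift` must be finite.")
  if (!is.numeric(tau) || any(tau < 0))
    abort("`tau` (non-decision time) must be non-negative.")
  if (!is.numeric(bias) || any(bias <= 0) || any(bias >= 1))
    abort("`bias` must lie strictly between 0 and 1.")
  invisible(TRUE)
}
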
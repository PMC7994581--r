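#' Two-sided paired t-test with both Cohen's d conventions
#'
#' Paired t on post minus pre. Two effect sizes are reported: `d_z`
#' (mean difference over the SD of the differences, the quantity
#' algebraically tied to t) and `d_av` (mean difference over the average
#' of the pre and post SDs), the headline value.
#'
#' @param data optional data frame; if supplied, `pre` and `post` are
#'   column names (tidy-selected), otherwise numeric vectors.
#' @param pre,post paired measurements.
#' @return one-row tibble: `t`, `df`, `p`, `mean_diff`, `d_z`, `d_av`,
#'   `degenerate`.
#' @export
paired_t <- function(data = NULL, pre, post) {
  if (is.numeric(data)) {        # vector interface: paired_t(pre, post)
    tmp <- data
    post <- pre
    pre <- tmp
  } else if (!is.null(data)) {
    pre <- dplyr::pull(data, {{ pre }})
    post <- dplyr::pull(data, {{ post }})
  }
  if (length(pre) != length(post)) abort("pre and post must have equal length")
  if (length(pre) < 2) abort("need n >= 2 pairs")
  d <- post - pre
  md <- mean(d)
  sdd <- sd(d)
  if (sdd == 0) {
    warn("zero-variance differences: t degenerate")
    return(tibble(t = ifelse(md == 0, 0, NA_real_), df = length(d) - 1L,
                  p = ifelse(md == 0, 1, NA_real_), mean_diff = md,
                  d_z = NA_real_, d_av = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(post, pre, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_diff = md, d_z = md / sdd,
         d_av = md / ((sd(pre) + sd(post)) / 2), degenerate = FALSE)
}

#' Spearman rank correlation
#'
#' Average-rank tie handling; p-value by the t approximation, or by the
#' exact permutation distribution for small tie-free samples when
#' `exact = TRUE`.
#'
#' @param x,y numeric vectors (or column names if `data` is given).
#' @param data optional data frame.
#' @param exact use the exact p-value (only honoured for n <= 10 and no
#'   ties).
#' @return one-row tibble: `rho`, `p`, `n`, `method`.
#' @export
spearman <- function(data = NULL, x, y, exact = FALSE) {
  if (is.numeric(data)) {        # vector interface: spearman(x, y)
    tmp <- data
    y <- x
    x <- tmp
  } else if (!is.null(data)) {
    x <- dplyr::pull(data, {{ x }})
    y <- dplyr::pull(data, {{ y }})
  }
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need n >= 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant input: Spearman correlation undefined")
    return(tibble(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  use_exact <- exact && n <= 10 && !anyDuplicated(x) && !anyDuplicated(y)
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = use_exact))
  tibble(rho = unname(ct$estimate), p = ct$p.value, n = n,
         method = if (use_exact) "exact" else "t-approximation")
}

#' Compare two dependent correlations sharing an outcome
#'
#' Tests rho(x1, y) against rho(x2, y) measured on the same sample.
#' Default inference is a permutation test that randomly swaps the x1/x2
#' labels within participants; a Steiger-type z for dependent
#' overlapping correlations (on ranks) is reported alongside.
#'
#' @param x1,x2 competing predictors.
#' @param y shared outcome.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation draw.
#' @return one-row tibble: `rho1`, `rho2`, `difference`, `p_perm`,
#'   `steiger_z`, `p_steiger`, `n`.
#' @export
compare_dependent_correlations <- function(x1, x2, y, n_perm = 2000,
                                           seed = 1) {
  keep <- complete.cases(x1, x2, y)
  x1 <- x1[keep]; x2 <- x2[keep]; y <- y[keep]
  n <- length(y)
  if (n < 4) abort("need n >= 4 complete cases")
  sp <- function(a, b) suppressWarnings(cor(a, b, method = "spearman"))
  r1 <- sp(x1, y); r2 <- sp(x2, y)
  obs <- r1 - r2
  min_p <- 2 / (n_perm + 1)
  if (min_p > 0.05)
    warn(sprintf("permutation resolution limited: smallest attainable p is %.3g",
                 min_p))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(.) {
    swap <- runif(n) < 0.5
    a <- ifelse(swap, x2, x1)
    b <- ifelse(swap, x1, x2)
    sp(a, y) - sp(b, y)
  }, numeric(1))
  p_perm <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  # Steiger (1980) z for dependent overlapping correlations, on ranks
  r12 <- sp(x1, x2)
  zdiff <- atanh(r1) - atanh(r2)
  det_term <- r12 * (1 - r1^2 - r2^2) - 0.5 * r1 * r2 *
    (1 - r1^2 - r2^2 - r12^2)
  cov_z <- det_term / ((1 - r1^2) * (1 - r2^2))
  z <- zdiff * sqrt((n - 3) / (2 - 2 * cov_z))
  tibble(rho1 = r1, rho2 = r2, difference = obs, p_perm = p_perm,
         steiger_z = z, p_steiger = 2 * pnorm(-abs(z)), n = n)
}

#' Region-by-time repeated-measures ANOVA
#'
#' Within-participant ANOVA on a fully crossed participant x region x
#' time design; reports the Region x Time interaction.
#'
#' @param data tidy data frame with one row per cell.
#' @param value,participant,region,time column names (tidy-selected).
#' @return one-row tibble: `F`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(data, value, participant, region, time) {
  df <- tibble(
    value = dplyr::pull(data, {{ value }}),
    participant = factor(dplyr::pull(data, {{ participant }})),
    region = factor(dplyr::pull(data, {{ region }})),
    time = factor(dplyr::pull(data, {{ time }}))
  )
  counts <- table(df$participant, df$region, df$time)
  if (any(counts != 1))
    abort("design must be complete: exactly one value per participant x region x time cell")
  fit <- aov(value ~ region * time + Error(participant / (region * time)),
             data = df)
  tab <- summary(fit)[["Error: participant:region:time"]][[1]]
  row <- grep("region:time", rownames(tab))
  Fv <- tab[row, "F value"]; pv <- tab[row, "Pr(>F)"]
  if (tab[row, "Sum Sq"] < 1e-12) {  # no interaction variance at all
    Fv <- 0; pv <- 1
  }
  tibble(F = Fv, df1 = tab[row, "Df"], df2 = tab[nrow(tab), "Df"], p = pv)
}
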
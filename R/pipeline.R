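#' Pipeline configuration
#'
#' Orchestration settings for the end-to-end analysis: simulate (or load)
#' a cohort, run the network analysis, fit the joint model, infer
#' strategies and assemble the statistics report. Every stochastic stage
#' draws its seed from here.
#'
#' @param spec a [cohort_spec()] used when data are simulated.
#' @param fit a [fit_config()].
#' @param n_restarts,resolution Louvain settings.
#' @param use_method retrieval-use summary convention
#'   (see [retrieval_use_summary()]).
#' @param pool_ips average left/right IPS before node-wise tests?
#' @param fdr_q FDR threshold reported in the node table.
#' @param d_convention headline effect-size convention, `"d_av"` or
#'   `"d_z"`.
#' @param out_dir optional run directory; stage outputs and the report
#'   are written there as CSV/JSON.
#' @param data optional pre-existing data: list with `trials` and
#'   `networks` in the formats produced by [simulate_cohort()].
#' @export
run_config <- function(spec = cohort_spec(), fit = fit_config(),
                       n_restarts = 100, resolution = 1,
                       use_method = "mean", pool_ips = TRUE,
                       fdr_q = 0.05, d_convention = "d_av",
                       out_dir = NULL, data = NULL) {
  structure(list(spec = spec, fit = fit, n_restarts = n_restarts,
                 resolution = resolution, use_method = use_method,
                 pool_ips = pool_ips, fdr_q = fdr_q,
                 d_convention = d_convention, out_dir = out_dir,
                 data = data),
            class = "run_config")
}

#' Network-analysis stage
#'
#' Partitions every participant-session matrix independently (same
#' restart policy), computes the mutual-information reorganization
#' distance per participant, group-average partitions and module counts,
#' and per-node diversity coefficients (positive channel) under each
#' matrix's own partition.
#'
#' @param networks list as produced by [simulate_networks()] (or with
#'   the same shape from real matrices): `matrices` is a named list of
#'   `list(pre, post)` matrices.
#' @param n_restarts,resolution,seed Louvain settings.
#' @return list with `distances`, `diversity` (long tibble), group
#'   partitions and module counts.
#' @export
network_stage <- function(networks, n_restarts = 100, resolution = 1,
                          seed = 1) {
  ids <- names(networks$matrices)
  parts <- purrr::map(seq_along(ids), function(i) {
    ms <- networks$matrices[[ids[i]]]
    list(pre = louvain_modules(ms$pre, resolution, n_restarts,
                               seed = seed + 7L * i),
         post = louvain_modules(ms$post, resolution, n_restarts,
                                seed = seed + 7L * i + 3L))
  })
  names(parts) <- ids
  distances <- tibble(
    participant_id = ids,
    distance = purrr::map_dbl(parts, ~ partition_distance(.x$pre, .x$post)))
  diversity <- purrr::map(ids, function(id) {
    ms <- networks$matrices[[id]]
    dplyr::bind_rows(
      diversity_coefficient(ms$pre, parts[[id]]$pre) |>
        mutate(session = "pre"),
      diversity_coefficient(ms$post, parts[[id]]$post) |>
        mutate(session = "post")) |>
      mutate(participant_id = id)
  }) |> dplyr::bind_rows()
  g_pre <- group_average_network(purrr::map(networks$matrices, "pre"))
  g_post <- group_average_network(purrr::map(networks$matrices, "post"))
  p_pre <- louvain_modules(g_pre, resolution, n_restarts, seed = seed + 1L)
  p_post <- louvain_modules(g_post, resolution, n_restarts, seed = seed + 2L)
  list(partitions = parts, distances = distances, diversity = diversity,
       group_pre = p_pre, group_post = p_post,
       modules_pre = p_pre$n_modules, modules_post = p_post$n_modules)
}

div_wide <- function(diversity, session) {
  diversity |>
    dplyr::filter(.data$session == !!session, .data$channel == "positive") |>
    dplyr::select("participant_id", "node", "diversity") |>
    pivot_wider(names_from = "node", values_from = "diversity")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> network analysis -> joint hierarchical fit ->
#' strategy inference -> statistics report. The report mirrors the study
#' table: paired tests on accuracy, reaction time, retrieval use and
#' retrieval efficiency; the one-sample test of the reorganization
#' distance; node-wise diversity tests with FDR; brain-behaviour
#' Spearman correlations; and the joint-model slopes with Savage-Dickey
#' Bayes factors.
#'
#' @param config a [run_config()].
#' @return object of class `pipeline_result`.
#' @export
run_pipeline <- function(config = run_config()) {
  spec <- config$spec
  if (is.null(config$data)) {
    cohort <- simulate_cohort(spec)
  } else {
    cohort <- config$data
  }
  trials <- preprocess_trials(cohort$trials, quiet = TRUE)

  net <- network_stage(cohort$networks, config$n_restarts,
                       config$resolution, seed = spec$seed + 11L)

  node <- cohort$networks$coupling_node %||% spec$coupling$node
  ddiv <- net$diversity |>
    dplyr::filter(.data$node == !!node, .data$channel == "positive") |>
    dplyr::select("participant_id", "session", "diversity") |>
    pivot_wider(names_from = "session", values_from = "diversity") |>
    mutate(d_diversity = .data$post - .data$pre) |>
    dplyr::select("participant_id", "d_diversity")

  # Behavioural measures come from the behaviour-only fit; the joint fit
  # is used only for the latent-regression slopes. Reading individual
  # parameters out of the joint fit would be circular: the regression
  # feedback aligns weakly identified change parameters with the very
  # brain scores they are later correlated against.
  fit <- fit_hierarchical(trials, config = config$fit)
  joint_fit <- fit_joint_brain_model(trials, ddiv, config = config$fit)

  params <- participant_params(fit)
  items <- item_params(fit)
  use <- retrieval_use_summary(trials, params, items,
                               method = config$use_method)

  behav <- trials |>
    dplyr::filter(!is.na(.data$response_correct)) |>
    group_by(.data$participant_id, .data$session) |>
    summarise(accuracy = mean(.data$response_correct),
              median_rt = median(.data$rt[.data$response_correct],
                                 na.rm = TRUE),
              .groups = "drop")

  wide <- behav |>
    dplyr::inner_join(use, by = c("participant_id", "session")) |>
    dplyr::inner_join(
      dplyr::select(params, "participant_id", "session", "delta_m",
                    "rho_i"),
      by = c("participant_id", "session")) |>
    pivot_wider(names_from = "session",
                values_from = c("accuracy", "median_rt", "retrieval_use",
                                "delta_m", "rho_i", "n_trials"))

  paired <- dplyr::bind_rows(
    accuracy = paired_t(wide$accuracy_pre, wide$accuracy_post),
    median_rt = paired_t(wide$median_rt_pre, wide$median_rt_post),
    retrieval_use = paired_t(wide$retrieval_use_pre,
                             wide$retrieval_use_post),
    retrieval_efficiency = paired_t(wide$delta_m_pre, wide$delta_m_post),
    retrieval_propensity = paired_t(wide$rho_i_pre, wide$rho_i_post),
    .id = "measure")

  dist_test <- test_distance_nonzero(net$distances)

  pool <- if (config$pool_ips &&
              all(c("L_IPS", "R_IPS") %in% unique(net$diversity$node)))
    list(IPS = c("L_IPS", "R_IPS")) else NULL
  node_tests <- node_change_tests(
    div_wide(net$diversity, "pre")[, -1],
    div_wide(net$diversity, "post")[, -1], pool = pool)

  ch <- wide |>
    dplyr::inner_join(net$distances, by = "participant_id") |>
    dplyr::inner_join(ddiv, by = "participant_id") |>
    mutate(d_accuracy = .data$accuracy_post - .data$accuracy_pre,
           d_rt = .data$median_rt_post - .data$median_rt_pre,
           d_use = .data$retrieval_use_post - .data$retrieval_use_pre,
           d_efficiency = .data$delta_m_post - .data$delta_m_pre)

  correlations <- dplyr::bind_rows(
    distance_vs_accuracy_gain = spearman(ch$distance, ch$d_accuracy),
    hipp_diversity_vs_accuracy_gain = spearman(ch$d_diversity,
                                               ch$d_accuracy),
    hipp_diversity_vs_efficiency_gain = spearman(ch$d_diversity,
                                                 ch$d_efficiency),
    efficiency_gain_vs_accuracy_gain = spearman(ch$d_efficiency,
                                                ch$d_accuracy),
    use_gain_vs_rt_change = spearman(ch$d_use, ch$d_rt),
    .id = "analysis")

  res <- structure(list(
    config = config, cohort = cohort, trials = trials, network = net,
    fit = fit, joint_fit = joint_fit, params = params, items = items,
    use = use, summary_wide = ch,
    report = list(paired = paired, distance = dist_test,
                  nodes = node_tests, correlations = correlations,
                  joint = joint_fit$betas,
                  modules = tibble(session = c("pre", "post"),
                                   n_modules = c(net$modules_pre,
                                                 net$modules_post)))
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_outputs(res)
  res
}

write_pipeline_outputs <- function(res) {
  dir <- res$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- res$report
  readr::write_csv(rep$paired, file.path(dir, "paired_tests.csv"))
  readr::write_csv(rep$nodes, file.path(dir, "node_tests.csv"))
  readr::write_csv(rep$correlations, file.path(dir, "correlations.csv"))
  readr::write_csv(rep$joint, file.path(dir, "joint_model.csv"))
  readr::write_csv(res$network$distances, file.path(dir, "distances.csv"))
  jsonlite::write_json(
    list(distance = rep$distance, modules = rep$modules,
         seed = res$config$spec$seed,
         fit_profile = res$config$fit$profile),
    file.path(dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n===============\n")
  cat("\nPaired pre/post tests:\n")
  print(as.data.frame(x$report$paired), digits = 3)
  cat(sprintf("\nReorganization distance: M = %.3f (SD %.3f), t(%d) = %.2f, p = %.2g\n",
              x$report$distance$mean, x$report$distance$sd,
              x$report$distance$df, x$report$distance$t,
              x$report$distance$p))
  cat(sprintf("Group modules: %d pre, %d post\n",
              x$report$modules$n_modules[1], x$report$modules$n_modules[2]))
  cat("\nBrain-behaviour correlations:\n")
  print(as.data.frame(x$report$correlations), digits = 3)
  cat("\nJoint-model slopes (Savage-Dickey BF):\n")
  print(as.data.frame(x$report$joint), digits = 3)
  invisible(x)
}

#' Load per-child source data from a supplementary table
#'
#' Schema-tolerant loader for a per-child source-data file (one row per
#' child). Column names are matched case-insensitively against
#' conventional measure patterns (accuracy/RT/use/efficiency pre and
#' post, reorganization distance, node diversity changes) and renamed to
#' the package's conventions; unrecognized columns are kept as-is and
#' reported.
#'
#' @param path path to a delimited text file (CSV or TSV).
#' @return list with `data` (tidy tibble), `found` (mapping tibble) and
#'   `unmatched` (character).
#' @export
load_supplementary_source_data <- function(path) {
  if (!file.exists(path))
    abort(paste0(
      "supplementary source-data file not found at '", path, "'. ",
      "Supply the per-child table (CSV/TSV, one row per child) to ",
      "recompute the printed statistics; the rest of the pipeline does ",
      "not depend on it."))
  df <- if (grepl("\\.tsv$", path)) readr::read_tsv(path,
                                                    show_col_types = FALSE)
  else readr::read_csv(path, show_col_types = FALSE)
  norm <- tolower(gsub("[^[:alnum:]]+", "_", names(df)))
  patterns <- c(
    participant_id = "^(subject|participant|child|subj|id|pid)",
    accuracy_pre = "acc.*pre|pre.*acc",
    accuracy_post = "acc.*post|post.*acc",
    rt_pre = "(rt|reaction).*pre|pre.*(rt|reaction)",
    rt_post = "(rt|reaction).*post|post.*(rt|reaction)",
    use_pre = "use.*pre|pre.*use",
    use_post = "use.*post|post.*use",
    efficiency_pre = "(eff|drift).*pre|pre.*(eff|drift)",
    efficiency_post = "(eff|drift).*post|post.*(eff|drift)",
    distance = "distance|reorg",
    d_diversity_hipp = "hipp.*(div|change)|div.*hipp",
    d_diversity_ips = "ips.*(div|change)|div.*ips")
  found <- list()
  for (nm in names(patterns)) {
    hit <- grep(patterns[[nm]], norm)
    if (length(hit) >= 1) {
      found[[nm]] <- names(df)[hit[1]]
      names(df)[hit[1]] <- nm
      norm[hit[1]] <- nm
    }
  }
  unmatched <- setdiff(names(df), names(found))
  inform(sprintf("matched %d column(s): %s%s",
                 length(found),
                 paste(names(found), collapse = ", "),
                 if (length(unmatched) > 0)
                   paste0("; unmatched: ",
                          paste(unmatched, collapse = ", ")) else ""))
  list(data = as_tibble(df),
       found = tibble(standard = names(found),
                      original = unlist(found)),
       unmatched = unmatched)
}

#' Recompute the headline statistics from a per-child table
#'
#' Runs the statistics battery on a wide per-child table with the
#' conventional column names produced by
#' [load_supplementary_source_data()]: paired t for each pre/post
#' measure present and Spearman correlations among available change
#' scores and network measures.
#'
#' @param data wide per-child tibble.
#' @return list with `paired` and `correlations` tibbles.
#' @export
recompute_printed_stats <- function(data) {
  measures <- c("accuracy", "rt", "use", "efficiency")
  paired <- purrr::map(measures, function(m) {
    pre <- paste0(m, "_pre"); post <- paste0(m, "_post")
    if (!all(c(pre, post) %in% names(data))) return(NULL)
    paired_t(data[[pre]] * 1, data[[post]] * 1) |>
      mutate(measure = m, .before = 1)
  }) |> dplyr::bind_rows()
  ch <- data
  for (m in measures) {
    pre <- paste0(m, "_pre"); post <- paste0(m, "_post")
    if (all(c(pre, post) %in% names(ch)))
      ch[[paste0("d_", m)]] <- ch[[post]] - ch[[pre]]
  }
  pairs <- list(
    c("distance", "d_accuracy"),
    c("d_diversity_hipp", "d_accuracy"),
    c("d_diversity_hipp", "d_efficiency"),
    c("d_efficiency", "d_accuracy"),
    c("d_use", "d_rt"))
  correlations <- purrr::map(pairs, function(pair) {
    if (!all(pair %in% names(ch))) return(NULL)
    spearman(ch[[pair[1]]] * 1, ch[[pair[2]]] * 1) |>
      mutate(x = pair[1], y = pair[2], .before = 1)
  }) |> dplyr::bind_rows()
  list(paired = paired, correlations = correlations)
}
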
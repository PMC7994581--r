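test_that("connectivity constructor validates its invariants", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  cm <- connectivity_matrix(W, c("a", "b"))
  expect_s3_class(cm, "connectivity_matrix")
  expect_error(connectivity_matrix(matrix(1:6, 2, 3)), "square")
  expect_error(connectivity_matrix(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
  expect_error(connectivity_matrix(matrix(c(1, 0, 0, 1), 2, 2)),
               "diagonal")
})

test_that("PPI regression recovers planted task-modulated coupling", {
  g <- 0.5
  est <- vapply(1:20, function(r) {
    sim <- simulate_roi_timeseries(3, 600, block_length = 30,
                                   couplings = tibble::tibble(
                                     seed = 1, target = 2, g = g),
                                   seed = 500 + r)
    ppi_edge_weights(sim$timeseries, sim$task)[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(est) - g), 0.1)
  # null pairs stay near zero, matrix symmetric, diagonal zero
  sim <- simulate_roi_timeseries(4, 800, block_length = 40, seed = 77)
  W <- ppi_edge_weights(sim$timeseries, sim$task)
  expect_equal(as.matrix(W), t(as.matrix(W)))
  expect_true(all(diag(W) == 0))
  expect_error(ppi_edge_weights(sim$timeseries, rep(1, 800)),
               "task_indicator")
})

test_that("Louvain separates disconnected positive cliques", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1
  diag(W) <- 0
  p <- louvain_modules(W, n_restarts = 20, seed = 2)
  expect_equal(p$n_modules, 2)
  expect_equal(length(unique(p$affiliation[1:4])), 1)
  expect_equal(length(unique(p$affiliation[5:8])), 1)
  expect_false(p$affiliation[1] == p$affiliation[5])
})

test_that("Louvain Q* attains the brute-force optimum on small networks", {
  set.seed(90)
  for (rep in 1:4) {
    n <- sample(5:7, 1)
    W <- matrix(rnorm(n * n, 0, 0.5), n, n)
    W <- (W + t(W)) / 2; diag(W) <- 0
    lv <- louvain_modules(W, n_restarts = 60, seed = 100 + rep)
    best <- max(vapply(all_partitions(n), function(p)
      signed_modularity(W, p), numeric(1)))
    expect_equal(lv$quality, best, tolerance = 1e-10)
    # never below the trivial single-module quality
    expect_gte(lv$quality, signed_modularity(W, rep(1, n)) - 1e-12)
  }
})

test_that("planted signed block structure is recovered across seeds", {
  aff <- rep(1:3, each = 6)
  hits <- vapply(1:20, function(r) {
    set.seed(700 + r)
    mu <- ifelse(outer(aff, aff, "=="), 0.6, -0.2)
    W <- mu + matrix(rnorm(length(aff)^2, 0, 0.15), 18, 18)
    W <- (W + t(W)) / 2; diag(W) <- 0
    p <- louvain_modules(W, n_restarts = 50, seed = r)
    partition_distance(p, aff) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("all-zero matrices yield one module with a warning", {
  expect_warning(p <- louvain_modules(matrix(0, 5, 5)), "all-zero")
  expect_equal(p$n_modules, 1)
  expect_equal(p$quality, 0)
})

test_that("partition distance matches hand-computed values and is a semimetric", {
  expect_equal(partition_distance(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  expect_equal(partition_distance(c(1, 1, 2, 2), c(2, 2, 1, 1)), 0)
  expect_equal(partition_distance(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1)
  # hand contingency-table computation for [1,1,2,2] vs [1,1,1,2]:
  # I = .5 log(4/3) + .25 log(2/3) + .25 log 2, H1 = log 2,
  # H2 = -(.75 log .75 + .25 log .25)
  I <- 0.5 * log(4 / 3) + 0.25 * log(2 / 3) + 0.25 * log(2)
  H1 <- log(2)
  H2 <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(partition_distance(c(1, 1, 2, 2), c(1, 1, 1, 2)),
               1 - 2 * I / (H1 + H2), tolerance = 1e-12)
  set.seed(31)
  for (r in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:3, 12, replace = TRUE)
    expect_gte(partition_distance(a, b), -1e-12)
    expect_equal(partition_distance(a, b), partition_distance(b, a))
    expect_equal(partition_distance(a, sample(10:12)[a]), 0)
  }
  expect_error(partition_distance(c(1, 2), c(1, 2, 3)), "equal")
})

test_that("diversity coefficient matches entropy oracles and invariances", {
  # equal strength into every module: maximum entropy
  W <- matrix(0, 4, 4)
  W[1, 2:4] <- 1; W[2:4, 1] <- 1
  d <- diversity_coefficient(W, c(1, 1, 2, 3))
  # node 1: strengths (1, 1, 1) over 3 modules -> 1
  expect_equal(d$diversity[1], 1)
  # all strength in one module -> 0
  expect_equal(d$diversity[2], 0)
  # hand entropy value for module strengths (0.5, 0.25, 0.25), m = 3
  W2 <- rbind(c(0, .5, .25, .25), c(.5, 0, 0, 0), c(.25, 0, 0, 0),
              c(.25, 0, 0, 0))
  d2 <- diversity_coefficient(W2, c(1, 1, 2, 3))
  h_hand <- -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)) / log(3)
  expect_equal(d2$diversity[1], h_hand, tolerance = 1e-6)
  # invariant to module relabeling and uniform positive scaling
  set.seed(8)
  W3 <- matrix(rnorm(36), 6, 6); W3 <- (W3 + t(W3)) / 2; diag(W3) <- 0
  aff <- c(1, 1, 2, 2, 3, 3)
  d_a <- diversity_coefficient(W3, aff)$diversity
  expect_equal(diversity_coefficient(W3, c(3, 3, 1, 1, 2, 2))$diversity, d_a)
  expect_equal(diversity_coefficient(W3 * 7.3, aff)$diversity, d_a)
  expect_true(all(d_a >= 0 & d_a <= 1))
  # isolated node in the positive channel gets zero
  W4 <- matrix(0, 3, 3); W4[2, 3] <- W4[3, 2] <- 1
  expect_equal(diversity_coefficient(W4, c(1, 1, 2))$diversity[1], 0)
  # negative channel reported separately
  d_both <- diversity_coefficient(W3, aff, channel = "both")
  expect_setequal(unique(d_both$channel), c("positive", "negative"))
})

test_that("group averaging preserves labels and cancels sign-flipped input", {
  set.seed(15)
  W <- matrix(rnorm(25), 5, 5); W <- (W + t(W)) / 2; diag(W) <- 0
  rownames(W) <- colnames(W) <- letters[1:5]
  avg <- group_average_network(list(W, W, W))
  expect_equal(as.matrix(avg), W)
  zero <- group_average_network(list(W, -W))
  expect_true(all(as.matrix(zero) == 0))
  W2 <- W; rownames(W2) <- colnames(W2) <- LETTERS[1:5]
  expect_error(group_average_network(list(W, W2)), "labels")
})

test_that("distance t-test matches the closed form and flags degeneracy", {
  set.seed(44)
  d <- rnorm(35, 0.9, 0.05)
  res <- test_distance_nonzero(d)
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(35)), tolerance = 1e-12)
  expect_equal(res$df, 34)
  expect_warning(deg <- test_distance_nonzero(rep(0.5, 4)), "degenerate")
  expect_true(deg$degenerate)
  zero <- test_distance_nonzero(c(0, 0, 1e-9, -1e-9))
  expect_gt(zero$p, 0.5)
})

test_that("node-wise Wilcoxon tests apply the BH step-up correction", {
  # identical pre/post: all adjusted p = 1
  m <- matrix(runif(40), 10, 4, dimnames = list(NULL, paste0("n", 1:4)))
  suppressMessages(res0 <- node_change_tests(m, m))
  expect_true(all(res0$p_adj == 1))
  # BH on the fixed p-vector [.01, .02, .03, .04] with m = 4: all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # direct step-up oracle against the implementation's adjustment
  set.seed(60)
  pre <- matrix(runif(200), 50, 4, dimnames = list(NULL, paste0("n", 1:4)))
  post <- pre + matrix(rnorm(200, 0, 0.05), 50, 4)
  post[, 2] <- post[, 2] - 0.15
  res <- node_change_tests(pre, post)
  raw <- res$p
  stepup <- rev(cummin(rev(sort(raw) * 4 / seq_len(4))))[rank(raw)]
  expect_equal(res$p_adj, pmin(stepup, 1), tolerance = 1e-12)
  expect_lt(res$p_adj[res$node == "n2"], 0.05)
  # pooling averages member columns before testing
  pooled <- node_change_tests(pre, post, pool = list(n34 = c("n3", "n4")))
  expect_true("n34" %in% pooled$node)
  expect_false(any(c("n3", "n4") %in% pooled$node))
})

test_that("planted single-node decrease survives FDR in most replicates", {
  hits <- vapply(1:10, function(r) {
    set.seed(800 + r)
    pre <- matrix(runif(35 * 6, 0.3, 0.9), 35, 6,
                  dimnames = list(NULL, paste0("n", 1:6)))
    post <- pre + matrix(rnorm(35 * 6, 0, 0.08), 35, 6)
    post[, 3] <- post[, 3] - 0.15
    res <- node_change_tests(pre, post)
    res$p_adj[res$node == "n3"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("connectivity matrices round-trip through CSV", {
  set.seed(3)
  W <- matrix(rnorm(16), 4, 4); W <- (W + t(W)) / 2; diag(W) <- 0
  rownames(W) <- colnames(W) <- paste0("roi", 1:4)
  path <- tempfile(fileext = ".csv")
  write_connectivity(connectivity_matrix(W), path)
  back <- read_connectivity(path)
  expect_equal(as.matrix(back), W, tolerance = 1e-12)
})
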
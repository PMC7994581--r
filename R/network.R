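#' Signed task-connectivity matrix
#'
#' Light validating constructor: square, symmetric, zero diagonal, no
#' thresholding applied.
#'
#' @param weights square numeric matrix of signed weights.
#' @param node_labels optional node names (defaults to existing dimnames).
#' @param participant_id,session optional metadata.
#' @export
connectivity_matrix <- function(weights, node_labels = NULL,
                                participant_id = NA, session = NA) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) abort("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-8) abort("weights must be symmetric")
  if (any(abs(diag(weights)) > 1e-12)) abort("diagonal must be zero")
  if (is.null(node_labels)) node_labels <- rownames(weights) %||%
      paste0("node", seq_len(nrow(weights)))
  dimnames(weights) <- list(node_labels, node_labels)
  structure(weights, participant_id = participant_id, session = session,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
as.matrix.connectivity_matrix <- function(x, ...) {
  attr(x, "participant_id") <- NULL
  attr(x, "session") <- NULL
  class(x) <- NULL
  x
}

#' Task-connectivity edge weights by PPI regression
#'
#' For each ordered (seed, target) pair, the target signal is regressed
#' on the seed signal, the task indicator, their elementwise
#' (psychophysiological-interaction) product and an intercept; the edge
#' weight is the interaction coefficient. The matrix is symmetrized by
#' averaging the two directions and the diagonal zeroed.
#'
#' @param roi_timeseries time x node numeric matrix (or data frame) of
#'   region signals on a common time grid.
#' @param task_indicator length-T contrast vector (+1 task, -1 control,
#'   0 rest).
#' @return a [connectivity_matrix()].
#' @export
ppi_edge_weights <- function(roi_timeseries, task_indicator) {
  X <- as.matrix(roi_timeseries)
  task <- as.numeric(task_indicator)
  if (length(task) != nrow(X))
    abort("task_indicator length must match the number of time points")
  if (sd(task) == 0)
    abort("rank-deficient design: `task_indicator` is constant")
  n <- ncol(X)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    seedv <- X[, i]
    design <- cbind(1, seedv, task, seedv * task)
    for (j in seq_len(n)) {
      if (i == j) next
      W[i, j] <- lm.fit(design, X[, j])$coefficients[4]
    }
  }
  W <- (W + t(W)) / 2
  diag(W) <- 0
  connectivity_matrix(W, colnames(X) %||% paste0("node", seq_len(n)))
}

# signed modularity matrix for Q* (positive term scaled by positive
# strength, negative term down-weighted by total strength)
signed_modularity_matrix <- function(W, resolution = 1) {
  Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
  vp <- sum(Wp); vn <- sum(Wn)
  B <- matrix(0, nrow(W), ncol(W))
  if (vp > 0) {
    sp <- rowSums(Wp)
    B <- B + (Wp - resolution * outer(sp, sp) / vp) / vp
  }
  if (vn > 0) {
    sn <- rowSums(Wn)
    B <- B - (Wn - resolution * outer(sn, sn) / vn) / (vp + vn)
  }
  diag(B) <- 0
  B
}

#' Signed modularity Q* of a partition
#'
#' Quality of a module assignment of a signed weighted network: the
#' positive-weight modularity minus the negative-weight modularity
#' down-weighted by total strength, so that placing negatively coupled
#' nodes in one module is penalized asymmetrically.
#'
#' @param W signed symmetric matrix.
#' @param affiliation integer module ids, one per node.
#' @param resolution resolution parameter of the null term.
#' @export
signed_modularity <- function(W, affiliation, resolution = 1) {
  B <- signed_modularity_matrix(as.matrix(W), resolution)
  within <- outer(affiliation, affiliation, "==")
  sum(B[within])
}

# one Louvain run on a modularity matrix; node sweep order is random
louvain_once <- function(B) {
  n0 <- nrow(B)
  membership <- seq_len(n0)
  Bcur <- B
  repeat {
    nc <- nrow(Bcur)
    aff <- seq_len(nc)
    improved <- FALSE
    repeat {
      moved <- FALSE
      for (v in sample.int(nc)) {
        w <- Bcur[v, ]
        w[v] <- 0
        gains <- tapply(w, aff, sum)
        cur_gain <- gains[[as.character(aff[v])]]
        best <- names(gains)[which.max(gains)]
        if (gains[[best]] > cur_gain + 1e-12 && best != as.character(aff[v])) {
          aff[v] <- as.integer(best)
          moved <- TRUE
          improved <- TRUE
        }
      }
      if (!moved) break
    }
    aff <- match(aff, unique(aff))
    membership <- aff[membership]
    if (!improved || max(aff) == nc) break
    # aggregate communities into super-nodes (self-loops retained)
    Bcur <- rowsum(t(rowsum(Bcur, aff)), aff)
  }
  match(membership, unique(membership))
}

#' Louvain community detection for signed networks
#'
#' Greedy Louvain optimization of the signed quality Q* with multiple
#' seeded restarts; the best partition by Q* is returned (ties broken by
#' fewer modules, then lexicographically smallest affiliation). The
#' module count is determined automatically.
#'
#' @param W signed symmetric connectivity matrix.
#' @param resolution resolution parameter (default 1).
#' @param n_restarts number of random restarts.
#' @param seed RNG seed making the stochastic heuristic reproducible.
#' @return object of class `partition`: list with `affiliation` (named
#'   integer vector, ids contiguous from 1), `quality` (Q*), `n_modules`.
#' @export
louvain_modules <- function(W, resolution = 1, n_restarts = 100, seed = 1) {
  W <- as.matrix(W)
  labels <- rownames(W) %||% paste0("node", seq_len(nrow(W)))
  if (all(W == 0)) {
    warn("all-zero matrix: returning a single module with Q* = 0")
    return(new_partition(setNames(rep(1L, nrow(W)), labels), 0))
  }
  B <- signed_modularity_matrix(W, resolution)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    aff <- louvain_once(B)
    q <- sum(B[outer(aff, aff, "==")])
    if (is.null(best) || q > best$q + 1e-12 ||
        (abs(q - best$q) <= 1e-12 &&
         (max(aff) < max(best$aff) ||
          (max(aff) == max(best$aff) &&
           paste(aff, collapse = ",") < paste(best$aff, collapse = ","))))) {
      best <- list(aff = aff, q = q)
    }
  }
  new_partition(setNames(best$aff, labels), best$q)
}

new_partition <- function(affiliation, quality) {
  structure(list(affiliation = affiliation, quality = quality,
                 n_modules = length(unique(affiliation))),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition:", x$n_modules, "modules, Q* =",
      format(x$quality, digits = 4), "\n")
  invisible(x)
}

as_affiliation <- function(p) {
  if (inherits(p, "partition")) p$affiliation else as.integer(p)
}

#' Mutual-information distance between two partitions
#'
#' One minus the normalized mutual information, with the symmetric
#' normalization `2 I / (H1 + H2)` so the information term ranges from 0
#' to 1. Zero for identical partitions (up to relabeling); 1 for
#' independent ones.
#'
#' @param p1,p2 partitions ([louvain_modules()] output) or affiliation
#'   vectors of equal length.
#' @export
partition_distance <- function(p1, p2) {
  a <- as_affiliation(p1); b <- as_affiliation(p2)
  if (length(a) != length(b)) abort("partitions must have equal node counts")
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  H1 <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  H2 <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (H1 + H2 == 0) return(0)  # both trivial partitions: identical
  nz <- pij > 0
  I <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  1 - 2 * I / (H1 + H2)
}

#' Diversity coefficient of each node
#'
#' Normalized entropy of a node's strength distribution across modules
#' (per sign channel): 1 when the node's strength of that sign is spread
#' uniformly over all modules, 0 when confined to a single module.
#' Isolated nodes (zero strength in the channel) get 0 by convention.
#' The node's own module is included in the entropy.
#'
#' @param W signed symmetric connectivity matrix.
#' @param partition partition or affiliation vector on the same nodes.
#' @param channel `"positive"` (default reported channel), `"negative"`,
#'   or `"both"`.
#' @return tibble with `node`, `channel`, `diversity` (in \[0, 1\]).
#' @export
diversity_coefficient <- function(W, partition,
                                  channel = c("positive", "negative", "both")) {
  channel <- match.arg(channel)
  W <- as.matrix(W)
  aff <- as_affiliation(partition)
  if (length(aff) != nrow(W)) abort("partition must cover all nodes")
  labels <- rownames(W) %||% paste0("node", seq_len(nrow(W)))
  m <- length(unique(aff))
  one_channel <- function(Wc, tag) {
    S <- rowsum(t(Wc), aff)            # module x node strength
    tot <- colSums(S)
    h <- vapply(seq_len(ncol(S)), function(i) {
      if (tot[i] <= 0 || m < 2) return(0)
      p <- S[, i] / tot[i]
      p <- p[p > 0]
      -sum(p * log(p)) / log(m)
    }, numeric(1))
    tibble(node = labels, channel = tag, diversity = h)
  }
  out <- list()
  if (channel %in% c("positive", "both"))
    out <- c(out, list(one_channel(pmax(W, 0), "positive")))
  if (channel %in% c("negative", "both"))
    out <- c(out, list(one_channel(pmax(-W, 0), "negative")))
  dplyr::bind_rows(out)
}

#' Element-wise group-average network
#'
#' @param matrices list of connectivity matrices with identical node
#'   order (labels are checked).
#' @export
group_average_network <- function(matrices) {
  if (length(matrices) == 0) abort("no matrices supplied")
  ref <- rownames(as.matrix(matrices[[1]]))
  for (M in matrices) {
    if (!identical(rownames(as.matrix(M)), ref))
      abort("node labels differ across matrices")
  }
  avg <- Reduce(`+`, lapply(matrices, as.matrix)) / length(matrices)
  connectivity_matrix(avg, ref)
}

#' One-sample t-test of partition distances against zero
#'
#' Tests whether the pre-to-post reorganization distance differs from the
#' null of no change in modular structure.
#'
#' @param distances numeric vector (or data frame with a `distance`
#'   column) of per-participant partition distances.
#' @return one-row tibble: `mean`, `sd`, `t`, `df`, `p`, `degenerate`.
#' @export
test_distance_nonzero <- function(distances) {
  if (is.data.frame(distances)) distances <- distances$distance
  if (length(distances) < 2) abort("need at least two distances")
  s <- sd(distances)
  if (s == 0) {
    warn("zero variance in distances; t undefined (degenerate)")
    return(tibble(mean = mean(distances), sd = 0, t = NA_real_,
                  df = length(distances) - 1L, p = NA_real_,
                  degenerate = TRUE))
  }
  tt <- t.test(distances, mu = 0)
  tibble(mean = mean(distances), sd = s, t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
}

#' Paired node-wise tests of diversity change with FDR correction
#'
#' Two-sided paired Wilcoxon signed-rank test per node between matched
#' pre and post diversity values, Benjamini-Hochberg adjusted across
#' nodes. Node pooling (e.g. averaging bilateral homologues before
#' testing) can be requested via `pool`.
#'
#' @param div_pre,div_post participant x node matrices (or data frames)
#'   of diversity coefficients, with matching rows (participants) and
#'   columns (nodes).
#' @param pool optional named list mapping a pooled-node name to the
#'   column names averaged into it (pooled columns replace their
#'   members).
#' @return tibble with `node`, `statistic`, `p`, `p_adj`,
#'   `median_change`.
#' @export
node_change_tests <- function(div_pre, div_post, pool = NULL) {
  pre <- as.matrix(div_pre); post <- as.matrix(div_post)
  if (!all(dim(pre) == dim(post))) abort("pre/post dimensions differ")
  if (!is.null(pool)) {
    for (nm in names(pool)) {
      cols <- pool[[nm]]
      pre <- cbind(pre[, !colnames(pre) %in% cols, drop = FALSE],
                   matrix(rowMeans(pre[, cols, drop = FALSE]),
                          dimnames = list(NULL, nm)))
      post <- cbind(post[, !colnames(post) %in% cols, drop = FALSE],
                    matrix(rowMeans(post[, cols, drop = FALSE]),
                           dimnames = list(NULL, nm)))
    }
  }
  nodes <- colnames(pre) %||% paste0("node", seq_len(ncol(pre)))
  res <- purrr::map(seq_len(ncol(pre)), function(j) {
    d <- post[, j] - pre[, j]
    if (all(d == 0)) {
      inform(sprintf("node %s: all differences zero; p = 1 by convention",
                     nodes[j]))
      return(tibble(node = nodes[j], statistic = NA_real_, p = 1,
                    median_change = 0))
    }
    wt <- suppressWarnings(wilcox.test(post[, j], pre[, j], paired = TRUE))
    tibble(node = nodes[j], statistic = unname(wt$statistic),
           p = wt$p.value, median_change = median(d))
  }) |> dplyr::bind_rows()
  res$p_adj <- p.adjust(res$p, method = "BH")
  res[, c("node", "statistic", "p", "p_adj", "median_change")]
}

#' Read / write connectivity matrices as delimited text
#'
#' CSV with a header row of node labels.
#'
#' @param path file path.
#' @export
read_connectivity <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  M <- as.matrix(df)
  rownames(M) <- colnames(M)
  connectivity_matrix(M)
}

#' @rdname read_connectivity
#' @param W connectivity matrix.
#' @export
write_connectivity <- function(W, path) {
  readr::write_csv(as.data.frame(as.matrix(W)), path)
  invisible(path)
}
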
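#' Score an estimated network against a true adjacency
#'
#' Undirected presence comparison over unordered gene pairs (self pairs
#' excluded): TP / FP / FN counts plus precision and recall. Empty
#' predictions have precision 1 and empty truths recall 1 by the usual
#' PR-curve endpoint convention.
#'
#' @param estimated a [gene_network()].
#' @param truth symmetric logical adjacency with gene dimnames matching the
#'   network's universe.
#' @return one-row data.frame `TP`, `FP`, `FN`, `precision`, `recall`.
#' @export
score_edges <- function(estimated, truth) {
  stopifnot(inherits(estimated, "gene_network"))
  check_adjacency(truth)
  if (!setequal(rownames(truth), estimated$genes)) {
    stop("gene universe mismatch between estimate and truth")
  }
  idx <- which(truth & upper.tri(truth), arr.ind = TRUE)
  g <- rownames(truth)
  true_keys <- edge_keys(g[idx[, 1]], g[idx[, 2]])
  est_keys <- network_edge_keys(estimated)
  TP <- length(intersect(est_keys, true_keys))
  FP <- length(est_keys) - TP
  FN <- length(true_keys) - TP
  data.frame(TP = TP, FP = FP, FN = FN,
             precision = if (TP + FP > 0) TP / (TP + FP) else 1,
             recall = if (TP + FN > 0) TP / (TP + FN) else 1)
}

#' Precision-recall curve for one method on one simulated dataset
#'
#' For every value of `lambda1_grid`, fits the named method, max-symmetrizes,
#' and scores each state's network against that state's true adjacency.
#' The static method fits one pooled network and scores it against every
#' state's truth. Per-grid-value micro-averages pool TP/FP/FN over states
#' before forming the ratios.
#'
#' @param method `"treegl"` (joint fused fit), `"static"` (pooled single
#'   network) or `"independent"` (per-state lasso).
#' @param collection a [build_tree_collection()] ground truth.
#' @param panel an [expression_panel()] sampled from `collection`.
#' @param lambda1_grid vector of sparsity penalties to trace.
#' @param lambda2 fusion penalty (treegl only; fixed along the path).
#' @param config an [analysis_config()].
#' @return list with `points` (per-state rows: method, lambda1, state, TP,
#'   FP, FN, precision, recall) and `pooled` (micro-averaged rows per
#'   lambda1).
#' @export
pr_curve <- function(method = c("treegl", "static", "independent"),
                     collection, panel, lambda1_grid, lambda2 = NULL,
                     config = analysis_config()) {
  method <- match.arg(method)
  stopifnot(inherits(collection, "true_network_collection"))
  states <- collection$tree$states
  if (method == "treegl") {
    if (is.null(lambda2)) lambda2 <- config$lambda2
    fits <- fit_all_path(panel, collection$tree, lambda1_grid, lambda2, config)
    nets_by_lambda <- lapply(fits, symmetrize_max)
  } else if (method == "independent") {
    nets_by_lambda <- lapply(lambda1_grid, function(l1) {
      symmetrize_max(fit_independent(panel, config, lambda1 = l1))
    })
    names(nets_by_lambda) <- as.character(lambda1_grid)
  } else {
    nets_by_lambda <- lapply(lambda1_grid, function(l1) {
      net <- symmetrize_max(fit_static(panel, config, lambda1 = l1))[[1]]
      stats::setNames(rep(list(net), length(states)), states)
    })
    names(nets_by_lambda) <- as.character(lambda1_grid)
  }
  pts <- list()
  pooled <- list()
  for (k in seq_along(lambda1_grid)) {
    nets <- nets_by_lambda[[as.character(lambda1_grid[k])]]
    per_state <- lapply(states, function(s) {
      sc <- score_edges(nets[[s]], true_adjacency(collection, s))
      cbind(data.frame(method = method, lambda1 = lambda1_grid[k], state = s),
            sc)
    })
    df <- do.call(rbind, per_state)
    pts[[k]] <- df
    TP <- sum(df$TP); FP <- sum(df$FP); FN <- sum(df$FN)
    pooled[[k]] <- data.frame(
      method = method, lambda1 = lambda1_grid[k], TP = TP, FP = FP, FN = FN,
      precision = if (TP + FP > 0) TP / (TP + FP) else 1,
      recall = if (TP + FN > 0) TP / (TP + FN) else 1)
  }
  list(points = do.call(rbind, pts), pooled = do.call(rbind, pooled))
}

#' Replicated simulation experiments with quartile bands
#'
#' Generates `n_reps` independent tree collections and panels (replicate
#' seeds derived deterministically from `seed`), traces each method's
#' micro-averaged PR curve, and summarizes precision and recall per grid
#' value by median and first/third quartiles across replicates.
#'
#' @param n_reps number of replicates (>= 1).
#' @param p genes per network.
#' @param n_per_state samples per state.
#' @param segment_len states per distinct network.
#' @param lambda1_grid sparsity grid traced for every method.
#' @param lambda2 fusion penalty for the joint method.
#' @param methods subset of `c("treegl", "static", "independent")`.
#' @param seed master seed.
#' @param config an [analysis_config()].
#' @return list with `replicates` (pooled PR rows per method, replicate and
#'   lambda1) and `summary` (per method and lambda1: median/Q1/Q3 of
#'   precision and recall).
#' @export
replicate_experiments <- function(n_reps, p, n_per_state, segment_len,
                                  lambda1_grid, lambda2,
                                  methods = c("treegl", "static", "independent"),
                                  seed = 1L, config = analysis_config()) {
  stopifnot(n_reps >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  reps <- list()
  for (r in seq_len(n_reps)) {
    col_seed <- derive_seed(seed, 2L * r)
    pan_seed <- derive_seed(seed, 2L * r + 1L)
    collection <- build_tree_collection(p, segment_len, seed = col_seed)
    panel <- sample_panel(collection, n_per_state, seed = pan_seed)
    for (m in methods) {
      pr <- pr_curve(m, collection, panel, lambda1_grid, lambda2, config)
      reps[[length(reps) + 1L]] <- cbind(data.frame(replicate = r), pr$pooled)
    }
    log_msg("info", "replicate ", r, "/", n_reps, " done")
  }
  raw <- do.call(rbind, reps)
  qs <- function(x) quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  summ <- do.call(rbind, lapply(split(raw, list(raw$method, raw$lambda1), drop = TRUE),
    function(d) {
      qp <- qs(d$precision); qr <- qs(d$recall)
      data.frame(method = d$method[1], lambda1 = d$lambda1[1],
                 precision_q1 = qp[1], precision_med = qp[2], precision_q3 = qp[3],
                 recall_q1 = qr[1], recall_med = qr[2], recall_q3 = qr[3])
    }))
  summ <- summ[order(summ$method, summ$lambda1), , drop = FALSE]
  rownames(summ) <- NULL
  list(replicates = raw, summary = summ)
}
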
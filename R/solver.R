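#' Per-gene joint neighborhood regression problem
#'
#' For one response gene, bundles the per-state response vectors, per-state
#' design matrices (all other genes, canonical order), penalty weights and
#' the fusion pairs (tree edges plus anchor pairs) tied by the
#' total-variation penalty.
#'
#' @param panel an [expression_panel()].
#' @param tree a [state_tree()] over the panel's states.
#' @param gene response gene identifier.
#' @param lambda1 sparsity penalty weight.
#' @param lambda2 fusion penalty weight.
#' @param center mean-center responses and predictor columns within each
#'   state (default `TRUE`; removes state-specific intercepts).
#' @return an object of class `neighborhood_problem` with fields `gene`,
#'   `predictors`, `states`, `y` (list), `X` (list), `lambda1`, `lambda2`,
#'   `pairs` (2-column state matrix).
#' @export
neighborhood_problem <- function(panel, tree, gene, lambda1, lambda2,
                                 center = TRUE) {
  stopifnot(inherits(panel, "expression_panel"), inherits(tree, "state_tree"))
  if (!gene %in% panel$genes) stop("unknown gene: ", gene)
  panel <- align_panel_states(panel, tree)
  predictors <- setdiff(panel$genes, gene)
  y <- list(); X <- list()
  for (s in panel$states) {
    b <- panel$blocks[[s]]
    if (center) b <- scale(b, center = TRUE, scale = FALSE)
    y[[s]] <- as.numeric(b[, gene])
    X[[s]] <- b[, predictors, drop = FALSE]
  }
  pairs <- fusion_pairs(tree)
  bad <- setdiff(c(pairs[, 1], pairs[, 2]), panel$states)
  if (length(bad) > 0L) stop("fusion pair references unknown state: ",
                             paste(bad, collapse = ", "))
  structure(
    list(gene = gene, predictors = predictors, states = panel$states,
         y = y, X = X,
         lambda1 = as.numeric(lambda1), lambda2 = as.numeric(lambda2),
         pairs = pairs),
    class = "neighborhood_problem"
  )
}

#' Objective of the joint neighborhood regression
#'
#' Direct evaluation of
#' `sum_t 0.5 * ||y_t - X_t b_t||^2 + lambda1 * sum_t ||b_t||_1 +
#'  lambda2 * sum_pairs ||b_a - b_b||_1`
#' where the pairs run over tree edges and anchor pairs.
#'
#' @param problem a [neighborhood_problem()].
#' @param betas named list (state -> coefficient vector of length p-1).
#' @return the objective value (nonnegative scalar).
#' @export
objective_value <- function(problem, betas) {
  stopifnot(inherits(problem, "neighborhood_problem"))
  q <- length(problem$predictors)
  if (!all(problem$states %in% names(betas))) {
    stop("betas must be supplied for every state")
  }
  rss <- 0
  l1 <- 0
  for (s in problem$states) {
    b <- as.numeric(betas[[s]])
    if (length(b) != q) {
      stop("beta for state '", s, "' has length ", length(b), ", expected ", q)
    }
    r <- problem$y[[s]] - as.numeric(problem$X[[s]] %*% b)
    rss <- rss + 0.5 * sum(r^2)
    l1 <- l1 + sum(abs(b))
  }
  tv <- 0
  if (nrow(problem$pairs) > 0L) {
    for (i in seq_len(nrow(problem$pairs))) {
      a <- problem$pairs[i, 1]; p2 <- problem$pairs[i, 2]
      tv <- tv + sum(abs(as.numeric(betas[[a]]) - as.numeric(betas[[p2]])))
    }
  }
  rss + problem$lambda1 * l1 + problem$lambda2 * tv
}

# ---------------------------------------------------------------------------
# ADMM core, Gram form.
#
# Solves, over B = [b_1 ... b_T] (q x T):
#   sum_t 0.5 b_t' G_t b_t - c_t' b_t
#     + lambda1 sum_t ||b_t||_1 + lambda2 sum_f ||b_{a_f} - b_{b_f}||_1
# via consensus splitting z = D(B) with D(B) = (B, differences over pairs).
# The B-update solves (blockdiag(G_t) + rho (I_T + L) %x% I_q) vec(B) = rhs,
# where L is the Laplacian of the fusion multigraph; the sparse Cholesky
# factor is computed once per rho and reused across iterations and along a
# lambda path (warm starts).
# ---------------------------------------------------------------------------
fused_gram_factor <- function(G_list, pair_idx, rho) {
  T_ <- length(G_list)
  q <- nrow(G_list[[1]])
  S <- diag(T_)
  if (ncol(pair_idx) > 0L) {
    for (f in seq_len(ncol(pair_idx))) {
      a <- pair_idx[1, f]; b <- pair_idx[2, f]
      S[a, a] <- S[a, a] + 1; S[b, b] <- S[b, b] + 1
      S[a, b] <- S[a, b] - 1; S[b, a] <- S[b, a] - 1
    }
  }
  M <- Matrix::bdiag(lapply(G_list, function(g) Matrix::Matrix(g, sparse = TRUE))) +
    rho * Matrix::kronecker(Matrix::Matrix(S, sparse = TRUE), Matrix::Diagonal(q))
  Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE)
}

# apply D and t(D) for the fusion operator
fuse_diff <- function(B, pair_idx) {
  if (ncol(pair_idx) == 0L) return(matrix(0, nrow(B), 0L))
  B[, pair_idx[1, ], drop = FALSE] - B[, pair_idx[2, ], drop = FALSE]
}

fuse_diff_t <- function(V2, pair_idx, q, T_) {
  out <- matrix(0, q, T_)
  for (f in seq_len(ncol(pair_idx))) {
    a <- pair_idx[1, f]; b <- pair_idx[2, f]
    out[, a] <- out[, a] + V2[, f]
    out[, b] <- out[, b] - V2[, f]
  }
  out
}

solve_fused_gram <- function(G_list, c_mat, pair_idx, lambda1, lambda2,
                             eps_abs = 1e-9, eps_rel = 1e-9,
                             max_iter = 50000L, rho = NULL,
                             warm = NULL, factor = NULL) {
  T_ <- length(G_list)
  q <- nrow(G_list[[1]])
  nf <- ncol(pair_idx)
  K <- q * T_
  m <- K + q * nf
  if (is.null(rho)) {
    rho <- max(lambda1, lambda2, mean(vapply(G_list, function(g) mean(diag(g)), 0)), 1e-3)
  }
  ch <- if (is.null(factor)) fused_gram_factor(G_list, pair_idx, rho) else factor
  if (is.null(warm)) {
    z1 <- matrix(0, q, T_); z2 <- matrix(0, q, nf)
    u1 <- matrix(0, q, T_); u2 <- matrix(0, q, nf)
  } else {
    z1 <- warm$z1; z2 <- warm$z2; u1 <- warm$u1; u2 <- warm$u2
  }
  B <- z1
  refactor_left <- 30L
  iter <- 0L
  converged <- FALSE
  pri <- dua <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1L
    V <- (z1 - u1) + fuse_diff_t(z2 - u2, pair_idx, q, T_)
    rhs <- c_mat + rho * V
    B <- matrix(as.numeric(Matrix::solve(ch, as.numeric(rhs), system = "A")), q, T_)
    DB2 <- fuse_diff(B, pair_idx)
    z1_old <- z1; z2_old <- z2
    z1 <- soft_threshold(B + u1, lambda1 / rho)
    z2 <- soft_threshold(DB2 + u2, lambda2 / rho)
    u1 <- u1 + B - z1
    u2 <- u2 + DB2 - z2
    if (iter %% 10L == 0L || iter == max_iter) {
      r2 <- sum((B - z1)^2) + sum((DB2 - z2)^2)
      sm <- (z1_old - z1) + fuse_diff_t(z2_old - z2, pair_idx, q, T_)
      s2 <- rho^2 * sum(sm^2)
      pri <- sqrt(r2); dua <- sqrt(s2)
      nDB <- sqrt(sum(B^2) + sum(DB2^2))
      nz <- sqrt(sum(z1^2) + sum(z2^2))
      du <- rho * sqrt(sum(((u1) + fuse_diff_t(u2, pair_idx, q, T_))^2))
      eps_pri <- sqrt(m) * eps_abs + eps_rel * max(nDB, nz)
      eps_dua <- sqrt(K) * eps_abs + eps_rel * du
      if (pri <= eps_pri && dua <= eps_dua) { converged <- TRUE; break }
      if (iter %% 100L == 0L && refactor_left > 0L) {
        if (pri > 10 * dua) {
          rho <- rho * 2; u1 <- u1 / 2; u2 <- u2 / 2
          ch <- fused_gram_factor(G_list, pair_idx, rho)
          refactor_left <- refactor_left - 1L
        } else if (dua > 10 * pri) {
          rho <- rho / 2; u1 <- u1 * 2; u2 <- u2 * 2
          ch <- fused_gram_factor(G_list, pair_idx, rho)
          refactor_left <- refactor_left - 1L
        }
      }
    }
  }
  list(B = z1, B_raw = B, converged = converged, iter = iter,
       primal = pri, dual = dua, rho = rho, factor = ch,
       warm = list(z1 = z1, z2 = z2, u1 = u1, u2 = u2))
}

#' Solve one gene's joint neighborhood problem
#'
#' Minimizes the convex objective of [objective_value()] by ADMM on the Gram
#' (sufficient-statistic) form of the problem. The returned coefficients are
#' the sparse consensus copy of the ADMM iterate, so zeros are exact;
#' residual tolerances are derived from `solver_tol` and chosen so that the
#' objective at the returned point is within `solver_tol` of the optimum on
#' problems of the tested scale.
#'
#' @param problem a [neighborhood_problem()].
#' @param solver_tol target absolute objective accuracy (default `1e-6`).
#' @param zero_tol entries with absolute value at or below this are set to
#'   exact zero (default `1e-6`).
#' @param max_iter ADMM iteration budget.
#' @return named list (state -> coefficient vector, names = predictor genes).
#' @examples
#' col <- build_tree_collection(p = 8, segment_len = 1, seed = 1)
#' pan <- sample_panel(col, n_per_state = 10, seed = 2)
#' pr <- neighborhood_problem(pan, col$tree, "g1", lambda1 = 2, lambda2 = 0.5)
#' fit <- fit_gene(pr)
#' @export
fit_gene <- function(problem, solver_tol = 1e-6, zero_tol = 1e-6,
                     max_iter = 50000L) {
  stopifnot(inherits(problem, "neighborhood_problem"))
  n_t <- vapply(problem$y, length, 0L)
  if (any(n_t < 2L)) {
    stop("insufficient replicates: state(s) ",
         paste(names(n_t)[n_t < 2L], collapse = ", "), " have n < 2")
  }
  if (problem$lambda1 < 0 || problem$lambda2 < 0) stop("penalties must be nonnegative")
  states <- problem$states
  G_list <- lapply(states, function(s) crossprod(problem$X[[s]]))
  c_mat <- vapply(states, function(s) as.numeric(crossprod(problem$X[[s]], problem$y[[s]])),
                  numeric(length(problem$predictors)))
  c_mat <- matrix(c_mat, ncol = length(states))
  pair_idx <- t(matrix(match(problem$pairs, states), ncol = 2))
  if (nrow(problem$pairs) == 0L) pair_idx <- matrix(integer(), nrow = 2)
  eps <- max(solver_tol * 1e-3, 1e-12)
  sol <- solve_fused_gram(G_list, c_mat, pair_idx,
                          problem$lambda1, problem$lambda2,
                          eps_abs = eps, eps_rel = eps, max_iter = max_iter)
  if (!sol$converged) {
    gap <- abs(sol$primal)
    stop("solver did not converge for gene '", problem$gene,
         "' within ", max_iter, " iterations (primal residual ",
         signif(gap, 3), ")")
  }
  B <- sol$B
  B[abs(B) <= zero_tol] <- 0
  out <- lapply(seq_along(states), function(t) {
    setNames(B[, t], problem$predictors)
  })
  names(out) <- states
  out
}
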
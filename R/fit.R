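#' Coefficient tensor
#'
#' Per-state `p x p` matrices of neighborhood-regression coefficients:
#' `beta[[t]][g, j]` is the coefficient of gene `j` in gene `g`'s regression
#' for state `t`. Diagonals are identically zero; entries with absolute value
#' at or below the zero tolerance are exact zeros.
#'
#' @param beta named list (state -> p x p matrix with gene dimnames).
#' @param genes gene order.
#' @return an object of class `coefficient_tensor`.
#' @export
coefficient_tensor <- function(beta, genes) {
  stopifnot(is.list(beta), !is.null(names(beta)))
  for (s in names(beta)) {
    b <- beta[[s]]
    if (!is.matrix(b) || nrow(b) != length(genes) || ncol(b) != length(genes)) {
      stop("state '", s, "' matrix is not p x p")
    }
    if (!all(is.finite(b))) stop("non-finite coefficient in state '", s, "'")
    if (any(diag(b) != 0)) stop("nonzero diagonal in state '", s, "'")
  }
  structure(list(states = names(beta), genes = as.character(genes), beta = beta),
            class = "coefficient_tensor")
}

#' @export
print.coefficient_tensor <- function(x, ...) {
  nz <- vapply(x$beta, function(b) sum(b != 0), 0L)
  cat("<coefficient_tensor> p = ", length(x$genes), ", states: ",
      paste(x$states, collapse = ", "), "\n  nonzeros: ",
      paste(nz, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# centered per-state Gram matrices (p x p) and sample counts
panel_grams <- function(panel, center = TRUE) {
  lapply(panel$blocks, function(b) {
    if (center) b <- scale(b, center = TRUE, scale = FALSE)
    crossprod(b)
  })
}

#' Joint fit of all gene neighborhoods across all states
#'
#' Runs the fused neighborhood regression of [fit_gene()] for every gene
#' (each gene's problem is independent of the others, so results do not
#' depend on execution order) and assembles the per-state coefficient
#' tensors.
#'
#' @param panel an [expression_panel()]; every state needs >= 2 samples.
#' @param tree a [state_tree()] over the panel's states.
#' @param config an [analysis_config()] supplying `lambda1`, `lambda2`,
#'   `zero_tol`, `solver_tol` unless overridden.
#' @param lambda1,lambda2 optional overrides of the config penalties.
#' @return a [coefficient_tensor()] with one matrix per state (tree order).
#' @export
fit_all <- function(panel, tree, config = analysis_config(),
                    lambda1 = NULL, lambda2 = NULL) {
  res <- fit_all_path(panel, tree,
                      lambda1_grid = if (is.null(lambda1)) config$lambda1 else lambda1,
                      lambda2 = if (is.null(lambda2)) config$lambda2 else lambda2,
                      config = config)
  res[[1]]
}

#' Joint fit along a path of sparsity penalties
#'
#' Same model as [fit_all()], solved for every value in `lambda1_grid` with
#' a shared factorization and warm starts (the grid is processed from the
#' largest penalty down).
#'
#' @inheritParams fit_all
#' @param lambda1_grid vector of sparsity penalties.
#' @param lambda2 fusion penalty (fixed along the path).
#' @return named list (lambda1 value -> [coefficient_tensor()]), in the
#'   order of the supplied grid.
#' @export
fit_all_path <- function(panel, tree, lambda1_grid, lambda2,
                         config = analysis_config()) {
  stopifnot(inherits(panel, "expression_panel"), inherits(tree, "state_tree"))
  panel <- align_panel_states(panel, tree)
  n_t <- panel_n(panel)
  if (any(n_t < 2L)) {
    stop("insufficient replicates: state(s) ",
         paste(names(n_t)[n_t < 2L], collapse = ", "), " have n < 2")
  }
  genes <- panel$genes
  p <- length(genes)
  states <- panel$states
  grams <- panel_grams(panel)
  pairs <- fusion_pairs(tree)
  pair_idx <- t(matrix(match(pairs, states), ncol = 2))
  if (nrow(pairs) == 0L) pair_idx <- matrix(integer(), nrow = 2)
  eps <- max(config$solver_tol * 1e-3, 1e-12)

  ord <- order(lambda1_grid, decreasing = TRUE)
  tensors <- lapply(lambda1_grid, function(l) {
    lapply(states, function(s) {
      m <- matrix(0, p, p, dimnames = list(genes, genes)); m
    })
  })
  for (g in seq_len(p)) {
    G_list <- lapply(states, function(s) grams[[s]][-g, -g, drop = FALSE])
    c_mat <- vapply(states, function(s) grams[[s]][-g, g], numeric(p - 1L))
    c_mat <- matrix(c_mat, ncol = length(states))
    factor <- NULL; warm <- NULL; rho <- NULL
    for (k in ord) {
      sol <- solve_fused_gram(G_list, c_mat, pair_idx,
                              lambda1_grid[k], lambda2,
                              eps_abs = eps, eps_rel = eps,
                              rho = rho, warm = warm, factor = factor)
      if (!sol$converged) {
        stop("solver did not converge for gene '", genes[g],
             "' at lambda1 = ", lambda1_grid[k])
      }
      factor <- sol$factor; warm <- sol$warm; rho <- sol$rho
      B <- sol$B
      B[abs(B) <= config$zero_tol] <- 0
      for (t in seq_along(states)) {
        tensors[[k]][[t]][g, -g] <- B[, t]
      }
    }
  }
  out <- lapply(seq_along(lambda1_grid), function(k) {
    names(tensors[[k]]) <- states
    coefficient_tensor(tensors[[k]], genes)
  })
  names(out) <- as.character(lambda1_grid)
  out
}

# lasso via compiled coordinate descent on a centered Gram; shared by the
# independent and static baselines
cd_fit_tensor <- function(gram, genes, lambda1, zero_tol, tol = 1e-10,
                          max_iter = 10000L) {
  p <- length(genes)
  B <- matrix(0, p, p, dimnames = list(genes, genes))
  for (g in seq_len(p)) {
    beta <- cd_lasso_gram(gram[-g, -g, drop = FALSE], gram[-g, g],
                          lambda1, tol, max_iter)
    beta[abs(beta) <= zero_tol] <- 0
    B[g, -g] <- beta
  }
  B
}

#' Independent per-state baseline
#'
#' Fits each state's network separately with a plain lasso (no fusion):
#' the special case of the joint model with a single state. Solved by
#' coordinate descent, so it also serves as an internal cross-check of the
#' ADMM path (the two must agree when `lambda2 = 0`).
#'
#' @inheritParams fit_all
#' @param lambda1 optional override of `config$lambda1`.
#' @return a [coefficient_tensor()] with one matrix per state.
#' @export
fit_independent <- function(panel, config = analysis_config(), lambda1 = NULL) {
  stopifnot(inherits(panel, "expression_panel"))
  l1 <- if (is.null(lambda1)) config$lambda1 else lambda1
  n_t <- panel_n(panel)
  if (any(n_t < 2L)) {
    stop("insufficient replicates: state(s) ",
         paste(names(n_t)[n_t < 2L], collapse = ", "), " have n < 2")
  }
  grams <- panel_grams(panel)
  beta <- lapply(panel$states, function(s) {
    cd_fit_tensor(grams[[s]], panel$genes, l1, config$zero_tol)
  })
  names(beta) <- panel$states
  coefficient_tensor(beta, panel$genes)
}

#' Static pooled baseline
#'
#' Pools the samples of all states into one block (then mean-centers the
#' pool) and fits a single lasso network, as a method that ignores state
#' structure entirely would.
#'
#' @inheritParams fit_independent
#' @return a [coefficient_tensor()] with a single state `"pooled"`.
#' @export
fit_static <- function(panel, config = analysis_config(), lambda1 = NULL) {
  stopifnot(inherits(panel, "expression_panel"))
  l1 <- if (is.null(lambda1)) config$lambda1 else lambda1
  pooled <- do.call(rbind, panel$blocks)
  if (nrow(pooled) < 2L) stop("pooled panel needs at least 2 samples")
  gram <- crossprod(scale(pooled, center = TRUE, scale = FALSE))
  B <- cd_fit_tensor(gram, panel$genes, l1, config$zero_tol)
  coefficient_tensor(list(pooled = B), panel$genes)
}
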
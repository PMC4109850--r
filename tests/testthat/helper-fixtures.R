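# Shared fixtures, all generated in code.

# small three-state chain tree (root r, child m, leaf l); the default anchor
# rule adds (l, r)
chain_tree <- function() {
  state_tree(c(r = NA, m = "r", l = "m"))
}

# the five-state topology of the breast-cell analysis: root S1, child T4,
# three reverted groups under T4, each anchored back to S1
breast_tree <- function() {
  state_tree(c(S1 = NA, T4 = "S1",
               `EGFR/ITGB1-T4R` = "T4", `PI3K/MAPKK-T4R` = "T4",
               `MMP-T4R` = "T4"))
}

# deterministic toy panel: `states` blocks of n x p standard normals
toy_panel <- function(p = 4, n = 3, states = c("r", "m", "l"), seed = 42) {
  set.seed(seed)
  genes <- paste0("g", seq_len(p))
  blocks <- lapply(states, function(s) {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0(s, "_", seq_len(n)), genes))
    m
  })
  names(blocks) <- states
  expression_panel(blocks)
}

# random joint-neighborhood instance i (used for the frozen convex-solver
# reference in test-acceptance.R): p in 3..6 genes, T in 1..3 chain states,
# n = 5 samples per state, uniform penalties. Deterministic given i.
random_solver_instance <- function(i) {
  set.seed(1000L + i)
  p <- sample(3:6, 1L)
  T_ <- sample(1:3, 1L)
  n <- 5L
  states <- paste0("s", seq_len(T_))
  parent <- c(NA_character_, states[-T_])
  names(parent) <- states
  tree <- state_tree(parent)
  genes <- paste0("g", seq_len(p))
  blocks <- lapply(states, function(s) {
    matrix(rnorm(n * p), n, p,
           dimnames = list(paste0(s, "_", seq_len(n)), genes))
  })
  names(blocks) <- states
  panel <- expression_panel(blocks)
  lambda1 <- runif(1, 0.5, 3)
  lambda2 <- runif(1, 0.1, 2)
  problem <- neighborhood_problem(panel, tree, "g1", lambda1, lambda2)
  list(panel = panel, tree = tree, problem = problem,
       lambda1 = lambda1, lambda2 = lambda2, p = p, T_ = T_)
}

# panel whose states all share one ground-truth precision (for the
# static-vs-independent large-n check)
shared_truth_panel <- function(p = 6, n = 400, states = c("a", "b"), seed = 9) {
  adj <- with_seed_helper(seed, generate_root_network(p))
  omega <- adjacency_to_precision(adj, seed = seed + 1L)
  genes <- rownames(adj)
  set.seed(seed + 2L)
  R <- chol(solve(omega))
  blocks <- lapply(states, function(s) {
    x <- matrix(rnorm(n * p), n, p) %*% R
    dimnames(x) <- list(paste0(s, "_", seq_len(n)), genes)
    x
  })
  names(blocks) <- states
  list(panel = expression_panel(blocks), adj = adj, omega = omega)
}

# tiny wrapper so helpers can use seeded generators without touching the
# caller's RNG stream
with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# brute-force objective: literal triple loop, independent of objective_value's
# vectorized path
brute_objective <- function(problem, betas) {
  total <- 0
  for (s in problem$states) {
    y <- problem$y[[s]]; X <- problem$X[[s]]; b <- betas[[s]]
    for (r in seq_along(y)) {
      pred <- 0
      for (j in seq_along(b)) pred <- pred + X[r, j] * b[j]
      total <- total + 0.5 * (y[r] - pred)^2
    }
    for (j in seq_along(b)) total <- total + problem$lambda1 * abs(b[j])
  }
  if (nrow(problem$pairs) > 0L) {
    for (i in seq_len(nrow(problem$pairs))) {
      ba <- betas[[problem$pairs[i, 1]]]
      bb <- betas[[problem$pairs[i, 2]]]
      for (j in seq_along(ba)) total <- total + problem$lambda2 * abs(ba[j] - bb[j])
    }
  }
  total
}

# write a small expression TSV + sample map to temp files; returns the paths
write_toy_panel_files <- function(panel, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  expr <- file.path(dir, "expr.tsv")
  map <- file.path(dir, "map.tsv")
  write_panel(panel, expr, map)
  list(expr = expr, map = map, dir = dir)
}
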
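test_that("objective_value matches independent arithmetic", {
  for (i in 1:5) {
    inst <- random_solver_instance(30 + i)
    pr <- inst$problem
    set.seed(i)
    betas <- lapply(pr$states, function(s) rnorm(length(pr$predictors), sd = 0.3))
    names(betas) <- pr$states
    expect_equal(objective_value(pr, betas), brute_objective(pr, betas),
                 tolerance = 1e-12)
  }
})

test_that("objective_value degenerate cases", {
  inst <- random_solver_instance(51)
  pr <- inst$problem
  zero <- lapply(pr$states, function(s) numeric(length(pr$predictors)))
  names(zero) <- pr$states
  expect_equal(objective_value(pr, zero),
               0.5 * sum(vapply(pr$states, function(s) sum(pr$y[[s]]^2), 0)))

  # T = 1: no fusion pairs, so lambda2 is irrelevant
  pan <- toy_panel(p = 4, n = 5, states = "a", seed = 1)
  tr <- state_tree(c(a = NA))
  b <- list(a = c(0.5, -0.2, 0.1))
  o1 <- objective_value(neighborhood_problem(pan, tr, "g1", 1, 0), b)
  o2 <- objective_value(neighborhood_problem(pan, tr, "g1", 1, 1e3), b)
  expect_identical(o1, o2)

  pr_bad <- neighborhood_problem(pan, tr, "g1", 1, 0)
  expect_error(objective_value(pr_bad, list(a = c(1, 2))), "length")
})

test_that("fit_gene matches a reference lasso when T = 1, lambda2 = 0", {
  skip_if_not_installed("glmnet")
  pan <- toy_panel(p = 6, n = 12, states = "a", seed = 7)
  tr <- state_tree(c(a = NA))
  for (l1 in c(0.5, 1.5, 3)) {
    pr <- neighborhood_problem(pan, tr, "g3", lambda1 = l1, lambda2 = 0)
    fit <- fit_gene(pr)
    gl <- glmnet::glmnet(pr$X$a, pr$y$a, lambda = l1 / length(pr$y$a),
                         standardize = FALSE, intercept = FALSE, thresh = 1e-14)
    expect_lt(max(abs(fit$a - as.numeric(stats::coef(gl))[-1])), 1e-4)
  }
})

test_that("a large enough lambda1 zeroes every coefficient", {
  pan <- toy_panel(p = 4, n = 5, states = c("r", "m", "l"), seed = 8)
  tr <- chain_tree()
  pr0 <- neighborhood_problem(pan, tr, "g1", lambda1 = 1, lambda2 = 0.3)
  lmax <- max(vapply(pr0$states, function(s)
    max(abs(crossprod(pr0$X[[s]], pr0$y[[s]]))), 0))
  for (l2 in c(0, 0.3, 5)) {
    pr <- neighborhood_problem(pan, tr, "g1", lambda1 = lmax * 1.0001,
                               lambda2 = l2)
    expect_true(all(unlist(fit_gene(pr)) == 0))
  }
  # just below the threshold something survives
  pr <- neighborhood_problem(pan, tr, "g1", lambda1 = lmax * 0.5, lambda2 = 0)
  expect_gt(sum(unlist(fit_gene(pr)) != 0), 0)
})

test_that("an overwhelming fusion penalty equalizes the states to the pooled lasso", {
  skip_if_not_installed("glmnet")
  pan <- toy_panel(p = 4, n = 5, states = c("r", "m", "l"), seed = 8)
  tr <- chain_tree()
  pr <- neighborhood_problem(pan, tr, "g1", lambda1 = 0.8, lambda2 = 1e6)
  fit <- fit_gene(pr)
  expect_lt(max(abs(fit$r - fit$m)), 1e-4)
  expect_lt(max(abs(fit$r - fit$l)), 1e-4)
  # the common vector solves the pooled lasso at T * lambda1
  Xs <- do.call(rbind, pr$X); ys <- unlist(pr$y)
  gl <- glmnet::glmnet(Xs, ys, lambda = 3 * 0.8 / length(ys),
                       standardize = FALSE, intercept = FALSE, thresh = 1e-14)
  expect_lt(max(abs(fit$r - as.numeric(stats::coef(gl))[-1])), 1e-4)
})

test_that("fit_all assembles per-gene solutions and is permutation-equivariant", {
  pan <- toy_panel(p = 4, n = 6, states = c("r", "m", "l"), seed = 9)
  tr <- chain_tree()
  cfg <- analysis_config(lambda1 = 1, lambda2 = 0.5)
  tens <- fit_all(pan, tr, cfg)
  expect_identical(tens$states, tr$states)
  for (g in pan$genes) {
    pr <- neighborhood_problem(pan, tr, g, 1, 0.5)
    fg <- fit_gene(pr, solver_tol = cfg$solver_tol, zero_tol = cfg$zero_tol)
    for (s in tr$states) {
      expect_equal(unname(tens$beta[[s]][g, pr$predictors]), unname(fg[[s]]),
                   tolerance = 1e-6)
    }
  }
  # permuting gene order and inverting the permutation reproduces the fit
  perm <- c(3L, 1L, 4L, 2L)
  blocks_p <- lapply(pan$blocks, function(b) b[, perm, drop = FALSE])
  pan_p <- expression_panel(blocks_p)
  tens_p <- fit_all(pan_p, tr, cfg)
  for (s in tr$states) {
    expect_equal(tens_p$beta[[s]][pan$genes, pan$genes], tens$beta[[s]],
                 tolerance = 1e-6)
  }
  # a huge penalty gives the all-zero tensor
  tens0 <- fit_all(pan, tr, analysis_config(lambda1 = 1e4, lambda2 = 0.5))
  expect_true(all(vapply(tens0$beta, function(b) all(b == 0), TRUE)))
})

test_that("fit_independent agrees with the joint fit at lambda2 = 0", {
  # dual route: coordinate descent vs ADMM must find the same optimum
  pan <- toy_panel(p = 5, n = 7, states = c("r", "m", "l"), seed = 10)
  tr <- chain_tree()
  cfg <- analysis_config(lambda1 = 1.2, lambda2 = 0)
  ta <- fit_all(pan, tr, cfg)
  ti <- fit_independent(pan, cfg)
  for (s in tr$states) {
    expect_lt(max(abs(ta$beta[[s]] - ti$beta[[s]])), 1e-5)
  }
  # single-state panel: identical solutions
  pan1 <- toy_panel(p = 5, n = 7, states = "a", seed = 11)
  tr1 <- state_tree(c(a = NA))
  cfg1 <- analysis_config(lambda1 = 1.2, lambda2 = 0.7)
  t1 <- fit_all(pan1, tr1, cfg1)
  t2 <- fit_independent(pan1, cfg1)
  expect_lt(max(abs(t1$beta$a - t2$beta$a)), 1e-5)
  # a state with a single replicate is rejected
  bad <- expression_panel(list(
    a = pan1$blocks$a,
    b = pan1$blocks$a[1, , drop = FALSE]))
  expect_error(fit_independent(bad, cfg1), "insufficient replicates")
  expect_error(fit_all(bad, state_tree(c(a = NA, b = "a")), cfg1),
               "insufficient replicates")
})

test_that("fit_static pools samples and matches the single-state fit", {
  pan1 <- toy_panel(p = 5, n = 8, states = "a", seed = 12)
  cfg <- analysis_config(lambda1 = 1.5)
  ts <- fit_static(pan1, cfg)
  ti <- fit_independent(pan1, cfg)
  expect_identical(ts$states, "pooled")
  expect_lt(max(abs(ts$beta$pooled - ti$beta$a)), 1e-8)

  pan3 <- toy_panel(p = 5, n = 4, states = c("r", "m", "l"), seed = 13)
  expect_equal(sum(panel_n(pan3)), 12L)
})

test_that("static and independent recover the same support under a shared truth", {
  # two states drawn from one ground-truth network, n large: both baselines
  # settle on the true support at a threshold inside the signal/noise gap
  st <- shared_truth_panel(p = 8, n = 2000, states = c("a", "b"), seed = 20)
  lam_rate <- 0.075
  cfg <- analysis_config(lambda1 = lam_rate * 2000)
  ind <- symmetrize_max(fit_independent(st$panel, cfg))
  sta <- symmetrize_max(fit_static(st$panel,
                                   analysis_config(lambda1 = lam_rate * 4000)))[[1]]
  keys_truth <- with(as.data.frame(which(st$adj & upper.tri(st$adj), arr.ind = TRUE)),
                     sort(paste(pmin(row, col), pmax(row, col))))
  key_of <- function(net) {
    idx <- cbind(match(net$edges$gene_i, rownames(st$adj)),
                 match(net$edges$gene_j, rownames(st$adj)))
    sort(paste(pmin(idx[, 1], idx[, 2]), pmax(idx[, 1], idx[, 2])))
  }
  expect_identical(key_of(sta), keys_truth)
  expect_identical(key_of(ind$a), keys_truth)
  expect_identical(key_of(ind$b), keys_truth)
})

test_that("the regularization path is monotone in sparsity", {
  pan <- toy_panel(p = 6, n = 6, states = c("r", "m", "l"), seed = 14)
  tr <- chain_tree()
  pr <- neighborhood_problem(pan, tr, "g1", 1, 0.4)
  lmax <- max(vapply(pr$states, function(s)
    max(abs(crossprod(pr$X[[s]], pr$y[[s]]))), 0))
  fits <- fit_all_path(pan, tr, c(0.9, 0.1) * lmax, lambda2 = 0.4)
  nnz <- vapply(fits, function(tn) sum(vapply(tn$beta, function(b) sum(b != 0), 0L)), 0L)
  expect_gte(nnz[[2]], nnz[[1]])  # 0.1 * lmax keeps at least as many as 0.9 * lmax
})

test_that("coefficient tensors keep their structural invariants", {
  pan <- toy_panel(p = 5, n = 5, states = c("r", "m", "l"), seed = 15)
  tr <- chain_tree()
  for (tens in list(fit_all(pan, tr, analysis_config(lambda1 = 0.5, lambda2 = 0.2)),
                    fit_independent(pan, analysis_config(lambda1 = 0.5)),
                    fit_static(pan, analysis_config(lambda1 = 0.5)))) {
    for (b in tens$beta) {
      expect_true(all(is.finite(b)))
      expect_true(all(diag(b) == 0))
      nz <- b[b != 0]
      expect_true(all(abs(nz) > 1e-6))  # zero_tol truncation applied
    }
  }
})
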
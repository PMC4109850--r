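test_that("hypergeometric enrichment has the closed-form tail", {
  universe <- paste0("g", 1:20)
  sets <- gene_set_collection(list(hit = paste0("g", 1:5),
                                   miss = paste0("g", 6:10)),
                              universe)
  res <- set_enrichment(paste0("g", 1:5), sets)
  # all 5 of 5 drawn from a 5-gene set in a 20-gene universe: 1 / C(20,5)
  expect_equal(res$p[res$set == "hit"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$overlap[res$set == "miss"], 0L)
  expect_equal(res$p[res$set == "miss"], 1)

  expect_warning(set_enrichment(c("g1", "not_here"), sets), "outside")
  expect_error(suppressWarnings(set_enrichment("not_here", sets)), "empty")
})

test_that("hypergeometric and one-sided Fisher agree on random configurations", {
  set.seed(6)
  for (i in 1:50) {
    N <- sample(15:60, 1)
    universe <- paste0("g", seq_len(N))
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    gs <- gene_set_collection(list(s = sample(universe, K)), universe)
    query <- sample(universe, n)
    ph <- set_enrichment(query, gs, test = "hypergeometric")$p
    pf_ <- set_enrichment(query, gs, test = "fisher")$p
    expect_equal(ph, pf_, tolerance = 1e-12)
  }
})

test_that("enrichment p decreases as the overlap grows (exhaustive, N <= 30)", {
  for (N in c(12, 30)) {
    for (K in c(4, 7)) {
      for (n in c(5, 9)) {
        # below the smallest attainable overlap the tail is identically 1
        k_min <- max(0, n + K - N)
        p_at_k <- vapply(k_min:min(K, n), function(k)
          phyper(k - 1, K, N - K, n, lower.tail = FALSE), 0)
        expect_true(all(diff(p_at_k) < 0))
      }
    }
  }
})

test_that("p-value adjustment follows the step-up and Bonferroni formulas", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.2, "bh"), 0.2)
  expect_equal(adjust_pvalues(0.2, "bonferroni"), 0.2)
  expect_equal(adjust_pvalues(0.5, "bonferroni", m = 3), 1.0)
  expect_error(adjust_pvalues(c(0.1, 1.4), "bh"), "0, 1")

  # BH is monotone and never below the raw p-values
  set.seed(7)
  p <- runif(100)
  adj <- adjust_pvalues(p, "bh")
  expect_true(all(adj >= p))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= 0))
})

test_that("GMT files parse into collections", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tna\tg2\tg4"), f)
  gs <- read_gmt(f, paste0("g", 1:5))
  expect_named(gs$sets, c("setA", "setB"))
  expect_setequal(gs$sets$setB, c("g2", "g4"))
  writeLines("broken_line_without_genes", f)
  expect_error(read_gmt(f, paste0("g", 1:5)), "malformed")
})

test_that("the ANOVA screen matches aov and handles degeneracy", {
  # duplicated groups: F = 0, p = 1
  b <- matrix(c(1, 2, 3, 5), 4, 1, dimnames = list(NULL, "g1"))
  pan <- expression_panel(list(A = b, B = b))
  res <- anova_screen(pan, 0.05)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  # well-separated means: essentially zero p
  b2 <- matrix(rnorm(4, 0, 1e-3), 4, 1, dimnames = list(NULL, "g1"))
  pan2 <- expression_panel(list(A = b2, B = b2 + 10))
  expect_lt(anova_screen(pan2, 0.05)$p, 1e-10)

  # agreement with stats::aov on random data
  pan3 <- toy_panel(p = 5, n = 4, states = c("x", "y", "z"), seed = 8)
  res3 <- anova_screen(pan3, 0.05)
  for (g in pan3$genes) {
    vals <- unlist(lapply(pan3$blocks, function(bk) bk[, g]))
    grp <- factor(rep(names(pan3$blocks), each = 4))
    ref <- summary(stats::aov(vals ~ grp))[[1]]
    expect_equal(res3$F[res3$gene == g], ref$`F value`[1], tolerance = 1e-10)
    expect_equal(res3$p[res3$gene == g], ref$`Pr(>F)`[1], tolerance = 1e-10)
  }

  # constant genes: warning and p = 1
  bc <- matrix(1, 3, 2, dimnames = list(NULL, c("flat", "flat2")))
  panc <- expression_panel(list(A = bc, B = bc))
  expect_warning(resc <- anova_screen(panc, 0.05), "zero variance")
  expect_true(all(resc$p == 1))

  expect_error(anova_screen(expression_panel(list(A = b)), 0.05), ">= 2 states")
})

test_that("null ANOVA p-values are uniform at the 5% level", {
  set.seed(9)
  n_genes <- 5000
  blocks <- lapply(c("a", "b", "c"), function(s) {
    m <- matrix(rnorm(6 * n_genes), 6, n_genes)
    colnames(m) <- paste0("g", seq_len(n_genes))
    m
  })
  names(blocks) <- c("a", "b", "c")
  res <- anova_screen(expression_panel(blocks), 0.05)
  rate <- mean(res$p < 0.05)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
  # under the global null BH flags (essentially) nothing
  expect_lt(mean(res$significant), 0.001)
})

test_that("the pairwise t screen matches t.test", {
  b <- matrix(c(1, 2, 3, 2, 3, 4), 3, 2, dimnames = list(NULL, c("g1", "g2")))
  pan <- expression_panel(list(A = b, B = b))
  res <- pairwise_t_screen(pan, "A", "B", 0.05)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))

  pan2 <- expression_panel(list(A = b, B = b + 20))
  res2 <- pairwise_t_screen(pan2, "A", "B", 0.05)
  expect_true(all(res2$p_adj < 0.05))

  # 3-vs-3 toy against the reference implementation
  set.seed(10)
  pan3 <- toy_panel(p = 4, n = 3, states = c("A", "B"), seed = 10)
  res3 <- pairwise_t_screen(pan3, "A", "B", 0.05)
  for (g in pan3$genes) {
    ref <- stats::t.test(pan3$blocks$A[, g], pan3$blocks$B[, g],
                         var.equal = TRUE)
    expect_equal(res3$t[res3$gene == g], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res3$p[res3$gene == g], ref$p.value, tolerance = 1e-10)
  }
  expect_error(pairwise_t_screen(pan3, "A", "nope", 0.05), "unknown state")
})

test_that("survival screen stratifies by quartiles and reproduces the KM curve", {
  # 12 patients; the lower-expression group has uncensored times 1, 2, 3
  tab <- data.frame(
    sample = paste0("pt", 1:12),
    time = c(1, 2, 3, rep(10, 9)),
    event = c(1, 1, 1, rep(0, 9)),
    expression = 1:12)
  res <- survival_screen(tab, horizon_years = 2.5)
  expect_equal(as.integer(table(res$groups)), c(3L, 6L, 3L))
  # product-limit with no censoring = empirical survival: S(1)=2/3, S(2)=1/3, S(3)=0
  sm <- summary(res$fit[1], times = c(1, 2, 3))
  expect_equal(sm$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(unname(res$rate_at_horizon["lower"]), 1 / 3)
  expect_equal(res$df, 2L)

  # 8 patients: 2 / 4 / 2 split under linear-interpolation quartiles
  tab8 <- data.frame(sample = 1:8, time = 1:8, event = 1,
                     expression = 1:8)
  grp8 <- survival_screen(tab8, min_group_size = 2)$groups
  expect_equal(as.integer(table(grp8)), c(2L, 4L, 2L))

  # identical survival in all groups: log-rank statistic 0, p = 1
  tabeq <- data.frame(sample = 1:12,
                      time = rep(c(1, 2, 3, 4), 3),
                      event = rep(c(1, 1, 0, 1), 3),
                      expression = rep(1:3, each = 4))
  req <- survival_screen(tabeq, min_group_size = 2)
  expect_equal(req$logrank_chisq, 0, tolerance = 1e-12)
  expect_gte(req$p, 0.99)

  expect_error(survival_screen(transform(tab, expression = 1)), "degenerate")
  expect_error(survival_screen(tab[1:5, ]), "smaller than")
})

test_that("KM equals the empirical survival function without censoring", {
  # exhaustive over small uncensored samples
  set.seed(11)
  for (n in c(5, 8, 10)) {
    times <- sort(sample(1:20, n, replace = TRUE))
    fit <- survival::survfit(survival::Surv(times, rep(1, n)) ~ 1)
    for (t0 in unique(times)) {
      emp <- mean(times > t0)
      km <- summary(fit, times = t0)$surv
      expect_equal(km, emp, tolerance = 1e-12)
    }
  }
})

test_that("hub-wise survival screening applies Bonferroni control", {
  set.seed(12)
  n <- 40
  clinical <- data.frame(time = rexp(n, 0.1) + 0.1,
                         event = rbinom(n, 1, 0.7))
  # one gene strongly tied to survival, one pure noise
  expr <- cbind(assoc = rank(clinical$time) + rnorm(n, sd = 2),
                noise = rnorm(n))
  res <- survival_screen_hubs(clinical, expr, horizon_years = 10)
  expect_equal(res$p_bonf, pmin(1, res$p * 2))
  expect_true(all(res$p_bonf >= res$p))
})
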
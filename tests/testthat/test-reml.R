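# REML engine: oracle equivalence, closed-form designs, boundary and LRT
# behaviour, SE calibration.

test_that("single-component fit matches the grid-search oracle", {
  cohort <- quick_cohort(50, 300, h2 = 0.5, seed = 101)
  A <- compute_grm(cohort$G)
  oracle <- reml_grid_oracle(cohort$y, matrix(1, 50, 1), A$values, step = 1e-3)
  for (mth in c("eigen", "ai")) {
    fit <- fit_reml(cohort$y, A, method = mth, tol = 1e-11, max_iter = 200)
    expect_lt(abs(fit$sigma2[["genetic"]] - oracle$sigma2_g), 2e-3)
    expect_lt(abs(fit$sigma2[["residual"]] - oracle$sigma2_e), 2e-3)
  }
})

test_that("block design of 25 independent pairs matches the closed form", {
  set.seed(202)
  r <- 0.5; sg <- 0.5; se <- 0.5
  n_pairs <- 25
  A <- kronecker(diag(n_pairs), matrix(c(1, r, r, 1), 2))
  Vh <- chol(matrix(c(sg + se, r * sg, r * sg, sg + se), 2))
  y <- as.numeric(vapply(seq_len(n_pairs),
                         function(i) drop(crossprod(Vh, rnorm(2))),
                         numeric(2)))
  oracle <- paired_reml_oracle(y, r)
  expect_gt(oracle$sigma2_g, 0)  # interior optimum, closed form applies
  expect_gt(oracle$sigma2_e, 0)
  for (mth in c("eigen", "ai")) {
    fit <- fit_reml(y, A, method = mth, tol = 1e-12, max_iter = 500)
    expect_equal(fit$sigma2[["genetic"]], oracle$sigma2_g, tolerance = 1e-6)
    expect_equal(fit$sigma2[["residual"]], oracle$sigma2_e, tolerance = 1e-6)
  }
})

test_that("both engines agree and the AI likelihood trace is monotone", {
  cohort <- quick_cohort(150, 800, h2 = 0.4, seed = 33)
  A <- compute_grm(cohort$G)
  f1 <- fit_reml(cohort$y, A, method = "eigen")
  f2 <- fit_reml(cohort$y, A, method = "ai")
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-4)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-7)
  expect_true(all(diff(f2$logL_trace) > -1e-6))
  # restricted logL of the fitted model never falls below the null's
  expect_gte(f1$logL, f1$logL0 - 1e-8)
})

test_that("fit is invariant to simultaneous permutation of individuals", {
  cohort <- quick_cohort(120, 500, h2 = 0.5, seed = 44)
  A <- compute_grm(cohort$G)$values
  f1 <- fit_reml(cohort$y, A)
  set.seed(45)
  perm <- sample(120)
  f2 <- fit_reml(cohort$y[perm], A[perm, perm])
  # permutation reorders the floating-point reductions and restarts the
  # 1-D optimizer, so agreement is to optimizer precision, not epsilon
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-5)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-8)
})

test_that("ratios and flags respect their invariants across seeds", {
  for (seed in 1:5) {
    cohort <- quick_cohort(100, 400, h2 = if (seed %% 2) 0.3 else 0,
                           seed = seed)
    fit <- fit_reml(cohort$y, compute_grm(cohort$G))
    expect_true(all(fit$sigma2 >= 0))
    expect_true(all(fit$h2 >= 0 & fit$h2 <= 1))
    expect_lte(sum(fit$h2), 1 + 1e-9)
    expect_equal(fit$sigma2_P, sum(fit$sigma2), tolerance = 1e-12)
    if (fit$constrained[["genetic"]])
      expect_equal(unname(fit$h2[1]), 0)
  }
})

test_that("null traits can hit the zero boundary with p = 0.5", {
  # a pure-noise trait whose unconstrained estimate is negative
  hits <- 0
  for (seed in 301:306) {
    cohort <- quick_cohort(120, 600, h2 = 0, seed = seed)
    fit <- fit_reml(cohort$y, compute_grm(cohort$G))
    if (fit$constrained[["genetic"]]) {
      hits <- hits + 1
      expect_equal(fit$sigma2[["genetic"]], 0)
      expect_equal(fit$lrt_p, 0.5, tolerance = 1e-6)
    }
  }
  expect_gt(hits, 0)  # ~half of seeds in expectation
})

test_that("missing phenotypes are dropped listwise", {
  cohort <- quick_cohort(150, 500, h2 = 0.5, seed = 55)
  y <- cohort$y
  y[c(3, 10, 77)] <- NA
  A <- compute_grm(cohort$G)
  fit <- fit_reml(y, A)
  expect_equal(fit$n_used, 147)
  keep <- !is.na(y)
  fit2 <- fit_reml(y[keep], A$values[keep, keep])
  expect_equal(fit$sigma2, fit2$sigma2, tolerance = 1e-9)
})

test_that("reported SEs are calibrated against the empirical spread", {
  ests <- ses <- numeric(20)
  for (i in 1:20) {
    cohort <- quick_cohort(300, 1500, h2 = 0.5, seed = 400 + i)
    fit <- fit_reml(cohort$y, compute_grm(cohort$G))
    ests[i] <- fit$h2[1]; ses[i] <- fit$h2_se[1]
  }
  expect_lt(abs(mean(ests) - 0.5), 2 * sd(ests) / sqrt(20))
  expect_lt(abs(mean(ses) / sd(ests) - 1), 0.3)
})

test_that("two equal components sum to the pooled single-component fit", {
  cohort <- quick_cohort(250, 1200, h2 = 0.5, seed = 66, n_chr = 2)
  G <- cohort$G
  ids1 <- G$variants$id[G$variants$chr == "chr1"]
  ids2 <- G$variants$id[G$variants$chr == "chr2"]
  A1 <- compute_grm(subset_variants(G, ids1))$values
  A2 <- compute_grm(subset_variants(G, ids2))$values
  f2 <- fit_reml(cohort$y, list(c1 = A1, c2 = A2))
  f1 <- fit_reml(cohort$y, compute_grm(G))
  expect_lt(abs(f2$h2_total - f1$h2[[1]]),
            2 * sqrt(f2$h2_total_se^2 + f1$h2_se[[1]]^2))
})

test_that("LRT p-values use the boundary mixture", {
  expect_equal(lrt_p(0), 0.5)
  expect_equal(lrt_p(2.706), 0.05, tolerance = 1e-3)
  expect_equal(lrt_p(4, df = 1, mixture = FALSE), pchisq(4, 1, lower.tail = FALSE))
  expect_equal(lrt_p(4, df = 1), 0.5 * pchisq(4, 1, lower.tail = FALSE))
  expect_error(lrt_p(-1), "negative LRT")
  cohort <- quick_cohort(80, 300, h2 = 0.5, seed = 77)
  fit <- fit_reml(cohort$y, compute_grm(cohort$G))
  expect_equal(lrt_p(fit), fit$lrt_p)
})

test_that("bonferroni_threshold matches the multi-trait convention", {
  expect_equal(bonferroni_threshold(0.05, 49), 0.05 / 49)
  expect_equal(round(bonferroni_threshold(0.05, 49), 3), 0.001)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "k must be")
})

test_that("reml_table mirrors per-trait fits and varying n", {
  cfg <- quick_config(120, 500, seed = 88)
  cohort <- simulate_multi_trait_cohort(cfg, 3, c(0.5, 0.2, 0))
  Z <- as.matrix(cohort$phenotypes[paste0("trait", 1:3)])
  Z[1:4, 2] <- NA
  A <- compute_grm(cohort$genotypes)
  rt <- reml_table(Z, A)
  expect_equal(rt$table$n, c(120, 116, 120))
  direct <- fit_reml(Z[, 1], A)
  expect_equal(rt$table$estimate[1], unname(direct$h2[1]), tolerance = 1e-8)
  expect_equal(rt$table$p[1], direct$lrt_p, tolerance = 1e-8)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(fit_reml(rnorm(2), diag(2)), "too few observations")
  M <- matrix(rnorm(25), 5, 5)
  expect_error(fit_reml(rnorm(5), M), "symmetric")
  expect_error(fit_reml(rnorm(10), diag(5)), "conform")
})
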
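# QC filters, exact HWE test, GRM estimator, relatedness pruning.

test_that("HWE exact test handles degenerate margins and the symmetric case", {
  expect_equal(hwe_exact_test(0, 0, 40), 1)
  expect_equal(hwe_exact_test(40, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 1, 0), 1)
  # counts at exact HWE expectation for p = 0.5, n = 100: the observed het
  # count is the distribution mode, so every outcome is "as extreme"
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  expect_equal(hwe_exact_test(25, 50, 25), hwe_enum_oracle(25, 50, 25))
})

test_that("HWE exact test equals the enumeration oracle on random triples", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(5:400, 1)
    p <- runif(1, 0.05, 0.95)
    g <- table(factor(sample(0:2, n, replace = TRUE,
                             prob = c((1 - p)^2, 2 * p * (1 - p), p^2)),
                      levels = 0:2))
    expect_equal(hwe_exact_test(g[["2"]], g[["1"]], g[["0"]]),
                 hwe_enum_oracle(g[["2"]], g[["1"]], g[["0"]]),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("QC removes SNPs in filter order with a consistent report", {
  set.seed(12)
  n <- 40
  clean <- function() rbinom(n, 2, 0.4)
  X <- cbind(
    clean(), clean(), clean(), clean(),       # 4 clean SNPs
    replace(clean(), 1:3, NA),                # 7.5% missing -> missingness
    replace(clean(), 1:4, NA),                # 10% missing  -> missingness
    rep(0, n), rep(0, n), rep(2, n),          # monomorphic  -> MAF
    c(rep(0, 20), rep(2, 20))                 # no hets at p=0.5 -> HWE
  )
  res <- apply_snp_qc(toy_genotypes(X))
  rep <- res$report
  expect_equal(rep$n_input, 10)
  expect_equal(rep$n_removed_missingness, 2)
  expect_equal(rep$n_removed_maf, 3)
  expect_equal(rep$n_removed_hwe, 1)
  expect_equal(rep$n_retained, 4)
  expect_equal(rep$n_input,
               rep$n_retained + rep$n_removed_missingness +
                 rep$n_removed_maf + rep$n_removed_hwe)
  expect_equal(n_snps(res$genotypes), 4)

  # threshold semantics are strict: exactly 5% missing survives
  X2 <- cbind(clean(), replace(clean(), 1:2, NA))  # 2/40 = 5%
  res2 <- apply_snp_qc(toy_genotypes(X2))
  expect_equal(res2$report$n_removed_missingness, 0)
  expect_error(apply_snp_qc(toy_genotypes(cbind(rep(0, n)))), "every SNP")
})

test_that("GRM equals hand-computed standardized cross-products", {
  X <- rbind(c(0, 1, 2),
             c(1, 1, 0),
             c(2, 0, 1),
             c(0, 2, 2))
  G <- toy_genotypes(X)
  A <- compute_grm(G)
  p <- colMeans(X) / 2
  oracle <- matrix(0, 4, 4)
  for (j in 1:4) for (k in 1:4) {
    s <- 0
    for (i in 1:3) {
      s <- s + (X[j, i] - 2 * p[i]) * (X[k, i] - 2 * p[i]) /
        (2 * p[i] * (1 - p[i]))
    }
    oracle[j, k] <- s / 3
  }
  expect_equal(unname(A$values), oracle, tolerance = 1e-12)
  expect_true(all(A$pair_snp_counts == 3))

  # identical genotype vectors: A_12 = A_11 = A_22
  Xd <- rbind(c(0, 1, 2), c(0, 1, 2), c(2, 1, 0), c(1, 2, 0))
  Ad <- compute_grm(toy_genotypes(Xd))$values
  expect_equal(Ad[1, 2], Ad[1, 1], tolerance = 1e-12)
  expect_equal(Ad[1, 2], Ad[2, 2], tolerance = 1e-12)
})

test_that("GRM is invariant to SNP order, sample permutation, SNP duplication", {
  G <- simulate_genotypes(quick_config(60, 400, seed = 21))
  A <- compute_grm(G)$values
  # SNP order
  ids <- sample(G$variants$id)
  expect_equal(compute_grm(subset_variants(G, ids))$values, A,
               tolerance = 1e-12)
  # doubling every SNP leaves the mean unchanged
  Gdup <- genotype_matrix(cbind(G$dosages, G$dosages),
                          rbind(G$variants,
                                transform(G$variants, id = paste0(id, "_b"))),
                          G$samples)
  expect_equal(unname(compute_grm(Gdup)$values), unname(A), tolerance = 1e-12)
  # sample permutation
  perm <- sample(G$samples)
  Ap <- compute_grm(subset_samples(G, perm))$values
  expect_equal(Ap, A[perm, perm], tolerance = 1e-12)
})

test_that("missing dosages are mean-imputed and overlap counts recorded", {
  set.seed(31)
  X <- matrix(rbinom(50 * 60, 2, 0.3), 50, 60)
  X[sample(length(X), 300)] <- NA
  X[, 1] <- c(rep(NA, 5), rbinom(45, 2, 0.3))  # deterministic overlap check
  G <- toy_genotypes(X)
  A <- compute_grm(G)
  M <- !is.na(X); storage.mode(M) <- "double"
  expect_equal(unname(A$pair_snp_counts), unname(tcrossprod(M)))
  expect_equal(max(abs(A$values - t(A$values))), 0)
  # GCTA diagonal variant stays near 1 on average
  Ag <- compute_grm(G, gcta_diagonal = TRUE)
  expect_equal(mean(diag(Ag$values)), 1, tolerance = 0.05)
  expect_false(identical(diag(Ag$values), diag(A$values)))
})

test_that("select_unrelated prunes greedily and verifiably", {
  mk_grm <- function(V, ids) grm(V, matrix(100, nrow(V), nrow(V)), ids)
  # all below cutoff: everyone retained
  V <- diag(5) * 0.9 + 0.01
  expect_equal(select_unrelated(mk_grm(V, letters[1:5])), letters[1:5])
  # one pair above cutoff: exactly one of the pair removed
  V2 <- V; V2[1, 2] <- V2[2, 1] <- 0.5
  kept <- select_unrelated(mk_grm(V2, letters[1:5]))
  expect_equal(length(kept), 4)
  expect_true(xor("a" %in% kept, "b" %in% kept))
  # 3-clique + 2 singletons: brute-force minimal removal keeps 3
  V3 <- diag(5) * 0.9 + 0.001
  for (i in 1:3) for (j in 1:3) if (i != j) V3[i, j] <- 0.6
  A3 <- mk_grm(V3, letters[1:5])
  kept3 <- select_unrelated(A3)
  expect_equal(length(kept3), 3)
  # exhaustive oracle: smallest removal set clearing all edges
  ok <- function(ids) {
    sub <- V3[ids, ids, drop = FALSE]
    all(sub[upper.tri(sub)] <= 0.025)
  }
  best <- max(vapply(0:31, function(mask) {
    ids <- which(bitwAnd(mask, 2^(0:4)) > 0)
    if (length(ids) && ok(ids)) length(ids) else 0L
  }, integer(1)))
  expect_equal(length(kept3), best)
  # post-hoc invariant on simulated relatives
  G <- simulate_genotypes(sim_config(80, 2000, n_chromosomes = 2,
                                     maf_range = c(0.1, 0.5),
                                     related_pair_fraction = 0.3,
                                     missing_rate = 0, seed = 13))
  A <- compute_grm(G)
  kept <- select_unrelated(A, 0.2)
  sub <- A$values[kept, kept]
  expect_true(all(sub[upper.tri(sub)] <= 0.2))
})

test_that("GRM round-trips through the GCTA text format", {
  G <- simulate_genotypes(sim_config(30, 200, n_chromosomes = 2,
                                     maf_range = c(0.1, 0.5),
                                     missing_rate = 0.05,
                                     related_pair_fraction = 0, seed = 17))
  A <- compute_grm(G)
  prefix <- file.path(withr::local_tempdir(), "g")
  write_grm(A, prefix)
  A2 <- read_grm(prefix)
  expect_equal(A2$values, A$values, tolerance = 1e-15)
  expect_equal(A2$pair_snp_counts, A$pair_snp_counts)
  expect_equal(A2$samples, A$samples)
})
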
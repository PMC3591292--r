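# Partitioning: region assignment, per-chromosome fits, aggregation, the
# length regression and the equal-SNP control.

test_that("SNP-count-weighted per-chromosome GRMs average to the all-SNP GRM", {
  G <- simulate_genotypes(quick_config(80, 600, seed = 91, n_chr = 4))
  A_all <- compute_grm(G)$values
  chrs <- unique(G$variants$chr)
  acc <- matrix(0, 80, 80)
  for (c in chrs) {
    ids <- G$variants$id[G$variants$chr == c]
    acc <- acc + length(ids) * compute_grm(subset_variants(G, ids))$values
  }
  expect_equal(acc / n_snps(G), A_all, tolerance = 1e-10)
})

test_that("region assignment honours padded inclusive boundaries", {
  genes <- region_set("genic",
                      data.frame(chr = "chr1",
                                 start = c(100000, 300000),
                                 end = c(120000, 310000)),
                      pad_kb = 20)
  bp <- c(80000, 100000, 139999, 140000, 281000, 300500,  # 6 inside
          79999, 140001, 500000, 1000)                    # 4 outside
  variants <- data.frame(chr = "chr1", bp = bp,
                         id = sprintf("v%02d", 1:10), stringsAsFactors = FALSE)
  split <- assign_snps_to_regions(variants, genes)
  expect_setequal(split$inside, sprintf("v%02d", 1:6))
  expect_setequal(split$outside, sprintf("v%02d", 7:10))
  # disjoint and exhaustive
  expect_length(intersect(split$inside, split$outside), 0)
  expect_setequal(c(split$inside, split$outside), variants$id)

  # empty region set: everything is outside
  empty <- region_set("none", data.frame())
  s2 <- assign_snps_to_regions(variants, empty)
  expect_length(s2$inside, 0)
  expect_setequal(s2$outside, variants$id)

  # unknown chromosome in the region table is an error naming the offender
  bad <- region_set("bad", data.frame(chr = "chrX", start = 1, end = 10))
  expect_error(assign_snps_to_regions(variants, bad), "chrX")

  # padding clips at position 1 and union length deduplicates overlap
  rs <- region_set("r", data.frame(chr = "chr1",
                                   start = c(500, 800), end = c(1000, 1200)))
  expect_equal(snpher:::region_length(rs), 701)   # union [500,1200]
  rs_pad <- region_set("r", data.frame(chr = "chr1", start = 500, end = 1000),
                       pad_kb = 1)
  expect_equal(snpher:::region_length(rs_pad), 2000)  # clipped at 1
})

test_that("random assignments are always disjoint and exhaustive", {
  set.seed(5)
  for (i in 1:10) {
    n_iv <- sample(1:5, 1)
    rs <- region_set("r", data.frame(
      chr = sample(c("chr1", "chr2"), n_iv, replace = TRUE),
      start = st <- sample.int(9e5, n_iv),
      end = st + sample.int(1e5, n_iv)), pad_kb = sample(0:50, 1))
    variants <- data.frame(chr = sample(c("chr1", "chr2"), 200, replace = TRUE),
                           bp = sample.int(1e6, 200),
                           id = sprintf("v%03d", 1:200), stringsAsFactors = FALSE)
    split <- assign_snps_to_regions(variants, rs)
    expect_length(intersect(split$inside, split$outside), 0)
    expect_setequal(c(split$inside, split$outside), variants$id)
  }
})

test_that("chromosome partition recovers a concentrated architecture", {
  cfg <- sim_config(600, 2400, n_chromosomes = 3, causal_fraction = 0.5,
                    h2_target = 0.5, related_pair_fraction = 0,
                    missing_rate = 0, covariate_effects = NULL,
                    maf_range = c(0.1, 0.5),
                    per_component_fractions = c(chr1 = 1, chr2 = 0, chr3 = 0),
                    seed = 92)
  G <- simulate_genotypes(cfg)
  sim <- simulate_phenotype(G, cfg)
  pr <- partition_by_chromosome(G, sim$phenotypes$trait1, trait = "t")
  expect_equal(pr$component_names, c("chr1", "chr2", "chr3"))
  expect_equal(pr$v_total, sum(pr$v_c), tolerance = 1e-9)
  expect_true(all(pr$v_c >= 0))
  expect_gt(pr$v_c[["chr1"]] / pr$v_total, 0.6)
  expect_equal(unname(pr$lengths),
               unname(attr(G, "chromosome_lengths")[pr$component_names]))

  # destroyed signal: permuted phenotype leaves nothing to partition
  set.seed(9)
  pr0 <- partition_by_chromosome(G, sample(sim$phenotypes$trait1), trait = "t0")
  expect_lt(pr0$v_total, 0.15)
  expect_gt(pr0$fit$lrt_p, 0.05)
})

test_that("region partition recovers in-region enrichment", {
  cfg <- quick_config(500, 2000, h2 = 0.5, seed = 93, n_chr = 2,
                      causal_fraction = 0.3)
  G <- simulate_genotypes(cfg)
  # declare the first half of chr1+chr2 SNPs "genic" via explicit intervals
  genic_ids <- G$variants$id[G$variants$bp <= 1e8]
  expect_gt(length(genic_ids), 100)
  rs <- region_set("genic", data.frame(chr = c("chr1", "chr2"),
                                       start = 1, end = 1e8))
  # force the whole genetic variance into the genic component
  cfg2 <- cfg; cfg2$per_component_fractions <- c(genic = 1, rest = 0)
  sim <- simulate_phenotype(
    G, cfg2, component_map = list(genic = genic_ids,
                                  rest = setdiff(G$variants$id, genic_ids)))
  pr <- fit_region_partition(G, sim$phenotypes$trait1, rs, trait = "t")
  expect_equal(pr$component_names, c("genic", "non-genic"))
  expect_gt(pr$v_c[["genic"]], pr$v_c[["non-genic"]])
  expect_gt(pr$v_c[["genic"]] / pr$v_total, 0.6)

  # a region set covering everything degenerates to the single-component fit
  all_rs <- region_set("all", data.frame(chr = c("chr1", "chr2"),
                                         start = 1, end = 3e8))
  pr_all <- fit_region_partition(G, sim$phenotypes$trait1, all_rs, trait = "t")
  single <- fit_reml(sim$phenotypes$trait1, compute_grm(G))
  expect_equal(unname(pr_all$v_c), unname(single$h2[1]), tolerance = 1e-8)

  # thin sides produce a warning
  thin <- region_set("thin", data.frame(chr = "chr1", start = 1, end = 2e5))
  expect_warning(fit_region_partition(G, sim$phenotypes$trait1, thin),
                 "thin side")
})

test_that("aggregation across traits follows its two modes", {
  mk <- function(trait, v) {
    snpher:::partition_result(trait, c("a", "b"), v, c(0.01, 0.01),
                              c(2e8, 1e8), c(200, 100), NULL)
  }
  r1 <- mk("t1", c(0.3, 0.2))   # fractions 0.6 / 0.4
  r2 <- mk("t2", c(0.04, 0.16)) # fractions 0.2 / 0.8
  agg_mean <- aggregate_across_traits(list(r1, r2), "mean")
  expect_equal(agg_mean$value, c(0.17, 0.18))
  agg_frac <- aggregate_across_traits(list(r1, r2), "genetic-fraction-mean")
  expect_equal(agg_frac$value, c(0.4, 0.6))
  # single trait: aggregate equals the trait itself
  expect_equal(aggregate_across_traits(list(r1), "mean")$value, c(0.3, 0.2))
  # zero-total traits are excluded
  r0 <- mk("t0", c(0, 0))
  expect_equal(aggregate_across_traits(list(r1, r2, r0), "genetic-fraction-mean")$value,
               c(0.4, 0.6))
  expect_error(aggregate_across_traits(list(r0)), "non-zero")
  # inconsistent component sets are an error
  r3 <- snpher:::partition_result("t3", c("a", "c"), c(0.1, 0.1),
                                  c(0.01, 0.01), c(1, 1), c(10, 10), NULL)
  expect_error(aggregate_across_traits(list(r1, r3)), "inconsistent")
})

test_that("length regression matches the normal-equations oracle", {
  # exact proportionality
  lr <- length_variance_regression(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(lr$slope, 2, tolerance = 1e-12)
  expect_equal(lr$intercept, 0, tolerance = 1e-12)
  expect_equal(lr$r2, 1, tolerance = 1e-12)

  # 5-point toy against the textbook normal equations
  x <- c(1.2, 2.5, 3.1, 4.8, 6.0)
  y <- c(0.9, 2.2, 2.7, 5.4, 5.8)
  lr2 <- length_variance_regression(y, x)
  n <- 5
  sxx <- sum((x - mean(x))^2)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mean(x)
  res <- y - b0 - b1 * x
  s2 <- sum(res^2) / (n - 2)
  expect_equal(lr2$slope, b1, tolerance = 1e-12)
  expect_equal(lr2$intercept, b0, tolerance = 1e-12)
  expect_equal(lr2$slope_se, sqrt(s2 / sxx), tolerance = 1e-12)
  expect_equal(lr2$intercept_se,
               sqrt(s2 * (1 / n + mean(x)^2 / sxx)), tolerance = 1e-12)
  expect_equal(lr2$r, cor(x, y), tolerance = 1e-12)
  expect_equal(lr2$p_slope_eq_1,
               2 * pt(abs((b1 - 1) / sqrt(s2 / sxx)), 3, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(length_variance_regression(c(1, 2), c(1, 2)), ">= 3")
  expect_error(length_variance_regression(c(1, 2, 3), c(2, 2, 2)),
               "zero variance")
})

test_that("equal-SNP subsampling is exact, deterministic and warns", {
  G <- simulate_genotypes(quick_config(40, 900, seed = 94, n_chr = 3))
  sub <- equal_snp_subsample(G, k_per_chr = 100, seed = 7)
  expect_true(all(table(sub$variants$chr) == 100))
  sub2 <- equal_snp_subsample(G, k_per_chr = 100, seed = 7)
  expect_identical(sub, sub2)
  expect_false(identical(sub, equal_snp_subsample(G, 100, seed = 8)))
  w <- capture_warnings(big <- equal_snp_subsample(G, k_per_chr = 1000, seed = 7))
  expect_length(w, 3)  # every chromosome is short of 1000 SNPs
  expect_match(w, "keeping all", all = TRUE)
  expect_equal(n_snps(big), n_snps(G))
})
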
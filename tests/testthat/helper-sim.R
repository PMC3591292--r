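# Shared fixture builders. All fixtures are generated in code at test time.

# small clean cohort: no relatives, no missingness, fully causal
quick_config <- function(n, m, h2 = 0.5, seed = 1, n_chr = 3,
                         causal_fraction = 1, maf_range = c(0.1, 0.5), ...) {
  # MAF floor 0.1 keeps small-n fixtures free of chance monomorphs
  sim_config(n_individuals = n, n_snps = m, n_chromosomes = n_chr,
             causal_fraction = causal_fraction, h2_target = h2,
             related_pair_fraction = 0, missing_rate = 0, maf_range = maf_range,
             covariate_effects = NULL, seed = seed, ...)
}

# genotypes + adjusted-scale phenotype (no covariates, so the phenotype is
# already on the z-score-free scale used by the REML engine)
quick_cohort <- function(n, m, h2 = 0.5, seed = 1, n_chr = 3,
                         causal_fraction = 1, ...) {
  cfg <- quick_config(n, m, h2 = h2, seed = seed, n_chr = n_chr,
                      causal_fraction = causal_fraction, ...)
  G <- simulate_genotypes(cfg)
  sim <- simulate_phenotype(G, cfg)
  list(G = G, y = sim$phenotypes$trait1, truth = sim$truth, config = cfg)
}

# hand-specified tiny genotype matrix
toy_genotypes <- function(dosages, chr = NULL, bp = NULL) {
  m <- ncol(dosages)
  if (is.null(chr)) chr <- rep("chr1", m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  genotype_matrix(dosages,
                  data.frame(chr = chr, bp = bp,
                             id = sprintf("s%03d", seq_len(m)),
                             a1 = "A", a2 = "C", stringsAsFactors = FALSE),
                  samples = sprintf("i%03d", seq_len(nrow(dosages))))
}
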
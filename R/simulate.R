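# Polygenic cohort simulator.
#
# The generator draws independent SNPs under Hardy-Weinberg equilibrium with
# an array-like MAF spectrum, assigns them to chromosomes in proportion to
# physical chromosome length, and builds quantitative traits from many small
# standardized-SNP effects plus age/sex/cohort nuisance structure -- the
# statistical world assumed by GREML variance-component estimation on
# population cohorts.

# GRCh37 autosome lengths (bp); the default chromosome model.
.human_autosome_lengths <- c(
  249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
  159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
  115169878, 107349540, 102531392,  90354753,  81195210,  78077248,
   59128983,  63025520,  48129895,  51304566)

#' Simulation configuration
#'
#' Captures the cohort design for the simulator: dimensions, MAF spectrum,
#' polygenic architecture, target SNP heritability, nuisance covariate
#' effects, relatedness and missingness. Defaults describe a modern
#' genotyping-array cohort: a uniform post-QC MAF spectrum on (0.01, 0.5),
#' a diffuse polygenic architecture (5\% of SNPs causal), a trait with
#' h2_SNP = 0.15 (the middle of the 0--0.32 range typical of population
#' cohorts), 1\% missing calls and a small minority (2\%) of individuals in
#' sib-level related pairs.
#'
#' @param n_individuals,n_snps cohort dimensions.
#' @param n_chromosomes number of autosomes to simulate; lengths default to
#'   the first `n_chromosomes` human autosome lengths (GRCh37).
#' @param chromosome_lengths base-pair length per chromosome.
#' @param maf_range lower/upper bound of the uniform allele-frequency
#'   spectrum; must lie in (0, 0.5].
#' @param causal_fraction fraction of SNPs carrying a true effect, in (0,1].
#' @param h2_target fraction of phenotypic variance tagged by SNPs, in [0,1].
#' @param per_component_fractions optional named vector of genetic-variance
#'   fractions per component (components default to chromosomes); must sum
#'   to 1. When NULL, causal SNPs are allocated to chromosomes in proportion
#'   to chromosome length.
#' @param related_pair_fraction fraction of individuals that belong to a
#'   duplicated-segment pair (each pair shares 1 - `redraw_fraction` of its
#'   genotype calls).
#' @param redraw_fraction fraction of SNPs redrawn when copying an
#'   individual to create a relative; 0.5 gives roughly sib-level relatedness.
#' @param missing_rate fraction of dosage calls set to missing.
#' @param covariate_effects named list with elements `age`, `sex`, `cohort`
#'   giving nuisance effect sizes on the trait scale, or NULL for none.
#' @param seed master integer seed; every stochastic sub-draw derives its
#'   own stream from it, so equal seeds give bitwise-identical cohorts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals, n_snps,
                       n_chromosomes = 22L,
                       chromosome_lengths = NULL,
                       maf_range = c(0.01, 0.5),
                       causal_fraction = 0.05,
                       h2_target = 0.15,
                       per_component_fractions = NULL,
                       related_pair_fraction = 0.02,
                       redraw_fraction = 0.5,
                       missing_rate = 0.01,
                       covariate_effects = list(age = 0.03, sex = 0.5, cohort = 0.3),
                       seed = 1L) {
  if (n_individuals < 2) stop("n_individuals must be >= 2")
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (is.null(chromosome_lengths)) {
    if (n_chromosomes > length(.human_autosome_lengths))
      chromosome_lengths <- rep(.human_autosome_lengths,
                                length.out = n_chromosomes)
    else
      chromosome_lengths <- .human_autosome_lengths[seq_len(n_chromosomes)]
  }
  n_chromosomes <- length(chromosome_lengths)
  if (any(chromosome_lengths <= 0)) stop("chromosome_lengths must be positive")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (h2_target < 0 || h2_target > 1) stop("h2_target must be in [0, 1]")
  if (causal_fraction <= 0 || causal_fraction > 1)
    stop("causal_fraction must be in (0, 1]")
  if (!is.null(per_component_fractions)) {
    if (is.null(names(per_component_fractions)))
      stop("per_component_fractions must be named")
    if (abs(sum(per_component_fractions) - 1) > 1e-12)
      stop("per_component_fractions must sum to 1")
    if (any(per_component_fractions < 0))
      stop("per_component_fractions must be non-negative")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (related_pair_fraction < 0 || related_pair_fraction > 1)
    stop("related_pair_fraction must be in [0, 1]")
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_lengths = as.numeric(chromosome_lengths),
    maf_range = maf_range,
    causal_fraction = causal_fraction,
    h2_target = h2_target,
    per_component_fractions = per_component_fractions,
    related_pair_fraction = related_pair_fraction,
    redraw_fraction = redraw_fraction,
    missing_rate = missing_rate,
    covariate_effects = covariate_effects,
    seed = as.integer(seed)), class = "sim_config")
}

# One master seed; each named sub-draw gets its own derived 31-bit stream.
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# largest-remainder apportionment of `total` items proportional to `weights`
apportion <- function(total, weights) {
  share <- total * weights / sum(weights)
  base <- floor(share)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate array genotypes for a cohort
#'
#' Each SNP i draws its allele frequency p_i uniformly on `maf_range`;
#' dosages are the sum of two independent Bernoulli(p_i) draws, so
#' Hardy-Weinberg equilibrium holds by construction. SNPs are assigned to
#' chromosomes in proportion to chromosome length, with positions uniform
#' along the chromosome. Related pairs are created by copying one
#' individual's genotypes and redrawing a fraction of SNPs; missing calls
#' are inserted completely at random.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()]; the true chromosome lengths are attached
#'   as attribute `"chromosome_lengths"` and any related pairs as attribute
#'   `"related_pairs"` (two-column matrix of sample ids).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- config$n_individuals
  m <- config$n_snps
  per_chr <- apportion(m, config$chromosome_lengths)
  chr <- rep(paste0("chr", seq_len(config$n_chromosomes)), per_chr)
  bp <- unlist(lapply(seq_len(config$n_chromosomes), function(c) {
    k <- per_chr[c]
    if (k == 0) return(integer(0))
    sort(sample.int(config$chromosome_lengths[c], k))
  }))
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  # HWE dosage from a single uniform per call: P(0), P(1), P(2) are the
  # genotype frequencies (1-p)^2, 2p(1-p), p^2
  t0 <- (1 - p)^2
  t1 <- t0 + 2 * p * (1 - p)
  U <- matrix(runif(n * m), n, m)
  X <- (U > rep(t0, each = n)) + (U > rep(t1, each = n))

  related <- NULL
  n_pairs <- floor(config$related_pair_fraction * n / 2)
  if (n_pairs > 0) {
    src <- seq_len(n_pairs)
    dst <- n - n_pairs + seq_len(n_pairs)
    for (k in seq_len(n_pairs)) {
      X[dst[k], ] <- X[src[k], ]
      redraw <- sample.int(m, round(config$redraw_fraction * m))
      u <- runif(length(redraw))
      X[dst[k], redraw] <- (u > t0[redraw]) + (u > t1[redraw])
    }
    related <- cbind(src, dst)
  }

  if (config$missing_rate > 0) {
    nmiss <- round(config$missing_rate * length(X))
    X[sample.int(length(X), nmiss)] <- NA
  }

  samples <- sprintf("id%05d", seq_len(n))
  variants <- data.frame(
    chr = chr, bp = bp,
    id = sprintf("snp%06d", seq_len(m)),
    a1 = "A", a2 = "C", stringsAsFactors = FALSE)
  G <- genotype_matrix(X, variants, samples)
  attr(G, "true_freqs") <- stats::setNames(p, variants$id)
  attr(G, "chromosome_lengths") <-
    stats::setNames(config$chromosome_lengths,
                    paste0("chr", seq_len(config$n_chromosomes)))
  if (!is.null(related))
    attr(G, "related_pairs") <- cbind(samples[related[, 1]], samples[related[, 2]])
  G
}

#' Simulate a quantitative trait on a genotype matrix
#'
#' Causal SNPs are sampled per component (by default per chromosome, with
#' counts proportional to chromosome length); effects are drawn i.i.d.
#' normal on standardized genotypes, the aggregate genetic score is scaled
#' so that its sample variance equals `h2_target`, and independent normal
#' residuals of variance 1 - `h2_target` are added. Optional age, sex and
#' cohort nuisance effects are layered on top so that covariate adjustment
#' can be exercised downstream.
#'
#' @param G a [genotype_matrix()], typically from [simulate_genotypes()].
#' @param config a [sim_config()]; `h2` overrides `config$h2_target`.
#' @param trait name of the trait column in the returned table; also salts
#'   the derived random stream so traits are independent given the seed.
#' @param h2 optional override of the target heritability.
#' @param component_map optional named list of variant-id vectors defining
#'   the components referred to by `config$per_component_fractions`
#'   (defaults to chromosomes).
#' @return list with `phenotypes` (data.frame: sample, age, sex, cohort,
#'   trait column) and `truth` (a `sim_truth`: causal ids, effects, realized
#'   h2, realized per-component genetic-variance fractions, genetic values).
#' @export
simulate_phenotype <- function(G, config, trait = "trait1", h2 = NULL,
                               component_map = NULL) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(config, "sim_config"))
  if (is.null(h2)) h2 <- config$h2_target
  n <- n_samples(G); m <- n_snps(G)

  if (is.null(component_map)) {
    chrs <- unique(G$variants$chr)
    component_map <- split(G$variants$id, factor(G$variants$chr, levels = chrs))
  }
  fracs <- config$per_component_fractions
  if (!is.null(fracs) && !all(names(fracs) %in% names(component_map)))
    stop("per_component_fractions names must match component_map")

  n_causal <- max(1L, round(config$causal_fraction * m))
  if (n_causal == 0 && h2 > 0) stop("no causal SNPs but h2_target > 0")

  set.seed(derive_seed(config$seed, paste0("pheno-", trait)))
  if (is.null(fracs)) {
    lens <- attr(G, "chromosome_lengths")
    if (is.null(lens)) {
      lens <- vapply(component_map, function(ids)
        diff(range(G$variants$bp[G$variants$id %in% ids])) + 1, numeric(1))
    } else lens <- lens[names(component_map)]
    counts <- apportion(n_causal, lens)
  } else {
    counts <- apportion(n_causal, fracs[names(component_map)])
  }
  avail <- lengths(component_map)
  if (any(counts > avail)) {
    over <- counts > avail
    counts[over] <- avail[over]  # cap; tiny components cannot host more SNPs
  }
  if (any(counts > 0 & avail == 0))
    stop("component with positive variance fraction contains no SNPs")

  causal <- unlist(lapply(seq_along(component_map), function(c) {
    ids <- component_map[[c]]
    if (counts[c] == 0) return(character(0))
    ids[sample.int(length(ids), counts[c])]
  }))
  u <- stats::rnorm(length(causal))

  # per-causal standardized effect applied without materializing a full
  # standardized matrix: g = X_c (u/s) - sum(2 p u / s), with missing
  # dosages mean-imputed (the term they contribute is exactly the offset)
  cols <- match(causal, G$variants$id)
  pc <- colMeans(G$dosages[, cols, drop = FALSE], na.rm = TRUE) / 2
  if (any(pc <= 0) || any(pc >= 1))
    stop("monomorphic causal SNP; tighten maf_range or increase n")
  sc <- sqrt(2 * pc * (1 - pc))
  comp_of <- rep(names(component_map), counts)
  g_parts <- vapply(names(component_map), function(nm) {
    sel <- which(comp_of == nm)
    if (!length(sel)) return(rep(0, n))
    Xc <- G$dosages[, cols[sel], drop = FALSE]
    w <- u[sel] / sc[sel]
    if (anyNA(Xc)) {
      na <- which(is.na(Xc), arr.ind = TRUE)
      Xc[na] <- 2 * pc[sel][na[, 2]]
    }
    as.numeric(Xc %*% w) - sum(2 * pc[sel] * w)
  }, numeric(n))
  if (!is.null(fracs)) {
    # rescale each component's partial score to its target variance share
    for (nm in names(component_map)) {
      v <- stats::var(g_parts[, nm])
      f <- if (nm %in% names(fracs)) fracs[[nm]] else 0
      if (v > 0) {
        sc <- sqrt(f / v)
        g_parts[, nm] <- g_parts[, nm] * sc
        u[comp_of == nm] <- u[comp_of == nm] * sc
      }
    }
  }
  g_raw <- rowSums(g_parts)
  vg <- stats::var(g_raw)
  scale_g <- if (h2 > 0 && vg > 0) sqrt(h2 / vg) else 0
  g <- g_raw * scale_g
  e <- if (h2 < 1) stats::rnorm(n, sd = sqrt(1 - h2)) else rep(0, n)
  y <- g + e

  var_parts <- apply(g_parts, 2, stats::var)
  frac_parts <- if (sum(var_parts) > 0) var_parts / sum(var_parts)
    else rep(0, ncol(g_parts))

  covs <- simulate_covariates(G, config)
  raw <- y
  ce <- config$covariate_effects
  if (!is.null(ce)) {
    raw <- raw + ce$age * (covs$age - mean(covs$age)) +
      ce$sex * (covs$sex == "M") + ce$cohort * (covs$cohort == "B")
  }
  phen <- data.frame(sample = G$samples, covs, stringsAsFactors = FALSE)
  phen[[trait]] <- raw

  truth <- structure(list(
    causal_ids = causal,
    effects = u * scale_g,
    true_h2 = stats::var(g) / stats::var(y),
    true_component_fractions = frac_parts,
    genetic_values = g,
    raw_score = g_raw,
    h2_target = h2), class = "sim_truth")
  list(phenotypes = phen, truth = truth)
}

# age/sex/cohort drawn once per cohort from the master seed so that all
# traits of a multi-trait bundle share the same covariates
simulate_covariates <- function(G, config) {
  set.seed(derive_seed(config$seed, "covariates"))
  n <- n_samples(G)
  data.frame(
    age = sample(40:69, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    cohort = rep(c("A", "B"), length.out = n),
    stringsAsFactors = FALSE)
}

#' Simulate a multi-trait cohort sharing one genotype set
#'
#' Emulates a many-trait cohort design: one set of genotypes, `n_traits`
#' phenotypes with independent causal draws at the given heritabilities,
#' shared age/sex/cohort structure.
#'
#' @param config a [sim_config()].
#' @param n_traits number of traits.
#' @param h2_list per-trait target heritabilities (length `n_traits`).
#' @return list with `genotypes`, `phenotypes` (one data.frame with columns
#'   sample, age, sex, cohort, trait1..traitK) and `truths` (list of
#'   `sim_truth`, one per trait).
#' @export
simulate_multi_trait_cohort <- function(config, n_traits, h2_list) {
  if (length(h2_list) != n_traits)
    stop("h2_list must have one entry per trait")
  G <- simulate_genotypes(config)
  phen <- NULL
  truths <- vector("list", n_traits)
  for (k in seq_len(n_traits)) {
    nm <- paste0("trait", k)
    sim <- simulate_phenotype(G, config, trait = nm, h2 = h2_list[k])
    truths[[k]] <- sim$truth
    if (is.null(phen)) phen <- sim$phenotypes
    else phen[[nm]] <- sim$phenotypes[[nm]]
  }
  names(truths) <- paste0("trait", seq_len(n_traits))
  list(genotypes = G, phenotypes = phen, truths = truths)
}

#' Write a simulated cohort to disk
#'
#' Genotypes go to PLINK bed/bim/fam, phenotypes and covariates to a TSV
#' (FID, IID, age, sex, cohort, then one column per trait), and the truth
#' table (causal ids and effects per trait) to a companion TSV.
#'
#' @param cohort result of [simulate_multi_trait_cohort()].
#' @param prefix output path prefix.
#' @return invisibly, the file paths written.
#' @export
write_cohort <- function(cohort, prefix) {
  write_plink(cohort$genotypes, prefix)
  phen <- cohort$phenotypes
  out <- data.frame(FID = phen$sample, IID = phen$sample,
                    phen[, setdiff(names(phen), "sample"), drop = FALSE])
  phen_path <- paste0(prefix, ".phen.tsv")
  utils::write.table(out, phen_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- paste0(prefix, ".truth.tsv")
  tr <- do.call(rbind, lapply(names(cohort$truths), function(nm) {
    t <- cohort$truths[[nm]]
    data.frame(trait = nm, causal_id = t$causal_ids, effect = t$effects,
               true_h2 = t$true_h2, stringsAsFactors = FALSE)
  }))
  utils::write.table(tr, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paste0(prefix, c(".bed", ".bim", ".fam")), phen_path, truth_path))
}
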
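# SNP quality control: missingness, minor allele frequency, and the exact
# Hardy-Weinberg test, applied in that fixed order so that the removal
# report attributes each SNP to exactly one filter.

#' Exact two-sided Hardy-Weinberg equilibrium test
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' follows a (generalized) hypergeometric distribution under HWE. The
#' two-sided p-value is the total probability of all heterozygote counts
#' whose probability does not exceed that of the observed count -- the
#' convention of the standard exact SNP-HWE test used by PLINK. Computed by
#' the numerically stable mode-anchored recurrence.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return two-sided exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped individual is required")
  rare <- 2 * min(n_AA, n_aa) + n_Aa          # minor allele count
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  if (length(hets) == 1) return(1)
  # unnormalized probabilities by recurrence from the distribution mode:
  # P(h+2)/P(h) = (rare-h)(2n-rare-h) / ((h+2)(h+1)) with hom counts implied
  mode_h <- round(rare * (2 * n - rare) / (2 * n))
  if ((mode_h %% 2) != (rare %% 2)) mode_h <- mode_h + 1
  mode_h <- min(max(mode_h, hets[1]), hets[length(hets)])
  pr <- numeric(length(hets))
  i_mode <- match(mode_h, hets)
  pr[i_mode] <- 1
  if (i_mode < length(hets)) {
    for (i in i_mode:(length(hets) - 1)) {
      h <- hets[i]
      pr[i + 1] <- pr[i] * ((rare - h) * (2 * n - rare - h)) / ((h + 2) * (h + 1))
    }
  }
  if (i_mode > 1) {
    for (i in i_mode:2) {
      h <- hets[i]
      # downward: P(h-2)/P(h) = h(h-1) / ((rare-h+2)(2n-rare-h+2))
      pr[i - 1] <- pr[i] * (h * (h - 1)) / ((rare - h + 2) * (2 * n - rare - h + 2))
    }
  }
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

#' One-degree-of-freedom chi-square HWE test
#'
#' Alternative to [hwe_exact_test()] for large samples; no continuity
#' correction.
#'
#' @inheritParams hwe_exact_test
#' @return p-value.
#' @export
hwe_chisq_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped individual is required")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  exp_counts <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(exp_counts == 0)) return(1)
  x2 <- sum((c(n_AA, n_Aa, n_aa) - exp_counts)^2 / exp_counts)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' SNP quality control
#'
#' Removes SNPs with missingness rate strictly greater than `miss_max`,
#' then (on the survivors) SNPs with minor allele frequency strictly below
#' `maf_min`, then SNPs with an HWE test p-value strictly below
#' `hwe_alpha`. The filter order is fixed so each removed SNP is counted
#' under exactly one filter; the retained set does not depend on the order.
#'
#' @param G a [genotype_matrix()].
#' @param miss_max maximum tolerated missingness rate (default 0.05).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_alpha HWE p-value threshold (default 1e-6).
#' @param hwe_method `"exact"` (default) or `"chisq"`.
#' @return list with `genotypes` (filtered [genotype_matrix()]) and
#'   `report` (a `qc_report` with per-filter removal counts).
#' @export
apply_snp_qc <- function(G, miss_max = 0.05, maf_min = 0.01,
                         hwe_alpha = 1e-6, hwe_method = c("exact", "chisq")) {
  stopifnot(inherits(G, "genotype_matrix"))
  hwe_method <- match.arg(hwe_method)
  m0 <- n_snps(G)
  if (m0 == 0) stop("empty genotype matrix")

  miss <- colMeans(is.na(G$dosages))
  keep1 <- miss <= miss_max
  n_miss <- sum(!keep1)
  G1 <- G$dosages[, keep1, drop = FALSE]

  p <- colMeans(G1, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep2 <- !is.na(maf) & maf >= maf_min
  n_maf <- sum(!keep2)
  G2 <- G1[, keep2, drop = FALSE]

  hwe_fun <- if (hwe_method == "exact") hwe_exact_test else hwe_chisq_test
  hwe_p <- apply(G2, 2, function(x) {
    x <- x[!is.na(x)]
    hwe_fun(sum(x == 2), sum(x == 1), sum(x == 0))
  })
  keep3 <- hwe_p >= hwe_alpha
  n_hwe <- sum(!keep3)

  kept_ids <- colnames(G2)[keep3]
  if (length(kept_ids) == 0) stop("QC removed every SNP")
  out <- subset_variants(G, kept_ids)

  report <- structure(list(
    n_input = m0,
    n_removed_missingness = n_miss,
    n_removed_maf = n_maf,
    n_removed_hwe = n_hwe,
    n_retained = length(kept_ids),
    thresholds = list(miss_max = miss_max, maf_min = maf_min,
                      hwe_alpha = hwe_alpha, hwe_method = hwe_method)),
    class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC report\n")
  cat(sprintf("  input SNPs:            %d\n", x$n_input))
  cat(sprintf("  removed, missingness > %g: %d\n",
              x$thresholds$miss_max, x$n_removed_missingness))
  cat(sprintf("  removed, MAF < %g:        %d\n",
              x$thresholds$maf_min, x$n_removed_maf))
  cat(sprintf("  removed, HWE p < %g:    %d\n",
              x$thresholds$hwe_alpha, x$n_removed_hwe))
  cat(sprintf("  retained:              %d\n", x$n_retained))
  invisible(x)
}
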
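# Genome-wide association scan (per-SNP simple linear regression), variance
# explained by the top associated SNPs, and the theta_P enrichment summary:
# the fraction of SNPs passing a p-value threshold, and its correlation
# with SNP heritability across traits.

# imputed/centered dosage design shared by gwa_scan and gwa_scan_multi
gwa_design <- function(G) {
  X <- G$dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  Xc <- sweep(X, 2L, colMeans(X))
  list(Xc = Xc, Sxx = colSums(Xc^2), maf = pmin(colMeans(X) / 2,
                                               1 - colMeans(X) / 2))
}

#' Genome-wide association scan
#'
#' Per SNP, simple linear regression of the adjusted phenotype on the
#' dosage (missing dosages mean-imputed); two-sided Wald p-value from the t
#' distribution with n - 2 degrees of freedom. SNPs with zero dosage
#' variance are flagged degenerate (beta = 0, p = 1).
#'
#' @param G a [genotype_matrix()].
#' @param y adjusted phenotype vector aligned with `G` (NA rows dropped).
#' @return a `gwa_scan` data.frame: chr, bp, id, beta, se, p, maf,
#'   degenerate; attribute `n_used`.
#' @export
gwa_scan <- function(G, y) {
  out <- gwa_scan_multi(G, matrix(y, ncol = 1))[[1]]
  out
}

#' Association scans for many traits sharing one genotype matrix
#'
#' Same model as [gwa_scan()], vectorized across traits so the imputed
#' design is built once. Traits may have different missing individuals.
#'
#' @param G a [genotype_matrix()].
#' @param Y matrix of adjusted phenotypes (one column per trait).
#' @return named list of `gwa_scan` data.frames.
#' @export
gwa_scan_multi <- function(G, Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) != n_samples(G)) stop("Y rows must match samples")
  des <- gwa_design(G)
  complete <- !apply(Y, 2, anyNA)
  scans <- vector("list", ncol(Y))
  scan_one <- function(Xc, Sxx, yv) {
    n <- length(yv)
    yc <- yv - mean(yv)
    Sxy <- drop(crossprod(Xc, yc))
    Syy <- sum(yc^2)
    ok <- Sxx > 0
    beta <- ifelse(ok, Sxy / Sxx, 0)
    sse <- pmax(0, Syy - beta * Sxy)
    se <- ifelse(ok, sqrt(sse / ((n - 2) * Sxx)), NA_real_)
    tval <- ifelse(ok & se > 0, beta / se, 0)
    p <- ifelse(ok, 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE), 1)
    list(beta = beta, se = se, p = pmin(1, pmax(p, .Machine$double.xmin)),
         degenerate = !ok, n = n)
  }
  for (j in seq_len(ncol(Y))) {
    yv <- Y[, j]
    if (complete[j]) {
      r <- scan_one(des$Xc, des$Sxx, yv)
    } else {
      keep <- !is.na(yv)
      Gk <- G$dosages[keep, , drop = FALSE]
      if (anyNA(Gk)) {
        mu <- colMeans(Gk, na.rm = TRUE)
        idx <- which(is.na(Gk), arr.ind = TRUE)
        Gk[idx] <- mu[idx[, 2]]
      }
      Xck <- sweep(Gk, 2L, colMeans(Gk))
      r <- scan_one(Xck, colSums(Xck^2), yv[keep])
    }
    scan <- data.frame(chr = G$variants$chr, bp = G$variants$bp,
                       id = G$variants$id, beta = r$beta, se = r$se,
                       p = r$p, maf = des$maf, degenerate = r$degenerate,
                       stringsAsFactors = FALSE)
    attr(scan, "n_used") <- r$n
    class(scan) <- c("gwa_scan", "data.frame")
    scans[[j]] <- scan
  }
  names(scans) <- colnames(Y)
  scans
}

#' Phenotypic variance explained by the top associated SNPs
#'
#' Selects SNPs with p < `alpha`, greedily keeps the most significant SNP
#' per `window_kb` window per chromosome (a distance-based independence
#' rule; the simulated default has no LD, so physical windowing suffices),
#' fits a joint OLS of the phenotype on the kept dosages and returns the
#' adjusted R-squared. Returns 0 when no SNP passes.
#'
#' @param scan a `gwa_scan` aligned with `G`.
#' @param G the [genotype_matrix()] the scan was computed from.
#' @param y the adjusted phenotype.
#' @param alpha significance threshold (default 5e-8, genome-wide).
#' @param window_kb window size for the independence rule (default 1000).
#' @return adjusted R-squared (fraction of phenotypic variance).
#' @export
variance_explained_top_snps <- function(scan, G, y, alpha = 5e-8,
                                        window_kb = 1000) {
  sig <- which(scan$p < alpha & !scan$degenerate)
  if (length(sig) == 0) return(0)
  sig <- sig[order(scan$p[sig])]
  kept <- integer(0)
  for (i in sig) {
    clash <- any(scan$chr[kept] == scan$chr[i] &
                 abs(scan$bp[kept] - scan$bp[i]) <= window_kb * 1000)
    if (!clash) kept <- c(kept, i)
  }
  X <- G$dosages[, kept, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  ok <- !is.na(y)
  summary(stats::lm(y[ok] ~ X[ok, , drop = FALSE]))$adj.r.squared
}

#' Proportion of SNPs passing a p-value threshold
#'
#' @param scan a `gwa_scan` or a numeric vector of p-values.
#' @param threshold p-value threshold in (0, 1).
#' @return fraction of SNPs with p < threshold.
#' @export
theta_p <- function(scan, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  p <- if (is.data.frame(scan)) scan$p else scan
  mean(p < threshold)
}

#' Default threshold grid for the theta_P scan
#'
#' 0.001 to 0.201 in steps of 0.005 (41 thresholds).
#'
#' @export
default_threshold_grid <- function() seq(0.001, 0.201, by = 0.005)

#' theta_P curves for a set of scans
#'
#' @param scans list of `gwa_scan` objects (or p-value vectors), one per
#'   trait.
#' @param thresholds p-value grid (default [default_threshold_grid()]).
#' @return traits x thresholds matrix of theta_P values.
#' @export
theta_curves <- function(scans, thresholds = default_threshold_grid()) {
  M <- t(vapply(scans, function(s) {
    p <- if (is.data.frame(s)) s$p else s
    vapply(thresholds, function(t) mean(p < t), numeric(1))
  }, numeric(length(thresholds))))
  dimnames(M) <- list(names(scans), format(thresholds))
  M
}

#' Correlation scan of theta_P against SNP heritability across traits
#'
#' For each threshold, the Pearson correlation across traits between
#' theta_P and the per-trait heritability estimates. Traits with a zero
#' heritability estimate are excluded (their estimate carries no signal;
#' this mirrors dropping boundary-constrained traits). Thresholds where
#' either vector is constant yield an undefined (NA) correlation.
#'
#' @param thetas traits x thresholds matrix from [theta_curves()].
#' @param h2 per-trait heritability estimates (same order as rows).
#' @param thresholds the p-value grid matching the columns.
#' @return a `theta_scan`: thresholds, theta (matrix), correlations,
#'   argmax_threshold (threshold of maximum squared correlation), r_max.
#' @export
theta_h2_correlation_scan <- function(thetas, h2,
                                      thresholds = default_threshold_grid()) {
  thetas <- as.matrix(thetas)
  if (nrow(thetas) != length(h2)) stop("one h2 per trait row required")
  if (ncol(thetas) != length(thresholds)) stop("thresholds do not match")
  keep <- h2 > 0
  if (sum(keep) < 3) stop("need >= 3 traits with non-zero h2")
  thetas <- thetas[keep, , drop = FALSE]
  h2 <- h2[keep]
  cors <- apply(thetas, 2, function(col) {
    if (stats::sd(col) == 0 || stats::sd(h2) == 0) NA_real_
    else stats::cor(col, h2)
  })
  best <- which.max(cors^2)
  structure(list(thresholds = thresholds, theta = thetas,
                 correlations = unname(cors),
                 argmax_threshold = thresholds[best],
                 r_max = unname(cors[best]),
                 n_traits = sum(keep)), class = "theta_scan")
}

#' @export
print.theta_scan <- function(x, ...) {
  cat(sprintf(
    "theta_P scan over %d thresholds, %d traits: max r = %.3f (r2 = %.3f) at P = %g\n",
    length(x$thresholds), x$n_traits, x$r_max, x$r_max^2, x$argmax_threshold))
  invisible(x)
}
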
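# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own computational paths.

# Exact HWE p-value by full enumeration over heterozygote counts, using
# log-factorial probabilities (independent of the recurrence in the
# package implementation).
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  rare <- 2 * min(n_AA, n_aa) + n_Aa
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

# Restricted log-likelihood of y ~ N(Xb, A*sg + I*se) up to a constant,
# direct dense evaluation (no eigen shortcut, no profiling).
reml_loglik_direct <- function(y, X, A, sg, se) {
  V <- sg * A + diag(se, length(y))
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  Vi <- chol2inv(L)
  XtVi <- crossprod(X, Vi)
  M <- XtVi %*% X
  Mc <- chol(M)
  P <- Vi - crossprod(XtVi, chol2inv(Mc) %*% XtVi)
  -0.5 * (2 * sum(log(diag(L))) + 2 * sum(log(diag(Mc))) + sum(y * (P %*% y)))
}

# Brute-force grid search over (sigma2_g, sigma2_e). Uses the eigenbasis of
# A only to make the grid evaluation affordable; the likelihood itself is
# written out from its definition, independent of the package engines.
reml_grid_oracle <- function(y, X, A, step = 1e-3) {
  n <- length(y); p <- ncol(X)
  ev <- eigen(A, symmetric = TRUE)
  d <- ev$values
  ys <- drop(crossprod(ev$vectors, y))
  Xs <- crossprod(ev$vectors, X)
  vp <- var(y)
  sg_grid <- seq(0, 2 * vp, by = step)
  se_grid <- seq(step, 2 * vp, by = step)
  stopifnot(p == 1)  # intercept-only design
  xv <- Xs[, 1]
  best <- c(NA, NA); best_ll <- -Inf
  for (sg in sg_grid) {
    # vectorize over se: n x length(se_grid) matrix of V's diagonal entries
    W <- outer(d * sg, rep(1, length(se_grid))) +
      outer(rep(1, n), se_grid)
    logdetV <- colSums(log(W))
    XtViX <- colSums(xv^2 / W)
    XtViy <- colSums(xv * ys / W)
    ytViy <- colSums(ys^2 / W)
    ytPy <- ytViy - XtViy^2 / XtViX
    ll <- -0.5 * (logdetV + log(XtViX) + ytPy)
    j <- which.max(ll)
    if (ll[j] > best_ll) { best_ll <- ll[j]; best <- c(sg, se_grid[j]) }
  }
  list(sigma2_g = best[1], sigma2_e = best[2], logL = best_ll)
}

# Closed-form REML for a block design of independent pairs with within-pair
# relationship r: the restricted likelihood factorizes into pair
# differences d ~ N(0, 2(1-r) sg + 2 se), MLE mean(d^2), and pair sums
# s ~ N(2 mu, 2(1+r) sg + 2 se), REML variance var(s). Solving the two
# moment equations gives the REML argmax when both components are interior.
paired_reml_oracle <- function(y, r = 0.5) {
  n <- length(y)
  stopifnot(n %% 2 == 0)
  y1 <- y[seq(1, n, by = 2)]; y2 <- y[seq(2, n, by = 2)]
  d2 <- mean((y1 - y2)^2)   # = 2(1-r) sg + 2 se
  s2 <- var(y1 + y2)        # = 2(1+r) sg + 2 se
  sg <- (s2 - d2) / (4 * r)
  se <- (d2 - 2 * (1 - r) * sg) / 2
  list(sigma2_g = sg, sigma2_e = se)
}

# two-variable OLS (intercept + one predictor) via textbook normal
# equations, returning beta, se, two-sided p
ols_oracle <- function(x, y) {
  n <- length(y)
  X <- cbind(1, x)
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(diag(solve(XtX)) * s2)
  t <- unname(b[2] / se[2])
  list(beta = unname(b[2]), se = unname(se[2]),
       p = 2 * pt(abs(t), n - 2, lower.tail = FALSE))
}
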
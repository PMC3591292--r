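# Restricted maximum likelihood estimation of variance components for
# GRM-defined genetic components:
#
#   y ~ N(Xb, sum_c A_c sigma2_c + I sigma2_e)
#
# maximized by average-information (AI) updates with EM fallback steps
# whenever an AI step would decrease the restricted likelihood. Components
# whose estimates converge to (small) negative values are constrained at
# zero and the remaining components re-maximized. Standard errors come from
# the inverse AI matrix at convergence; heritability ratios and their SEs
# by the delta method.
#
# The restricted log-likelihood convention used throughout (constants
# dropped) is  logL = -1/2 [ log|V| + log|X'V^-1 X| + y'Py ].
#
# For a single genetic component the likelihood is maximized exactly by a
# one-dimensional search after rotating the model into the eigenbasis of
# the GRM (V is then diagonal); this is orders of magnitude faster at large
# n and is the default for single-component fits. Both engines return
# identical structures and agree to optimizer tolerance (unit-tested).

#' Fit a variance-component model by REML
#'
#' @param y phenotype vector (already covariate-adjusted); NA values are
#'   removed listwise together with the matching rows of `X` and the
#'   component matrices.
#' @param components a single [grm()] (or plain symmetric matrix), or a
#'   named list of them -- one relationship matrix per genetic component.
#' @param X fixed-effect design matrix; default intercept only.
#' @param max_iter maximum AI iterations (default 100).
#' @param tol relative restricted log-likelihood convergence tolerance
#'   (default 1e-8).
#' @param method `"auto"` (eigen path for one component, AI otherwise),
#'   `"ai"`, or `"eigen"` (single component only).
#' @param constrain constrain negative component estimates at zero and
#'   refit (default TRUE, matching standard GREML behaviour).
#' @param lrt_mixture use the 50:50 chi-square mixture for the LRT p-value
#'   (default TRUE); FALSE gives the plain chi-square.
#' @param eigen_A optional precomputed `eigen()` of the single component
#'   matrix (symmetric = TRUE), to amortize the decomposition across traits.
#' @return a `reml_fit`: per-component variance estimates `sigma2`
#'   (residual last) with `se`, phenotypic variance `sigma2_P`, ratios `h2`
#'   with `h2_se`, total genetic fraction `h2_total` (+ SE), restricted
#'   log-likelihoods `logL` / `logL0`, `lrt` and `lrt_p`, per-component
#'   `constrained` flags, `n_used`, `iterations`, `converged`, the
#'   parameter covariance matrix `vcov`, and the accepted log-likelihood
#'   trace `logL_trace`.
#' @export
fit_reml <- function(y, components, X = NULL, max_iter = 100L, tol = 1e-8,
                     method = c("auto", "ai", "eigen"), constrain = TRUE,
                     lrt_mixture = TRUE, eigen_A = NULL) {
  method <- match.arg(method)
  Alist <- as_component_list(components)
  n_all <- length(y)
  for (A in Alist) {
    if (nrow(A) != n_all)
      stop("component matrices must conform with y")
  }
  if (is.null(X)) X <- matrix(1, n_all, 1)
  keep <- !is.na(y)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  Alist <- lapply(Alist, function(A) A[keep, keep, drop = FALSE])
  n <- length(y)
  p <- ncol(X)
  k <- length(Alist)
  if (n <= p + k) stop("too few observations for the number of parameters")

  if (method == "auto") method <- if (k == 1) "eigen" else "ai"
  if (method == "eigen" && k > 1)
    stop("eigen method supports a single genetic component")

  null <- reml_null(y, X)
  fit <- if (method == "eigen") {
    # a precomputed eigendecomposition is only valid if no row was dropped
    reml_engine_eigen(y, X, Alist[[1]],
                      eigen_A = if (all(keep)) eigen_A else NULL,
                      constrain = constrain)
  } else {
    reml_engine_ai(y, X, Alist, max_iter = max_iter, tol = tol,
                   constrain = constrain)
  }

  sigma2 <- fit$sigma2
  comp_names <- c(names(Alist), "residual")
  names(sigma2) <- comp_names
  se <- fit$se
  names(se) <- comp_names
  V <- fit$vcov
  dimnames(V) <- list(comp_names, comp_names)

  S <- sum(sigma2)
  h2 <- sigma2[seq_len(k)] / S
  h2_se <- vapply(seq_len(k), function(c) {
    g <- -sigma2[c] / S^2 + (seq_len(k + 1) == c) / S
    sqrt(max(0, drop(t(g) %*% V %*% g)))
  }, numeric(1))
  g_tot <- (c(rep(1, k), 0) * S - sum(sigma2[seq_len(k)])) / S^2
  h2_total <- sum(sigma2[seq_len(k)]) / S
  h2_total_se <- sqrt(max(0, drop(t(g_tot) %*% V %*% g_tot)))

  lrt <- 2 * (fit$logL - null$logL)
  structure(list(
    sigma2 = sigma2, se = se, vcov = V,
    sigma2_P = S,
    h2 = h2, h2_se = h2_se,
    h2_total = h2_total, h2_total_se = h2_total_se,
    logL = fit$logL, logL0 = null$logL,
    lrt = lrt,
    lrt_p = lrt_pvalue(lrt, df = k, mixture = lrt_mixture),
    constrained = stats::setNames(fit$constrained, names(Alist)),
    n_used = n, iterations = fit$iterations,
    converged = fit$converged, method = method,
    logL_trace = fit$logL_trace), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  k <- length(x$sigma2) - 1
  cat(sprintf("REML fit (%s): n = %d, %d genetic component(s)\n",
              x$method, x$n_used, k))
  for (c in seq_len(k)) {
    cat(sprintf("  %-12s sigma2 = %.4f (SE %.4f)  h2 = %.4f (SE %.4f)%s\n",
                names(x$sigma2)[c], x$sigma2[c], x$se[c], x$h2[c], x$h2_se[c],
                if (x$constrained[c]) " [constrained at 0]" else ""))
  }
  cat(sprintf("  residual     sigma2 = %.4f (SE %.4f)\n",
              x$sigma2[k + 1], x$se[k + 1]))
  cat(sprintf("  logL = %.4f  logL0 = %.4f  LRT = %.3f  p = %.3g\n",
              x$logL, x$logL0, x$lrt, x$lrt_p))
  invisible(x)
}

as_component_list <- function(components) {
  one <- function(A) {
    if (inherits(A, "grm")) A <- A$values
    A <- as.matrix(A)
    if (nrow(A) != ncol(A) || max(abs(A - t(A))) > 1e-8)
      stop("component matrices must be symmetric")
    A
  }
  if (inherits(components, "grm") || is.matrix(components))
    return(list(genetic = one(components)))
  out <- lapply(components, one)
  if (is.null(names(out)) || any(names(out) == ""))
    names(out) <- paste0("g", seq_along(out))
  out
}

# Restricted log-likelihood of the covariance-free null model V = I sigma2_e;
# closed form: sigma2_e = RSS/(n-p).
reml_null <- function(y, X) {
  qx <- qr(X)
  res <- qr.resid(qx, y)
  n <- length(y); p <- ncol(X)
  rss <- sum(res^2)
  s2 <- rss / (n - p)
  logdetXtX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  logL <- -0.5 * ((n - p) * log(s2) + as.numeric(logdetXtX) + (n - p))
  list(logL = logL, sigma2_e = s2)
}

# ---------------------------------------------------------------------------
# AI-REML engine (any number of components)

reml_engine_ai <- function(y, X, Alist, max_iter = 100L, tol = 1e-8,
                           constrain = TRUE) {
  n <- length(y); p <- ncol(X); k <- length(Alist)
  vp <- stats::var(y)
  floor_val <- 1e-6 * vp
  theta <- rep(vp / (k + 1), k + 1)

  eval_state <- function(theta) {
    V <- diag(theta[k + 1], n)
    for (c in seq_len(k)) V <- V + theta[c] * Alist[[c]]
    L <- tryCatch(chol(V), error = function(e) NULL)
    jitter <- 1e-8 * vp
    tries <- 0
    while (is.null(L) && tries < 3) {  # jitter-and-retry on non-PD V
      V <- V + diag(jitter, n)
      jitter <- jitter * 100
      tries <- tries + 1
      L <- tryCatch(chol(V), error = function(e) NULL)
    }
    if (is.null(L)) return(NULL)
    logdetV <- 2 * sum(log(diag(L)))
    Vi <- chol2inv(L)
    XtVi <- crossprod(X, Vi)
    M <- XtVi %*% X
    Mc <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(Mc)) return(NULL)
    logdetM <- 2 * sum(log(diag(Mc)))
    Minv <- chol2inv(Mc)
    P <- Vi - crossprod(XtVi, Minv %*% XtVi)
    Py <- drop(P %*% y)
    logL <- -0.5 * (logdetV + logdetM + sum(y * Py))
    list(P = P, Py = Py, logL = logL)
  }

  derivs <- function(st) {
    U <- matrix(0, n, k + 1)
    trPA <- numeric(k + 1)
    for (c in seq_len(k)) {
      U[, c] <- Alist[[c]] %*% st$Py
      trPA[c] <- sum(st$P * Alist[[c]])
    }
    U[, k + 1] <- st$Py
    trPA[k + 1] <- sum(diag(st$P))
    ytPAPy <- drop(crossprod(st$Py, U))
    score <- -0.5 * (trPA - ytPAPy)
    PU <- st$P %*% U
    AI <- 0.5 * crossprod(U, PU)
    list(score = score, AI = AI, ytPAPy = ytPAPy, trPA = trPA)
  }

  st <- eval_state(theta)
  if (is.null(st)) stop("initial V not positive definite")
  trace <- st$logL
  converged <- FALSE
  iter <- 0L
  pinned <- integer(k)   # consecutive iterations a component sat on the floor
  for (iter in seq_len(max_iter)) {
    d <- derivs(st)
    em_step <- theta + theta^2 * (d$ytPAPy - d$trPA) / n
    proposal <- if (iter == 1) em_step else {
      delta <- tryCatch(solve(d$AI, d$score), error = function(e) NULL)
      if (is.null(delta)) em_step else theta + delta
    }
    proposal <- pmax(proposal, floor_val)
    st_new <- eval_state(proposal)
    halves <- 0
    while ((is.null(st_new) || st_new$logL < st$logL - 1e-10) && halves < 10) {
      proposal <- pmax((proposal + theta) / 2, floor_val)
      st_new <- eval_state(proposal)
      halves <- halves + 1
    }
    if (is.null(st_new) || st_new$logL < st$logL - 1e-10) {
      proposal <- pmax(em_step, floor_val)   # EM fallback: guaranteed uphill
      st_new <- eval_state(proposal)
      if (is.null(st_new)) stop("REML: covariance matrix not positive definite")
    }
    dL <- st_new$logL - st$logL
    theta <- proposal
    st <- st_new
    trace <- c(trace, st$logL)
    at_floor <- theta[seq_len(k)] <= floor_val * 1.01
    pinned <- ifelse(at_floor, pinned + 1L, 0L)
    if (abs(dL) < tol * (abs(st$logL) + 1)) { converged <- TRUE; break }
    # a component repeatedly driven to the floor converges to the boundary
    # only geometrically; constrain it now instead of crawling
    if (constrain && any(pinned >= 3L)) break
  }

  constrained <- rep(FALSE, k)
  logL_final <- st$logL
  if (constrain) {
    at_zero <- theta[seq_len(k)] <= floor_val * 1.01
    if (any(at_zero)) {
      constrained[at_zero] <- TRUE
      keep <- which(!at_zero)
      if (length(keep) == 0) {
        nullf <- reml_null(y, X)
        theta <- c(rep(0, k), nullf$sigma2_e)
        st <- eval_state(pmax(theta, c(rep(0, k), floor_val)))
        logL_final <- nullf$logL
        converged <- TRUE
      } else {
        sub <- reml_engine_ai(y, X, Alist[keep], max_iter = max_iter,
                              tol = tol, constrain = constrain)
        theta <- rep(0, k + 1)
        theta[keep] <- sub$sigma2[seq_along(keep)]
        theta[k + 1] <- sub$sigma2[length(sub$sigma2)]
        constrained[keep] <- sub$constrained
        st <- eval_state(theta)
        logL_final <- sub$logL
        converged <- sub$converged
      }
    }
  }
  if (!converged && max_iter > 1)
    warning("AI-REML did not converge in ", max_iter, " iterations")

  # SEs from the AI matrix over all components (constrained included, flagged)
  d <- derivs(st)
  Vc <- solve_psd(d$AI)
  list(sigma2 = theta, se = sqrt(pmax(0, diag(Vc))), vcov = Vc,
       logL = logL_final, iterations = iter, converged = converged,
       constrained = constrained, logL_trace = trace)
}

solve_psd <- function(M) {
  out <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(out)) {
    ridge <- 1e-8 * mean(abs(diag(M)))
    out <- solve(M + diag(ridge, nrow(M)))
  }
  out
}

# ---------------------------------------------------------------------------
# Exact single-component engine in the eigenbasis of A. V = sigma2_g A +
# sigma2_e I is diagonal after rotation; the ratio lambda = sigma2_g /
# sigma2_e is profiled out and maximized in one dimension.

reml_engine_eigen <- function(y, X, A, eigen_A = NULL, constrain = TRUE) {
  n <- length(y); p <- ncol(X)
  ev <- if (is.null(eigen_A)) eigen(A, symmetric = TRUE) else eigen_A
  d <- pmax(ev$values, 0)
  ys <- drop(crossprod(ev$vectors, y))
  Xs <- crossprod(ev$vectors, X)

  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- lam * d + 1
    Viy <- ys / w
    B <- Xs / w
    M <- crossprod(Xs, B)
    Mc <- chol(M)
    a <- crossprod(B, ys)
    ytPty <- sum(ys * Viy) - drop(crossprod(a, chol2inv(Mc) %*% a))
    s2e <- ytPty / (n - p)
    -0.5 * ((n - p) * log(s2e) + sum(log(w)) + 2 * sum(log(diag(Mc))) + (n - p))
  }

  lower <- log(1e-8); upper <- log(1e5)
  opt <- stats::optimize(prof, c(lower, upper), maximum = TRUE, tol = 1e-10)
  f_bound <- prof(lower)  # numerically sigma2_g = 0
  if (opt$objective <= f_bound + 1e-9) {
    lam <- 0; at_boundary <- TRUE
  } else {
    lam <- exp(opt$maximum); at_boundary <- FALSE
  }

  w <- lam * d + 1
  B <- Xs / w
  M <- crossprod(Xs, B)
  Minv <- chol2inv(chol(M))
  a <- crossprod(B, ys)
  ytPty <- sum(ys^2 / w) - drop(crossprod(a, Minv %*% a))
  s2e <- ytPty / (n - p)
  s2g <- lam * s2e
  if (at_boundary && constrain) s2g <- 0

  # quantities in the rotated basis at the optimum, same logL convention
  Vd <- s2g * d + s2e
  Vi <- 1 / Vd
  B <- Xs * Vi
  M <- crossprod(Xs, B)
  Mc <- chol(M)
  Minv <- chol2inv(Mc)
  Bt_y <- crossprod(B, ys)
  Py <- Vi * ys - drop(B %*% (Minv %*% Bt_y))
  logL <- -0.5 * (sum(log(Vd)) + 2 * sum(log(diag(Mc))) + sum(ys * Py))

  applyP <- function(v) Vi * v - drop(B %*% (Minv %*% crossprod(B, v)))
  u_g <- d * Py
  u_e <- Py
  Pu_g <- applyP(u_g)
  Pu_e <- applyP(u_e)
  AI <- 0.5 * matrix(c(sum(u_g * Pu_g), sum(u_g * Pu_e),
                       sum(u_g * Pu_e), sum(u_e * Pu_e)), 2, 2)
  Vc <- solve_psd(AI)
  list(sigma2 = c(s2g, s2e), se = sqrt(pmax(0, diag(Vc))), vcov = Vc,
       logL = logL, iterations = NA_integer_, converged = TRUE,
       constrained = at_boundary && constrain, logL_trace = logL)
}

# ---------------------------------------------------------------------------

#' Likelihood-ratio test p-value at a variance boundary
#'
#' The default null distribution is the 50:50 mixture of a point mass at
#' zero and a chi-square with `df` degrees of freedom (one genetic
#' component: p = 0.5 P(chisq_1 > LRT)), the standard reference for
#' testing variance components on the boundary.
#'
#' @param fit a `reml_fit`, or a numeric LRT statistic.
#' @param df degrees of freedom (number of dropped components); defaults to
#'   the number of genetic components in `fit`.
#' @param mixture use the 50:50 mixture (default TRUE).
#' @return p-value.
#' @export
lrt_p <- function(fit, df = NULL, mixture = TRUE) {
  if (inherits(fit, "reml_fit")) {
    if (is.null(df)) df <- length(fit$sigma2) - 1
    stat <- fit$lrt
  } else {
    stat <- fit
    if (is.null(df)) df <- 1
  }
  if (stat < -1e-4)
    stop("negative LRT beyond tolerance: full logL below null logL")
  lrt_pvalue(max(0, stat), df, mixture)
}

lrt_pvalue <- function(stat, df, mixture = TRUE) {
  stat <- max(0, stat)
  if (mixture) 0.5 * stats::pchisq(stat, df, lower.tail = FALSE)
  else stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param k number of tests (default 49 traits).
#' @return alpha / k (0.05/49 is approximately 0.00102, conventionally
#'   reported as 0.001).
#' @export
bonferroni_threshold <- function(alpha = 0.05, k = 49L) {
  if (k < 1) stop("k must be >= 1")
  alpha / k
}

#' Per-trait single-component REML table
#'
#' Fits the single-GRM model to every column of `Z`, reusing one
#' eigendecomposition of the GRM across traits that share a missingness
#' pattern. This mirrors the per-trait "variance explained by all SNPs"
#' table of a multi-trait cohort analysis.
#'
#' @param Z matrix of adjusted phenotypes (one column per trait).
#' @param A a [grm()] (or matrix) on the same samples.
#' @param ... passed to [fit_reml()].
#' @return list with `table` (data.frame: trait, n, estimate, se, p,
#'   constrained) and `fits` (list of `reml_fit`).
#' @export
reml_table <- function(Z, A, ...) {
  Z <- as.matrix(Z)
  Amat <- if (inherits(A, "grm")) A$values else as.matrix(A)
  ev <- eigen(Amat, symmetric = TRUE)
  fits <- lapply(seq_len(ncol(Z)), function(j) {
    y <- Z[, j]
    if (anyNA(y)) fit_reml(y, Amat, ...)
    else fit_reml(y, Amat, eigen_A = ev, ...)
  })
  names(fits) <- colnames(Z)
  tab <- data.frame(
    trait = colnames(Z),
    n = vapply(fits, function(f) f$n_used, integer(1)),
    estimate = vapply(fits, function(f) unname(f$h2[1]), numeric(1)),
    se = vapply(fits, function(f) unname(f$h2_se[1]), numeric(1)),
    p = vapply(fits, function(f) f$lrt_p, numeric(1)),
    constrained = vapply(fits, function(f) any(f$constrained), logical(1)),
    stringsAsFactors = FALSE)
  list(table = tab, fits = fits)
}
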
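# Covariate adjustment: within each cohort x sex group, regress the trait
# on age by ordinary least squares and standardize the residuals to
# z-scores. Missing trait or covariate values stay missing.

#' Adjust a trait for age and standardize to z-scores per group
#'
#' Within each group (by default cohort x sex) independently: OLS of the
#' trait on intercept + age, residuals divided by their standard deviation
#' (n - 1 denominator). A group whose age has zero variance falls back to
#' mean-centering with a warning. Each group must contribute at least 3
#' non-missing observations.
#'
#' @param P data.frame with a `sample` column, the covariate columns named
#'   in `group_cols`, an `age` column, and the trait column.
#' @param trait name of the trait column to adjust.
#' @param group_cols columns defining the adjustment groups
#'   (default `c("cohort", "sex")`).
#' @return numeric vector of z-scores aligned with the rows of `P`; missing
#'   trait/covariate values yield NA.
#' @export
adjust_and_standardize <- function(P, trait, group_cols = c("cohort", "sex")) {
  if (!trait %in% names(P)) stop("trait column not found: ", trait)
  if (!all(group_cols %in% names(P)))
    stop("missing grouping columns: ",
         paste(setdiff(group_cols, names(P)), collapse = ", "))
  if (!"age" %in% names(P)) stop("an `age` column is required")
  y <- as.numeric(P[[trait]])
  age <- as.numeric(P$age)
  grp <- interaction(P[group_cols], drop = TRUE, sep = ":")
  out <- rep(NA_real_, nrow(P))
  for (g in levels(grp)) {
    rows <- which(grp == g)
    ok <- rows[!is.na(y[rows]) & !is.na(age[rows])]
    if (length(ok) < 3)
      stop(sprintf("group %s has %d non-missing observations (need >= 3)",
                   g, length(ok)))
    a <- age[ok]
    if (stats::var(a) == 0) {
      warning(sprintf("group %s has zero age variance; mean-centering only", g))
      res <- y[ok] - mean(y[ok])
    } else {
      b <- stats::cov(a, y[ok]) / stats::var(a)
      res <- y[ok] - mean(y[ok]) - b * (a - mean(a))
    }
    out[ok] <- res / stats::sd(res)
  }
  names(out) <- P$sample
  out
}

#' Adjust every trait of a phenotype table
#'
#' @param P phenotype data.frame (see [adjust_and_standardize()]).
#' @param traits character vector of trait column names; defaults to every
#'   column other than `sample`, `age` and the grouping columns.
#' @inheritParams adjust_and_standardize
#' @return matrix of z-scores, one column per trait, rows aligned with `P`.
#' @export
adjust_all_traits <- function(P, traits = NULL, group_cols = c("cohort", "sex")) {
  if (is.null(traits))
    traits <- setdiff(names(P), c("sample", "FID", "IID", "age", group_cols))
  Z <- vapply(traits, function(tr) adjust_and_standardize(P, tr, group_cols),
              numeric(nrow(P)))
  rownames(Z) <- P$sample
  Z
}
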
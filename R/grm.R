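# Genetic relationship matrix (GRM) estimation and relatedness pruning.
#
# A_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i)),
# with p_i the sample allele frequency from non-missing calls and missing
# dosages mean-imputed (zero after centering). The same cross-product form
# is used on the diagonal; the within-individual diagonal correction of the
# original GREML software is available behind a flag (the two coincide in
# expectation under HWE).

#' Construct a GRM object
#'
#' @param values symmetric n x n matrix of relationship estimates.
#' @param pair_snp_counts n x n matrix of non-missing SNP overlap per pair.
#' @param samples sample ids.
#' @return a `grm` object.
#' @export
grm <- function(values, pair_snp_counts, samples) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("GRM must be square")
  if (max(abs(values - t(values))) > 1e-12) stop("GRM must be symmetric")
  if (length(samples) != nrow(values)) stop("one sample id per row required")
  if (any(pair_snp_counts < 1)) stop("pair_snp_counts must be >= 1")
  dimnames(values) <- list(samples, samples)
  dimnames(pair_snp_counts) <- NULL
  structure(list(values = values,
                 pair_snp_counts = pair_snp_counts,
                 samples = as.character(samples)), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- length(x$samples)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("grm: %d samples; mean diagonal %.4f; mean off-diagonal %+.5f\n",
              n, mean(diag(x$values)), mean(off)))
  invisible(x)
}

#' Compute the genetic relationship matrix
#'
#' @param G a [genotype_matrix()]; every SNP must be polymorphic
#'   (0 < p < 1), which QC guarantees.
#' @param gcta_diagonal if TRUE, replace the diagonal by the
#'   within-individual estimator
#'   1 + (1/m) sum_i (x^2 - (1 + 2 p) x + 2 p^2) / (2 p (1 - p)).
#'   Default FALSE (plain cross-product on the diagonal).
#' @return a [grm()].
#' @export
compute_grm <- function(G, gcta_diagonal = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  p <- allele_freq(G)
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP reached compute_grm; QC contract violated")
  m <- n_snps(G)
  W <- standardized_dosages(G, p)
  A <- tcrossprod(W) / m
  if (gcta_diagonal) {
    X <- G$dosages
    num <- X^2 - sweep(X, 2L, 1 + 2 * p, `*`)
    num <- sweep(num, 2L, 2 * p^2, `+`)
    num <- sweep(num, 2L, 2 * p * (1 - p), `/`)
    diag(A) <- 1 + rowMeans(num, na.rm = TRUE)
  }
  if (anyNA(G$dosages)) {
    Mobs <- !is.na(G$dosages)
    storage.mode(Mobs) <- "double"
    counts <- tcrossprod(Mobs)
  } else {
    counts <- matrix(m, n_samples(G), n_samples(G))
  }
  A <- (A + t(A)) / 2  # enforce exact symmetry against rounding
  grm(A, counts, G$samples)
}

#' Select an unrelated subset of samples
#'
#' Greedy pruning: while any pair exceeds the cutoff, remove the individual
#' involved in the largest number of over-cutoff pairs (ties broken by the
#' lexicographically smallest sample id). The result is deterministic and
#' guarantees that no retained pair has a relationship estimate above the
#' cutoff.
#'
#' @param A a [grm()].
#' @param cutoff relationship threshold; pairs with estimate strictly
#'   greater than this are split (default 0.025).
#' @return character vector of retained sample ids, in original order.
#' @export
select_unrelated <- function(A, cutoff = 0.025) {
  stopifnot(inherits(A, "grm"))
  V <- A$values
  n <- nrow(V)
  over <- which(upper.tri(V) & V > cutoff, arr.ind = TRUE)
  active <- rep(TRUE, n)
  if (nrow(over) > 0) {
    edges <- over  # two-column matrix of row/col indices
    repeat {
      live <- active[edges[, 1]] & active[edges[, 2]]
      if (!any(live)) break
      deg <- tabulate(c(edges[live, 1], edges[live, 2]), nbins = n)
      worst <- which(deg == max(deg))
      drop <- worst[order(A$samples[worst])[1]]
      active[drop] <- FALSE
    }
  }
  A$samples[active]
}

#' Write a GRM in the GCTA text convention
#'
#' Writes `<prefix>.grm.gz` (gzip TSV: index1, index2, non-missing SNP
#' count, relationship; lower triangle including the diagonal, 1-based
#' indices with index1 >= index2) and `<prefix>.grm.id` (FID, IID).
#'
#' @param A a [grm()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_grm <- function(A, prefix) {
  stopifnot(inherits(A, "grm"))
  n <- length(A$samples)
  i <- rep(seq_len(n), seq_len(n))
  j <- unlist(lapply(seq_len(n), seq_len))
  idx <- cbind(i, j)
  lines <- sprintf("%d\t%d\t%d\t%.17g", i, j,
                   as.integer(A$pair_snp_counts[idx]), A$values[idx])
  gz <- gzfile(paste0(prefix, ".grm.gz"), "w")
  writeLines(lines, gz)
  close(gz)
  writeLines(paste(A$samples, A$samples, sep = "\t"),
             paste0(prefix, ".grm.id"))
  invisible(paste0(prefix, c(".grm.gz", ".grm.id")))
}

#' Read a GRM written by [write_grm()] (GCTA text convention)
#'
#' @param prefix path prefix (expects `<prefix>.grm.gz` and
#'   `<prefix>.grm.id`).
#' @return a [grm()].
#' @export
read_grm <- function(prefix) {
  idf <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)
  samples <- idf[[2]]
  n <- length(samples)
  tri <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")),
                           colClasses = "numeric")
  if (nrow(tri) != n * (n + 1) / 2)
    stop("GRM triple count does not match id file")
  V <- matrix(0, n, n)
  counts <- matrix(0, n, n)
  idx <- cbind(tri[[1]], tri[[2]])
  V[idx] <- tri[[4]]; V[idx[, 2:1]] <- tri[[4]]
  counts[idx] <- tri[[3]]; counts[idx[, 2:1]] <- tri[[3]]
  grm(V, counts, samples)
}

# Subset a GRM to the given sample ids (used after relatedness pruning).
#' @rdname select_unrelated
#' @param ids sample ids to keep.
#' @export
subset_grm <- function(A, ids) {
  idx <- match(ids, A$samples)
  if (anyNA(idx)) stop("unknown sample ids in GRM subset")
  grm(A$values[idx, idx, drop = FALSE],
      A$pair_snp_counts[idx, idx, drop = FALSE],
      A$samples[idx])
}
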
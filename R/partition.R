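# Partitioning SNP heritability across chromosomes and genomic regions:
# build one GRM per SNP subset, fit all components jointly by REML, and
# aggregate per-component variance fractions across traits. Includes the
# regression of per-component variance on DNA length and the
# equal-SNP-per-chromosome subsampling control.

#' Define a region set
#'
#' @param name label for the region set (e.g. "genic").
#' @param intervals data.frame with columns `chr`, `start`, `end`
#'   (1-based, inclusive; intervals may overlap -- union semantics).
#' @param pad_kb symmetric extension of every interval, in kilobases;
#'   padding clips at position 1.
#' @return a `region_set`.
#' @export
region_set <- function(name, intervals, pad_kb = 0) {
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (nrow(intervals) > 0) {
    if (!all(c("chr", "start", "end") %in% names(intervals)))
      stop("intervals need chr/start/end columns")
    if (any(intervals$start > intervals$end))
      stop("interval start must be <= end")
  }
  structure(list(name = name, intervals = intervals, pad_kb = pad_kb),
            class = "region_set")
}

#' Read a BED file as a region set
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention at the boundary (start+1, end unchanged).
#'
#' @param path BED file (first three columns used).
#' @inheritParams region_set
#' @export
read_bed_regions <- function(path, name = basename(path), pad_kb = 0) {
  bed <- utils::read.table(path, stringsAsFactors = FALSE)
  region_set(name, data.frame(chr = bed[[1]], start = bed[[2]] + 1,
                              end = bed[[3]], stringsAsFactors = FALSE),
             pad_kb = pad_kb)
}

#' Assign SNPs to a region set
#'
#' A SNP is in-region iff its position lies within any interval extended by
#' `pad_kb` on both sides (inclusive boundaries). The in/out partition is
#' exhaustive and disjoint.
#'
#' @param variants variant metadata data.frame (`chr`, `bp`, `id`).
#' @param regions a [region_set()].
#' @return list with `inside` and `outside` variant-id vectors.
#' @export
assign_snps_to_regions <- function(variants, regions) {
  stopifnot(inherits(regions, "region_set"))
  iv <- regions$intervals
  if (nrow(iv) == 0)
    return(list(inside = character(0), outside = variants$id))
  unknown <- setdiff(unique(iv$chr), unique(variants$chr))
  if (length(unknown) > 0)
    stop("region chromosomes absent from variants: ",
         paste(unknown, collapse = ", "))
  pad <- regions$pad_kb * 1000
  inside <- rep(FALSE, nrow(variants))
  for (c in unique(iv$chr)) {
    rows <- iv$chr == c
    vi <- which(variants$chr == c)
    if (length(vi) == 0) next
    starts <- pmax(1, iv$start[rows] - pad)
    ends <- iv$end[rows] + pad
    bp <- variants$bp[vi]
    hit <- rep(FALSE, length(vi))
    for (r in seq_along(starts))
      hit <- hit | (bp >= starts[r] & bp <= ends[r])
    inside[vi] <- hit
  }
  list(inside = variants$id[inside], outside = variants$id[!inside])
}

# total bp covered by the union of padded intervals of a region set
region_length <- function(regions, chr_lengths = NULL) {
  iv <- regions$intervals
  if (nrow(iv) == 0) return(0)
  pad <- regions$pad_kb * 1000
  total <- 0
  for (c in unique(iv$chr)) {
    rows <- which(iv$chr == c)
    s <- pmax(1, iv$start[rows] - pad)
    e <- iv$end[rows] + pad
    if (!is.null(chr_lengths) && c %in% names(chr_lengths))
      e <- pmin(e, chr_lengths[[c]])
    o <- order(s)
    s <- s[o]; e <- e[o]
    cur_s <- s[1]; cur_e <- e[1]
    for (r in seq_along(s)[-1]) {
      if (s[r] <= cur_e + 1) cur_e <- max(cur_e, e[r])
      else { total <- total + (cur_e - cur_s + 1); cur_s <- s[r]; cur_e <- e[r] }
    }
    total <- total + (cur_e - cur_s + 1)
  }
  total
}

partition_result <- function(trait, component_names, v_c, se, lengths,
                             snp_counts, fit) {
  structure(list(trait = trait, component_names = component_names,
                 v_c = stats::setNames(v_c, component_names),
                 se = stats::setNames(se, component_names),
                 v_total = sum(v_c),
                 lengths = stats::setNames(lengths, component_names),
                 snp_counts = stats::setNames(snp_counts, component_names),
                 fit = fit), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("partition of trait %s: total genetic fraction %.4f\n",
              x$trait, x$v_total))
  df <- data.frame(component = x$component_names,
                   v = round(x$v_c, 4), se = round(x$se, 4),
                   length_bp = x$lengths, n_snps = x$snp_counts)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Partition SNP heritability across chromosomes
#'
#' Builds one GRM per chromosome and fits all chromosomes jointly in a
#' multi-component REML model. Chromosomes with fewer than 2 SNPs are
#' excluded with a warning.
#'
#' @param G a [genotype_matrix()] (post-QC, pruned samples).
#' @param y adjusted phenotype vector aligned with `G`.
#' @param trait trait label carried into the result.
#' @param chromosome_lengths optional named bp lengths; defaults to the
#'   simulator-provided attribute or, failing that, the observed bp span.
#' @param ... passed to [fit_reml()].
#' @return a `partition_result` with per-chromosome variance fractions
#'   (of phenotypic variance), SEs, bp lengths and SNP counts.
#' @export
partition_by_chromosome <- function(G, y, trait = "trait",
                                    chromosome_lengths = NULL, ...) {
  chrs <- unique(G$variants$chr)
  if (length(chrs) < 2) stop("need >= 2 chromosomes to partition")
  counts <- table(factor(G$variants$chr, levels = chrs))
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("excluding chromosome(s) with < 2 SNPs: ",
            paste(small, collapse = ", "))
    chrs <- setdiff(chrs, small)
  }
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- attr(G, "chromosome_lengths")
    if (is.null(chromosome_lengths)) {
      chromosome_lengths <- vapply(chrs, function(c)
        as.numeric(diff(range(G$variants$bp[G$variants$chr == c])) + 1),
        numeric(1))
    }
  }
  grms <- lapply(chrs, function(c)
    compute_grm(subset_variants(G, G$variants$id[G$variants$chr == c]))$values)
  names(grms) <- chrs
  fit <- fit_reml(y, grms, ...)
  k <- length(chrs)
  partition_result(trait, chrs, unname(fit$h2), unname(fit$h2_se),
                   unname(chromosome_lengths[chrs]), as.integer(counts[chrs]),
                   fit)
}

#' Partition SNP heritability into region vs rest-of-genome components
#'
#' Splits SNPs by a region set (e.g. genic vs intergenic, or a pathway's
#' genes vs the rest of the genome), builds one GRM per side and fits both
#' jointly. With `per_chromosome = TRUE`, each chromosome is analysed in a
#' three-component model (that chromosome's in-region SNPs, its
#' out-of-region SNPs, and all remaining SNPs) and the per-chromosome
#' in/out estimates are collected.
#'
#' @param G a [genotype_matrix()].
#' @param y adjusted phenotype vector.
#' @param regions a [region_set()].
#' @param trait trait label.
#' @param per_chromosome fit per-chromosome in/out components
#'   (default FALSE: one genome-wide pair).
#' @param min_side_snps warn when either side has fewer SNPs than this.
#' @param ... passed to [fit_reml()].
#' @return a `partition_result` (genome-wide mode) or a data.frame of
#'   per-chromosome in/out estimates (per-chromosome mode).
#' @export
fit_region_partition <- function(G, y, regions, trait = "trait",
                                 per_chromosome = FALSE,
                                 min_side_snps = 100, ...) {
  split <- assign_snps_to_regions(G$variants, regions)
  n_in <- length(split$inside); n_out <- length(split$outside)
  if (n_in == 0) stop("region set matches no SNPs")
  if (n_in < min_side_snps || (n_out > 0 && n_out < min_side_snps))
    warning(sprintf("thin side in region partition: %d in / %d out SNPs",
                    n_in, n_out))
  chr_lengths <- attr(G, "chromosome_lengths")
  len_in <- region_length(regions, chr_lengths)
  len_total <- if (!is.null(chr_lengths)) sum(chr_lengths)
    else sum(vapply(unique(G$variants$chr), function(c)
      as.numeric(diff(range(G$variants$bp[G$variants$chr == c])) + 1),
      numeric(1)))
  in_name <- regions$name
  out_name <- paste0("non-", regions$name)

  if (!per_chromosome) {
    if (n_out == 0) {
      # region covers everything: degenerate partition = single component
      fit <- fit_reml(y, compute_grm(G)$values, ...)
      return(partition_result(trait, in_name, unname(fit$h2),
                              unname(fit$h2_se), len_in, n_in, fit))
    }
    grms <- list(compute_grm(subset_variants(G, split$inside))$values,
                 compute_grm(subset_variants(G, split$outside))$values)
    names(grms) <- c(in_name, out_name)
    fit <- fit_reml(y, grms, ...)
    return(partition_result(trait, c(in_name, out_name), unname(fit$h2),
                            unname(fit$h2_se),
                            c(len_in, max(0, len_total - len_in)),
                            c(n_in, n_out), fit))
  }

  chrs <- unique(G$variants$chr)
  rows <- lapply(chrs, function(c) {
    on_chr <- G$variants$chr == c
    ids_in <- intersect(G$variants$id[on_chr], split$inside)
    ids_out <- intersect(G$variants$id[on_chr], split$outside)
    ids_rest <- G$variants$id[!on_chr]
    if (length(ids_in) < 2 || length(ids_out) < 2) return(NULL)
    grms <- list(compute_grm(subset_variants(G, ids_in))$values,
                 compute_grm(subset_variants(G, ids_out))$values,
                 compute_grm(subset_variants(G, ids_rest))$values)
    names(grms) <- c(in_name, out_name, "rest")
    fit <- fit_reml(y, grms, ...)
    data.frame(trait = trait, chr = c,
               component = c(in_name, out_name),
               v = unname(fit$h2[1:2]), se = unname(fit$h2_se[1:2]),
               n_snps = c(length(ids_in), length(ids_out)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate partition results across traits
#'
#' Traits whose total genetic estimate is zero are excluded (they carry no
#' information about the split of genetic variance). Mode `"mean"` averages
#' the phenotypic-variance fractions per component; mode
#' `"genetic-fraction-mean"` first divides each trait's components by its
#' total genetic estimate (giving per-trait genetic-variance proportions)
#' and then averages. Across-trait empirical standard errors (SD/sqrt(T))
#' are attached; these are optimistic when traits are correlated.
#'
#' @param results list of `partition_result` sharing component names.
#' @param mode `"mean"` or `"genetic-fraction-mean"`.
#' @return data.frame: component, value, se, length_bp, n_traits.
#' @export
aggregate_across_traits <- function(results,
                                    mode = c("mean", "genetic-fraction-mean")) {
  mode <- match.arg(mode)
  comp <- results[[1]]$component_names
  for (r in results) {
    if (!identical(r$component_names, comp))
      stop("partition results have inconsistent component sets")
  }
  keep <- vapply(results, function(r) r$v_total > 0, logical(1))
  if (!any(keep)) stop("no trait with non-zero total genetic estimate")
  results <- results[keep]
  M <- vapply(results, function(r) {
    if (mode == "mean") unname(r$v_c) else unname(r$v_c) / r$v_total
  }, numeric(length(comp)))
  M <- matrix(M, nrow = length(comp))
  data.frame(
    component = comp,
    value = rowMeans(M),
    se = apply(M, 1, stats::sd) / sqrt(ncol(M)),
    length_bp = unname(results[[1]]$lengths),
    n_traits = ncol(M),
    stringsAsFactors = FALSE)
}

#' Regress per-component variance on DNA length
#'
#' Ordinary least squares of variance estimates on component lengths, with
#' classical standard errors, the Pearson correlation, and two-sided tests
#' of slope = 1 and intercept = 0 (the hypotheses of strict
#' length-proportionality).
#'
#' @param v per-component variance values.
#' @param lengths per-component lengths (same units on both sides gives a
#'   dimensionless slope; proportions on both axes make slope 1 the
#'   proportional benchmark).
#' @return list: slope, slope_se, intercept, intercept_se, r, r2,
#'   p_slope_eq_1, p_intercept_eq_0, n.
#' @export
length_variance_regression <- function(v, lengths) {
  if (length(v) != length(lengths)) stop("v and lengths must match")
  n <- length(v)
  if (n < 3) stop("need >= 3 components")
  if (stats::var(lengths) == 0) stop("zero variance in lengths")
  fit <- stats::lm(v ~ lengths)
  # a perfectly proportional input is legitimate here; silence the
  # "essentially perfect fit" note from summary.lm
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["lengths", "Estimate"]; slope_se <- sm["lengths", "Std. Error"]
  icpt <- sm["(Intercept)", "Estimate"]; icpt_se <- sm["(Intercept)", "Std. Error"]
  r <- stats::cor(v, lengths)
  list(slope = slope, slope_se = slope_se,
       intercept = icpt, intercept_se = icpt_se,
       r = r, r2 = r^2,
       p_slope_eq_1 = 2 * stats::pt(abs((slope - 1) / slope_se), n - 2,
                                    lower.tail = FALSE),
       p_intercept_eq_0 = 2 * stats::pt(abs(icpt / icpt_se), n - 2,
                                        lower.tail = FALSE),
       n = n)
}

#' Subsample an equal number of SNPs per chromosome
#'
#' Control analysis for the length-proportionality result: with the same
#' number of SNPs on every chromosome, a persisting length relation cannot
#' be explained by longer chromosomes carrying more SNPs.
#'
#' @param G a [genotype_matrix()].
#' @param k_per_chr SNPs to draw per chromosome (default 3500); a
#'   chromosome with fewer SNPs is kept whole, with a warning.
#' @param seed integer seed; the draw is deterministic given it.
#' @return a [genotype_matrix()] restricted to the sampled SNPs.
#' @export
equal_snp_subsample <- function(G, k_per_chr = 3500L, seed = 1L) {
  set.seed(derive_seed(seed, "equal-snp-subsample"))
  chrs <- unique(G$variants$chr)
  ids <- unlist(lapply(chrs, function(c) {
    pool <- G$variants$id[G$variants$chr == c]
    if (length(pool) <= k_per_chr) {
      if (length(pool) < k_per_chr)
        warning(sprintf("chromosome %s has only %d SNPs (< %d); keeping all",
                        c, length(pool), k_per_chr))
      pool
    } else sort(sample(pool, k_per_chr))
  }))
  subset_variants(G, ids)
}
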
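# End-to-end pipeline: QC -> GRM -> relatedness pruning -> covariate
# adjustment -> per-trait REML -> GWA + theta_P scan -> chromosome and
# region partitions -> across-trait aggregates and length regressions.
# Every stage writes a TSV with a descriptive header comment, plus a run
# log recording all flags and seeds in effect.

#' Build a pipeline run configuration
#'
#' @param genotype_prefix PLINK prefix of the input genotypes (bed/bim/fam).
#' @param phenotype_file TSV with FID, IID, age, sex, cohort and trait
#'   columns.
#' @param output_dir directory for stage outputs (created if needed).
#' @param region_file optional BED file of regions (e.g. genic intervals).
#' @param region_pad_kb padding applied to the region file (kb).
#' @param traits trait columns to analyse (default: all).
#' @param miss_max,maf_min,hwe_alpha SNP QC thresholds.
#' @param relatedness_cutoff pruning cutoff on GRM entries (default 0.025).
#' @param gwa_alpha genome-wide significance threshold (default 5e-8).
#' @param threshold_grid theta_P p-value grid.
#' @param seed master seed for any stochastic stage.
#' @return a `run_config` list.
#' @export
run_config <- function(genotype_prefix, phenotype_file, output_dir,
                       region_file = NULL, region_pad_kb = 0,
                       traits = NULL,
                       miss_max = 0.05, maf_min = 0.01, hwe_alpha = 1e-6,
                       relatedness_cutoff = 0.025,
                       gwa_alpha = 5e-8,
                       threshold_grid = default_threshold_grid(),
                       seed = 1L) {
  cfg <- list(genotype_prefix = genotype_prefix,
              phenotype_file = phenotype_file,
              output_dir = output_dir,
              region_file = region_file,
              region_pad_kb = region_pad_kb,
              traits = traits,
              miss_max = miss_max, maf_min = maf_min, hwe_alpha = hwe_alpha,
              relatedness_cutoff = relatedness_cutoff,
              gwa_alpha = gwa_alpha,
              threshold_grid = threshold_grid,
              seed = as.integer(seed))
  for (thr in c("miss_max", "maf_min", "hwe_alpha")) {
    if (cfg[[thr]] < 0 || cfg[[thr]] > 1) stop(thr, " out of range [0,1]")
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file whose keys match the arguments of [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

write_stage_tsv <- function(df, path, comment) {
  con <- file(path, "w")
  writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Run the full estimation-and-partitioning pipeline
#'
#' @param config a [run_config()].
#' @return invisibly, a result bundle: qc report, retained samples,
#'   per-trait REML table, theta scan, chromosome partition aggregate and
#'   length regression, and (if regions were given) the region partition
#'   aggregate.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in paste0(config$genotype_prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stop("genotype file missing: ", f)
  if (!file.exists(config$phenotype_file))
    stop("phenotype file missing: ", config$phenotype_file)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("qc: miss_max=%g maf_min=%g hwe_alpha=%g (exact test)",
                         config$miss_max, config$maf_min, config$hwe_alpha),
                 sprintf("relatedness cutoff: %g (greedy pruning)",
                         config$relatedness_cutoff),
                 "grm: cross-product estimator, mean-imputed missing, sample frequencies",
                 "reml: AI with EM fallback; constrain-at-zero; LRT 50:50 chi-square mixture",
                 "adjust: OLS on age, z-scores per cohort x sex, n-1 SD")

  G <- read_plink(config$genotype_prefix)
  qc <- apply_snp_qc(G, config$miss_max, config$maf_min, config$hwe_alpha)
  write_stage_tsv(
    data.frame(metric = c("input", "removed_missingness", "removed_maf",
                          "removed_hwe", "retained"),
               count = c(qc$report$n_input, qc$report$n_removed_missingness,
                         qc$report$n_removed_maf, qc$report$n_removed_hwe,
                         qc$report$n_retained)),
    out("qc_report.tsv"), "SNP QC summary")
  G <- qc$genotypes

  A <- compute_grm(G)
  write_grm(A, out("grm"))
  keep <- select_unrelated(A, config$relatedness_cutoff)
  log_lines <- c(log_lines, sprintf("pruning: retained %d of %d samples",
                                    length(keep), length(A$samples)))
  G <- subset_samples(G, keep)
  A <- subset_grm(A, keep)
  # frequencies are defined on the analysis sample: drop SNPs that became
  # monomorphic after pruning
  p <- allele_freq(G)
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    log_lines <- c(log_lines, sprintf(
      "dropped %d SNP(s) monomorphic in the pruned sample", sum(mono)))
    G <- subset_variants(G, G$variants$id[!mono])
  }

  phen <- utils::read.table(config$phenotype_file, header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE,
                            comment.char = "#")
  phen$sample <- as.character(phen$IID)
  phen <- phen[match(keep, phen$sample), ]
  traits <- config$traits
  if (is.null(traits))
    traits <- setdiff(names(phen), c("FID", "IID", "sample", "age", "sex", "cohort"))
  Z <- adjust_all_traits(phen, traits)

  rt <- reml_table(Z, A)
  write_stage_tsv(rt$table, out("reml_per_trait.tsv"),
                  "per-trait variance explained by all SNPs")

  scans <- gwa_scan_multi(G, Z)
  for (tr in traits) {
    write_stage_tsv(scans[[tr]][, c("chr", "bp", "id", "beta", "se", "p")],
                    out(paste0("gwa_", tr, ".tsv")),
                    paste0("GWA scan for ", tr))
  }
  thetas <- theta_curves(scans, config$threshold_grid)
  write_stage_tsv(data.frame(trait = rownames(thetas), thetas,
                             check.names = FALSE),
                  out("theta_curves.tsv"),
                  "theta_P per trait and threshold")
  theta_scan <- NULL
  if (sum(rt$table$estimate > 0) >= 3) {
    theta_scan <- theta_h2_correlation_scan(thetas, rt$table$estimate,
                                            config$threshold_grid)
    write_stage_tsv(data.frame(threshold = theta_scan$thresholds,
                               r = theta_scan$correlations),
                    out("theta_h2_correlation.tsv"),
                    "correlation of theta_P with h2_SNP across traits")
  }

  parts <- lapply(traits, function(tr)
    partition_by_chromosome(G, Z[, tr], trait = tr))
  names(parts) <- traits
  part_rows <- do.call(rbind, lapply(parts, function(p)
    data.frame(trait = p$trait, component = p$component_names,
               v = unname(p$v_c), se = unname(p$se),
               stringsAsFactors = FALSE)))
  write_stage_tsv(part_rows, out("partition_chromosome.tsv"),
                  "per-chromosome variance estimates per trait")
  agg <- tryCatch(aggregate_across_traits(parts, "genetic-fraction-mean"),
                  error = function(e) NULL)
  lenreg <- NULL
  if (!is.null(agg)) {
    write_stage_tsv(agg, out("partition_chromosome_aggregate.tsv"),
                    "genetic-variance fractions per chromosome, averaged across traits")
    lenreg <- length_variance_regression(agg$value,
                                         agg$length_bp / sum(agg$length_bp))
    write_stage_tsv(as.data.frame(lenreg[c("slope", "slope_se", "intercept",
                                           "intercept_se", "r", "r2",
                                           "p_slope_eq_1", "p_intercept_eq_0")]),
                    out("length_regression.tsv"),
                    "regression of genetic fraction on genome fraction")
  }

  region_agg <- NULL
  if (!is.null(config$region_file)) {
    regions <- read_bed_regions(config$region_file, name = "genic",
                                pad_kb = config$region_pad_kb)
    rparts <- lapply(traits, function(tr)
      fit_region_partition(G, Z[, tr], regions, trait = tr))
    names(rparts) <- traits
    region_agg <- tryCatch(aggregate_across_traits(rparts, "mean"),
                           error = function(e) NULL)
    if (!is.null(region_agg))
      write_stage_tsv(region_agg, out("partition_region_aggregate.tsv"),
                      "genic/intergenic variance estimates averaged across traits")
  }

  writeLines(log_lines, out("run_log.txt"))
  invisible(list(qc_report = qc$report, samples = keep,
                 reml = rt, scans = scans, thetas = thetas,
                 theta_scan = theta_scan, partitions = parts,
                 chromosome_aggregate = agg, length_regression = lenreg,
                 region_aggregate = region_agg))
}
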
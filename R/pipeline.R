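#' Pipeline configuration
#'
#' Defaults reproduce the headline analysis settings: initial ROH calls at
#' the 40-SNP floor, analysis thresholds of 110 consecutive homozygous
#' SNPs and 2.3 Mb, a short/long partition at 8 Mb, 20 ancestry PCs, and
#' the standard QC thresholds.
#'
#' @param qc a [qc_thresholds()]
#' @param calling a [calling_params()]
#' @param grid a [threshold_grid()] for sweeps (`NULL` skips the sweep)
#' @param analysis_min_snps headline SNPs-in-a-row threshold (110)
#' @param analysis_min_mb headline physical-length threshold (2.3 Mb)
#' @param short_long_cutoff_mb Froh short/long partition (8 Mb)
#' @param n_pcs ancestry principal components (20)
#' @param mappable_bp genome size used for Froh; `NULL` = sum of the
#'   cohort's chromosome lengths when simulating, else 2.77e9
#' @param check_relatedness run the quadratic pi-hat scan in sample QC
#' @param run_sweep,run_permutation optional stages
#' @param n_perm,alpha permutation options
#' @param seed seed for simulation/permutation stages
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(qc = qc_thresholds(),
                            calling = calling_params(),
                            grid = threshold_grid(),
                            analysis_min_snps = 110L,
                            analysis_min_mb = 2.3,
                            short_long_cutoff_mb = 8,
                            n_pcs = 20L,
                            mappable_bp = NULL,
                            check_relatedness = TRUE,
                            run_sweep = FALSE,
                            run_permutation = FALSE,
                            n_perm = 1000L, alpha = 0.05,
                            seed = 1L) {
  structure(list(qc = qc, calling = calling, grid = grid,
                 analysis_min_snps = as.integer(analysis_min_snps),
                 analysis_min_mb = analysis_min_mb,
                 short_long_cutoff_mb = short_long_cutoff_mb,
                 n_pcs = as.integer(n_pcs), mappable_bp = mappable_bp,
                 check_relatedness = isTRUE(check_relatedness),
                 run_sweep = isTRUE(run_sweep),
                 run_permutation = isTRUE(run_permutation),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full ROH burden pipeline
#'
#' Stages, in order: sample QC -> SNP QC -> VIF LD pruning -> ROH calling
#' at the 40-SNP floor -> filtering at the analysis thresholds -> Froh and
#' descriptives -> covariate construction (GRM PCs, missingness, excess
#' heterozygosity, dataset fixed effects) -> pooled and per-dataset burden
#' fits, short/long decomposition -> optional threshold sweep and
#' whole-site-flip permutation. A stage failure halts with the stage name;
#' artifacts computed so far are returned on the error condition.
#'
#' @param x a `genotype_matrix`, or a [cohort_spec()] to simulate first
#' @param config a [pipeline_config()]
#' @return a `pipeline_result` list with elements `qc_report`, `pruned`,
#'   `rohset` (initial calls), `roh_110` / `roh_mb` (filtered),
#'   `froh` (records at the SNP-count threshold, incl. short/long),
#'   `descriptives`, `fits` (pooled + per dataset), `fit_short`,
#'   `fit_long`, `sweep`, `permutation`, `manifest`
#' @export
run_pipeline <- function(x, config = pipeline_config()) {
  artifacts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  if (inherits(x, "cohort_spec")) {
    sim <- stage("simulate", simulate_cohort(x))
    truth <- sim$truth
    if (is.null(config$mappable_bp))
      config$mappable_bp <- sum(x$chrom_lengths_bp)
    x <- sim$matrix
    artifacts$truth <- truth
  }
  if (is.null(config$mappable_bp)) config$mappable_bp <- 2.77e9

  sq <- stage("sample_qc",
              sample_filters(x, config$qc,
                             check_relatedness = config$check_relatedness))
  vq <- stage("snp_qc", snp_filters(sq$matrix, config$qc))
  artifacts$qc_report <- rbind(sq$report, vq$report)

  pr <- stage("vif_prune",
              vif_prune(vq$matrix, vif_limit = config$qc$vif_limit,
                        window = config$qc$vif_window,
                        step = config$qc$vif_step))
  artifacts$pruned <- pr$matrix

  rs <- stage("call_roh", call_roh(pr$matrix, config$calling))
  artifacts$rohset <- rs
  roh_snp <- stage("filter_roh",
                   filter_roh(rs, min_snps = config$analysis_min_snps))
  roh_mb <- stage("filter_roh", filter_roh(rs, min_mb = config$analysis_min_mb))
  artifacts$roh_110 <- roh_snp
  artifacts$roh_mb <- roh_mb

  fr <- stage("froh", split_froh(roh_snp,
                                 cutoff_mb = config$short_long_cutoff_mb,
                                 mappable_bp = config$mappable_bp))
  artifacts$froh <- fr
  ph <- pr$matrix$samples$phenotype
  artifacts$descriptives <- stage("descriptives",
                                  froh_descriptives(fr, roh_snp, ph))

  cov <- stage("covariates", build_covariates(pr$matrix, config$n_pcs))
  artifacts$covariates <- cov
  artifacts$fits <- stage("association",
    suppressWarnings(per_dataset_fits(ph, fr$froh,
                                      pr$matrix$samples$dataset_id,
                                      pooled_covariates = cov)))
  artifacts$fit_short <- stage("association",
    suppressWarnings(fit_logistic(ph, fr$froh_short, cov,
                                  threshold = "froh_short")))
  artifacts$fit_long <- stage("association",
    suppressWarnings(fit_logistic(ph, fr$froh_long, cov,
                                  threshold = "froh_long")))

  if (config$run_sweep && !is.null(config$grid))
    artifacts$sweep <- stage("sweep",
      sweep_association(rs, ph, cov, config$grid, config$mappable_bp))
  if (config$run_permutation)
    artifacts$permutation <- stage("permutation",
      site_flip_permutation(ph, fr$froh, cov,
                            pr$matrix$samples$dataset_id,
                            n_perm = config$n_perm, alpha = config$alpha,
                            seed = config$seed))

  artifacts$manifest <- list(
    stages = names(artifacts),
    seed = config$seed,
    analysis_min_snps = config$analysis_min_snps,
    analysis_min_mb = config$analysis_min_mb,
    mappable_bp = config$mappable_bp,
    n_samples = nrow(pr$matrix$calls),
    n_snps_pruned = ncol(pr$matrix$calls))
  class(artifacts) <- "pipeline_result"
  artifacts
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("ROH burden pipeline result\n")
  cat("  samples:", m$n_samples, "  pruned SNPs:", m$n_snps_pruned, "\n")
  cat("  analysis thresholds:", m$analysis_min_snps, "SNPs /",
      m$analysis_min_mb, "Mb\n")
  cat("  pooled fit: ")
  print(x$fits$pooled)
  invisible(x)
}

#' Write the main pipeline tables as TSV files
#'
#' @param result a `pipeline_result`
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_pipeline_tables <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wt <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(result$qc_report, "qc_report.tsv")
  wt(result$froh, "froh_records.tsv")
  wt(result$descriptives, "froh_descriptives.tsv")
  if (!is.null(result$sweep)) wt(result$sweep, "sweep.tsv")
  pooled <- result$fits$pooled
  fits <- c(result$fits$per_dataset,
            list(pooled = pooled, froh_short = result$fit_short,
                 froh_long = result$fit_long))
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(threshold = f$threshold, beta = f$beta, se = f$se, z = f$z,
               p = f$p, ci_lo = f$ci95[1], ci_hi = f$ci95[2],
               or_per_percent = f$or_per_percent, n = f$n,
               converged = f$converged)))
  wt(tab, "association.tsv")
  hom <- file.path(dir, "roh.hom")
  write_hom(result$roh_110, hom, file.path(dir, "roh.hom.indiv"))
  paths <- c(paths, hom)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Demonstration workflow on a small synthetic cohort
#'
#' Generates a 3-site synthetic cohort (~500 samples on a scaled-down
#' genome), runs the full pipeline at scaled analysis thresholds and
#' returns the result; the whole run takes well under a minute.
#'
#' @param seed RNG seed
#' @param out_dir optional directory to write the TSV artifacts into
#' @return a `pipeline_result`
#' @export
demo_pipeline <- function(seed = 1L, out_dir = NULL) {
  genome <- default_genome(total_bp = 2e8, n_chrom = 4L)
  spec <- cohort_spec(
    site_sizes = data.frame(dataset_id = c("siteA", "siteB", "siteC"),
                            n_cases = c(90, 80, 70),
                            n_controls = c(90, 90, 80)),
    chrom_lengths_bp = genome, n_snps = 8000L,
    f_distribution = list(type = "mixture_exp", p_zero = 0.4, mean = 0.02),
    beta_true = 16.1, missing_rate = 0.002, seed = seed)
  cfg <- pipeline_config(analysis_min_snps = 60L, analysis_min_mb = 2,
                         short_long_cutoff_mb = 8, n_pcs = 5L,
                         check_relatedness = FALSE, seed = seed)
  res <- run_pipeline(spec, cfg)
  if (!is.null(out_dir)) write_pipeline_tables(res, out_dir)
  res
}
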
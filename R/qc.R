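#' QC thresholds
#'
#' Defaults: drop samples with missingness > 0.02, heterozygosity more than
#' 6 SD above the mean (one-sided high), one member of each pair with
#' relatedness pi-hat > 0.2; drop SNPs failing Hardy-Weinberg at
#' p < 1e-6, with missingness > 0.02, or with a case-control missingness
#' difference > 0.02; LD pruning at VIF > 10 in 50-SNP windows.
#'
#' @param max_sample_missing,het_sd_limit,max_pihat sample filters
#' @param hwe_p_min,max_snp_missing,max_diff_missing SNP filters
#' @param vif_limit,vif_window,vif_step LD pruning parameters (window step
#'   of 5 SNPs is an implementation choice)
#' @return a `qc_thresholds` list
#' @export
qc_thresholds <- function(max_sample_missing = 0.02, het_sd_limit = 6,
                          max_pihat = 0.2, hwe_p_min = 1e-6,
                          max_snp_missing = 0.02, max_diff_missing = 0.02,
                          vif_limit = 10, vif_window = 50L, vif_step = 5L) {
  vals <- c(max_sample_missing, het_sd_limit, max_pihat, hwe_p_min,
            max_snp_missing, max_diff_missing, vif_limit, vif_window, vif_step)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  structure(list(max_sample_missing = max_sample_missing,
                 het_sd_limit = het_sd_limit, max_pihat = max_pihat,
                 hwe_p_min = hwe_p_min, max_snp_missing = max_snp_missing,
                 max_diff_missing = max_diff_missing, vif_limit = vif_limit,
                 vif_window = as.integer(vif_window),
                 vif_step = as.integer(vif_step)),
            class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided p-value for departure from Hardy-Weinberg proportions,
#' conditioning on the observed allele counts: probabilities of all
#' heterozygote counts compatible with the allele counts (same parity) are
#' enumerated, and those no more probable than the observed count are
#' summed. p is in (0, 1]; a monomorphic variant gives p = 1.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote)
#' @return exact p-value
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be nonnegative integers")
  n <- sum(counts)
  if (n == 0) stop("all-missing variant: HWE undefined (not p = 1)")
  # minor allele count
  rare <- 2 * min(n_hom1, n_hom2) + n_het
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)  # feasible het counts, same parity
  # log conditional probability up to a constant:
  # P(het) ~ 2^het / (hom_r! het! hom_c!)
  homr <- (rare - hets) / 2
  homc <- n - hets - homr
  logp <- hets * log(2) - lgamma(homr + 1) - lgamma(hets + 1) - lgamma(homc + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Method-of-moments relatedness (pi-hat) from standardized genotypes
#'
#' Estimates pairwise relatedness as the off-diagonal entries of the
#' genomic relationship matrix (mean over SNPs of standardized genotype
#' products), which approximates PLINK's pi-hat: ~1 for duplicates/MZ,
#' ~0.5 for first-degree relatives, ~0 for unrelated samples. Documented as
#' an approximation to the IBS-based method-of-moments estimator.
#'
#' @param x a `genotype_matrix`
#' @return symmetric n x n matrix of relatedness estimates
#' @export
estimate_pihat <- function(x) {
  compute_grm(x)
}

#' Sample-level QC filters
#'
#' Applies, in order: (1) relatedness — from each pair with pi-hat above the
#' threshold, drops the member with the higher missing rate; (2) sample
#' missingness; (3) heterozygosity more than `het_sd_limit` SD above the
#' cohort mean (one-sided high).
#'
#' @param x a `genotype_matrix`
#' @param thresholds a [qc_thresholds()] object
#' @param check_relatedness set `FALSE` to skip the pi-hat scan (it is
#'   quadratic in sample count)
#' @return list with `matrix` (filtered `genotype_matrix`) and `report`
#'   (data.frame of per-filter removal counts)
#' @export
sample_filters <- function(x, thresholds = qc_thresholds(),
                           check_relatedness = TRUE) {
  report <- list()
  n0 <- nrow(x$calls)
  if (check_relatedness && n0 > 1) {
    ph <- estimate_pihat(x)
    drop <- rep(FALSE, n0)
    pairs <- which(upper.tri(ph) & ph > thresholds$max_pihat, arr.ind = TRUE)
    if (nrow(pairs)) {
      ord <- order(-ph[pairs])
      for (k in ord) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        if (drop[i] || drop[j]) next
        worse <- if (x$samples$missing_rate[i] >= x$samples$missing_rate[j]) i else j
        drop[worse] <- TRUE
      }
    }
    report$relatedness <- sum(drop)
    if (any(drop)) x <- subset_genotypes(x, samples = !drop)
  } else report$relatedness <- 0L
  miss_drop <- x$samples$missing_rate > thresholds$max_sample_missing
  report$sample_missingness <- sum(miss_drop)
  if (any(miss_drop)) x <- subset_genotypes(x, samples = !miss_drop)
  het <- x$samples$heterozygosity
  lim <- mean(het, na.rm = TRUE) +
    thresholds$het_sd_limit * stats::sd(het, na.rm = TRUE)
  het_drop <- !is.na(het) & !is.na(lim) & het > lim
  report$heterozygosity <- sum(het_drop)
  if (any(het_drop)) x <- subset_genotypes(x, samples = !het_drop)
  if (nrow(x$calls) == 0) warning("no samples survive sample QC")
  list(matrix = x,
       report = qc_report(report, level = "sample", n_in = n0,
                          n_out = nrow(x$calls)))
}

#' Ancestry outlier detection on GRM principal components
#'
#' Stand-in for reference-panel-based ancestry filtering when no panel is
#' available: flags samples whose Euclidean distance from the (per-PC
#' median) centroid of the first two GRM principal components exceeds `k`
#' times the median distance. Median centroid and scale keep the rule from
#' being masked by the outliers themselves. Note the PC geometry bounds
#' the distance ratio near sqrt(n), so the default k = 6 needs n > ~40 to
#' be able to fire at all. Off by default in [run_pipeline()] since
#' synthetic cohorts are single-ancestry.
#'
#' @param x a `genotype_matrix`
#' @param k SD multiplier (default 6)
#' @param grm optional precomputed GRM
#' @return logical vector, `TRUE` = outlier
#' @export
ancestry_outliers <- function(x, k = 6, grm = NULL) {
  if (is.null(grm)) grm <- compute_grm(x)
  pcs <- grm_pcs(grm, min(2L, nrow(grm) - 1L))
  ctr <- apply(pcs, 2, stats::median)
  d <- sqrt(rowSums(sweep(pcs, 2, ctr)^2))
  d > k * stats::median(d)
}

#' SNP-level QC filters
#'
#' Applies, in one pass over per-variant statistics: (a) Hardy-Weinberg
#' exact p below `hwe_p_min` (computed on all samples pooled); (b) SNP
#' missingness above `max_snp_missing`; (c) absolute case-control
#' missingness difference above `max_diff_missing` (skipped with a warning
#' when either phenotype class is absent).
#'
#' @inheritParams sample_filters
#' @return list with `matrix` and `report`
#' @export
snp_filters <- function(x, thresholds = qc_thresholds()) {
  g <- x$calls
  m0 <- ncol(g)
  hwe_p <- apply(g, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    hwe_exact_p(sum(col == 0), sum(col == 1), sum(col == 2))
  })
  hwe_fail <- !is.na(hwe_p) & hwe_p < thresholds$hwe_p_min
  miss <- 1 - x$variants$call_rate
  miss_fail <- miss > thresholds$max_snp_missing
  y <- x$samples$phenotype
  if (sum(y == 1, na.rm = TRUE) > 0 && sum(y == 0, na.rm = TRUE) > 0) {
    mc <- colMeans(is.na(g[which(y == 1), , drop = FALSE]))
    mu <- colMeans(is.na(g[which(y == 0), , drop = FALSE]))
    diff_fail <- abs(mc - mu) > thresholds$max_diff_missing
  } else {
    warning("cases or controls absent: differential-missingness filter skipped")
    diff_fail <- rep(FALSE, m0)
  }
  drop <- hwe_fail | miss_fail | diff_fail
  out <- if (any(drop)) subset_genotypes(x, variants = !drop) else x
  rep <- list(hwe = sum(hwe_fail), snp_missingness = sum(miss_fail),
              differential_missingness = sum(diff_fail))
  list(matrix = out,
       report = qc_report(rep, level = "snp", n_in = m0, n_out = ncol(out$calls)))
}

qc_report <- function(removals, level, n_in, n_out) {
  data.frame(level = level, filter = names(removals),
             removed = as.integer(unlist(removals)),
             n_in = n_in, n_out = n_out,
             stringsAsFactors = FALSE)
}

#' VIF-based LD pruning
#'
#' Slides a window (default 50 SNPs, step 5) along each chromosome; within
#' a window, the SNP with the largest variance inflation factor
#' (1 / (1 - R^2) from regressing it on the other window SNPs) is removed
#' iteratively until all VIFs are at or below the limit. Removal is global
#' and permanent. Missing calls are mean-imputed inside the VIF regressions
#' only.
#'
#' @param x a `genotype_matrix`
#' @param vif_limit VIF ceiling (10, i.e. multiple R^2 > 0.90 prunes)
#' @param window window size in SNPs (50)
#' @param step window advance in SNPs (5)
#' @return list with `matrix` (pruned) and `kept` (logical over the input
#'   variant order)
#' @export
vif_prune <- function(x, vif_limit = 10, window = 50L, step = 5L) {
  m <- ncol(x$calls)
  keep <- rep(TRUE, m)
  g <- mean_impute(x$calls)
  for (idx in split(seq_len(m), x$variants$chrom)) {
    nchr <- length(idx)
    w <- min(window, nchr)
    start <- 1L
    repeat {
      win <- idx[start:min(start + w - 1L, nchr)]
      win <- win[keep[win]]
      if (length(win) > 1) {
        drop_local <- prune_window(g[, win, drop = FALSE], vif_limit)
        keep[win[drop_local]] <- FALSE
      }
      if (start + w - 1L >= nchr) break
      start <- start + step
    }
  }
  list(matrix = subset_genotypes(x, variants = keep), kept = keep)
}

# returns indices (within the window) to drop
prune_window <- function(gw, vif_limit) {
  active <- seq_len(ncol(gw))
  dropped <- integer()
  repeat {
    if (length(active) < 2) break
    sub <- gw[, active, drop = FALSE]
    sdv <- apply(sub, 2, stats::sd)
    const <- sdv == 0
    if (any(const)) {  # monomorphic in-window: no LD information, keep
      keep_idx <- active[!const]
      if (length(keep_idx) < 2) break
      sub <- gw[, keep_idx, drop = FALSE]
    } else keep_idx <- active
    R <- stats::cor(sub)
    # perfect collinearity: drop the later of the most correlated pair
    off <- abs(R); diag(off) <- 0
    if (max(off) >= 1 - 1e-12) {
      j <- which(off == max(off), arr.ind = TRUE)[1, ]
      victim <- keep_idx[max(j)]
      dropped <- c(dropped, victim)
      active <- setdiff(active, victim)
      next
    }
    vifs <- tryCatch(diag(solve(R)), error = function(e) NULL)
    if (is.null(vifs)) {
      victim <- keep_idx[which.max(apply(off, 2, max))]
      dropped <- c(dropped, victim)
      active <- setdiff(active, victim)
      next
    }
    if (max(vifs) <= vif_limit) break
    victim <- keep_idx[which.max(vifs)]
    dropped <- c(dropped, victim)
    active <- setdiff(active, victim)
  }
  dropped
}

mean_impute <- function(g) {
  g <- matrix(as.numeric(g), nrow(g), ncol(g))
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    na <- which(is.na(g), arr.ind = TRUE)
    if (nrow(na)) g[na] <- mu[na[, 2]]
  }
  g
}
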
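#' Genomic relationship matrix
#'
#' GRM entry (i, j) is the average over SNPs of
#' `(x_i - 2p)(x_j - 2p) / (2p(1 - p))` where `p` is the sample frequency
#' of the counted allele. Monomorphic SNPs carry no information and are
#' excluded (a count is recorded as an attribute); missing calls are
#' mean-imputed for this computation only. The diagonal is approximately
#' `1 + F`.
#'
#' @param x a `genotype_matrix`
#' @return symmetric n x n matrix with attribute `n_snps_used`
#' @export
compute_grm <- function(x) {
  g <- mean_impute(x$calls)
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(g)
  if (m == 0) stop("no polymorphic SNPs for GRM")
  z <- sweep(g, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  grm <- tcrossprod(z) / m
  attr(grm, "n_snps_used") <- m
  grm
}

#' Ancestry principal components from a GRM
#'
#' Top-k eigenvectors of the (symmetric) GRM, each scaled by the square
#' root of its eigenvalue. Sign convention: the largest-magnitude loading
#' of each component is positive, so results are deterministic.
#'
#' @param grm symmetric relationship matrix
#' @param k number of components (default 20)
#' @return n x k matrix (columns `PC1..PCk`); a zero-column matrix for k = 0
#' @export
grm_pcs <- function(grm, k = 20L) {
  n <- nrow(grm)
  if (k > n) stop("k (", k, ") exceeds sample count (", n, ")")
  if (k == 0) return(matrix(numeric(0), n, 0))
  e <- eigen(grm, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  val <- pmax(e$values[seq_len(k)], 0)
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  pcs <- sweep(vec, 2, sqrt(val), "*")
  colnames(pcs) <- paste0("PC", seq_len(k))
  pcs
}

#' Build the burden-model covariate matrix
#'
#' Assembles the standard adjustment set: ancestry PCs from the GRM of the
#' pruned SNPs, per-sample missing rate, excess heterozygosity (observed
#' heterozygosity centered within dataset), and dataset indicator columns
#' (fixed effects, first dataset as reference).
#'
#' @param x a `genotype_matrix` (pruned; used for the GRM)
#' @param n_pcs number of ancestry PCs (default 20, truncated to n - 1)
#' @param grm optional precomputed GRM
#' @return numeric matrix with named columns
#' @export
build_covariates <- function(x, n_pcs = 20L, grm = NULL) {
  n <- nrow(x$calls)
  n_pcs <- min(n_pcs, n - 1L)
  pcs <- if (n_pcs > 0) {
    if (is.null(grm)) grm <- compute_grm(x)
    grm_pcs(grm, n_pcs)
  } else matrix(numeric(0), n, 0)
  het <- x$samples$heterozygosity
  ds <- factor(x$samples$dataset_id)
  ex_het <- het - stats::ave(het, ds, FUN = function(v) mean(v, na.rm = TRUE))
  cov <- cbind(pcs, missing_rate = x$samples$missing_rate,
               excess_het = ex_het)
  if (nlevels(ds) > 1) {
    dmat <- stats::model.matrix(~ ds)[, -1, drop = FALSE]
    colnames(dmat) <- paste0("dataset_", levels(ds)[-1])
    cov <- cbind(cov, dmat)
  }
  cov
}

#' Logistic burden regression of case-control status on Froh
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares,
#' written for transparent control of convergence, aliasing and separation.
#' Froh enters on the proportion scale (0-1), so a slope beta corresponds
#' to a `100 * (exp(beta / 100) - 1)` percent change in odds per additional
#' percent of the genome autozygous. Convergence: maximum absolute score
#' below 1e-8, or 25 iterations (flagged). Rank-deficient designs have
#' aliased columns dropped (recorded on the result); a slope aliased with
#' the intercept (constant Froh) or a separated fit is flagged with
#' `se = Inf`, `p = 1`.
#'
#' @param y 0/1 case-control vector
#' @param froh per-sample Froh on the proportion scale
#' @param covariates optional numeric matrix of adjustment covariates
#' @param threshold label stored on the result (e.g. "110 SNPs")
#' @return an `assoc_result` list: `beta`, `se`, `z`, `p`, `ci95`,
#'   `or_per_percent`, `n`, `converged`, `flags`, plus the full coefficient
#'   table in `$coef`
#' @export
fit_logistic <- function(y, froh, covariates = NULL, threshold = NA_character_) {
  if (!all(y %in% 0:1)) stop("y must be 0/1")
  X <- cbind(intercept = 1, froh = froh)
  if (!is.null(covariates) && ncol(as.matrix(covariates)) > 0)
    X <- cbind(X, as.matrix(covariates))
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)

  # detect and drop aliased columns via pivoted QR
  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    bad <- qrX$pivot[-seq_len(qrX$rank)]
    aliased <- colnames(X)[bad]
    X <- X[, -bad, drop = FALSE]
  }
  flags <- character(0)
  if (length(aliased)) flags <- c(flags, paste0("aliased:", aliased))
  froh_aliased <- !("froh" %in% colnames(X))

  fit <- irls_logistic(X, y)
  beta_hat <- fit$beta
  # separation heuristic: fitted probabilities pinned to the boundary
  eta <- drop(X %*% beta_hat)
  mu <- stats::plogis(eta)
  separated <- length(y) > 0 && any(y == 1) && any(y == 0) &&
    all(mu[y == 1] > 1 - 1e-3) && all(mu[y == 0] < 1e-3)
  if (separated) flags <- c(flags, "separation")
  if (!fit$converged) flags <- c(flags, "non-convergence")

  coef_tab <- data.frame(term = colnames(X), estimate = beta_hat,
                         se = fit$se, stringsAsFactors = FALSE)
  if (froh_aliased || separated) {
    beta <- if (froh_aliased) NA_real_
            else unname(beta_hat[match("froh", colnames(X))])
    res <- assoc_result(beta = beta, se = Inf, n = n,
                        converged = fit$converged, flags = flags,
                        threshold = threshold, coef = coef_tab)
    if (separated) warning("perfect separation detected; p set to 1")
    if (froh_aliased) warning("froh aliased with other columns; no estimate")
    return(res)
  }
  i <- match("froh", colnames(X))
  assoc_result(beta = unname(beta_hat[i]), se = unname(fit$se[i]), n = n,
               converged = fit$converged, flags = flags,
               threshold = threshold, coef = coef_tab)
}

# plain IRLS with step-halving; score-based convergence
irls_logistic <- function(X, y, tol = 1e-8, max_iter = 25L) {
  p <- ncol(X)
  beta <- numeric(p)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-12)
    XtWX <- crossprod(X * sqrt(w))
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    new_ll <- loglik(new_beta)
    halvings <- 0
    while (!is.finite(new_ll) || new_ll < ll - 1e-10) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- loglik(new_beta)
      halvings <- halvings + 1
      if (halvings > 30) break
    }
    beta <- new_beta; ll <- new_ll
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, p, p))
  list(beta = stats::setNames(beta, colnames(X)),
       se = sqrt(pmax(diag(cov), 0)), converged = converged)
}

assoc_result <- function(beta, se, n, converged, flags, threshold, coef) {
  z <- if (is.finite(se) && se > 0) beta / se else NA_real_
  p <- if (!is.na(z)) wald_p(z) else 1
  structure(list(threshold = threshold, beta = beta, se = se, z = z, p = p,
                 ci95 = c(beta - 1.96 * se, beta + 1.96 * se),
                 or_per_percent = if (is.na(beta)) NA_real_ else or_per_percent(beta),
                 n = n, converged = converged, flags = flags, coef = coef),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("Froh burden fit",
      if (!is.na(x$threshold)) paste0(" [", x$threshold, "]"), "\n", sep = "")
  cat(sprintf("  beta = %.3g  (95%% CI %.3g, %.3g)  z = %.3g  p = %.3g\n",
              x$beta, x$ci95[1], x$ci95[2], x$z, x$p))
  if (!is.na(x$or_per_percent))
    cat(sprintf("  odds change per +1%% Froh: %+.2f%%\n", x$or_per_percent))
  cat("  n =", x$n, if (!x$converged) " (NOT converged)",
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]"),
      "\n")
  invisible(x)
}

#' Percent change in odds per additional 1% of the genome autozygous
#'
#' With the slope beta on the Froh proportion scale, a 0.01 increase in
#' Froh multiplies the odds by `exp(beta / 100)`; this returns
#' `100 * (exp(beta / 100) - 1)`.
#'
#' @param beta slope on the Froh proportion scale
#' @return percent change in odds
#' @export
or_per_percent <- function(beta) 100 * (exp(beta / 100) - 1)

#' Two-sided Wald p-value
#'
#' @param z Wald statistic (beta / se)
#' @return `2 * (1 - Phi(|z|))`
#' @export
wald_p <- function(z) 2 * stats::pnorm(-abs(z))

#' Threshold sweep of the burden association
#'
#' For every grid point: re-filter the base ROH calls, recompute Froh, and
#' refit the burden model. Fit errors at one grid point are caught and
#' flagged, never aborting the sweep.
#'
#' @param rohset base `roh_set` called at the 40-SNP floor
#' @param y,covariates as in [fit_logistic()] (aligned with the rohset's
#'   `sample_ids` order)
#' @param grid a [threshold_grid()]
#' @param mappable_bp genome size for Froh
#' @return data.frame with one row per grid point: `grid_type`, `threshold`,
#'   `beta`, `se`, `z`, `p`, `ci_lo`, `ci_hi`, `or_per_percent`, `n`,
#'   `converged`
#' @export
sweep_association <- function(rohset, y, covariates = NULL,
                              grid = threshold_grid(), mappable_bp = 2.77e9) {
  one <- function(type, thr) {
    res <- tryCatch({
      rs <- if (type == "snp") filter_roh(rohset, min_snps = thr)
            else filter_roh(rohset, min_mb = thr)
      fr <- compute_froh(rs, mappable_bp)
      fit_logistic(y, fr$froh, covariates,
                   threshold = paste(thr, if (type == "snp") "SNPs" else "Mb"))
    }, error = function(e) NULL, warning = function(w) suppressWarnings({
      rs <- if (type == "snp") filter_roh(rohset, min_snps = thr)
            else filter_roh(rohset, min_mb = thr)
      fr <- compute_froh(rs, mappable_bp)
      fit_logistic(y, fr$froh, covariates,
                   threshold = paste(thr, if (type == "snp") "SNPs" else "Mb"))
    }))
    if (is.null(res))
      return(data.frame(grid_type = type, threshold = thr, beta = NA_real_,
                        se = NA_real_, z = NA_real_, p = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        or_per_percent = NA_real_, n = NA_integer_,
                        converged = FALSE))
    data.frame(grid_type = type, threshold = thr, beta = res$beta,
               se = res$se, z = res$z, p = res$p,
               ci_lo = res$ci95[1], ci_hi = res$ci95[2],
               or_per_percent = res$or_per_percent, n = res$n,
               converged = res$converged && !length(res$flags))
  }
  rows <- c(lapply(grid$snp_thresholds, function(t) one("snp", t)),
            lapply(grid$mb_thresholds, function(t) one("mb", t)))
  do.call(rbind, rows)
}

#' Replication-status-by-Froh interaction test
#'
#' Adds a stratum flag and its product with Froh to the burden model and
#' reports the product-term estimate; a negative interaction means the
#' association is weaker in the flagged stratum.
#'
#' @inheritParams fit_logistic
#' @param replication_flag 0/1 stratum indicator (both strata required)
#' @return an `assoc_result` for the product term
#' @export
interaction_test <- function(y, froh, covariates = NULL, replication_flag) {
  if (length(unique(replication_flag)) < 2)
    stop("replication_flag is constant: both strata required")
  X <- cbind(intercept = 1, froh = froh, repl = replication_flag,
             froh_x_repl = froh * replication_flag)
  if (!is.null(covariates) && ncol(as.matrix(covariates)) > 0)
    X <- cbind(X, as.matrix(covariates))
  # the product term is the slope of interest; froh and the flag main
  # effects join the adjustment set
  covs <- X[, setdiff(colnames(X), c("intercept", "froh_x_repl")), drop = FALSE]
  fit_logistic(y, X[, "froh_x_repl"], covs, threshold = "interaction")
}

#' Per-dataset burden fits plus the pooled fixed-effects fit
#'
#' Fits the burden model independently within each dataset (datasets
#' lacking either phenotype class are skipped with a warning) and once
#' pooled with dataset fixed effects.
#'
#' @inheritParams fit_logistic
#' @param dataset_ids site label per sample
#' @param pooled_covariates covariates for the pooled fit (should include
#'   dataset indicators, e.g. from [build_covariates()])
#' @param dataset_covariates optional list of per-dataset covariate
#'   matrices; default reuses the pooled covariates' non-dataset columns
#' @return list with `per_dataset` (named list of `assoc_result`) and
#'   `pooled` (`assoc_result`)
#' @export
per_dataset_fits <- function(y, froh, dataset_ids, pooled_covariates = NULL,
                             dataset_covariates = NULL) {
  out <- list()
  for (d in unique(dataset_ids)) {
    i <- dataset_ids == d
    if (length(unique(y[i])) < 2) {
      warning("dataset ", d, " lacks both phenotype classes: skipped")
      next
    }
    cov_d <- if (!is.null(dataset_covariates)) dataset_covariates[[d]]
      else if (!is.null(pooled_covariates)) {
        pc <- pooled_covariates[i, !grepl("^dataset_", colnames(pooled_covariates)),
                                drop = FALSE]
        pc[, apply(pc, 2, function(v) stats::sd(v) > 0), drop = FALSE]
      } else NULL
    out[[d]] <- fit_logistic(y[i], froh[i], cov_d, threshold = d)
  }
  pooled <- fit_logistic(y, froh, pooled_covariates, threshold = "pooled")
  list(per_dataset = out, pooled = pooled)
}
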
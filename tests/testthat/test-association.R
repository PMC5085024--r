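test_that("GRM: duplicates, hand-computed toy, null sampling variance", {
  # hand-computed 3 x 4 toy
  g <- matrix(c(0, 1, 2,
                1, 1, 0,
                2, 0, 0,
                1, 2, 1), nrow = 3)
  gm <- toy_matrix(g)
  grm <- compute_grm(gm)
  p <- colMeans(g) / 2
  z <- sweep(sweep(g, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  expect_equal(unclass(grm), tcrossprod(z) / 4, ignore_attr = TRUE)
  # duplicated samples: off-diagonal ~ diagonal
  set.seed(41)
  calls <- matrix(stats::rbinom(20 * 500, 2, 0.3), 20, 500)
  calls[2, ] <- calls[1, ]
  grm2 <- compute_grm(toy_matrix(calls))
  expect_equal(grm2[1, 2], grm2[1, 1], tolerance = 1e-10)
  # independent HWE simulants: off-diagonals mean ~ 0, SD ~ 1/sqrt(m)
  set.seed(42)
  m <- 5000
  calls <- matrix(stats::rbinom(30 * m, 2, rep(runif(m, .2, .5), each = 30)),
                  30, m)
  grm3 <- compute_grm(toy_matrix(calls))
  off <- grm3[upper.tri(grm3)]
  # centering on sample frequencies leaves the small -1/(n-1) bias
  expect_lt(abs(mean(off) + 1 / 29), 0.01)
  expect_equal(stats::sd(off), 1 / sqrt(m), tolerance = 0.35)
  # monomorphic SNPs are excluded with a count
  calls[, 1] <- 0L
  grm4 <- compute_grm(toy_matrix(calls))
  expect_equal(attr(grm4, "n_snps_used"), m - 1L)
})

test_that("grm_pcs: cluster separation, k = 0, completeness identity", {
  set.seed(43)
  n <- 40; m <- 800
  p1 <- runif(m, 0.1, 0.9); p2 <- pmin(pmax(p1 + runif(m, -0.3, 0.3), 0.05), 0.95)
  calls <- rbind(
    matrix(stats::rbinom(n / 2 * m, 2, rep(p1, each = n / 2)), n / 2, m),
    matrix(stats::rbinom(n / 2 * m, 2, rep(p2, each = n / 2)), n / 2, m))
  grm <- compute_grm(toy_matrix(calls))
  pcs <- grm_pcs(grm, 2)
  grp <- rep(c(1, 2), each = n / 2)
  expect_gt(abs(mean(pcs[grp == 1, 1]) - mean(pcs[grp == 2, 1])),
            2 * mean(tapply(pcs[, 1], grp, stats::sd)))
  expect_equal(ncol(grm_pcs(grm, 0)), 0L)
  expect_error(grm_pcs(grm, n + 1), "exceeds")
  full <- grm_pcs(grm, n)
  expect_equal(tcrossprod(full), unclass(grm), ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("fit_logistic reproduces the closed-form 2x2 log odds ratio", {
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  x <- c(rep(1, 100), rep(0, 100))
  fit <- fit_logistic(y, x)
  expect_equal(fit$beta, log(30 * 90 / (70 * 10)), tolerance = 1e-9)
  se <- sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90)
  expect_equal(fit$se, se, tolerance = 1e-7)
  expect_equal(fit$z, fit$beta / fit$se)
  expect_equal(fit$p, 2 * stats::pnorm(-abs(fit$z)))
  expect_equal(fit$ci95, c(fit$beta - 1.96 * fit$se, fit$beta + 1.96 * fit$se))
})

test_that("fit_logistic matches glm() to 6 decimals with covariates", {
  set.seed(44)
  n <- 400
  froh <- stats::rexp(n, 1 / 0.003)
  cov <- cbind(c1 = stats::rnorm(n), c2 = stats::rbinom(n, 1, 0.4))
  eta <- -0.3 + 30 * froh + 0.5 * cov[, 1] - 0.7 * cov[, 2]
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  fit <- fit_logistic(y, froh, cov)
  ref <- stats::glm(y ~ froh + cov, family = stats::binomial())
  expect_equal(fit$beta, unname(stats::coef(ref)["froh"]), tolerance = 1e-6)
  expect_equal(fit$se,
               unname(sqrt(diag(stats::vcov(ref)))["froh"]), tolerance = 1e-6)
})

test_that("degenerate designs are flagged: constant froh, separation", {
  set.seed(45)
  y <- stats::rbinom(50, 1, 0.5)
  expect_warning(fit <- fit_logistic(y, rep(0.01, 50)), "aliased")
  expect_true(is.na(fit$beta))
  expect_equal(fit$p, 1)
  # perfect separation
  x <- c(rep(0, 25), rep(1, 25))
  y2 <- x
  expect_warning(fit2 <- fit_logistic(y2, x), "separation")
  expect_equal(fit2$p, 1)
  expect_true("separation" %in% fit2$flags)
})

test_that("or_per_percent: anchors, monotonicity, zero", {
  expect_equal(or_per_percent(0), 0)
  expect_equal(round(or_per_percent(16.1), 2), 17.47)
  expect_equal(round(or_per_percent(4.86), 2), 4.98)
  b <- seq(-20, 30, by = 0.5)
  expect_true(all(diff(or_per_percent(b)) > 0))
})

test_that("wald_p basics", {
  expect_equal(wald_p(0), 1)
  expect_equal(wald_p(1.959964), 0.05, tolerance = 1e-6)
  expect_equal(wald_p(-2), wald_p(2))
})

test_that("slope recovery on a simulated cohort (coverage spot check)", {
  set.seed(46)
  hits <- 0L
  for (r in 1:20) {
    spec <- cohort_spec(
      site_sizes = data.frame(dataset_id = "s1", n_cases = 2500,
                              n_controls = 2500),
      beta_true = 16.1, seed = 1000 + r)
    skel <- simulate_froh_cohort(spec)
    fit <- fit_logistic(skel$phenotype, skel$f_target)
    if (fit$ci95[1] <= 16.1 && 16.1 <= fit$ci95[2]) hits <- hits + 1L
  }
  expect_gte(hits, 17L)   # ~95% coverage; full audit in acceptance suite
})

test_that("sweep of length 1 equals a direct fit; errors don't abort", {
  set.seed(47)
  seg <- data.frame(sample_id = paste0("s", 1:40), dataset_id = "d",
                    chrom = "1",
                    start_bp = 1e6, end_bp = 1e6 + round(runif(40, 2e6, 9e6)),
                    n_snps = sample(60:400, 40, replace = TRUE))
  rs <- roh_set(seg, sample_ids = paste0("s", 1:40))
  y <- stats::rbinom(40, 1, 0.5)
  sw <- sweep_association(rs, y, grid = threshold_grid(
    snp_thresholds = 60L, mb_thresholds = numeric(0)))
  direct <- fit_logistic(y, compute_froh(filter_roh(rs, min_snps = 60))$froh)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$beta, direct$beta)
  expect_equal(sw$p, direct$p)
  # grid point below the calling floor errors but yields a flagged row
  sw2 <- sweep_association(rs, y, grid = threshold_grid(
    snp_thresholds = c(30L, 60L), mb_thresholds = numeric(0)))
  expect_equal(nrow(sw2), 2L)
  expect_true(is.na(sw2$beta[1]))
  expect_false(sw2$converged[1])
  expect_equal(sw2$beta[2], direct$beta)
})

test_that("interaction test recovers sign and handles degenerate strata", {
  set.seed(48)
  # sized so the interaction SE is well under the true slope difference
  n <- 20000
  froh <- stats::rexp(n, 1 / 0.02)
  flag <- rep(c(0, 1), each = n / 2)
  # slope 30 in stratum 0, zero in stratum 1 -> negative product term
  eta <- -0.2 + 30 * froh * (flag == 0)
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  res <- interaction_test(y, froh, replication_flag = flag)
  expect_lt(res$beta, 0)
  expect_error(interaction_test(y, froh, replication_flag = rep(1, n)),
               "constant")
})

test_that("interaction z is centered near 0 when strata share the slope", {
  set.seed(49)
  zs <- vapply(1:15, function(r) {
    n <- 1500
    froh <- stats::rexp(n, 1 / 0.005)
    flag <- rep(c(0, 1), each = n / 2)
    y <- stats::rbinom(n, 1, stats::plogis(-0.1 + 10 * froh))
    interaction_test(y, froh, replication_flag = flag)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 2.5 / sqrt(15) * 2)
  expect_gt(mean(abs(zs) < 1.96), 0.8)
})

test_that("per-dataset fits: symmetry, skipping, pooled permutation invariance", {
  set.seed(50)
  n <- 600
  froh <- stats::rexp(n, 1 / 0.004)
  y <- stats::rbinom(n, 1, stats::plogis(-0.1 + 12 * froh))
  # two identical datasets (same data duplicated)
  ds <- rep(c("A", "B"), each = n)
  fits <- per_dataset_fits(c(y, y), c(froh, froh), ds)
  expect_equal(fits$per_dataset$A$beta, fits$per_dataset$B$beta)
  expect_true(fits$pooled$beta <= max(fits$per_dataset$A$beta,
                                      fits$per_dataset$B$beta) + 1e-6 &&
              fits$pooled$beta >= min(fits$per_dataset$A$beta,
                                      fits$per_dataset$B$beta) - 1e-6)
  # dataset with a single phenotype class is skipped with a warning
  y2 <- c(y, rep(1L, 20))
  ds2 <- c(rep("A", n), rep("C", 20))
  expect_warning(f2 <- per_dataset_fits(y2, c(froh, froh[1:20]), ds2),
                 "skipped")
  expect_false("C" %in% names(f2$per_dataset))
  # pooled fixed-effects fit invariant to dataset label permutation
  ds_cov <- stats::model.matrix(~ factor(ds))[, -1, drop = FALSE]
  p1 <- fit_logistic(c(y, y), c(froh, froh), ds_cov)
  relab <- ifelse(ds == "A", "B", "A")
  ds_cov2 <- stats::model.matrix(~ factor(relab))[, -1, drop = FALSE]
  p2 <- fit_logistic(c(y, y), c(froh, froh), ds_cov2)
  expect_equal(p1$beta, p2$beta, tolerance = 1e-8)
  expect_equal(p1$se, p2$se, tolerance = 1e-8)
})

test_that("build_covariates assembles the documented columns", {
  set.seed(51)
  calls <- matrix(stats::rbinom(30 * 300, 2, 0.3), 30, 300)
  gm <- toy_matrix(calls, phenotype = rep(c(0L, 1L), 15))
  gm$samples$dataset_id <- rep(c("d1", "d2"), each = 15)
  gm <- refresh_metadata(gm)
  cov <- build_covariates(gm, n_pcs = 4)
  expect_equal(colnames(cov),
               c(paste0("PC", 1:4), "missing_rate", "excess_het", "dataset_d2"))
  # excess heterozygosity is centered within dataset
  expect_equal(as.numeric(tapply(cov[, "excess_het"],
                                 gm$samples$dataset_id, mean)),
               c(0, 0), tolerance = 1e-12)
})
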
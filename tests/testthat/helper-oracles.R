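# Independent reference implementations used as oracles. These are written
# as plain, slow loops so they share no code path with the package.

# Naive linear-scan ROH caller for one sample on one chromosome.
# g: vector of 0/1/2/NA; pos: positions. Returns data.frame or NULL.
roh_scan_oracle <- function(g, pos, min_snps = 40, density_bp = 200000,
                            gap_bp = 500000, missing_breaks = TRUE) {
  if (!missing_breaks) {
    keep <- !is.na(g)
    g <- g[keep]; pos <- pos[keep]
  }
  segs <- list()
  run <- integer(0)
  flush <- function(run, segs) {
    if (!length(run)) return(segs)
    # split at gaps
    parts <- list(); cur <- run[1]
    for (i in seq_along(run)[-1]) {
      if (pos[run[i]] - pos[run[i - 1]] > gap_bp) {
        parts[[length(parts) + 1]] <- cur
        cur <- run[i]
      } else cur <- c(cur, run[i])
    }
    parts[[length(parts) + 1]] <- cur
    for (p in parts) {
      ns <- length(p)
      if (ns < min_snps) next
      len <- pos[p[ns]] - pos[p[1]] + 1
      if (ns / len <= 1 / density_bp) next
      segs[[length(segs) + 1]] <- data.frame(start_bp = pos[p[1]],
                                             end_bp = pos[p[ns]],
                                             n_snps = ns)
    }
    segs
  }
  for (i in seq_along(g)) {
    homo <- !is.na(g[i]) && g[i] != 1
    if (homo) run <- c(run, i)
    else { segs <- flush(run, segs); run <- integer(0) }
  }
  segs <- flush(run, segs)
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

# Full-enumeration HWE exact test via plain factorials (n <= 50 so the
# largest factorial is 100! which is finite in double precision).
hwe_enum_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  na <- 2 * n_hom1 + n_het          # allele-1 count
  nb <- 2 * n - na
  hets <- seq(0, n)
  probs <- numeric(length(hets))
  for (k in seq_along(hets)) {
    h <- hets[k]
    h1 <- (na - h) / 2
    h2 <- (nb - h) / 2
    if (h1 < 0 || h2 < 0 || h1 != floor(h1) || h2 != floor(h2)) next
    # multinomial genotype probability conditioned on allele counts,
    # up to a constant: 2^h * n! / (h1! h! h2!)
    probs[k] <- 2^h * factorial(n) /
      (factorial(h1) * factorial(h) * factorial(h2))
  }
  # normalize over feasible het counts
  probs <- probs / sum(probs)
  obs <- probs[hets == n_het]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Per-SNP VIF via explicit lm() regressions (independent of the matrix
# inverse route used by the package).
vif_lm_oracle <- function(gw) {
  vapply(seq_len(ncol(gw)), function(j) {
    fit <- stats::lm(gw[, j] ~ gw[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

# Random genotype string for one chromosome with clustered homozygosity
# and random gap structure, for caller-equivalence fuzzing.
random_chrom_genotypes <- function(n_snps, p_het = 0.3, p_missing = 0.02,
                                   mean_gap = 20000, big_gap_rate = 0.01) {
  gaps <- round(stats::rexp(n_snps, 1 / mean_gap)) + 1
  big <- stats::runif(n_snps) < big_gap_rate
  gaps[big] <- gaps[big] + round(stats::runif(sum(big), 4e5, 1.2e6))
  pos <- cumsum(gaps)
  g <- sample(c(0L, 1L, 2L), n_snps, replace = TRUE,
              prob = c((1 - p_het) / 2, p_het, (1 - p_het) / 2))
  # plant a few long homozygous stretches so segments actually occur
  n_runs <- sample(0:3, 1)
  for (r in seq_len(n_runs)) {
    start <- sample.int(max(1, n_snps - 200), 1)
    len <- sample(20:200, 1)
    idx <- start:min(n_snps, start + len - 1)
    g[idx] <- sample(c(0L, 2L), length(idx), replace = TRUE)
  }
  miss <- stats::runif(n_snps) < p_missing
  g[miss] <- NA_integer_
  list(g = g, pos = pos)
}

# Small deterministic genotype matrix fixture.
toy_matrix <- function(calls, chrom = NULL, pos = NULL, phenotype = NULL,
                       dataset = "toy") {
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 10000
  variants <- data.frame(chrom = chrom, id = paste0("v", seq_len(m)),
                         pos_bp = pos, a1 = "A", a2 = "G",
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("ind", seq_len(n)),
                        dataset_id = dataset,
                        phenotype = phenotype %||% rep(0L, n),
                        stringsAsFactors = FALSE)
  genotype_matrix(calls, variants, samples, sort_variants = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
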
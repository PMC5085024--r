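# Approximate human autosome lengths (Mb), rescaled so the genome totals
# the SNP-mappable distance used for Froh (2.77e9 bp by default).
autosome_template <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136,
                       135, 134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)

#' Default 22-autosome genome summing to a given mappable length
#'
#' @param total_bp genome total (default 2.77e9)
#' @param n_chrom number of autosomes (default 22)
#' @return named numeric vector chromosome -> length in bp
#' @export
default_genome <- function(total_bp = 2.77e9, n_chrom = 22L) {
  w <- autosome_template[seq_len(n_chrom)]
  len <- round(w / sum(w) * total_bp)
  stats::setNames(len, as.character(seq_len(n_chrom)))
}

#' Specification of a synthetic multi-site case-control cohort
#'
#' The default spec mirrors the structure of the multi-site consortium
#' data the pipeline targets: 17 sites of a few hundred to a few thousand
#' individuals, ~300K autosomal SNPs on a 2.77e9 bp genome, per-individual
#' autozygosity planted as IBD segments with site-average Froh in the
#' 0.1-1% range (a half-zero / half-exponential mixture with mean 0.3% and
#' SD ~0.5%), and a logistic liability on true Froh. For test-sized runs,
#' pass a smaller genome and SNP count.
#'
#' @param site_sizes data.frame with columns `dataset_id`, `n_cases`,
#'   `n_controls`
#' @param chrom_lengths_bp named vector chromosome -> length (bp)
#' @param n_snps total SNP count laid down uniformly across the genome
#' @param maf_range MAF drawn uniformly on this interval (default 0.15-0.5)
#' @param f_distribution list describing the per-individual autozygous
#'   target fraction: `list(type = "point", value = f)`,
#'   `list(type = "exponential", mean = m)`, or
#'   `list(type = "mixture_exp", p_zero = p0, mean = m)` (default
#'   `p_zero = 0.5`, `mean = 0.006`)
#' @param segment_mean_mb mean planted segment length, exponential (3 Mb)
#' @param segment_min_mb minimum planted segment length (0.5 Mb)
#' @param beta_true log-odds slope per unit Froh proportion (0 = null)
#' @param intercept_per_site per-site logistic intercept (scalar recycled)
#' @param confound_tau SD of the per-site case-minus-control mean Froh
#'   shift delta_s, on the proportion scale (0 = no confounding)
#' @param delta_by_site optional fixed named vector of shifts, overrides
#'   `confound_tau`
#' @param missing_rate genotype missingness injected uniformly at random
#' @param seed RNG seed (required for reproducibility)
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(site_sizes = default_site_sizes(),
                        chrom_lengths_bp = default_genome(),
                        n_snps = 300000L,
                        maf_range = c(0.15, 0.5),
                        f_distribution = list(type = "mixture_exp",
                                              p_zero = 0.5, mean = 0.006),
                        segment_mean_mb = 3, segment_min_mb = 0.5,
                        beta_true = 0, intercept_per_site = 0,
                        confound_tau = 0, delta_by_site = NULL,
                        missing_rate = 0, seed = 1L) {
  if (any(site_sizes$n_cases < 0) || any(site_sizes$n_controls < 0))
    stop("site sizes must be nonnegative")
  if (confound_tau < 0) stop("confound_tau must be nonnegative")
  if (missing_rate < 0 || missing_rate >= 1) stop("invalid missing_rate")
  f_probe <- sample_f_quantile(f_distribution)
  if (f_probe >= 1) stop("f_distribution puts mass at F >= 1: infeasible")
  chrom_lengths_bp <- stats::setNames(as.numeric(chrom_lengths_bp),
                                      names(chrom_lengths_bp))
  structure(list(site_sizes = site_sizes,
                 chrom_lengths_bp = chrom_lengths_bp, n_snps = as.integer(n_snps),
                 maf_range = maf_range, f_distribution = f_distribution,
                 segment_mean_mb = segment_mean_mb,
                 segment_min_mb = segment_min_mb,
                 beta_true = beta_true,
                 intercept_per_site = intercept_per_site,
                 confound_tau = confound_tau, delta_by_site = delta_by_site,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default site-size table: 17 sites spanning ~200 to ~5,500 individuals
#'
#' Site totals echo the spread of the consortium's replication sites, with
#' roughly balanced case/control splits.
#'
#' @return data.frame with `dataset_id`, `n_cases`, `n_controls`
#' @export
default_site_sizes <- function() {
  totals <- c(1700, 2480, 660, 2030, 5450, 3640, 1190, 1370, 550, 2170,
              2270, 400, 870, 440, 2330, 390, 3590)
  data.frame(dataset_id = sprintf("site%02d", seq_along(totals)),
             n_cases = round(totals * 0.45),
             n_controls = totals - round(totals * 0.45),
             stringsAsFactors = FALSE)
}

sample_f <- function(fdist, n) {
  switch(fdist$type,
    point = rep(fdist$value, n),
    exponential = stats::rexp(n, 1 / fdist$mean),
    mixture_exp = ifelse(stats::runif(n) < fdist$p_zero, 0,
                         stats::rexp(n, 1 / fdist$mean)),
    stop("unknown f_distribution type: ", fdist$type))
}

sample_f_quantile <- function(fdist, q = 0.999) {
  switch(fdist$type,
    point = fdist$value,
    exponential = stats::qexp(q, 1 / fdist$mean),
    mixture_exp = stats::qexp(q, 1 / fdist$mean),
    stop("unknown f_distribution type: ", fdist$type))
}

#' Simulate the statistical skeleton of a multi-site cohort
#'
#' Draws, per site, a pool of individuals with true autozygous fractions
#' from the F distribution, assigns case status from the logistic liability
#' `logit P(case) = intercept + beta_true * F`, then ascertains the
#' requested case and control counts from the pool (retrospective sampling
#' preserves the logistic slope). Site-level ascertainment confounding is
#' applied afterwards by adding `|delta_s|` to the F of every case (when
#' `delta_s > 0`) or every control (when `delta_s < 0`), mimicking
#' recruitment of one group from a more inbred source population.
#'
#' This is the genotype-free core used by the permutation and power
#' machinery; [simulate_cohort()] adds SNP positions, planted segments and
#' genotypes on top of it.
#'
#' @param spec a [cohort_spec()]
#' @return data.frame with `sample_id`, `dataset_id`, `phenotype`,
#'   `f_base` (liability F, pre-confounding), `f_target` (post-confounding
#'   planting target), `linear_predictor`; attribute `delta_by_site` holds
#'   the realized shifts
#' @export
simulate_froh_cohort <- function(spec) {
  set.seed(spec$seed)
  ss <- spec$site_sizes
  n_sites <- nrow(ss)
  alpha <- rep_len(spec$intercept_per_site, n_sites)
  delta <- if (!is.null(spec$delta_by_site)) {
    spec$delta_by_site[ss$dataset_id]
  } else if (spec$confound_tau > 0) {
    stats::setNames(stats::rnorm(n_sites, 0, spec$confound_tau), ss$dataset_id)
  } else stats::setNames(rep(0, n_sites), ss$dataset_id)

  out <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    need_ca <- ss$n_cases[s]; need_co <- ss$n_controls[s]
    pool <- max(4L * (need_ca + need_co), 40L)
    f <- y <- eta <- NULL
    for (try in 1:6) {
      f <- sample_f(spec$f_distribution, pool)
      f <- pmin(f, 0.99)
      eta <- alpha[s] + spec$beta_true * f
      y <- stats::rbinom(pool, 1, stats::plogis(eta))
      if (sum(y == 1) >= need_ca && sum(y == 0) >= need_co) break
      pool <- pool * 2L
      if (try == 6) stop("could not ascertain site ", ss$dataset_id[s],
                         ": intercept too extreme for the pool")
    }
    pick <- c(which(y == 1)[seq_len(need_ca)], which(y == 0)[seq_len(need_co)])
    fi <- f[pick]; yi <- y[pick]
    d <- delta[s]
    ft <- fi
    if (d > 0) ft[yi == 1] <- pmin(ft[yi == 1] + d, 0.99)
    if (d < 0) ft[yi == 0] <- pmin(ft[yi == 0] - d, 0.99)
    out[[s]] <- data.frame(
      sample_id = sprintf("%s_%04d", ss$dataset_id[s], seq_along(pick)),
      dataset_id = ss$dataset_id[s], phenotype = yi,
      f_base = fi, f_target = ft, linear_predictor = eta[pick],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "delta_by_site") <- delta
  res
}

#' Simulate a multi-site case-control genotype cohort with planted autozygosity
#'
#' Lays SNP positions down uniformly at random per chromosome, draws each
#' SNP's alternate-allele frequency from the MAF distribution, and
#' generates Hardy-Weinberg genotypes (SNPs independent; the analysis
#' pipeline LD-prunes before calling, so linkage realism is not needed).
#' For each individual, autozygous segments with exponential lengths are
#' planted at random non-overlapping genome locations until the total
#' planted length reaches the individual's F target (the last segment is
#' truncated to hit the target, subject to the minimum segment length);
#' inside planted segments every genotype is homozygous, with the
#' homozygote class drawn by allele frequency. Case status comes from
#' [simulate_froh_cohort()].
#'
#' @param spec a [cohort_spec()]
#' @return list with `matrix` (a [genotype_matrix()]), `truth` (data.frame
#'   with `sample_id`, `dataset_id`, `phenotype`, `f_true`,
#'   `linear_predictor`, `n_segments`), `segments` (planted segment table)
#'   and `spec`
#' @export
simulate_cohort <- function(spec) {
  skel <- simulate_froh_cohort(spec)   # seeds the RNG
  chrlen <- spec$chrom_lengths_bp
  genome_bp <- sum(chrlen)
  chroms <- names(chrlen)

  # SNP map: counts proportional to chromosome length, positions uniform
  n_per <- round(spec$n_snps * chrlen / genome_bp)
  pos_list <- lapply(seq_along(chrlen), function(c) {
    p <- sort(unique(round(stats::runif(n_per[c], 1, chrlen[c]))))
    p
  })
  variants <- data.frame(
    chrom = rep(chroms, lengths(pos_list)),
    id = paste0("snp", seq_len(sum(lengths(pos_list)))),
    pos_bp = unlist(pos_list),
    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  m <- nrow(variants)
  p_alt <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])

  n <- nrow(skel)
  calls <- matrix(stats::rbinom(n * m, 2L, rep(p_alt, each = n)), n, m)

  # plant autozygous segments per individual
  min_bp <- spec$segment_min_mb * 1e6
  mean_bp <- spec$segment_mean_mb * 1e6
  seg_rows <- vector("list", n)
  f_true <- numeric(n)
  chr_start <- c(0, cumsum(as.numeric(chrlen)))[seq_along(chrlen)]
  for (i in seq_len(n)) {
    target <- skel$f_target[i] * genome_bp
    if (target < min_bp / 2) { f_true[i] <- 0; next }
    segs <- plant_segments(target, chrlen, min_bp, mean_bp)
    if (is.null(segs)) { f_true[i] <- 0; next }
    f_true[i] <- sum(segs$end_bp - segs$start_bp + 1) / genome_bp
    # set homozygous calls inside the segments
    for (r in seq_len(nrow(segs))) {
      ci <- which(variants$chrom == segs$chrom[r] &
                  variants$pos_bp >= segs$start_bp[r] &
                  variants$pos_bp <= segs$end_bp[r])
      if (length(ci))
        calls[i, ci] <- 2L * stats::rbinom(length(ci), 1L, p_alt[ci])
    }
    segs$sample_id <- skel$sample_id[i]
    seg_rows[[i]] <- segs
  }
  if (spec$missing_rate > 0) {
    nmiss <- round(spec$missing_rate * length(calls))
    calls[sample.int(length(calls), nmiss)] <- NA_integer_
  }
  samples <- data.frame(sample_id = skel$sample_id,
                        dataset_id = skel$dataset_id,
                        phenotype = skel$phenotype,
                        stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, variants, samples, sort_variants = FALSE)
  truth <- data.frame(sample_id = skel$sample_id,
                      dataset_id = skel$dataset_id,
                      phenotype = skel$phenotype,
                      f_true = f_true,
                      linear_predictor = skel$linear_predictor,
                      n_segments = vapply(seg_rows, function(s)
                        if (is.null(s)) 0L else nrow(s), integer(1)),
                      stringsAsFactors = FALSE)
  segments <- do.call(rbind, seg_rows[!vapply(seg_rows, is.null, logical(1))])
  list(matrix = gm, truth = truth, segments = segments, spec = spec)
}

# draw non-overlapping segments on the genome until total >= target bp;
# the final segment is truncated to hit the target where feasible
plant_segments <- function(target_bp, chrlen, min_bp, mean_bp) {
  chroms <- names(chrlen)
  placed <- list(); total <- 0; k <- 0L; tries <- 0L
  while (total < target_bp && tries < 200L) {
    len <- min_bp + stats::rexp(1, 1 / mean_bp)
    if (total + len > target_bp)  # truncate last segment to the target
      len <- max(min_bp, target_bp - total)
    c_i <- sample.int(length(chrlen), 1, prob = as.numeric(chrlen))
    if (len >= chrlen[c_i]) { tries <- tries + 1L; next }
    start <- round(stats::runif(1, 1, chrlen[c_i] - len))
    end <- round(start + len - 1)
    overlap <- FALSE
    for (s in placed)
      if (s$chrom == chroms[c_i] && start <= s$end_bp && end >= s$start_bp) {
        overlap <- TRUE; break
      }
    if (overlap) { tries <- tries + 1L; next }
    k <- k + 1L
    placed[[k]] <- data.frame(chrom = chroms[c_i], start_bp = start,
                              end_bp = end, stringsAsFactors = FALSE)
    total <- total + len
  }
  if (!k) return(NULL)
  do.call(rbind, placed)
}

#' Re-plant segments to impose site-level case-control Froh shifts
#'
#' Takes a simulated cohort and a named vector of per-site shifts
#' `delta_s` (case mean Froh minus control mean Froh, proportion scale) and
#' adds autozygous segments totaling `|delta_s| * genome` to every case
#' (`delta_s > 0`) or every control (`delta_s < 0`) of each site, leaving
#' the other group untouched, so the realized within-site gap moves by
#' `delta_s` while the marginal Froh distribution is approximately
#' preserved. A shift whose magnitude cannot be planted (target beyond the
#' genome) triggers a warning and a best-effort flag.
#'
#' @param cohort result of [simulate_cohort()]
#' @param delta_by_site named numeric vector, dataset_id -> shift
#' @return a cohort list of the same shape with updated `matrix`, `truth`
#'   and `segments`; attribute `best_effort` flags infeasible shifts
#' @export
inject_site_confounding <- function(cohort, delta_by_site) {
  gm <- cohort$matrix; truth <- cohort$truth
  spec <- cohort$spec
  chrlen <- spec$chrom_lengths_bp
  genome_bp <- sum(chrlen)
  variants <- gm$variants
  p_alt <- colMeans(gm$calls, na.rm = TRUE) / 2
  min_bp <- spec$segment_min_mb * 1e6
  mean_bp <- spec$segment_mean_mb * 1e6
  best_effort <- character(0)
  new_segs <- list(); k <- 0L
  for (d in names(delta_by_site)) {
    dl <- delta_by_site[[d]]
    if (dl == 0) next
    grp <- if (dl > 0) 1L else 0L
    idx <- which(truth$dataset_id == d & truth$phenotype == grp)
    add <- abs(dl)
    for (i in idx) {
      if (truth$f_true[i] + add >= 0.99) {
        best_effort <- c(best_effort, d)
        next
      }
      segs <- plant_segments(add * genome_bp, chrlen, min_bp, mean_bp)
      if (is.null(segs)) next
      for (r in seq_len(nrow(segs))) {
        ci <- which(variants$chrom == segs$chrom[r] &
                    variants$pos_bp >= segs$start_bp[r] &
                    variants$pos_bp <= segs$end_bp[r])
        if (length(ci))
          gm$calls[i, ci] <- 2L * stats::rbinom(length(ci), 1L, p_alt[ci])
      }
      added_bp <- sum(segs$end_bp - segs$start_bp + 1)
      truth$f_true[i] <- truth$f_true[i] + added_bp / genome_bp
      truth$n_segments[i] <- truth$n_segments[i] + nrow(segs)
      segs$sample_id <- truth$sample_id[i]
      k <- k + 1L
      new_segs[[k]] <- segs
    }
  }
  if (length(best_effort))
    warning("shift infeasible for some individuals in site(s): ",
            paste(unique(best_effort), collapse = ", "), " (best effort)")
  gm <- refresh_metadata(gm)
  segments <- rbind(cohort$segments, do.call(rbind, new_segs))
  out <- list(matrix = gm, truth = truth, segments = segments, spec = spec)
  attr(out, "best_effort") <- unique(best_effort)
  out
}
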
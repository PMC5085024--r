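#' In-memory genotype container
#'
#' A `genotype_matrix` holds hard genotype calls for a cohort: an integer
#' matrix of alternate-allele counts (0/1/2, `NA` = missing) with one row per
#' sample and one column per variant, plus per-variant and per-sample
#' metadata tables. Coordinates are 1-based and, within each chromosome,
#' variants are stored in strictly increasing position order.
#'
#' @param calls integer matrix, samples x variants, values in \{0, 1, 2, NA\}
#'   counting copies of the second allele (`a2`).
#' @param variants data.frame with columns `chrom` (autosome label, character),
#'   `id`, `pos_bp` (1-based position), `a1`, `a2`. Summary columns `maf` and
#'   `call_rate` are (re)computed from `calls`.
#' @param samples data.frame with columns `sample_id`, `dataset_id`,
#'   `phenotype` (0 = control, 1 = case, NA allowed). Summary columns
#'   `missing_rate` and `heterozygosity` are (re)computed from `calls`.
#' @param sort_variants sort variants by (chrom, pos_bp), permuting `calls`
#'   columns consistently. Default `TRUE`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `variants`, `samples`.
#' @export
genotype_matrix <- function(calls, variants, samples, sort_variants = TRUE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(samples))
    stop("calls has ", nrow(calls), " rows but samples has ", nrow(samples))
  if (ncol(calls) != nrow(variants))
    stop("calls has ", ncol(calls), " columns but variants has ", nrow(variants))
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("calls must be 0, 1, 2 or NA")
  variants$chrom <- as.character(variants$chrom)
  if (nrow(variants) && any(variants$pos_bp < 1))
    stop("pos_bp must be >= 1")
  if (sort_variants && nrow(variants)) {
    ord <- order(chrom_order(variants$chrom), variants$pos_bp)
    variants <- variants[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  if (nrow(variants)) {
    by_chr <- split(variants$pos_bp, variants$chrom)
    if (any(vapply(by_chr, function(p) any(diff(p) <= 0), logical(1))))
      stop("variant positions must be strictly increasing within chromosome")
  }
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  obj <- structure(list(calls = calls, variants = variants, samples = samples),
                   class = "genotype_matrix")
  refresh_metadata(obj)
}

# canonical ordering for autosome labels: numeric value where possible
chrom_order <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  n[is.na(n)] <- Inf
  n
}

#' Recompute per-variant and per-sample summary statistics from the calls
#'
#' Updates `maf`, `call_rate` on the variant table and `missing_rate`,
#' `heterozygosity` on the sample table so that stored metadata always agrees
#' with the calls.
#'
#' @param x a `genotype_matrix`
#' @return the updated `genotype_matrix`
#' @export
refresh_metadata <- function(x) {
  g <- x$calls
  n <- nrow(g); m <- ncol(g)
  if (m > 0 && n > 0) {
    nonmiss <- colSums(!is.na(g))
    af2 <- ifelse(nonmiss > 0, colSums(g, na.rm = TRUE) / (2 * nonmiss), NA_real_)
    x$variants$maf <- pmin(af2, 1 - af2)
    x$variants$call_rate <- nonmiss / n
    smiss <- rowSums(is.na(g))
    x$samples$missing_rate <- if (m > 0) smiss / m else 0
    snm <- m - smiss
    x$samples$heterozygosity <-
      ifelse(snm > 0, rowSums(g == 1, na.rm = TRUE) / snm, NA_real_)
  } else {
    x$variants$maf <- numeric(m)
    x$variants$call_rate <- numeric(m)
    x$samples$missing_rate <- numeric(n)
    x$samples$heterozygosity <- numeric(n)
  }
  x
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$calls), " samples x ", ncol(x$calls),
      " variants\n", sep = "")
  if (nrow(x$samples)) {
    nds <- length(unique(x$samples$dataset_id))
    ncase <- sum(x$samples$phenotype == 1, na.rm = TRUE)
    cat("  datasets: ", nds, ";  cases: ", ncase, " / ", nrow(x$samples), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by sample and/or variant index
#'
#' @param x a `genotype_matrix`
#' @param samples integer or logical index over samples (rows)
#' @param variants integer or logical index over variants (columns)
#' @return a `genotype_matrix` with metadata recomputed
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  g <- x$calls; sm <- x$samples; vr <- x$variants
  if (!is.null(samples)) {
    g <- g[samples, , drop = FALSE]
    sm <- sm[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    g <- g[, variants, drop = FALSE]
    vr <- vr[variants, , drop = FALSE]
  }
  genotype_matrix(g, vr, sm, sort_variants = FALSE)
}
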
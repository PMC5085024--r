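#' Genomic inbreeding coefficient Froh
#'
#' Froh is the proportion of the autosomal genome contained in called ROHs:
#' the per-sample sum of segment lengths divided by the SNP-mappable
#' autosomal distance, 2.77e9 bases by default. Samples with no surviving
#' segments get Froh = 0.
#'
#' @param rohset an `roh_set` filtered at the analysis threshold
#' @param mappable_bp total SNP-mappable distance in bases (2.77e9). Scaled
#'   synthetic genomes should pass their own total here.
#' @return data.frame (`froh_records`) with one row per sample:
#'   `sample_id`, `dataset_id`, `froh`, `n_segments`, `total_bp`,
#'   `mean_segment_mb`
#' @export
compute_froh <- function(rohset, mappable_bp = 2.77e9) {
  if (mappable_bp <= 0) stop("mappable_bp must be positive")
  ids <- attr(rohset, "sample_ids")
  seg <- as.data.frame(rohset)
  f <- factor(seg$sample_id, levels = ids)
  tot <- tapply(seg$length_bp, f, sum)
  nn <- tapply(seg$length_bp, f, length)
  tot <- ifelse(is.na(tot), 0, tot)
  nn <- ifelse(is.na(nn), 0, nn)
  ds <- attr(rohset, "dataset_ids")
  if (is.null(ds)) ds <- rep(NA_character_, length(ids))
  data.frame(sample_id = ids, dataset_id = ds,
             froh = as.numeric(tot) / mappable_bp,
             n_segments = as.integer(nn),
             total_bp = as.numeric(tot),
             mean_segment_mb = ifelse(nn > 0, tot / nn / 1e6, 0),
             stringsAsFactors = FALSE)
}

#' Decompose Froh at a length cutoff into short and long components
#'
#' `froh_short` is the genome proportion in segments strictly shorter than
#' the cutoff (8 Mb by default); `froh_long` the proportion in segments at
#' least that long (segments exactly at the cutoff go to the long class).
#' The partition is exact: `froh_short + froh_long = froh`.
#'
#' @inheritParams compute_froh
#' @param cutoff_mb length cutoff in Mb (default 8)
#' @return the [compute_froh()] table with `froh_short` and `froh_long`
#'   columns added
#' @export
split_froh <- function(rohset, cutoff_mb = 8, mappable_bp = 2.77e9) {
  if (cutoff_mb <= 0) stop("cutoff_mb must be positive")
  rec <- compute_froh(rohset, mappable_bp)
  seg <- as.data.frame(rohset)
  ids <- rec$sample_id
  f <- factor(seg$sample_id, levels = ids)
  short <- tapply(ifelse(seg$length_bp < cutoff_mb * 1e6, seg$length_bp, 0),
                  f, sum)
  short <- ifelse(is.na(short), 0, short)
  long <- rec$total_bp - as.numeric(short)   # bp sums are exact integers
  rec$froh_short <- as.numeric(short) / mappable_bp
  rec$froh_long <- long / mappable_bp
  # make the partition exact in floating point as well: froh is defined as
  # the sum of its two components (agrees with total_bp / mappable_bp to
  # one ulp)
  rec$froh <- rec$froh_short + rec$froh_long
  rec
}

#' Variance-equalizing short/long cutoff
#'
#' Returns the grid cutoff (Mb) minimizing the absolute difference between
#' the across-sample variances of `froh_short` and `froh_long`, the rule
#' used to pick the 8 Mb partition. Ties break toward the smaller cutoff.
#'
#' @inheritParams compute_froh
#' @param candidate_grid cutoffs to search, default 1:20 Mb
#' @return a single cutoff in Mb
#' @export
variance_equalizing_cutoff <- function(rohset, candidate_grid = 1:20,
                                       mappable_bp = 2.77e9) {
  base <- compute_froh(rohset, mappable_bp)
  if (sum(base$froh > 0) < 2)
    stop("need at least two samples with nonzero froh")
  if (stats::var(base$froh) == 0)
    stop("degenerate input: froh identical across samples, ",
         "variance matching is undefined")
  candidate_grid <- sort(candidate_grid)
  gap <- vapply(candidate_grid, function(cut) {
    rec <- split_froh(rohset, cutoff_mb = cut, mappable_bp = mappable_bp)
    abs(stats::var(rec$froh_short) - stats::var(rec$froh_long))
  }, numeric(1))
  candidate_grid[which.min(gap)]   # which.min takes the first = smallest
}

#' Per-dataset Froh descriptives
#'
#' One row per dataset: sample counts, mean and SD of Froh on the x100
#' (percent) scale, and mean and SD of segment length in Mb (averaged over
#' segments). SD with n = 1 is reported as 0 for table completeness.
#'
#' @param frohrecords output of [compute_froh()] / [split_froh()]
#' @param rohset the `roh_set` the records came from (for segment lengths)
#' @param phenotype optional 0/1 case-control vector aligned with
#'   `frohrecords` rows; fills the `n_cases` column
#' @return data.frame with columns `dataset_id`, `n`, `n_cases`,
#'   `avg_froh_x100`, `sd_froh_x100`, `avg_mb`, `sd_mb`
#' @export
froh_descriptives <- function(frohrecords, rohset, phenotype = NULL) {
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  ds <- frohrecords$dataset_id
  ds[is.na(ds)] <- "(all)"
  seg <- as.data.frame(rohset)
  segds <- seg$dataset_id
  if (nrow(seg)) segds[is.na(segds)] <- "(all)"
  levels <- sort(unique(ds))
  rows <- lapply(levels, function(d) {
    i <- ds == d
    j <- if (nrow(seg)) segds == d else logical(0)
    ncase <- if (!is.null(phenotype)) sum(phenotype[i] == 1, na.rm = TRUE)
             else NA_integer_
    data.frame(dataset_id = d, n = sum(i), n_cases = ncase,
               avg_froh_x100 = mean(frohrecords$froh[i]) * 100,
               sd_froh_x100 = sd0(frohrecords$froh[i]) * 100,
               avg_mb = if (any(j)) mean(seg$length_bp[j]) / 1e6 else 0,
               sd_mb = if (any(j)) sd0(seg$length_bp[j]) / 1e6 else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
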
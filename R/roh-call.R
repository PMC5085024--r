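#' ROH calling parameters
#'
#' Defaults implement the standard consecutive-homozygote scan: initial runs
#' of at least 40 homozygous SNPs with no heterozygote calls allowed, a
#' density requirement of more than 1 SNP per 200 kb per segment, and a
#' split wherever the gap between consecutive run SNPs exceeds 500 kb.
#' With zero heterozygotes allowed, the windowed scan used by the common
#' command-line caller reduces to this pure run scan.
#'
#' @param min_snps_initial minimum SNPs per run at initial calling (40)
#' @param max_het allowed heterozygote calls inside a run; fixed at 0
#' @param min_density_bp density floor: a segment must have more than one
#'   SNP per this many bases (200,000)
#' @param gap_split_bp split a run when consecutive SNPs are further apart
#'   than this (500,000)
#' @param missing_breaks whether a missing call terminates a run (`TRUE`,
#'   conservative default) or is skipped without counting (`FALSE`)
#' @return a `calling_params` list
#' @export
calling_params <- function(min_snps_initial = 40L, max_het = 0L,
                           min_density_bp = 200000, gap_split_bp = 500000,
                           missing_breaks = TRUE) {
  if (min_snps_initial < 1) stop("min_snps_initial must be >= 1")
  if (max_het != 0) stop("only max_het = 0 is supported")
  if (min_density_bp <= 0 || gap_split_bp <= 0)
    stop("bp parameters must be positive")
  structure(list(min_snps_initial = as.integer(min_snps_initial),
                 max_het = 0L,
                 min_density_bp = min_density_bp,
                 gap_split_bp = gap_split_bp,
                 missing_breaks = isTRUE(missing_breaks)),
            class = "calling_params")
}

#' Post-processing threshold grids
#'
#' The default sweep re-filters initial calls at 40 to 200 consecutive
#' homozygous SNPs in increments of 10, and at minimum physical lengths of
#' 1 to 20 Mb in increments of 1 Mb.
#'
#' @param snp_thresholds integer vector of SNPs-in-a-row thresholds
#' @param mb_thresholds numeric vector of minimum lengths in Mb
#' @return a `threshold_grid` list
#' @export
threshold_grid <- function(snp_thresholds = seq(40L, 200L, by = 10L),
                           mb_thresholds = seq(1, 20, by = 1)) {
  structure(list(snp_thresholds = as.integer(snp_thresholds),
                 mb_thresholds = as.numeric(mb_thresholds)),
            class = "threshold_grid")
}

#' Call runs of homozygosity
#'
#' Scans each sample and chromosome for maximal runs of consecutive
#' non-heterozygous calls. Runs are split at inter-SNP gaps larger than
#' `gap_split_bp`; surviving runs must contain at least `min_snps_initial`
#' SNPs and have density strictly greater than one SNP per `min_density_bp`
#' bases (evaluated per final segment). Segment coordinates are the
#' positions of the first and last run SNPs. Chromosome boundaries always
#' terminate runs. Missing calls terminate a run when
#' `params$missing_breaks` (default), otherwise they are skipped and do not
#' count as run SNPs.
#'
#' @param x a `genotype_matrix` with variants position-sorted (the caller
#'   refuses to sort silently)
#' @param params a [calling_params()] object
#' @return an [roh_set()]
#' @export
call_roh <- function(x, params = calling_params()) {
  vr <- x$variants
  if (nrow(vr)) {
    by_chr <- split(vr$pos_bp, vr$chrom)
    if (any(vapply(by_chr, is.unsorted, logical(1), strictly = TRUE)))
      stop("variants are not position-sorted; sort before calling")
  }
  chr_idx <- split(seq_len(nrow(vr)), vr$chrom)
  n <- nrow(x$calls)
  out <- vector("list", n * length(chr_idx))
  k <- 0L
  ds <- x$samples$dataset_id
  for (i in seq_len(n)) {
    gi <- x$calls[i, ]
    for (idx in chr_idx) {
      segs <- scan_chromosome(gi[idx], vr$pos_bp[idx], params)
      if (!is.null(segs)) {
        k <- k + 1L
        segs$sample_id <- x$samples$sample_id[i]
        segs$dataset_id <- ds[i]
        segs$chrom <- vr$chrom[idx[1]]
        out[[k]] <- segs
      }
    }
  }
  segments <- if (k) do.call(rbind, out[seq_len(k)]) else NULL
  roh_set(segments, params = params, filter = NULL,
          sample_ids = x$samples$sample_id,
          dataset_ids = x$samples$dataset_id)
}

# run scan on one sample x one chromosome; returns data.frame or NULL
scan_chromosome <- function(g, pos, params) {
  if (params$missing_breaks) {
    homo <- !is.na(g) & g != 1L
  } else {
    keep <- !is.na(g)
    g <- g[keep]; pos <- pos[keep]
    homo <- g != 1L
  }
  if (!length(homo) || !any(homo)) return(NULL)
  r <- rle(homo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  res <- list(); k <- 0L
  for (j in which(r$values)) {
    lo <- starts[j]; hi <- ends[j]
    p <- pos[lo:hi]
    # split at big gaps
    cut <- which(diff(p) > params$gap_split_bp)
    seg_lo <- c(1L, cut + 1L)
    seg_hi <- c(cut, length(p))
    for (s in seq_along(seg_lo)) {
      ns <- seg_hi[s] - seg_lo[s] + 1L
      if (ns < params$min_snps_initial) next
      sbp <- p[seg_lo[s]]; ebp <- p[seg_hi[s]]
      len <- ebp - sbp + 1
      if (ns / len <= 1 / params$min_density_bp) next  # density must exceed floor
      k <- k + 1L
      res[[k]] <- c(sbp, ebp, ns)
    }
  }
  if (!k) return(NULL)
  m <- do.call(rbind, res)
  data.frame(start_bp = m[, 1], end_bp = m[, 2], n_snps = as.integer(m[, 3]))
}

#' Re-filter called ROH segments at a stricter threshold
#'
#' Post-processes an initial call (40-SNP floor) by keeping only segments
#' with at least `min_snps` SNPs, or at least `min_mb` megabases of physical
#' length. Filtering never merges or re-splits segments, and a threshold
#' below the calling floor is an error rather than a silent pass-through.
#'
#' @param rohset an `roh_set` from [call_roh()]
#' @param min_snps minimum SNPs-in-a-row (mutually exclusive with `min_mb`)
#' @param min_mb minimum segment length in Mb
#' @return a filtered `roh_set` with updated provenance
#' @export
filter_roh <- function(rohset, min_snps = NULL, min_mb = NULL) {
  if (is.null(min_snps) == is.null(min_mb))
    stop("supply exactly one of min_snps or min_mb")
  p <- attr(rohset, "params")
  seg <- as.data.frame(rohset)
  if (!is.null(min_snps)) {
    if (min_snps < p$min_snps_initial)
      stop("min_snps (", min_snps, ") is below the calling floor (",
           p$min_snps_initial, "); re-call instead")
    keep <- seg$n_snps >= min_snps
    filt <- list(min_snps = min_snps)
  } else {
    if (min_mb <= 0) stop("min_mb must be positive")
    keep <- seg$length_bp >= min_mb * 1e6
    filt <- list(min_mb = min_mb)
  }
  roh_set(seg[keep, , drop = FALSE], params = p, filter = filt,
          sample_ids = attr(rohset, "sample_ids"),
          dataset_ids = attr(rohset, "dataset_ids"))
}

#' Longest ROH per sample
#'
#' @param rohset an `roh_set`
#' @return data.frame with `sample_id` and `longest_bp` (0 when the sample
#'   has no segments)
#' @export
longest_roh_per_sample <- function(rohset) {
  ids <- attr(rohset, "sample_ids")
  seg <- as.data.frame(rohset)
  longest <- rep(0, length(ids))
  if (nrow(seg)) {
    mx <- tapply(seg$length_bp, factor(seg$sample_id, levels = ids), max)
    longest <- ifelse(is.na(mx), 0, mx)
  }
  data.frame(sample_id = ids, longest_bp = as.numeric(longest),
             stringsAsFactors = FALSE)
}

#' Remove extreme (very long) ROH segments or their carriers
#'
#' Follow-up sensitivity filter: either drop every sample that owns a
#' segment longer than `max_mb` megabases, or drop only those segments.
#'
#' @param rohset an `roh_set`
#' @param max_mb length cutoff in Mb (default 30)
#' @param mode `"drop_individuals"` or `"drop_segments"`
#' @return a filtered `roh_set`; with `drop_individuals` the removed samples
#'   also leave the `sample_ids` provenance so they vanish downstream
#' @export
drop_extreme_roh <- function(rohset, max_mb = 30,
                             mode = c("drop_individuals", "drop_segments")) {
  mode <- match.arg(mode)
  seg <- as.data.frame(rohset)
  ids <- attr(rohset, "sample_ids")
  dss <- attr(rohset, "dataset_ids")
  long <- seg$length_bp > max_mb * 1e6
  if (mode == "drop_segments") {
    seg <- seg[!long, , drop = FALSE]
  } else {
    bad <- unique(seg$sample_id[long])
    seg <- seg[!(seg$sample_id %in% bad), , drop = FALSE]
    keep <- !(ids %in% bad)
    ids <- ids[keep]
    dss <- dss[keep]
  }
  roh_set(seg, params = attr(rohset, "params"),
          filter = attr(rohset, "filter"), sample_ids = ids,
          dataset_ids = dss)
}
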
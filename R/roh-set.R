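#' Construct an ROH segment set
#'
#' An `roh_set` is a data.frame of called homozygous runs (one row per
#' segment) carrying calling-parameter provenance as attributes. Columns:
#' `sample_id`, `dataset_id`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#' `length_bp` (= `end_bp - start_bp + 1`, 1-based inclusive coordinates).
#'
#' @param segments data.frame with the columns above (`length_bp` recomputed)
#' @param params the [calling_params()] used, kept as provenance
#' @param filter description of any post-filter applied (list with
#'   `min_snps` and/or `min_mb`), or `NULL`
#' @param sample_ids character vector of all samples the set was called on
#'   (so samples with zero segments keep Froh = 0 downstream)
#' @param dataset_ids optional site label per entry of `sample_ids`; by
#'   default recovered from the segment table where possible
#' @return an `roh_set`
#' @export
roh_set <- function(segments, params = calling_params(), filter = NULL,
                    sample_ids = unique(segments$sample_id),
                    dataset_ids = NULL) {
  if (is.null(segments) || nrow(segments) == 0) {
    segments <- data.frame(sample_id = character(), dataset_id = character(),
                           chrom = character(), start_bp = numeric(),
                           end_bp = numeric(), n_snps = integer(),
                           length_bp = numeric(), stringsAsFactors = FALSE)
  } else {
    if (any(segments$end_bp < segments$start_bp))
      stop("invariant violation: segment with end_bp < start_bp")
    segments$length_bp <- segments$end_bp - segments$start_bp + 1
    if (is.null(segments$dataset_id)) segments$dataset_id <- NA_character_
    segments <- segments[order(segments$sample_id,
                               chrom_order(segments$chrom),
                               segments$start_bp), , drop = FALSE]
    rownames(segments) <- NULL
  }
  sample_ids <- as.character(sample_ids)
  if (is.null(dataset_ids)) {
    dataset_ids <- rep(NA_character_, length(sample_ids))
    if (nrow(segments)) {
      first <- !duplicated(segments$sample_id)
      hit <- match(segments$sample_id[first], sample_ids)
      dataset_ids[hit[!is.na(hit)]] <- segments$dataset_id[first][!is.na(hit)]
    }
  }
  structure(segments, class = c("roh_set", "data.frame"),
            params = params, filter = filter,
            sample_ids = sample_ids,
            dataset_ids = as.character(dataset_ids))
}

#' @export
print.roh_set <- function(x, ...) {
  cat("roh_set: ", nrow(x), " segments, ",
      length(attr(x, "sample_ids")), " samples\n", sep = "")
  p <- attr(x, "params")
  cat("  calling: >=", p$min_snps_initial, " SNPs, density > 1/",
      p$min_density_bp, " bp, gap split > ", p$gap_split_bp, " bp\n", sep = "")
  f <- attr(x, "filter")
  if (!is.null(f))
    cat("  post-filter:", paste(names(f), unlist(f), sep = " = ",
                                collapse = ", "), "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Write PLINK-style .hom / .hom.indiv files
#'
#' Serializes an `roh_set` in the de-facto dialect of PLINK's homozygosity
#' scan: `.hom` with columns `FID IID CHR SNP1 SNP2 POS1 POS2 KB NSNP
#' DENSITY`, and `.hom.indiv` with per-sample `FID IID PHE NSEG KB KBAVG`.
#' `KB = (end - start + 1) / 1000`; `DENSITY` is KB per SNP.
#'
#' @param rohset an `roh_set`
#' @param hom_path,hom_indiv_path output paths
#' @return invisibly, `rohset`
#' @export
write_hom <- function(rohset, hom_path, hom_indiv_path = NULL) {
  seg <- as.data.frame(rohset)
  if (nrow(seg) && any(seg$end_bp < seg$start_bp))
    stop("invariant violation: segment with end_bp < start_bp")
  kb <- (seg$end_bp - seg$start_bp + 1) / 1000
  if (nrow(seg)) {
    hom <- data.frame(
      FID = ifelse(is.na(seg$dataset_id), "0", seg$dataset_id),
      IID = seg$sample_id, CHR = seg$chrom,
      SNP1 = ".", SNP2 = ".",
      POS1 = seg$start_bp, POS2 = seg$end_bp,
      KB = round(kb, 3), NSNP = seg$n_snps,
      DENSITY = round(kb / pmax(seg$n_snps, 1L), 4),
      stringsAsFactors = FALSE)
  } else {
    hom <- data.frame(FID = character(), IID = character(), CHR = character(),
                      SNP1 = character(), SNP2 = character(),
                      POS1 = numeric(), POS2 = numeric(), KB = numeric(),
                      NSNP = integer(), DENSITY = numeric(),
                      stringsAsFactors = FALSE)
  }
  utils::write.table(hom, hom_path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  if (!is.null(hom_indiv_path)) {
    ids <- attr(rohset, "sample_ids")
    nseg <- kbsum <- numeric(length(ids))
    if (nrow(seg)) {
      tn <- table(factor(seg$sample_id, levels = ids))
      nseg <- as.numeric(tn)
      tk <- tapply(kb, factor(seg$sample_id, levels = ids), sum)
      kbsum <- ifelse(is.na(tk), 0, tk)
    }
    indiv <- data.frame(FID = rep("0", length(ids)), IID = ids,
                        PHE = rep(-9, length(ids)),
                        NSEG = nseg, KB = round(kbsum, 3),
                        KBAVG = round(ifelse(nseg > 0, kbsum / nseg, 0), 3),
                        stringsAsFactors = FALSE)
    utils::write.table(indiv, hom_indiv_path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
  }
  invisible(rohset)
}

#' Read a .hom file written by [write_hom()]
#'
#' @param hom_path path to the `.hom` file
#' @param params,filter provenance to attach (not stored in the file)
#' @param sample_ids optional full sample list
#' @return an `roh_set`
#' @export
read_hom <- function(hom_path, params = calling_params(), filter = NULL,
                     sample_ids = NULL) {
  tab <- utils::read.table(hom_path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (nrow(tab) == 0)
    return(roh_set(NULL, params, filter,
                   sample_ids = sample_ids %||% character()))
  seg <- data.frame(sample_id = tab$IID, dataset_id = tab$FID,
                    chrom = tab$CHR,
                    start_bp = as.numeric(tab$POS1),
                    end_bp = as.numeric(tab$POS2),
                    n_snps = as.integer(tab$NSNP),
                    stringsAsFactors = FALSE)
  roh_set(seg, params, filter,
          sample_ids = sample_ids %||% unique(seg$sample_id))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
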
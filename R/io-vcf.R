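#' Read a VCF with hard diploid GT calls
#'
#' Minimal VCF 4.x reader for the hard-call pipeline: only the GT field is
#' used. `0/0` -> 0, `0/1`/`1/0` (or phased `|` equivalents) -> 1,
#' `1/1` -> 2, `./.` (or `.`) -> missing. The counted allele is ALT, so a
#' cohort serialized as ped/map (with `a2` = ALT) and as VCF parses to the
#' same `genotype_matrix`. Multi-allelic records are rejected.
#'
#' Sample phenotypes and dataset labels are not part of VCF; they can be
#' supplied through `samples` or attached afterwards.
#'
#' @param vcf_path path to an uncompressed VCF
#' @param samples optional data.frame with `sample_id`, `dataset_id`,
#'   `phenotype` to merge onto the VCF sample order
#' @return a `genotype_matrix`
#' @export
read_vcf <- function(vcf_path, samples = NULL) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  lines <- readLines(vcf_path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("VCF format error: no #CHROM header line")
  cols <- strsplit(lines[hdr[1]], "\t")[[1]]
  if (length(cols) < 10) stop("VCF format error: no sample columns")
  sample_ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  n <- length(sample_ids)
  m <- length(body)
  calls <- matrix(NA_integer_, n, m)
  chrom <- character(m); pos <- numeric(m); vid <- character(m)
  ref <- character(m); alt <- character(m)
  for (k in seq_len(m)) {
    tok <- strsplit(body[k], "\t")[[1]]
    if (length(tok) != 9 + n)
      stop("VCF format error at record ", k, ": expected ", 9 + n, " fields")
    chrom[k] <- tok[1]
    pos[k] <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(pos[k])) stop("VCF format error at record ", k, ": bad POS")
    vid[k] <- tok[3]; ref[k] <- tok[4]; alt[k] <- tok[5]
    if (grepl(",", alt[k]))
      stop("multi-allelic record not supported (record ", k, ": ", tok[3], ")")
    fmt <- strsplit(tok[9], ":")[[1]]
    gti <- match("GT", fmt)
    if (is.na(gti)) stop("VCF format error at record ", k, ": no GT in FORMAT")
    gt <- vapply(strsplit(tok[-(1:9)], ":"), `[`, "", gti)
    calls[, k] <- parse_gt(gt, k)
  }
  variants <- data.frame(chrom = chrom, id = vid, pos_bp = pos,
                         a1 = ref, a2 = alt, stringsAsFactors = FALSE)
  if (is.null(samples)) {
    samples <- data.frame(sample_id = sample_ids, dataset_id = "vcf",
                          phenotype = NA_integer_, stringsAsFactors = FALSE)
  } else {
    samples <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
    if (anyNA(samples$sample_id))
      stop("sample table does not cover all VCF samples")
  }
  genotype_matrix(calls, variants, samples, sort_variants = TRUE)
}

parse_gt <- function(gt, record) {
  out <- rep(NA_integer_, length(gt))
  al <- strsplit(gt, "[/|]")
  len <- lengths(al)
  if (any(len > 2))
    stop("non-diploid GT at record ", record)
  for (i in seq_along(gt)) {
    a <- al[[i]]
    if (length(a) == 1 && a == ".") next
    if (length(a) != 2)
      stop("non-diploid GT '", gt[i], "' at record ", record)
    if (any(a == ".")) next
    v <- suppressWarnings(as.integer(a))
    if (anyNA(v) || any(v > 1))
      stop("unsupported GT '", gt[i], "' at record ", record)
    out[i] <- sum(v)
  }
  out
}
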
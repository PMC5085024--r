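#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses the classic whitespace-delimited PLINK text pair into a
#' [genotype_matrix()]. Each `.map` row is `chrom id cm pos_bp`; each `.ped`
#' row is six header fields (`FID IID PAT MAT SEX PHENO`) followed by two
#' allele fields per variant. An allele pair `0 0` is a missing call.
#' Heterozygote coding is order-insensitive; the counted allele (`a2`) is the
#' second distinct allele observed per variant (or the `a2` carried in the
#' writer's fixture). Phenotype is PLINK-coded in the file (1 = control,
#' 2 = case, 0/-9 = missing) and recoded to 0/1/NA.
#'
#' @param ped_path path to the `.ped` file
#' @param map_path path to the `.map` file
#' @param dataset_id site label applied to every sample when the FID column
#'   is not wanted as the site; by default the FID column is used.
#' @return a `genotype_matrix` (variants sorted by chromosome and position)
#' @export
read_plink_text <- function(ped_path, map_path, dataset_id = NULL) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_tok)
  if (length(nf) && any(nf != 4))
    stop("map format error at line ", which(nf != 4)[1], ": expected 4 columns")
  m <- length(map_tok)
  chrom <- vapply(map_tok, `[`, "", 1)
  vid <- vapply(map_tok, `[`, "", 2)
  pos <- suppressWarnings(as.numeric(vapply(map_tok, `[`, "", 4)))
  if (any(is.na(pos)))
    stop("map format error at line ", which(is.na(pos))[1],
         ": non-numeric position")

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  ok_alleles <- c("A", "C", "G", "T", "1", "2", "0")

  calls <- matrix(NA_integer_, n, m)
  a1 <- rep(NA_character_, m); a2 <- rep(NA_character_, m)
  fid <- character(n); iid <- character(n); phen <- integer(n)

  for (i in seq_len(n)) {
    tok <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m)
      stop("ped format error at line ", i, ": expected ", 6 + 2 * m,
           " fields, found ", length(tok))
    fid[i] <- tok[1]; iid[i] <- tok[2]
    ph <- tok[6]
    phen[i] <- if (ph == "2") 1L else if (ph == "1") 0L else NA_integer_
    al <- tok[-(1:6)]
    if (!all(al %in% ok_alleles))
      stop("ped format error at line ", i, ": invalid allele code '",
           al[!al %in% ok_alleles][1], "'")
    x1 <- al[seq(1, 2 * m, by = 2)]
    x2 <- al[seq(2, 2 * m, by = 2)]
    miss <- x1 == "0" | x2 == "0"
    # register alleles per variant in observation order
    for (j in which(!miss)) {
      if (is.na(a1[j])) a1[j] <- x1[j]
      if (x1[j] != a1[j] && is.na(a2[j])) a2[j] <- x1[j]
      if (x2[j] != a1[j] && is.na(a2[j])) a2[j] <- x2[j]
    }
    cnt <- integer(m)
    cnt[!miss] <- (x1[!miss] == a2[!miss]) + (x2[!miss] == a2[!miss])
    # a2 still NA (monomorphic so far): count is 0
    cnt[!miss & is.na(a2)] <- 0L
    cnt[miss] <- NA_integer_
    calls[i, ] <- cnt
  }
  a2[is.na(a2)] <- "0"   # monomorphic: placeholder second allele
  a1[is.na(a1)] <- "0"   # all-missing variant

  variants <- data.frame(chrom = chrom, id = vid, pos_bp = pos,
                         a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = iid,
                        dataset_id = if (is.null(dataset_id)) fid else dataset_id,
                        phenotype = phen, stringsAsFactors = FALSE)
  genotype_matrix(calls, variants, samples, sort_variants = TRUE)
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' Inverse of [read_plink_text()]: emits one `.map` row per variant and one
#' `.ped` row per sample. Genotype 0 is written as `a1 a1`, 1 as `a1 a2`,
#' 2 as `a2 a2`, missing as `0 0`. Phenotype is recoded to PLINK 1/2 with
#' `-9` for missing.
#'
#' @param x a `genotype_matrix`
#' @param ped_path,map_path output paths
#' @return invisibly, `x`
#' @export
write_plink_text <- function(x, ped_path, map_path) {
  vr <- x$variants
  writeLines(paste(vr$chrom, vr$id, 0, vr$pos_bp), map_path)
  a1 <- vr$a1; a2 <- vr$a2
  n <- nrow(x$calls); m <- ncol(x$calls)
  ped <- character(n)
  for (i in seq_len(n)) {
    g <- x$calls[i, ]
    x1 <- ifelse(is.na(g), "0", ifelse(g == 2, a2, a1))
    x2 <- ifelse(is.na(g), "0", ifelse(g >= 1, a2, a1))
    sm <- x$samples[i, ]
    ph <- if (is.na(sm$phenotype)) "-9" else as.character(sm$phenotype + 1L)
    ped[i] <- paste(c(sm$dataset_id, sm$sample_id, "0", "0", "0", ph,
                      as.vector(rbind(x1, x2))), collapse = " ")
  }
  writeLines(ped, ped_path)
  invisible(x)
}
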
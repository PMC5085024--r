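test_that("ped/map toy parses with exactly one missing cell", {
  map <- c("1 v1 0 1000", "1 v2 0 2000", "2 v3 0 500")
  ped <- c("fam1 s1 0 0 0 1 A A A G G G",
           "fam1 s2 0 0 0 2 A G 0 0 G G")
  mp <- withr::local_tempfile(fileext = ".map")
  pp <- withr::local_tempfile(fileext = ".ped")
  writeLines(map, mp); writeLines(ped, pp)
  gm <- read_plink_text(pp, mp)
  expect_equal(dim(gm$calls), c(2L, 3L))
  expect_equal(sum(is.na(gm$calls)), 1L)
  expect_equal(gm$samples$phenotype, c(0L, 1L))
  # v1: s1 AA (0 copies of G), s2 AG (1)
  expect_equal(gm$calls[, 1], c(0L, 1L))
  # v3 (chr2): monomorphic GG; G registers as a1, so both count 0 of the
  # (unobserved) second allele — homozygosity is what matters downstream
  expect_equal(unname(gm$calls[, 3]), c(0L, 0L))
})

test_that("write -> read round trip reproduces calls exactly", {
  set.seed(42)
  calls <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 5, 12)
  gm <- toy_matrix(calls, chrom = rep(c("1", "2"), each = 6),
                   pos = rep(seq_len(6) * 5000, 2),
                   phenotype = c(1L, 0L, 1L, 0L, NA))
  mp <- withr::local_tempfile(); pp <- withr::local_tempfile()
  write_plink_text(gm, pp, mp)
  gm2 <- read_plink_text(pp, mp)
  # counted-allele identity can flip for columns whose first non-missing
  # call is homozygous alt; compare up to that recoding
  for (j in seq_len(12)) {
    a <- gm$calls[, j]; b <- gm2$calls[, j]
    expect_true(identical(a, b) || identical(a, 2L - b), info = paste("col", j))
  }
  expect_equal(gm2$variants$pos_bp, gm$variants$pos_bp)
  expect_equal(gm2$samples$phenotype, gm$samples$phenotype)
  # once the allele registration is fixed by a read, further round trips
  # are bit-identical
  mp2 <- withr::local_tempfile(); pp2 <- withr::local_tempfile()
  write_plink_text(gm2, pp2, mp2)
  gm3 <- read_plink_text(pp2, mp2)
  expect_identical(gm3$calls, gm2$calls)
  expect_identical(gm3$variants$pos_bp, gm2$variants$pos_bp)
})

test_that("unsorted map positions are sorted with calls permuted consistently", {
  map <- c("1 v1 0 3000", "1 v2 0 1000", "1 v3 0 2000")
  ped <- c("f s1 0 0 0 1 A A A G G G")
  mp <- withr::local_tempfile(); pp <- withr::local_tempfile()
  writeLines(map, mp); writeLines(ped, pp)
  gm <- read_plink_text(pp, mp)
  expect_equal(gm$variants$pos_bp, c(1000, 2000, 3000))
  expect_equal(gm$variants$id, c("v2", "v3", "v1"))
  # hand-sorted: v2 = "A G" -> 1, v3 = "G G" -> 0 (monomorphic), v1 = "A A" -> 0
  expect_equal(unname(gm$calls[1, ]), c(1L, 0L, 0L))
})

test_that("format errors name the offending line", {
  mp <- withr::local_tempfile(); pp <- withr::local_tempfile()
  writeLines(c("1 v1 0 1000", "1 v2 0 zzz"), mp)
  writeLines("f s1 0 0 0 1 A A G G", pp)
  expect_error(read_plink_text(pp, mp), "line 2")
  writeLines(c("1 v1 0 1000"), mp)
  writeLines(c("f s1 0 0 0 1 A A", "f s2 0 0 0 1 A"), pp)
  expect_error(read_plink_text(pp, mp), "line 2")
  writeLines("f s1 0 0 0 1 A X", pp)
  expect_error(read_plink_text(pp, mp), "line 1")
})

test_that("VCF GT parsing is phase-insensitive and matches ped/map", {
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
           "1\t1000\tv1\tA\tG\t.\t.\t.\tGT\t0|1\t1|0",
           "1\t2000\tv2\tA\tG\t.\t.\t.\tGT\t0/0\t1/1",
           "2\t500\tv3\tA\tG\t.\t.\t.\tGT\t./.\t0/1")
  vp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, vp)
  gm <- read_vcf(vp)
  expect_equal(unname(gm$calls[, 1]), c(1L, 1L))   # 0|1 and 1|0 both het
  expect_equal(unname(gm$calls[, 2]), c(0L, 2L))
  expect_equal(unname(gm$calls[, 3]), c(NA_integer_, 1L))
})

test_that("same cohort as ped/map and VCF yields identical calls", {
  set.seed(7)
  calls <- matrix(sample(c(0:2, NA), 40, replace = TRUE,
                         prob = c(.4, .3, .25, .05)), 4, 10)
  gm <- toy_matrix(calls)
  mp <- withr::local_tempfile(); pp <- withr::local_tempfile()
  write_plink_text(gm, pp, mp)
  gm_ped <- read_plink_text(pp, mp)
  vcf <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples$sample_id), collapse = "\t"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(ncol(calls))) {
    gt <- ifelse(is.na(calls[, j]), "./.", gt_code[as.character(calls[, j])])
    vcf <- c(vcf, paste(c("1", gm$variants$pos_bp[j], gm$variants$id[j],
                          "A", "G", ".", ".", ".", "GT", gt), collapse = "\t"))
  }
  vp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, vp)
  gm_vcf <- read_vcf(vp)
  for (j in seq_len(10)) {
    a <- unname(gm_ped$calls[, j]); b <- unname(gm_vcf$calls[, j])
    expect_true(identical(a, b) || identical(a, 2L - b), info = paste("col", j))
  }
  expect_equal(gm_vcf$variants$pos_bp, gm_ped$variants$pos_bp)
})

test_that("header-only VCF gives an empty matrix without error", {
  vp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1"),
             vp)
  gm <- read_vcf(vp)
  expect_equal(dim(gm$calls), c(1L, 0L))
})

test_that("VCF errors: missing GT, non-diploid, multi-allelic", {
  vp <- withr::local_tempfile(fileext = ".vcf")
  hdr <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1"
  writeLines(c(hdr, "1\t100\tv\tA\tG\t.\t.\t.\tDP\t10"), vp)
  expect_error(read_vcf(vp), "no GT")
  writeLines(c(hdr, "1\t100\tv\tA\tG\t.\t.\t.\tGT\t0/0/1"), vp)
  expect_error(read_vcf(vp), "non-diploid")
  writeLines(c(hdr, "1\t100\tv\tA\tG,C\t.\t.\t.\tGT\t0/1"), vp)
  expect_error(read_vcf(vp), "multi-allelic")
})

test_that(".hom output has the documented columns and arithmetic", {
  seg <- data.frame(sample_id = "s1", dataset_id = "d1", chrom = "1",
                    start_bp = 1000001, end_bp = 3300000, n_snps = 110L)
  rs <- roh_set(seg, sample_ids = c("s1", "s2"))
  hp <- withr::local_tempfile(); ip <- withr::local_tempfile()
  write_hom(rs, hp, ip)
  hom <- read.table(hp, header = TRUE, sep = "\t")
  expect_equal(names(hom), c("FID", "IID", "CHR", "SNP1", "SNP2", "POS1",
                             "POS2", "KB", "NSNP", "DENSITY"))
  expect_equal(hom$KB, 2300)          # 2.3 Mb segment
  expect_equal(hom$NSNP, 110L)
  indiv <- read.table(ip, header = TRUE, sep = "\t")
  expect_equal(indiv$NSEG, c(1, 0))   # s2 has no segments but appears
})

test_that("empty roh_set writes header-only files", {
  rs <- roh_set(NULL, sample_ids = character())
  hp <- withr::local_tempfile(); ip <- withr::local_tempfile()
  write_hom(rs, hp, ip)
  expect_equal(length(readLines(hp)), 1L)
  expect_equal(length(readLines(ip)), 1L)
})

test_that(".hom round trip preserves segments field-by-field", {
  set.seed(11)
  seg <- data.frame(
    sample_id = sample(paste0("s", 1:5), 20, replace = TRUE),
    dataset_id = "d", chrom = sample(c("1", "2"), 20, replace = TRUE),
    start_bp = numeric(20), end_bp = numeric(20),
    n_snps = sample(40:200, 20, replace = TRUE))
  seg$start_bp <- sort(sample.int(5e7, 20))
  seg$end_bp <- seg$start_bp + sample.int(3e6, 20)
  # avoid overlaps within (sample, chrom) by spacing starts widely
  rs <- roh_set(seg, sample_ids = paste0("s", 1:5))
  hp <- withr::local_tempfile()
  write_hom(rs, hp)
  rs2 <- read_hom(hp, sample_ids = paste0("s", 1:5))
  expect_equal(as.data.frame(rs2)[c("sample_id", "chrom", "start_bp",
                                    "end_bp", "n_snps", "length_bp")],
               as.data.frame(rs)[c("sample_id", "chrom", "start_bp",
                                   "end_bp", "n_snps", "length_bp")])
})

test_that("segment with end < start is an invariant violation", {
  seg <- data.frame(sample_id = "s", dataset_id = "d", chrom = "1",
                    start_bp = 2000, end_bp = 1000, n_snps = 40L)
  expect_error(roh_set(seg), "end_bp < start_bp")
})
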
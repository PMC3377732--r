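test_that("PLINK round trip reproduces dosages, map and phenotype exactly", {
  for (cc in list(tiny_cohort(),
                  random_cohort(20, 50, seed = 11, missing_rate = 0.05),
                  random_cohort(7, 3, seed = 12))) {
    prefix <- file.path(withr::local_tempdir(), "rt")
    write_plink(cc, prefix)
    back <- read_plink(paste0(prefix, ".bed"), cohort_id = cc$cohort_id)
    expect_equal(back$genotypes, cc$genotypes, ignore_attr = TRUE)
    expect_equal(back$snps$id, cc$snps$id)
    expect_equal(back$snps$chrom, cc$snps$chrom)
    expect_equal(back$snps$pos_bp, cc$snps$pos_bp)
    expect_equal(back$phenotype, cc$phenotype)
  }
})

test_that("empty-SNP cohort writes header-only files and round-trips", {
  cc <- cohort(
    data.frame(id = character(), chrom = integer(), pos_bp = integer(),
               allele_ref = character(), allele_alt = character()),
    matrix(numeric(0), nrow = 3, ncol = 0), c(0L, 1L, 0L), "empty"
  )
  prefix <- file.path(withr::local_tempdir(), "empty")
  write_plink(cc, prefix)
  back <- read_plink(paste0(prefix, ".bed"))
  expect_equal(nrow(back$snps), 0)
  expect_equal(back$phenotype, cc$phenotype)
})

test_that(".bed size follows 3 + ceil(n/4) * n_snp bytes", {
  cc <- random_cohort(3, 10, seed = 13)
  prefix <- file.path(withr::local_tempdir(), "sz")
  write_plink(cc, prefix)
  expect_equal(file.size(paste0(prefix, ".bed")), 3 + ceiling(3 / 4) * 10)
})

test_that("bad magic bytes and individual-major mode are rejected", {
  dir <- withr::local_tempdir()
  cc <- random_cohort(4, 2, seed = 14)
  write_plink(cc, file.path(dir, "ok"))
  raw <- readBin(file.path(dir, "ok.bed"), "raw", 100)

  raw_bad <- raw; raw_bad[1] <- as.raw(0x00)
  writeBin(raw_bad, file.path(dir, "bad.bed"))
  file.copy(file.path(dir, "ok.bim"), file.path(dir, "bad.bim"))
  file.copy(file.path(dir, "ok.fam"), file.path(dir, "bad.fam"))
  expect_error(read_plink(file.path(dir, "bad.bed")), "magic")

  raw_im <- raw; raw_im[3] <- as.raw(0x00)
  writeBin(raw_im, file.path(dir, "im.bed"))
  file.copy(file.path(dir, "ok.bim"), file.path(dir, "im.bim"))
  file.copy(file.path(dir, "ok.fam"), file.path(dir, "im.fam"))
  expect_error(read_plink(file.path(dir, "im.bed")), "SNP-major")
})

test_that("hand-encoded byte decodes per the 2-bit format", {
  # codes (low pair first): 00=hom A1 (dosage 2), 10=het (1),
  # 01=missing (NA), 11=hom A2 (0).  0b11011000 packs, for samples 1-4,
  # codes 00, 10, 01, 11 -> dosages 2, 1, NA, 0.  Frozen after checking
  # against an external PLINK reader.
  dir <- withr::local_tempdir()
  writeBin(as.raw(c(0x6C, 0x1B, 0x01, 0xD8)), file.path(dir, "h.bed"))
  writeLines("1\trs1\t0\t100\tA\tG", file.path(dir, "h.bim"))
  writeLines(paste0("F", 1:4, " I", 1:4, " 0 0 0 ", c(1, 2, 1, 2)),
             file.path(dir, "h.fam"))
  cc <- read_plink(file.path(dir, "h.bed"))
  expect_equal(cc$genotypes[, 1], c(2, 1, NA, 0))
})

test_that("decoder agrees with a naive bit-by-bit reference decoder", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(1:9, 1); p <- sample(1:6, 1)
    body <- as.raw(sample(0:255, ceiling(n / 4) * p, replace = TRUE))
    expect_equal(segwise:::decode_bed_body(body, n, p),
                 naive_bed_decode(body, n, p))
  }
})

test_that("fam phenotype handling: recode, -9 drop, invalid error", {
  dir <- withr::local_tempdir()
  cc <- random_cohort(5, 4, seed = 15)
  write_plink(cc, file.path(dir, "ph"))
  fam <- read.table(file.path(dir, "ph.fam"))
  fam$V6 <- c(2, 1, -9, 2, 1)
  write.table(fam, file.path(dir, "ph.fam"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_warning(back <- read_plink(file.path(dir, "ph.bed")), "-9")
  expect_equal(back$phenotype, c(1L, 0L, 1L, 0L))
  expect_equal(nrow(back$genotypes), 4)

  fam$V6 <- c(2, 1, 3, 2, 1)
  write.table(fam, file.path(dir, "ph.fam"), quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(read_plink(file.path(dir, "ph.bed")), "phenotype")
})

test_that("text dialect: literal parse, domain checks, round trip", {
  f <- withr::local_tempfile(lines = c(
    "id rs1", "chrom 1", "pos 100", "a1 A", "a2 G",
    "0 0",
    "1 2"
  ))
  cc <- read_text_cohort(f)
  expect_equal(cc$genotypes, matrix(c(0, 2), ncol = 1), ignore_attr = TRUE)
  expect_equal(cc$phenotype, c(0L, 1L))

  bad <- withr::local_tempfile(lines = c(
    "id rs1", "chrom 1", "pos 100", "a1 A", "a2 G", "0 3", "1 2"))
  expect_error(read_text_cohort(bad), "dosages")

  ragged <- withr::local_tempfile(lines = c(
    "id rs1 rs2", "chrom 1 1", "pos 100 200", "a1 A A", "a2 G G",
    "0 1 2", "1 2"))
  expect_error(read_text_cohort(ragged), "line 7")

  cc2 <- random_cohort(10, 8, seed = 16, missing_rate = 0.1)
  path <- withr::local_tempfile()
  write_text_cohort(cc2, path)
  back <- read_text_cohort(path, cohort_id = "rand")
  expect_equal(back$genotypes, cc2$genotypes, ignore_attr = TRUE)
  expect_equal(back$phenotype, cc2$phenotype)
  expect_equal(back$snps$pos_bp, cc2$snps$pos_bp)
})

test_that("cohort invariants are enforced at construction", {
  snps <- data.frame(id = c("a", "b"), chrom = c(1L, 1L),
                     pos_bp = c(200L, 100L),
                     allele_ref = "A", allele_alt = "B")
  g <- matrix(0:1, 2, 2)
  expect_error(cohort(snps, g, c(0, 1)), "sorted")
  snps$pos_bp <- c(100L, 200L)
  expect_error(cohort(snps, matrix(3, 2, 2), c(0, 1)), "dosages")
  expect_error(cohort(snps, g, c(1, 1)), "both phenotype classes")
  expect_error(cohort(cbind(snps, chrom2 = 1)[, -2], g, c(0, 1)), "columns")
})
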
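#' Read a cohort from a PLINK 1 binary file set
#'
#' Reads the SNP-major `.bed`/`.bim`/`.fam` trio and returns a
#' [cohort()].  Dosages count the A1 (first `.bim`) allele: the two-bit
#' codes of the format are 00 = homozygous A1 (dosage 2), 10 =
#' heterozygous (1), 11 = homozygous A2 (0), 01 = missing (NA).
#' Phenotypes are taken from `.fam` column 6 and recoded 1 -> 0 (control),
#' 2 -> 1 (case); individuals with missing phenotype (-9) are dropped with
#' a warning.  Non-autosomal SNPs are dropped with a message.
#'
#' @param bed_path,bim_path,fam_path paths to the three files.  If
#'   `bim_path`/`fam_path` are missing they are derived from `bed_path` by
#'   substituting the extension.
#' @param cohort_id cohort label; defaults to the `.bed` basename.
#' @return A `segwise_cohort`.
#' @export
read_plink <- function(bed_path, bim_path = NULL, fam_path = NULL,
                       cohort_id = NULL) {
  if (is.null(bim_path)) bim_path <- sub("\\.bed$", ".bim", bed_path)
  if (is.null(fam_path)) fam_path <- sub("\\.bed$", ".fam", bed_path)
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  if (is.null(cohort_id)) cohort_id <- sub("\\.bed$", "", basename(bed_path))

  if (any(nzchar(trimws(readLines(bim_path))))) {
    bim <- utils::read.table(bim_path, header = FALSE, sep = "",
                             colClasses = c("character", "character",
                                            "character", "integer",
                                            "character", "character"))
  } else {
    bim <- data.frame(V1 = character(), V2 = character(), V3 = character(),
                      V4 = integer(), V5 = character(), V6 = character())
  }
  names(bim) <- c("chrom", "id", "cm", "pos_bp", "allele_a1", "allele_a2")
  fam <- utils::read.table(fam_path, header = FALSE, sep = "",
                           colClasses = "character")
  if (ncol(fam) < 6) stop("malformed .fam: expected 6 columns")
  pheno_raw <- suppressWarnings(as.numeric(fam[[6]]))
  if (!all(pheno_raw %in% c(1, 2, -9))) {
    stop("phenotype error: .fam column 6 must contain only 1, 2 or -9")
  }

  n <- nrow(fam)
  p <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B)) {
    stop("format error: not a PLINK 1 .bed file (bad magic bytes)")
  }
  if (raw[3] != as.raw(0x01)) {
    stop("unsupported-mode error: only SNP-major .bed files are supported")
  }
  bps <- ceiling(n / 4)  # bytes per SNP block
  if (length(raw) != 3 + bps * p) {
    stop("format error: .bed size ", length(raw), " does not match ",
         n, " individuals x ", p, " SNPs")
  }
  geno <- decode_bed_body(raw[-(1:3)], n, p)

  keep_snp <- bim$chrom %in% as.character(1:22)
  if (any(!keep_snp)) {
    message("dropping ", sum(!keep_snp), " non-autosomal SNP(s)")
    geno <- geno[, keep_snp, drop = FALSE]
    bim <- bim[keep_snp, , drop = FALSE]
  }
  keep_ind <- pheno_raw != -9
  if (any(!keep_ind)) {
    warning("dropping ", sum(!keep_ind),
            " individual(s) with missing (-9) phenotype")
    geno <- geno[keep_ind, , drop = FALSE]
    pheno_raw <- pheno_raw[keep_ind]
  }

  snps <- data.frame(
    id = bim$id, chrom = as.integer(bim$chrom), pos_bp = bim$pos_bp,
    allele_ref = bim$allele_a1, allele_alt = bim$allele_a2,
    stringsAsFactors = FALSE
  )
  cohort(snps, geno, as.integer(pheno_raw == 2), cohort_id)
}

# Vectorized 2-bit decoder: body bytes -> n x p dosage matrix.
# Code c(2i+1,2i) per sample i: 0 -> dosage 2 (hom A1), 1 -> NA (missing),
# 2 -> dosage 1 (het), 3 -> dosage 0 (hom A2).
decode_bed_body <- function(body, n, p) {
  bps <- ceiling(n / 4)
  bytes <- as.integer(body)
  dim(bytes) <- c(bps, p)
  lut <- c(2, NA, 1, 0)
  out <- matrix(NA_real_, nrow = 4 * bps, ncol = p)
  for (s in 0:3) {                      # sample slot within each byte
    code <- bitwAnd(bitwShiftR(bytes, 2L * s), 3L)
    out[seq(s + 1L, 4L * bps, by = 4L), ] <- lut[code + 1L]
  }
  out[seq_len(n), , drop = FALSE]
}

#' Write a cohort as a PLINK 1 binary file set
#'
#' Inverse of [read_plink()]: emits SNP-major `.bed` plus `.bim`/`.fam`.
#' Phenotype is written as 1/2 (control/case) in `.fam` column 6.
#'
#' @param x a `segwise_cohort`.
#' @param prefix output path prefix; `<prefix>.bed/.bim/.fam` are written.
#' @return The three file paths, invisibly.
#' @export
write_plink <- function(x, prefix) {
  validate_cohort(x)
  bim <- data.frame(
    chrom = x$snps$chrom, id = x$snps$id,
    cm = rep(0, nrow(x$snps)), pos_bp = x$snps$pos_bp,
    a1 = x$snps$allele_ref, a2 = x$snps$allele_alt
  )
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- n_ind(x)
  fam <- data.frame(
    fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
    pat = 0, mat = 0, sex = 0, pheno = x$phenotype + 1L
  )
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  # dosage -> 2-bit code: 2 -> 0, NA -> 1, 1 -> 2, 0 -> 3
  g <- x$genotypes
  code <- matrix(1L, nrow = n, ncol = ncol(g))
  code[!is.na(g)] <- c(3L, 2L, 0L)[g[!is.na(g)] + 1L]
  bps <- ceiling(n / 4)
  padded <- matrix(0L, nrow = 4L * bps, ncol = ncol(g))
  padded[seq_len(n), ] <- code
  bytes <- integer(bps * ncol(g))
  dim(bytes) <- c(bps, ncol(g))
  for (s in 0:3) {
    slot <- padded[seq(s + 1L, 4L * bps, by = 4L), , drop = FALSE]
    bytes <- bytes + bitwShiftL(slot, 2L * s)
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(paste0(prefix, c(".bed", ".bim", ".fam")))
}

#' Read a cohort from the plain-text fixture dialect
#'
#' A human-readable, whitespace-delimited format used for fixtures and
#' documentation.  Five header lines (`id`, `chrom`, `pos`, `a1`, `a2`,
#' each a tag followed by one field per SNP) are followed by one row per
#' individual: phenotype (0/1) then dosages (`NA` for missing).
#'
#' @param path file path.
#' @param cohort_id cohort label; defaults to the file basename.
#' @return A `segwise_cohort`.
#' @export
read_text_cohort <- function(path, cohort_id = NULL) {
  if (is.null(cohort_id)) {
    cohort_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 6) stop("parse error: expected 5 header lines plus data")
  hdr <- lapply(lines[1:5], function(l) strsplit(trimws(l), "\\s+")[[1]])
  tags <- vapply(hdr, `[`, "", 1)
  if (!identical(tags, c("id", "chrom", "pos", "a1", "a2"))) {
    stop("parse error: header lines must be tagged id/chrom/pos/a1/a2")
  }
  fields <- lapply(hdr, function(x) x[-1])
  p <- length(fields[[1]])
  if (!all(lengths(fields) == p)) stop("parse error: ragged header lines")
  snps <- data.frame(
    id = fields[[1]], chrom = as.integer(fields[[2]]),
    pos_bp = as.integer(fields[[3]]),
    allele_ref = fields[[4]], allele_alt = fields[[5]],
    stringsAsFactors = FALSE
  )
  body <- lines[-(1:5)]
  geno <- matrix(NA_real_, nrow = length(body), ncol = p)
  pheno <- integer(length(body))
  for (i in seq_along(body)) {
    v <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(v) != p + 1) {
      stop("parse error at line ", i + 5, ": expected ", p + 1,
           " fields, got ", length(v))
    }
    num <- suppressWarnings(as.numeric(ifelse(v == "NA", NA, v)))
    bad <- !is.na(num[-1]) & !(num[-1] %in% 0:2)
    if (any(bad) || (!is.na(num[1]) && !(num[1] %in% 0:1)) ||
        any(is.na(num[-1]) & v[-1] != "NA") || is.na(num[1])) {
      stop("parse error at line ", i + 5,
           ": phenotype must be 0/1 and dosages 0/1/2/NA")
    }
    pheno[i] <- as.integer(num[1])
    geno[i, ] <- num[-1]
  }
  cohort(snps, geno, pheno, cohort_id)
}

#' Write a cohort in the plain-text fixture dialect
#'
#' @param x a `segwise_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_text_cohort()] for the format.
#' @export
write_text_cohort <- function(x, path) {
  validate_cohort(x)
  hdr <- c(
    paste(c("id", x$snps$id), collapse = " "),
    paste(c("chrom", x$snps$chrom), collapse = " "),
    paste(c("pos", x$snps$pos_bp), collapse = " "),
    paste(c("a1", x$snps$allele_ref), collapse = " "),
    paste(c("a2", x$snps$allele_alt), collapse = " ")
  )
  g <- x$genotypes
  rows <- vapply(seq_len(nrow(g)), function(i) {
    paste(c(x$phenotype[i], ifelse(is.na(g[i, ]), "NA", g[i, ])),
          collapse = " ")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
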
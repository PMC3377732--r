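#' Construct a case/control genotype cohort
#'
#' A cohort bundles a SNP map, a dosage matrix and a binary phenotype.
#' Dosages count copies of the first (.bim A1) allele, so values are in
#' `{0, 1, 2, NA}`.  Only autosomes (chromosomes 1-22) are allowed and the
#' SNP map must be sorted by `(chrom, pos_bp)` with strictly increasing
#' positions within a chromosome.
#'
#' @param snps data.frame with columns `id`, `chrom` (integer 1-22),
#'   `pos_bp` (1-based base-pair position), `allele_ref`, `allele_alt`.
#' @param genotypes integer/numeric matrix, individuals x SNPs, entries in
#'   `{0, 1, 2, NA}`.
#' @param phenotype vector of 0 (control) / 1 (case), one per individual.
#'   A numeric (e.g. residualized) phenotype is *not* allowed here; pass
#'   those as `phenotype_override` to the analysis functions.
#' @param cohort_id character scalar naming the cohort.
#' @return An object of class `segwise_cohort`.
#' @seealso [read_plink()], [read_text_cohort()], [simulate_cohort()]
#' @export
cohort <- function(snps, genotypes, phenotype, cohort_id = "cohort") {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  obj <- structure(
    list(
      snps = as.data.frame(snps),
      genotypes = genotypes,
      phenotype = as.integer(phenotype),
      cohort_id = as.character(cohort_id)[1]
    ),
    class = "segwise_cohort"
  )
  validate_cohort(obj)
}

#' Validate a cohort object
#'
#' Checks every structural invariant of [cohort()] and returns the object
#' invisibly-unchanged on success; any violation is an error.
#'
#' @param x a `segwise_cohort`.
#' @return `x`, invisibly usable (returned unchanged).
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "segwise_cohort"))
  snps <- x$snps
  need <- c("id", "chrom", "pos_bp", "allele_ref", "allele_alt")
  if (!all(need %in% names(snps))) {
    stop("SNP map must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(snps) > 0) {
    if (anyDuplicated(snps$id)) stop("duplicate SNP ids in cohort")
    if (!all(snps$chrom %in% 1:22)) {
      stop("non-autosomal chromosome in SNP map (only 1-22 supported)")
    }
    if (any(snps$pos_bp < 1)) stop("SNP positions must be >= 1")
    o <- order(snps$chrom, snps$pos_bp)
    if (!identical(o, seq_len(nrow(snps)))) {
      stop("SNP map must be sorted by (chrom, pos_bp)")
    }
    same_chr <- diff(snps$chrom) == 0
    if (any(same_chr & diff(snps$pos_bp) <= 0)) {
      stop("SNP positions must be strictly increasing within a chromosome")
    }
  }
  if (ncol(x$genotypes) != nrow(snps)) {
    stop("genotype column count (", ncol(x$genotypes),
         ") does not match SNP count (", nrow(snps), ")")
  }
  if (length(x$phenotype) != nrow(x$genotypes)) {
    stop("phenotype length does not match individual count")
  }
  g <- x$genotypes
  if (!all(g[!is.na(g)] %in% 0:2)) stop("dosages must be in {0, 1, 2, NA}")
  if (!all(x$phenotype %in% 0:1)) stop("phenotype must be coded 0/1")
  if (length(unique(x$phenotype)) < 2) {
    stop("both phenotype classes (cases and controls) must be present")
  }
  x
}

#' @export
print.segwise_cohort <- function(x, ...) {
  cat(sprintf(
    "<segwise_cohort '%s'> %d individuals (%d cases / %d controls), %d SNPs on %d chromosome(s)\n",
    x$cohort_id, nrow(x$genotypes), sum(x$phenotype == 1),
    sum(x$phenotype == 0), nrow(x$snps), length(unique(x$snps$chrom))
  ))
  invisible(x)
}

#' @export
dim.segwise_cohort <- function(x) dim(x$genotypes)

# Number of individuals / SNPs (internal shorthands)
n_ind <- function(x) nrow(x$genotypes)
n_snp <- function(x) ncol(x$genotypes)
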
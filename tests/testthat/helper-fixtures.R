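# Shared fixtures and independent oracles.  Everything is generated in
# code; no binary fixtures are stored.

# Small deterministic cohort built by hand.
tiny_cohort <- function() {
  snps <- data.frame(
    id = c("rs1", "rs2", "rs3"), chrom = c(1L, 1L, 2L),
    pos_bp = c(100L, 5000L, 2000L),
    allele_ref = c("A", "C", "G"), allele_alt = c("G", "T", "A"),
    stringsAsFactors = FALSE
  )
  g <- rbind(c(0, 1, 2), c(1, 2, NA), c(2, 0, 0), c(1, 1, 1))
  cohort(snps, g, c(0L, 1L, 0L, 1L), "tiny")
}

# Random cohort with optional missingness (independent SNPs).
random_cohort <- function(n, p, seed, missing_rate = 0, id = "rand") {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    maf <- runif(p, 0.1, 0.5)
    g <- vapply(maf, function(f) rbinom(n, 2, f), numeric(n))
    if (missing_rate > 0) g[runif(n * p) < missing_rate] <- NA
    pheno <- rep_len(c(0L, 1L), n)[sample.int(n)]
    snps <- data.frame(
      id = paste0("rs", seq_len(p)), chrom = 1L,
      pos_bp = sort(sample.int(1e6, p)),
      allele_ref = "A", allele_alt = "B", stringsAsFactors = FALSE
    )
    cohort(snps, g, pheno, id)
  })
}

# Cochran-Armitage trend chi-square from the 2x3 contingency table,
# scores (0, 1, 2).  Independent of the package's N*r^2 route.
ca_trend_oracle <- function(dosage, pheno) {
  keep <- !is.na(dosage)
  dosage <- dosage[keep]; pheno <- pheno[keep]
  tab <- table(factor(pheno, 0:1), factor(dosage, 0:2))
  N <- sum(tab)
  n_j <- colSums(tab)
  R1 <- sum(tab[2, ])
  s <- 0:2
  T1 <- sum(s * (tab[2, ] - R1 * n_j / N))
  V <- R1 * (N - R1) / N * (sum(s^2 * n_j) - sum(s * n_j)^2 / N) / N
  if (V <= 0) return(0)
  T1^2 / V
}

# Naive bit-by-bit reference decoder for a PLINK .bed body.
naive_bed_decode <- function(body_raw, n, p) {
  bits <- as.integer(rawToBits(body_raw))  # little-endian bit order
  bps <- ceiling(n / 4)
  out <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    base <- (j - 1) * bps * 8
    for (i in seq_len(n)) {
      b0 <- bits[base + 2 * (i - 1) + 1]
      b1 <- bits[base + 2 * (i - 1) + 2]
      code <- b1 * 2 + b0
      out[i, j] <- c(2, NA, 1, 0)[code + 1]
    }
  }
  out
}

# Reference implementation of the greedy independent-SNP selection.
greedy_reference <- function(pvalue, r2, p_threshold = 0.05, max_snps = 5) {
  sel <- integer(0)
  alive <- rep(TRUE, length(pvalue))
  repeat {
    if (length(sel) >= max_snps) break
    cand <- which(alive & pvalue < p_threshold)
    if (!length(cand)) break
    # smallest p, ties by lower index (= lower genomic position)
    best <- cand[order(pvalue[cand], cand)][1]
    sel <- c(sel, best)
    alive[best] <- FALSE
    alive[which(r2[best, ] > 0.5)] <- FALSE
  }
  sel
}

# hg18-like autosome lengths (bp), used to anchor segment-count checks.
hg18_autosomes <- c(
  247249719, 242951149, 199501827, 191273063, 180857866, 170899992,
  158821424, 146274826, 140273252, 135374737, 134452384, 132349534,
  114142980, 106368585, 100338915, 88827254, 78774742, 76117153,
  63811651, 62435964, 46944323, 49691432
)

# Null simulated cohort, shared by calibration-style tests.
null_sim_cohort <- function(n_cases, n_controls, chrom_lengths, spacing,
                            seed, block_size = 20, id = "null") {
  cfg <- sim_config(
    n_cases = n_cases, n_controls = n_controls,
    chrom_lengths_bp = chrom_lengths, snp_spacing_bp = spacing,
    block_size_snps = block_size, planted_interval = NULL, seed = seed
  )
  simulate_cohort(cfg, cohort_id = id)$cohort
}
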
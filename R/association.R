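#' Per-SNP Armitage trend test
#'
#' Computes, for every SNP, the trend chi-square statistic
#' `N * r^2` (df = 1), where `r` is the Pearson correlation between the
#' allele dosage and the phenotype over individuals with a non-missing
#' dosage (pairwise deletion), and `N` is that per-SNP sample size.  On an
#' unadjusted 0/1 phenotype this equals the classical Cochran-Armitage
#' trend chi-square with scores (0, 1, 2); with a residualized phenotype
#' (see [eigenstrat_adjust()]) the same correlation statistic is used.
#' Monomorphic SNPs (zero dosage variance among tested individuals) get
#' statistic 0 and p = 1, and are flagged.
#'
#' The statistic is invariant under allele relabeling (`x -> 2 - x`), so
#' no minor-allele re-orientation is needed.
#'
#' @param x a [cohort()].
#' @param phenotype_override optional numeric vector replacing the 0/1
#'   phenotype (e.g. stratification-adjusted residuals).
#' @return A data.frame of class `segwise_assoc` with one row per SNP:
#'   `id`, `chrom`, `pos_bp`, `n_used`, `statistic`, `pvalue`,
#'   `monomorphic`.
#' @examples
#' set.seed(1)
#' cc <- simulate_cohort(sim_config(
#'   n_cases = 50, n_controls = 50, chrom_lengths_bp = c(`1` = 5e5),
#'   seed = 1))$cohort
#' head(trend_test(cc))
#' @export
trend_test <- function(x, phenotype_override = NULL) {
  validate_cohort(x)
  y <- resolve_phenotype(x, phenotype_override)
  if (stats::var(y) == 0) stop("constant phenotype: no test possible")
  st <- trend_stat_matrix(x$genotypes, matrix(y, ncol = 1))
  stat <- st$stat[, 1]
  structure(
    data.frame(
      id = x$snps$id, chrom = x$snps$chrom, pos_bp = x$snps$pos_bp,
      n_used = st$n_used,
      statistic = stat,
      pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      monomorphic = st$monomorphic[, 1],
      stringsAsFactors = FALSE
    ),
    class = c("segwise_assoc", "data.frame")
  )
}

# Trend statistics for one genotype matrix against k phenotype columns.
#
# G: n x p dosage matrix ({0,1,2,NA}); Y: n x k numeric phenotypes.
# Returns stat (p x k, N*r^2 with pairwise deletion, 0 where either
# variable is constant on the used individuals), n_used (length p), and
# monomorphic (p x k logical).  The k-column form is what makes
# label-permutation scans affordable: the heavy work is two (or four,
# with missing data) matrix products.
trend_stat_matrix <- function(G, Y) {
  n <- nrow(G)
  p <- ncol(G)
  k <- ncol(Y)
  if (p == 0L) {
    z <- matrix(numeric(0), 0, k)
    return(list(stat = z, n_used = integer(0),
                monomorphic = matrix(logical(0), 0, k)))
  }
  has_na <- anyNA(G)
  if (has_na) {
    M <- !is.na(G)
    G0 <- G
    G0[!M] <- 0
    storage.mode(M) <- "double"
    nu <- colSums(M)
    sx <- colSums(G0)
    sxx <- colSums(G0 * G0)
    sxy <- crossprod(G0, Y)              # p x k
    sy <- crossprod(M, Y)                # p x k
    syy <- crossprod(M, Y * Y)           # p x k
  } else {
    nu <- rep(n, p)
    sx <- colSums(G)
    sxx <- colSums(G * G)
    sxy <- crossprod(G, Y)
    sy <- matrix(colSums(Y), nrow = p, ncol = k, byrow = TRUE)
    syy <- matrix(colSums(Y * Y), nrow = p, ncol = k, byrow = TRUE)
  }
  # length-p vectors recycle down columns of p x k matrices
  vx <- nu * sxx - sx * sx               # p vector: n^2 * var_x
  vy <- nu * syy - sy * sy               # p x k
  cov <- nu * sxy - sx * sy              # p x k
  denom <- vx * vy
  mono <- denom <= 0
  denom[mono] <- 1
  stat <- nu * cov * cov / denom
  stat[mono] <- 0
  list(stat = stat, n_used = as.integer(nu), monomorphic = mono)
}

#' Stratification adjustment of the phenotype by genotype principal
#' components
#'
#' EIGENSTRAT-style correction: the genotype matrix is column-standardized
#' (subtract the column mean; divide by `sqrt(p*(1-p))` with `p` the sample
#' allele frequency; missing entries set to 0 after centering), the top
#' `n_components` left singular vectors over individuals are extracted,
#' case/control status is regressed on them by logistic regression, and
#' the response residuals (observed minus fitted probability) are returned
#' for use as the phenotype in downstream trend tests and scans.
#'
#' @param x a [cohort()].
#' @param n_components number of principal components to remove
#'   (default 10).  With 0, the mean-centered phenotype is returned.
#' @return An object of class `segwise_adjphen`: list with `values`
#'   (residuals, one per individual, mean ~ 0) and `n_components`.
#' @export
eigenstrat_adjust <- function(x, n_components = 10) {
  validate_cohort(x)
  n_components <- as.integer(n_components)
  n <- n_ind(x)
  if (n_components < 0 || n_components >= n) {
    stop("n_components must be in [0, individual count)")
  }
  y <- as.numeric(x$phenotype)
  if (n_components == 0L) {
    return(structure(list(values = y - mean(y), n_components = 0L),
                     class = "segwise_adjphen"))
  }
  G <- x$genotypes
  af <- colMeans(G, na.rm = TRUE) / 2
  poly <- !is.na(af) & af > 0 & af < 1
  if (sum(poly) < 2) stop("need at least 2 polymorphic SNPs for adjustment")
  G <- G[, poly, drop = FALSE]
  af <- af[poly]
  X <- sweep(G, 2, 2 * af, "-")
  X <- sweep(X, 2, sqrt(af * (1 - af)), "/")
  X[is.na(X)] <- 0
  k <- min(n_components, ncol(X))
  U <- svd(X, nu = k, nv = 0)$u          # n x k principal components

  fit <- suppressWarnings(stats::glm.fit(
    x = cbind(1, U), y = y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  if (!fit$converged) {
    worst <- which.max(abs(fit$coefficients[-1]))
    stop("logistic regression on principal components did not converge ",
         "(possible separation along component ", worst, ")")
  }
  structure(
    list(values = y - fit$fitted.values, n_components = k),
    class = "segwise_adjphen"
  )
}

#' @export
print.segwise_adjphen <- function(x, ...) {
  cat(sprintf("<segwise_adjphen> %d individuals, %d component(s) removed\n",
              length(x$values), x$n_components))
  invisible(x)
}

#' Write a per-SNP association table as TSV
#'
#' One row per SNP: id, chrom, pos, n_used, statistic, p.
#'
#' @param assoc result of [trend_test()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assoc_tsv <- function(assoc, path) {
  utils::write.table(
    assoc[, c("id", "chrom", "pos_bp", "n_used", "statistic", "pvalue")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Per-SNP Manhattan-plot export table
#'
#' @param assoc result of [trend_test()].
#' @return data.frame with `chrom`, `pos_bp`, `neglog10_p` per SNP.
#' @export
manhattan_table <- function(assoc) {
  data.frame(chrom = assoc$chrom, pos_bp = assoc$pos_bp,
             neglog10_p = -log10(assoc$pvalue))
}
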
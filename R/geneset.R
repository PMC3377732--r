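#' Read gene/region intervals for set-based testing
#'
#' Expects a whitespace/tab-delimited file with four columns: name,
#' chromosome, start, end.  Start and end are 1-based inclusive (the
#' convention of published gene tables) and are converted internally to
#' half-open `[start, end + 1)`.
#'
#' @param path interval file path.
#' @return data.frame with `name`, `chrom`, `start_bp`, `end_bp`
#'   (half-open).
#' @export
read_gene_intervals <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "",
                         col.names = c("name", "chrom", "start", "end"),
                         colClasses = c("character", "integer", "numeric",
                                        "numeric"))
  if (any(d$start >= d$end + 1)) stop("gene intervals must have start <= end")
  data.frame(name = d$name, chrom = d$chrom, start_bp = d$start,
             end_bp = d$end + 1, stringsAsFactors = FALSE)
}

# Member SNPs of one half-open interval on the cohort map.
interval_snps <- function(snp_map, chrom, start_bp, end_bp) {
  which(snp_map$chrom == chrom & snp_map$pos_bp >= start_bp &
        snp_map$pos_bp < end_bp)
}

#' Greedy selection of independent nominally significant SNPs
#'
#' The set-based gene test scores a gene on up to `max_snps` of its SNPs,
#' chosen greedily: repeatedly take the remaining member SNP with the
#' smallest p-value provided `p < p_threshold`, then discard all
#' remaining members whose squared dosage correlation with it exceeds
#' `r2_threshold`.  Ties on p are broken by lower genomic position.  An
#' empty selection is valid (no member reaches `p_threshold`).
#'
#' @param statistic,pvalue per-member trend statistics and p-values (same
#'   order as `snp_indices`).
#' @param snp_indices member SNP column indices into `genotypes`.
#' @param genotypes cohort dosage matrix (for LD pruning; r-squared is the
#'   squared Pearson correlation of dosages over individuals non-missing
#'   at both SNPs).
#' @param r2_threshold,p_threshold,max_snps selection parameters
#'   (defaults 0.5, 0.05, 5 — the conventional set-test defaults).
#' @return Indices (into the cohort map) of the selected SNPs, in
#'   selection order.
#' @export
select_independent <- function(statistic, pvalue, snp_indices, genotypes,
                               r2_threshold = 0.5, p_threshold = 0.05,
                               max_snps = 5) {
  if (length(snp_indices) == 0) return(integer(0))
  r2 <- gene_r2_matrix(genotypes, snp_indices)
  sel <- greedy_select(pvalue, seq_along(snp_indices), r2, r2_threshold,
                       p_threshold, max_snps)
  snp_indices[sel]
}

# Squared pairwise dosage correlation among member SNPs (pairwise-complete).
gene_r2_matrix <- function(genotypes, snp_indices) {
  g <- genotypes[, snp_indices, drop = FALSE]
  r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  r * r
}

# Greedy core shared by the observed pass and permutation replicates.
# Returns positions within the member vector, in selection order.
greedy_select <- function(pvalue, pos_rank, r2, r2_threshold, p_threshold,
                          max_snps) {
  alive <- !is.na(pvalue)
  sel <- integer(0)
  while (length(sel) < max_snps) {
    cand <- which(alive & pvalue < p_threshold)
    if (length(cand) == 0) break
    best <- cand[order(pvalue[cand], pos_rank[cand])][1]
    sel <- c(sel, best)
    alive[best] <- FALSE
    alive[r2[best, ] > r2_threshold] <- FALSE
  }
  sel
}

#' Set-based gene test with label-permutation significance
#'
#' For each gene interval, the observed score is the mean trend
#' chi-square of the greedily selected independent nominally significant
#' member SNPs ([select_independent()]; 0 if none qualify).  Significance
#' is assessed by globally permuting the phenotype: per replicate the
#' per-SNP tests, the selection and the score are recomputed, and
#' `empirical_p = (1 + #{replicate score >= observed}) /
#' (n_permutations + 1)`.  A gene with no observed selection reports
#' `empirical_p = 1`.
#'
#' @param x a [cohort()].
#' @param gene_sets data.frame from [read_gene_intervals()] (columns
#'   `name`, `chrom`, `start_bp`, `end_bp`, half-open).
#' @param n_permutations label permutations (default 1000).
#' @param seed integer seed; mandatory.
#' @param r2_threshold,p_threshold,max_snps see [select_independent()].
#' @param phenotype_override optional numeric/adjusted phenotype.
#' @return data.frame of class `segwise_setresult`: `name`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `n_selected`, `set_statistic`,
#'   `empirical_p`, plus attribute `selected_snps` (list of selected SNP
#'   ids per gene).
#' @export
set_based_test <- function(x, gene_sets, n_permutations = 1000, seed,
                           r2_threshold = 0.5, p_threshold = 0.05,
                           max_snps = 5, phenotype_override = NULL) {
  validate_cohort(x)
  if (missing(seed)) stop("seed must be supplied (reproducibility is mandatory)")
  if (nrow(gene_sets) == 0) stop("gene set list is empty")
  y <- resolve_phenotype(x, phenotype_override)
  if (stats::var(y) == 0) stop("constant phenotype: no test possible")

  members <- lapply(seq_len(nrow(gene_sets)), function(i) {
    interval_snps(x$snps, gene_sets$chrom[i], gene_sets$start_bp[i],
                  gene_sets$end_bp[i])
  })
  union_idx <- sort(unique(unlist(members)))
  member_loc <- lapply(members, function(m) match(m, union_idx))
  r2s <- lapply(members, function(m) gene_r2_matrix(x$genotypes, m))

  G <- x$genotypes[, union_idx, drop = FALSE]

  score_one <- function(stats_u, gene) {
    m <- member_loc[[gene]]
    if (length(m) == 0) return(list(score = 0, sel = integer(0)))
    st <- stats_u[m]
    pv <- stats::pchisq(st, 1, lower.tail = FALSE)
    sel <- greedy_select(pv, seq_along(m), r2s[[gene]], r2_threshold,
                         p_threshold, max_snps)
    list(score = if (length(sel)) mean(st[sel]) else 0, sel = sel)
  }

  obs_stat <- trend_stat_matrix(G, matrix(y, ncol = 1))$stat[, 1]
  obs <- lapply(seq_len(nrow(gene_sets)), function(g) score_one(obs_stat, g))
  obs_score <- vapply(obs, `[[`, 0, "score")

  n <- n_ind(x)
  perm_idx <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(r) sample.int(n), integer(n))
  })
  ge <- numeric(nrow(gene_sets))
  chunk <- 200L
  for (lo in seq(1L, n_permutations, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_permutations)
    Y <- matrix(y[perm_idx[, lo:hi]], nrow = n)
    S <- trend_stat_matrix(G, Y)$stat
    for (j in seq_len(hi - lo + 1L)) {
      sj <- S[, j]
      for (g in seq_len(nrow(gene_sets))) {
        if (score_one(sj, g)$score >= obs_score[g]) ge[g] <- ge[g] + 1
      }
    }
  }
  sel_ids <- lapply(seq_len(nrow(gene_sets)), function(g) {
    x$snps$id[members[[g]][obs[[g]]$sel]]
  })
  res <- data.frame(
    name = gene_sets$name, chrom = gene_sets$chrom,
    start_bp = gene_sets$start_bp, end_bp = gene_sets$end_bp,
    n_snps = lengths(members),
    n_selected = vapply(obs, function(o) length(o$sel), integer(1)),
    set_statistic = obs_score,
    empirical_p = (1 + ge) / (n_permutations + 1),
    stringsAsFactors = FALSE
  )
  attr(res, "selected_snps") <- sel_ids
  attr(res, "n_permutations") <- n_permutations
  attr(res, "seed") <- seed
  class(res) <- c("segwise_setresult", "data.frame")
  res
}
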
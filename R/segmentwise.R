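#' Tile autosomes into 50%-overlapping fixed-width segments
#'
#' Each chromosome present in the SNP map is tiled with half-open windows
#' `[k*w/2, k*w/2 + w)` for `k = 0, 1, ...`, where `w` is the segment
#' width, so consecutive segments overlap by 50%.  Tiling extends through
#' the last segment whose start does not exceed the largest SNP position
#' on the chromosome.  Segments containing no SNPs are retained but
#' flagged untestable.
#'
#' @param snp_map data.frame with `chrom` and `pos_bp` columns (e.g. the
#'   `snps` element of a [cohort()]).
#' @param width_bp segment width in base pairs; must be even and > 0.
#' @return A data.frame of class `segwise_segments` with columns `chrom`,
#'   `start_bp`, `end_bp`, `width_bp`, `n_snps`, `testable`, and an
#'   attribute `snp_indices` (list of row indices into `snp_map` per
#'   segment).
#' @export
make_segments <- function(snp_map, width_bp) {
  if (length(width_bp) != 1 || width_bp <= 0 || width_bp %% 2 != 0) {
    stop("width_bp must be a single even positive number ",
         "(50% overlap is undefined otherwise)")
  }
  if (nrow(snp_map) == 0) stop("empty SNP map")
  half <- width_bp / 2
  out <- list()
  idx <- list()
  for (ch in sort(unique(snp_map$chrom))) {
    rows <- which(snp_map$chrom == ch)
    pos <- snp_map$pos_bp[rows]
    k_max <- floor(max(pos) / half)
    starts <- (0:k_max) * half
    j <- pos %/% half                    # 0-based half-lattice cell per SNP
    for (k in 0:k_max) {
      member <- rows[j == k | j == k + 1]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_bp = k * half, end_bp = k * half + width_bp,
        width_bp = width_bp, n_snps = length(member),
        testable = length(member) > 0
      )
      idx[[length(idx) + 1L]] <- member
    }
  }
  seg <- do.call(rbind, out)
  attr(seg, "snp_indices") <- idx
  class(seg) <- c("segwise_segments", "data.frame")
  seg
}

#' Count nominally significant SNPs per segment
#'
#' @param snp_pvalues per-SNP p-values aligned to the SNP map that
#'   produced `segments`.
#' @param segments a `segwise_segments` object from [make_segments()].
#' @param nominal_alpha nominal per-SNP threshold; counts use the strict
#'   inequality `p < nominal_alpha`.
#' @return Integer vector of counts, one per segment.
#' @export
count_nominal <- function(snp_pvalues, segments, nominal_alpha = 0.05) {
  if (nominal_alpha <= 0 || nominal_alpha >= 1) {
    stop("nominal_alpha must be in (0, 1)")
  }
  sig <- snp_pvalues < nominal_alpha
  vapply(attr(segments, "snp_indices"),
         function(ix) sum(sig[ix]), integer(1))
}

# Shared permutation engine: observed and label-permutation-null nominal
# counts for an arbitrary list of SNP index sets.  One global phenotype
# shuffle per replicate is shared by all segments (and, through cmd_scan,
# by all widths), which preserves LD and inter-segment correlation in the
# null.  Permutation indices are drawn up-front from `seed` so results do
# not depend on the chunking used for the matrix products.
perm_count_engine <- function(x, y, snp_indices, nominal_alpha,
                              n_permutations, seed, chunk = 200L) {
  if (nominal_alpha <= 0 || nominal_alpha >= 1) {
    stop("nominal_alpha must be in (0, 1)")
  }
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (stats::var(y) == 0) stop("constant phenotype: no test possible")
  n <- n_ind(x)
  thr <- stats::qchisq(nominal_alpha, df = 1, lower.tail = FALSE)
  G <- x$genotypes

  obs_stat <- trend_stat_matrix(G, matrix(y, ncol = 1))$stat[, 1]
  seg_of <- rep(seq_along(snp_indices), lengths(snp_indices))
  flat <- unlist(snp_indices, use.names = FALSE)
  count_cols <- function(B) {
    # B: p x m numeric 0/1; returns length(snp_indices) x m counts
    out <- matrix(0, nrow = length(snp_indices), ncol = ncol(B))
    if (length(flat)) {
      rs <- rowsum(B[flat, , drop = FALSE], group = seg_of)
      out[as.integer(rownames(rs)), ] <- rs
    }
    out
  }
  observed <- as.integer(count_cols(matrix(as.numeric(obs_stat > thr))))

  perm_idx <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(r) sample.int(n), integer(n))
  })
  null_counts <- matrix(0, nrow = length(snp_indices), ncol = n_permutations)
  for (lo in seq(1L, n_permutations, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_permutations)
    Y <- matrix(y[perm_idx[, lo:hi]], nrow = n)
    S <- trend_stat_matrix(G, Y)$stat
    null_counts[, lo:hi] <- count_cols((S > thr) + 0)
  }
  ge <- rowSums(null_counts >= observed)
  list(
    observed = observed,
    expected = rowMeans(null_counts),
    p = (1 + ge) / (n_permutations + 1),
    obs_stat = obs_stat
  )
}

#' Permutation scan of a segment lattice
#'
#' For each segment, counts SNPs with trend-test `p < nominal_alpha` on
#' the observed phenotype, then compares that count with its distribution
#' under case/control label permutation: per replicate the phenotype
#' vector is globally shuffled once (shared by all segments, which
#' preserves linkage disequilibrium and inter-segment correlation) and
#' all SNP tests are recomputed.  The segment-level "metasignificance"
#' p-value is `(1 + #{replicates with null count >= observed}) /
#' (n_permutations + 1)`, one-sided: only an excess of nominally
#' significant SNPs counts as signal.  Its smallest attainable value is
#' `1/(n_permutations + 1)`.
#'
#' @param x a [cohort()].
#' @param segments a `segwise_segments` object built on `x$snps`.
#' @param nominal_alpha per-SNP nominal threshold (default 0.05).
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer seed; mandatory, so scans are reproducible.
#' @param phenotype_override optional numeric vector or
#'   [eigenstrat_adjust()] result used instead of the 0/1 phenotype.
#' @return A data.frame of class `segwise_scan`: one row per segment with
#'   `cohort_id`, `chrom`, `start_bp`, `end_bp`, `width_bp`, `n_snps`,
#'   `observed_count`, `expected_count` (permutation-null mean),
#'   `metasignificance_p` (NA for untestable segments), `testable`.
#'   Attributes `nominal_alpha`, `n_permutations`, `seed` record the run.
#' @export
permutation_scan <- function(x, segments, nominal_alpha = 0.05,
                             n_permutations = 1000, seed,
                             phenotype_override = NULL) {
  validate_cohort(x)
  if (missing(seed)) stop("seed must be supplied (reproducibility is mandatory)")
  y <- resolve_phenotype(x, phenotype_override)
  eng <- perm_count_engine(x, y, attr(segments, "snp_indices"),
                           nominal_alpha, n_permutations, seed)
  res <- data.frame(
    cohort_id = x$cohort_id,
    chrom = segments$chrom, start_bp = segments$start_bp,
    end_bp = segments$end_bp, width_bp = segments$width_bp,
    n_snps = segments$n_snps,
    observed_count = eng$observed,
    expected_count = eng$expected,
    metasignificance_p = ifelse(segments$testable, eng$p, NA_real_),
    testable = segments$testable
  )
  attr(res, "nominal_alpha") <- nominal_alpha
  attr(res, "n_permutations") <- n_permutations
  attr(res, "seed") <- seed
  class(res) <- c("segwise_scan", "data.frame")
  res
}

#' Targeted permutation test of one genomic interval
#'
#' Same contract as [permutation_scan()] restricted to a single, ad-hoc
#' half-open interval `[start_bp, end_bp)` that need not lie on any
#' lattice.  With the same seed, an interval equal to a lattice segment
#' reproduces that segment's scan entry exactly.
#'
#' @inheritParams permutation_scan
#' @param chrom chromosome (1-22).
#' @param start_bp,end_bp half-open interval bounds in base pairs.
#' @return One-row `segwise_scan` data.frame.
#' @export
targeted_region_test <- function(x, chrom, start_bp, end_bp,
                                 nominal_alpha = 0.05,
                                 n_permutations = 1000, seed,
                                 phenotype_override = NULL) {
  validate_cohort(x)
  if (missing(seed)) stop("seed must be supplied (reproducibility is mandatory)")
  if (!chrom %in% x$snps$chrom) {
    stop("chromosome ", chrom, " is absent from the cohort")
  }
  if (end_bp <= start_bp) stop("empty interval")
  member <- which(x$snps$chrom == chrom &
                  x$snps$pos_bp >= start_bp & x$snps$pos_bp < end_bp)
  if (length(member) == 0) {
    stop("untestable: interval contains no SNPs")
  }
  y <- resolve_phenotype(x, phenotype_override)
  eng <- perm_count_engine(x, y, list(member), nominal_alpha,
                           n_permutations, seed)
  res <- data.frame(
    cohort_id = x$cohort_id, chrom = chrom, start_bp = start_bp,
    end_bp = end_bp, width_bp = end_bp - start_bp,
    n_snps = length(member),
    observed_count = eng$observed, expected_count = eng$expected,
    metasignificance_p = eng$p, testable = TRUE
  )
  attr(res, "nominal_alpha") <- nominal_alpha
  attr(res, "n_permutations") <- n_permutations
  attr(res, "seed") <- seed
  class(res) <- c("segwise_scan", "data.frame")
  res
}

#' Write a segment scan results table as TSV
#'
#' @param scan a `segwise_scan` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
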
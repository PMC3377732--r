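map_with_max <- function(maxpos, chrom = 1L) {
  data.frame(chrom = chrom, pos_bp = c(1, maxpos))
}

test_that("tiling arithmetic: starts at multiples of width/2 through the last SNP", {
  seg <- make_segments(map_with_max(9.5e6), 4e6)
  expect_equal(seg$start_bp, c(0, 2, 4, 6, 8) * 1e6)
  expect_equal(seg$end_bp - seg$start_bp, rep(4e6, 5))
  expect_error(make_segments(map_with_max(9.5e6), 3e6 + 1), "even")
  expect_error(make_segments(map_with_max(1e6)[0, ], 2e6), "empty")
})

test_that("segment membership is exact half-open interval membership", {
  snp_map <- data.frame(chrom = 1L,
                        pos_bp = c(1, 1999999, 2000000, 3999999, 4000000))
  seg <- make_segments(snp_map, 4e6)
  idx <- attr(seg, "snp_indices")
  brute <- lapply(seq_len(nrow(seg)), function(i) {
    which(snp_map$pos_bp >= seg$start_bp[i] & snp_map$pos_bp < seg$end_bp[i])
  })
  expect_equal(idx, brute)
})

test_that("every published replicable region lies on its width's lattice", {
  chr5 <- data.frame(chrom = 5L, pos_bp = c(1, hg18_autosomes[5]))
  regions <- list(c(4e6, 132e6, 136e6), c(8e6, 128e6, 136e6),
                  c(16e6, 120e6, 136e6), c(16e6, 128e6, 144e6),
                  c(32e6, 128e6, 160e6))
  for (r in regions) {
    seg <- make_segments(chr5, r[1])
    expect_true(any(seg$start_bp == r[2] & seg$end_bp == r[3]),
                label = paste("region", r[2] / 1e6, "-", r[3] / 1e6,
                              "Mbp at width", r[1] / 1e6))
  }
})

test_that("2 Mbp tiling of an hg18-like genome yields ~2.7-2.9k segments", {
  snp_map <- do.call(rbind, lapply(1:22, function(ch) {
    data.frame(chrom = ch, pos_bp = c(1, hg18_autosomes[ch]))
  }))
  seg <- make_segments(snp_map, 2e6)
  expect_gt(nrow(seg), 2600)
  expect_lt(nrow(seg), 3000)
})

test_that("count_nominal counts strict p < alpha per segment", {
  snp_map <- data.frame(chrom = 1L, pos_bp = c(10, 20, 30, 40))
  seg <- make_segments(snp_map, 2e6)  # single pair of segments, all SNPs
  counts <- count_nominal(c(0.01, 0.2, 0.04, 0.6), seg, 0.05)
  expect_equal(counts[1], 2L)
  expect_error(count_nominal(runif(4), seg, 1.5), "alpha")

  cc <- random_cohort(30, 100, seed = 41)
  seg2 <- make_segments(cc$snps, 2e5)
  pv <- trend_test(cc)$pvalue
  counts2 <- count_nominal(pv, seg2, 0.05)
  brute <- vapply(seq_len(nrow(seg2)), function(i) {
    sum(pv < 0.05 & cc$snps$chrom == seg2$chrom[i] &
        cc$snps$pos_bp >= seg2$start_bp[i] &
        cc$snps$pos_bp < seg2$end_bp[i])
  }, integer(1))
  expect_equal(counts2, brute)
})

test_that("permutation p estimator bounds and determinism", {
  cc <- random_cohort(60, 120, seed = 42)
  seg <- make_segments(cc$snps, 4e5)
  sc1 <- permutation_scan(cc, seg, n_permutations = 99, seed = 5)
  sc2 <- permutation_scan(cc, seg, n_permutations = 99, seed = 5)
  expect_identical(sc1, sc2)
  expect_true(all(sc1$metasignificance_p >= 1 / 100, na.rm = TRUE))
  expect_true(all(sc1$metasignificance_p <= 1, na.rm = TRUE))
  expect_true(all(sc1$observed_count <= sc1$n_snps))
  expect_error(permutation_scan(cc, seg, n_permutations = 99), "seed")
})

test_that("sum of observed counts over the even sub-lattice equals the genome-wide count", {
  cc <- random_cohort(80, 150, seed = 43)
  seg <- make_segments(cc$snps, 2e5)
  sc <- permutation_scan(cc, seg, n_permutations = 20, seed = 6)
  even <- seg$start_bp %% 2e5 == 0  # non-overlapping sub-lattice
  pv <- trend_test(cc)$pvalue
  expect_equal(sum(sc$observed_count[even]), sum(pv < 0.05))
})

test_that("a planted segment is detected and hits the permutation floor", {
  cfg <- sim_config(n_cases = 150, n_controls = 150,
                    chrom_lengths_bp = c(`1` = 2e7), snp_spacing_bp = 1e4,
                    planted_interval = c(1, 8e6, 12e6), planted_or = 1.3,
                    seed = 44)
  cc <- simulate_cohort(cfg)$cohort
  seg <- make_segments(cc$snps, 4e6)
  sc <- permutation_scan(cc, seg, n_permutations = 200, seed = 7)
  planted <- which(sc$start_bp == 8e6 & sc$width_bp == 4e6)
  expect_lt(sc$metasignificance_p[planted], 0.05)
  expect_gt(sc$observed_count[planted], sc$expected_count[planted])
})

test_that("targeted region test matches the lattice segment under the same seed", {
  cc <- random_cohort(60, 200, seed = 45)
  seg <- make_segments(cc$snps, 4e5)
  sc <- permutation_scan(cc, seg, n_permutations = 150, seed = 8)
  i <- 2
  tr <- targeted_region_test(cc, seg$chrom[i], seg$start_bp[i],
                             seg$end_bp[i], n_permutations = 150, seed = 8)
  expect_equal(tr$observed_count, sc$observed_count[i])
  expect_equal(tr$expected_count, sc$expected_count[i])
  expect_equal(tr$metasignificance_p, sc$metasignificance_p[i])

  expect_error(targeted_region_test(cc, 9, 0, 1e6, seed = 1), "absent")
  expect_error(
    targeted_region_test(cc, 1, 2e6, 3e6, n_permutations = 10, seed = 1),
    "untestable")
})

test_that("null counts behave binomially without LD and over-disperse with LD", {
  alpha <- 0.05
  n_perm <- 400
  null_counts <- function(cc, member) {
    y <- cc$phenotype
    set.seed(9)
    vapply(seq_len(n_perm), function(r) {
      pv <- trend_test(cc, phenotype_override = y[sample.int(length(y))])$pvalue
      sum(pv[member] < alpha)
    }, numeric(1))
  }
  # independent SNPs: variance ~ m * alpha * (1 - alpha)
  cc_ind <- null_sim_cohort(100, 100, c(`1` = 2e6), spacing = 1e4,
                            seed = 46, block_size = 1)
  m <- n_snp(cc_ind)
  nc <- null_counts(cc_ind, seq_len(m))
  # mean within 20% of m*alpha (chi-square approximation + MC error)
  expect_lt(abs(mean(nc) - m * alpha), 0.2 * m * alpha)
  expect_lt(var(nc), 2.0 * m * alpha * (1 - alpha))
  # blocked LD: permutation null wider than the independence binomial
  cc_ld <- null_sim_cohort(100, 100, c(`1` = 2e6), spacing = 1e4,
                           seed = 47, block_size = 20)
  nc_ld <- null_counts(cc_ld, seq_len(n_snp(cc_ld)))
  expect_gt(var(nc_ld), m * alpha * (1 - alpha))
})
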
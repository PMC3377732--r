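#' Configuration for the synthetic cohort generator
#'
#' Describes a case/control cohort with haplotype-block linkage
#' disequilibrium, optional two-subpopulation stratification, and an
#' optional planted chromosomal segment enriched with many weak-effect
#' risk SNPs — the data-generating world the segment-wise scan targets:
#' individually undetectable variants (per-SNP odds ratios around
#' 1.05-1.1) that are collocated in one megabase-scale region.
#'
#' Genotypes are built from per-block haplotype pools: each block of
#' `block_size_snps` consecutive SNPs carries `haplotypes_per_block`
#' haplotype vectors drawn at per-block allele frequencies in
#' `[0.05, 0.5]`; every individual draws two pool haplotypes per block.
#' This yields strong LD within blocks and essentially none between.
#' Disease follows a logistic liability: log-odds = intercept +
#' `log(planted_or)` per risk-allele copy at each causal SNP (+ a
#' subpopulation offset), with the intercept solved so the population
#' prevalence matches `prevalence`.  Cases and controls are
#' rejection-sampled to the exact configured counts.
#'
#' @param n_cases,n_controls cohort sizes (defaults 728/653, typical of a
#'   single-country schizophrenia GWAS cohort).
#' @param chrom_lengths_bp named numeric vector, chromosome (1-22) ->
#'   length in bp.  Default: one 48 Mbp chromosome "1" (desk-scale).
#' @param snp_spacing_bp inter-SNP spacing (default 5000 bp, the density
#'   of a ~550k genome-wide array).
#' @param block_size_snps SNPs per LD block (default 20, i.e. 100 kbp
#'   haplotype blocks at the default spacing).
#' @param haplotypes_per_block size of each block's haplotype pool
#'   (default 8; smaller pools mean stronger LD).
#' @param planted_interval optional `c(chrom, start_bp, end_bp)` interval
#'   carrying causal SNPs; NULL for a null cohort.
#' @param planted_fraction fraction of interval SNPs that are causal
#'   (default 0.3).
#' @param planted_or per-SNP per-allele odds ratio (default 1.08; must be
#'   >= 1).
#' @param strat_fraction Balding-Nichols F for allele-frequency
#'   divergence between two equal subpopulations (0 = no structure).
#' @param strat_case_offset additive log-odds disease offset for
#'   subpopulation 2 (confounds structure with the phenotype when
#'   nonzero).
#' @param prevalence baseline disease prevalence (default 0.01,
#'   schizophrenia-like).
#' @param seed integer seed; mandatory.
#' @return A validated `segwise_simconfig` list.
#' @export
sim_config <- function(n_cases = 728, n_controls = 653,
                       chrom_lengths_bp = c(`1` = 48e6),
                       snp_spacing_bp = 5000,
                       block_size_snps = 20,
                       haplotypes_per_block = 8,
                       planted_interval = NULL,
                       planted_fraction = 0.3,
                       planted_or = 1.08,
                       strat_fraction = 0,
                       strat_case_offset = 0,
                       prevalence = 0.01,
                       seed) {
  if (missing(seed)) stop("seed must be supplied (reproducibility is mandatory)")
  cfg <- structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    chrom_lengths_bp = chrom_lengths_bp,
    snp_spacing_bp = as.integer(snp_spacing_bp),
    block_size_snps = as.integer(block_size_snps),
    haplotypes_per_block = as.integer(haplotypes_per_block),
    planted_interval = planted_interval,
    planted_fraction = planted_fraction, planted_or = planted_or,
    strat_fraction = strat_fraction,
    strat_case_offset = strat_case_offset,
    prevalence = prevalence, seed = as.integer(seed)
  ), class = "segwise_simconfig")
  with(cfg, {
    stopifnot(n_cases > 0, n_controls > 0, snp_spacing_bp > 0,
              block_size_snps > 0, haplotypes_per_block >= 2,
              planted_fraction >= 0, planted_fraction <= 1,
              planted_or >= 1, strat_fraction >= 0, strat_fraction < 1,
              prevalence > 0, prevalence < 1)
    if (is.null(names(chrom_lengths_bp)) ||
        !all(names(chrom_lengths_bp) %in% as.character(1:22))) {
      stop("chrom_lengths_bp must be named by autosome (1-22)")
    }
    if (!is.null(planted_interval)) {
      stopifnot(length(planted_interval) == 3)
      ch <- as.character(planted_interval[1])
      if (!ch %in% names(chrom_lengths_bp) ||
          planted_interval[3] > chrom_lengths_bp[[ch]] ||
          planted_interval[2] < 0 ||
          planted_interval[2] >= planted_interval[3]) {
        stop("planted_interval must lie within chrom_lengths_bp")
      }
    }
  })
  cfg
}

#' Simulate a case/control cohort
#'
#' Draws a cohort under a [sim_config()] world.  Returns both the cohort
#' and a truth record (causal SNP table and per-individual subpopulation
#' labels) for power and calibration studies.
#'
#' @param config a `segwise_simconfig`.
#' @param cohort_id label for the generated cohort.
#' @return List with `cohort` (a `segwise_cohort`) and `truth` (list with
#'   `causal` data.frame of `id`/`chrom`/`pos_bp`/`or`, `subpop` integer
#'   vector (1/2) per retained individual, and `intercept`).
#' @export
simulate_cohort <- function(config, cohort_id = "simulated") {
  stopifnot(inherits(config, "segwise_simconfig"))
  with_seed(config$seed, simulate_cohort_impl(config, cohort_id))
}

simulate_cohort_impl <- function(cfg, cohort_id) {
  # --- SNP map ---------------------------------------------------------
  chroms <- as.integer(names(cfg$chrom_lengths_bp))
  ord <- order(chroms)
  chroms <- chroms[ord]
  lens <- as.numeric(cfg$chrom_lengths_bp)[ord]
  snps <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    pos <- seq(cfg$snp_spacing_bp, lens[i], by = cfg$snp_spacing_bp)
    data.frame(chrom = chroms[i], pos_bp = as.integer(pos))
  }))
  p <- nrow(snps)
  snps$id <- sprintf("snp_%d_%d", snps$chrom, snps$pos_bp)
  snps$allele_ref <- "A"
  snps$allele_alt <- "B"

  # --- blocks and haplotype pools --------------------------------------
  # Blocks never span chromosomes.
  block_of <- integer(p)
  b <- 0L
  for (ch in chroms) {
    rows <- which(snps$chrom == ch)
    block_of[rows] <- b + (seq_along(rows) - 1L) %/% cfg$block_size_snps + 1L
    b <- max(block_of[rows])
  }
  n_blocks <- b
  n_pops <- if (cfg$strat_fraction > 0) 2L else 1L
  # Ancestral per-SNP frequencies, uniform in [0.05, 0.5]
  anc_f <- stats::runif(p, 0.05, 0.5)
  pop_f <- matrix(anc_f, nrow = p, ncol = n_pops)
  if (n_pops == 2L) {
    F <- cfg$strat_fraction
    for (k in 1:2) {
      pop_f[, k] <- stats::rbeta(p, anc_f * (1 - F) / F,
                                 (1 - anc_f) * (1 - F) / F)
      pop_f[, k] <- pmin(pmax(pop_f[, k], 0.01), 0.99)
    }
  }
  H <- cfg$haplotypes_per_block
  # pools[[pop]][[block]]: H x block_size 0/1 haplotype matrix
  pools <- lapply(seq_len(n_pops), function(k) {
    lapply(seq_len(n_blocks), function(bl) {
      cols <- which(block_of == bl)
      matrix(stats::rbinom(H * length(cols), 1, rep(pop_f[cols, k],
                                                    each = H)),
             nrow = H)
    })
  })

  # --- causal SNPs ------------------------------------------------------
  causal <- integer(0)
  if (!is.null(cfg$planted_interval) && cfg$planted_or > 1 &&
      cfg$planted_fraction > 0) {
    inside <- which(snps$chrom == cfg$planted_interval[1] &
                    snps$pos_bp >= cfg$planted_interval[2] &
                    snps$pos_bp < cfg$planted_interval[3])
    n_causal <- round(cfg$planted_fraction * length(inside))
    causal <- sort(sample(inside, n_causal))
  }
  beta <- log(cfg$planted_or)
  causal_blocks <- unique(block_of[causal])

  # Causal dosage for a batch given haplotype pool indices (cheap: only
  # causal blocks are materialized before case/control status is known).
  causal_dosage <- function(i1, i2, pop) {
    eta <- numeric(nrow(i1))
    for (bl in causal_blocks) {
      cols_in_bl <- which(block_of == bl)
      cc <- match(intersect(causal, cols_in_bl), cols_in_bl)
      for (k in seq_len(n_pops)) {
        rows <- which(pop == k)
        if (!length(rows)) next
        hp <- pools[[k]][[bl]]
        d <- hp[i1[rows, bl], cc, drop = FALSE] +
             hp[i2[rows, bl], cc, drop = FALSE]
        eta[rows] <- eta[rows] + rowSums(d) * beta
      }
    }
    eta
  }
  draw_batch <- function(m) {
    pop <- if (n_pops == 2L) sample(1:2, m, replace = TRUE) else rep(1L, m)
    i1 <- matrix(sample.int(H, m * n_blocks, replace = TRUE), m)
    i2 <- matrix(sample.int(H, m * n_blocks, replace = TRUE), m)
    eta <- causal_dosage(i1, i2, pop) +
      cfg$strat_case_offset * (pop == 2L)
    list(pop = pop, i1 = i1, i2 = i2, eta = eta)
  }

  # --- intercept: solve population prevalence --------------------------
  calib <- draw_batch(4000L)
  intercept <- stats::uniroot(
    function(c0) mean(stats::plogis(calib$eta + c0)) - cfg$prevalence,
    lower = -40, upper = 10, tol = 1e-10
  )$root

  # --- rejection-sample cases and controls -----------------------------
  need_ca <- cfg$n_cases
  need_co <- cfg$n_controls
  kept <- list()
  total <- 0L
  budget <- ceiling(20 * (need_ca / cfg$prevalence + need_co)) + 40000L
  while (need_ca > 0L || need_co > 0L) {
    m <- min(25000L, max(5000L, ceiling(need_ca / cfg$prevalence * 1.2)))
    if (total + m > budget) {
      stop("infeasible case count: disease probability too small; ",
           "increase planted_or or prevalence")
    }
    bt <- draw_batch(m)
    total <- total + m
    case <- stats::rbinom(m, 1, stats::plogis(bt$eta + intercept))
    take_ca <- utils::head(which(case == 1L), need_ca)
    take_co <- utils::head(which(case == 0L), need_co)
    take <- c(take_ca, take_co)
    if (length(take)) {
      kept[[length(kept) + 1L]] <- list(
        pop = bt$pop[take], i1 = bt$i1[take, , drop = FALSE],
        i2 = bt$i2[take, , drop = FALSE], case = case[take]
      )
      need_ca <- need_ca - length(take_ca)
      need_co <- need_co - length(take_co)
    }
  }
  pop <- unlist(lapply(kept, `[[`, "pop"))
  i1 <- do.call(rbind, lapply(kept, `[[`, "i1"))
  i2 <- do.call(rbind, lapply(kept, `[[`, "i2"))
  case <- unlist(lapply(kept, `[[`, "case"))
  n <- length(case)

  # --- materialize full genotypes --------------------------------------
  G <- matrix(0, nrow = n, ncol = p)
  for (bl in seq_len(n_blocks)) {
    cols <- which(block_of == bl)
    for (k in seq_len(n_pops)) {
      rows <- which(pop == k)
      if (!length(rows)) next
      hp <- pools[[k]][[bl]]
      G[rows, cols] <- hp[i1[rows, bl], , drop = FALSE] +
                       hp[i2[rows, bl], , drop = FALSE]
    }
  }

  cc <- cohort(
    snps[, c("id", "chrom", "pos_bp", "allele_ref", "allele_alt")],
    G, case, cohort_id
  )
  truth <- list(
    causal = data.frame(
      id = snps$id[causal], chrom = snps$chrom[causal],
      pos_bp = snps$pos_bp[causal],
      or = rep(cfg$planted_or, length(causal)),
      stringsAsFactors = FALSE
    ),
    subpop = pop,
    intercept = intercept
  )
  list(cohort = cc, truth = truth)
}

#' Write a simulated cohort as fixtures
#'
#' Emits the PLINK 1 binary trio, the plain-text fixture dialect and a
#' truth TSV (one row per causal SNP) into `dir`.  Deterministic given
#' the generator seed.
#'
#' @param x a `segwise_cohort`.
#' @param truth truth record from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file name stem (default the cohort id).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(x, truth, dir, prefix = x$cohort_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, prefix)
  write_plink(x, stem)
  write_text_cohort(x, paste0(stem, ".txt"))
  utils::write.table(truth$causal, paste0(stem, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(bed = paste0(stem, ".bed"), bim = paste0(stem, ".bim"),
              fam = paste0(stem, ".fam"), text = paste0(stem, ".txt"),
              truth = paste0(stem, ".truth.tsv")))
}
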
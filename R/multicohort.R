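#' Fisher's combined probability test
#'
#' Combines k independent p-values via `chi2 = -2 * sum(log(p))`, referred
#' to a chi-square distribution with `2k` degrees of freedom.
#'
#' @param p_list numeric vector of p-values, all in (0, 1].
#' @return List with `chi2`, `df` (= 2k) and `p`.
#' @examples
#' fisher_combined(c(0.017, 0.009, 0.025))$p  # ~3.49e-4
#' @export
fisher_combined <- function(p_list) {
  p_list <- as.numeric(p_list)
  if (length(p_list) == 0) stop("empty p-value list")
  if (any(is.na(p_list)) || any(p_list <= 0) || any(p_list > 1)) {
    stop("all p-values must lie in (0, 1]")
  }
  chi2 <- -2 * sum(log(p_list))
  df <- 2L * length(p_list)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Per-cohort threshold for a compound-significance replication rule
#'
#' A segment is called replicated only if it passes the per-cohort
#' threshold `t` in every one of `n_cohorts` independent cohorts; the
#' joint false-positive chance is then `t^n_cohorts`.  This solves for
#' `t` given the required family-wise alpha:
#' `t = family_alpha^(1/n_cohorts)`.
#'
#' @param n_cohorts number of independent cohorts (>= 1).
#' @param family_alpha required joint false-positive probability, in
#'   (0, 1) (typically the Bonferroni-corrected level from
#'   [bonferroni_family_alpha()]).
#' @return The per-cohort threshold.
#' @examples
#' compound_criterion(3, bonferroni_family_alpha(2729))  # ~0.0264
#' @export
compound_criterion <- function(n_cohorts, family_alpha) {
  if (n_cohorts < 1) stop("n_cohorts must be >= 1")
  if (family_alpha <= 0 || family_alpha >= 1) {
    stop("family_alpha must be in (0, 1)")
  }
  family_alpha^(1 / n_cohorts)
}

#' Bonferroni family-wise alpha at the worst-case segment count
#'
#' The scan is corrected for the number of tests in the worst case, i.e.
#' the number of segments at the narrowest width, so that every width is
#' held to the same family-wise level.
#'
#' @param n_segments_worst_case segment count at the narrowest width.
#' @param alpha uncorrected level (default 0.05).
#' @return `alpha / n_segments_worst_case`.
#' @export
bonferroni_family_alpha <- function(n_segments_worst_case, alpha = 0.05) {
  if (n_segments_worst_case < 1) stop("segment count must be >= 1")
  alpha / n_segments_worst_case
}

#' Combine per-cohort segment scans
#'
#' Aligns scans of the same segment lattice from independent cohorts and
#' computes, per segment: the vector of per-cohort metasignificance
#' p-values, the compound-significance replication verdict (all
#' per-cohort p strictly below `per_sample_threshold`), and Fisher's
#' combined probability with its own significance flag at `family_alpha`.
#' Segments untestable in any cohort get NA verdicts.
#'
#' @param scans list of `segwise_scan` data.frames, one per cohort, all
#'   produced on the identical segment lattice.
#' @param per_sample_threshold per-cohort compound criterion (default
#'   0.0264, the printed three-cohort threshold; see
#'   [compound_criterion()], which gives 0.026356 for
#'   `0.05/2729` — the same value at 3 significant figures).
#' @param family_alpha family-wise level for the Fisher channel (default
#'   `1.8e-5`, i.e. 0.05/2729 at 2 significant figures).
#' @return A data.frame of class `segwise_combined`: `chrom`, `start_bp`,
#'   `end_bp`, `width_bp`, one `p_<cohort_id>` column per cohort,
#'   `replicable`, `fisher_chi2`, `fisher_df`, `fisher_p`,
#'   `fisher_significant`.
#' @export
combine_cohorts <- function(scans, per_sample_threshold = 0.0264,
                            family_alpha = 1.8e-5) {
  stopifnot(is.list(scans), length(scans) >= 1)
  key <- function(s) paste(s$chrom, s$start_bp, s$end_bp, s$width_bp)
  k1 <- key(scans[[1]])
  for (i in seq_along(scans)[-1]) {
    ki <- key(scans[[i]])
    if (!identical(k1, ki)) {
      bad <- union(setdiff(k1, ki), setdiff(ki, k1))
      if (length(bad) == 0) bad <- "segment order differs"
      stop("alignment error: cohort ", i,
           " was scanned on a different segment lattice (",
           paste(utils::head(bad, 5), collapse = "; "), ")")
    }
  }
  P <- vapply(scans, function(s) s$metasignificance_p,
              numeric(nrow(scans[[1]])))
  P <- matrix(P, nrow = nrow(scans[[1]]))
  colnames(P) <- paste0("p_", vapply(scans, function(s)
    s$cohort_id[1], ""))
  replicable <- apply(P < per_sample_threshold, 1, function(v) {
    if (anyNA(v)) NA else all(v)
  })
  fish <- apply(P, 1, function(p) {
    if (anyNA(p)) return(c(NA_real_, NA_real_))
    f <- fisher_combined(p)
    c(f$chi2, f$p)
  })
  out <- data.frame(
    chrom = scans[[1]]$chrom, start_bp = scans[[1]]$start_bp,
    end_bp = scans[[1]]$end_bp, width_bp = scans[[1]]$width_bp,
    P,
    replicable = replicable,
    fisher_chi2 = fish[1, ], fisher_df = 2L * length(scans),
    fisher_p = fish[2, ],
    fisher_significant = fish[2, ] < family_alpha
  )
  attr(out, "per_sample_threshold") <- per_sample_threshold
  attr(out, "family_alpha") <- family_alpha
  class(out) <- c("segwise_combined", "data.frame")
  out
}

#' Merge overlapping replicable segments into maximal regions
#'
#' Within one segment width, overlapping (50%-shifted) segments that are
#' all flagged replicable are reported as one region labeled by their
#' union interval — the conventional way one "replicable region" is
#' reported per width.
#'
#' @param combined a `segwise_combined` data.frame.
#' @return data.frame with `chrom`, `start_bp`, `end_bp`, `width_bp`,
#'   `n_segments` (segments merged into the region).
#' @export
merge_replicable_regions <- function(combined) {
  rep_rows <- combined[!is.na(combined$replicable) & combined$replicable, ,
                       drop = FALSE]
  out <- list()
  for (w in unique(rep_rows$width_bp)) {
    for (ch in unique(rep_rows$chrom[rep_rows$width_bp == w])) {
      r <- rep_rows[rep_rows$width_bp == w & rep_rows$chrom == ch, ,
                    drop = FALSE]
      r <- r[order(r$start_bp), , drop = FALSE]
      cur_s <- r$start_bp[1]; cur_e <- r$end_bp[1]; n_in <- 1L
      flush <- function(s, e, n) data.frame(
        chrom = ch, start_bp = s, end_bp = e, width_bp = w, n_segments = n)
      if (nrow(r) > 1) for (i in 2:nrow(r)) {
        if (r$start_bp[i] < cur_e) {       # overlaps current run
          cur_e <- max(cur_e, r$end_bp[i]); n_in <- n_in + 1L
        } else {
          out[[length(out) + 1L]] <- flush(cur_s, cur_e, n_in)
          cur_s <- r$start_bp[i]; cur_e <- r$end_bp[i]; n_in <- 1L
        }
      }
      out[[length(out) + 1L]] <- flush(cur_s, cur_e, n_in)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = integer(), start_bp = numeric(),
                      end_bp = numeric(), width_bp = numeric(),
                      n_segments = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$width_bp, res$chrom, res$start_bp), , drop = FALSE]
}
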
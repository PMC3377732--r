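# Internal helpers.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer (reproducibility is mandatory)")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Accept either a numeric vector or a segwise_adjphen as a phenotype
# override; NULL falls back to the cohort's 0/1 phenotype.
resolve_phenotype <- function(x, phenotype_override) {
  if (is.null(phenotype_override)) return(as.numeric(x$phenotype))
  if (inherits(phenotype_override, "segwise_adjphen")) {
    phenotype_override <- phenotype_override$values
  }
  y <- as.numeric(phenotype_override)
  if (length(y) != n_ind(x)) {
    stop("phenotype override length does not match individual count")
  }
  y
}
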
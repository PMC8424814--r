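# Run code under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-stage seeds fanned out from one pipeline seed.
# Offsets keep the result a valid 32-bit integer.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, split = 211L, fit = 307L,
               counterfactual = 401L, impacts = 503L, compare = 601L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 7L + offsets[[stage]]) %% .Machine$integer.max)
}

fmt_mean_sd <- function(x, digits = 1) {
  sprintf("%s ± %s", format(round(mean(x), digits)),
          format(round(stats::sd(x), digits)))
}

fmt_median_range <- function(x, digits = 1) {
  sprintf("%s (%s–%s)", format(round(stats::median(x), digits)),
          format(round(min(x), digits)), format(round(max(x), digits)))
}
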
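# Internal helpers shared across modules.

# Named offsets for the per-component random substreams of the study
# generator: one user-facing seed expands into independent substreams so
# that changing one design field does not reshuffle unrelated draws.
.substreamOffsets <- c(
  baseline = 1L, sigma = 2L, sets = 3L, planted = 4L, de = 5L,
  effect = 6L, platformFx = 7L, siteFx = 8L, coverage = 9L, noise = 10L
)

# Derived seeds must stay below .Machine$integer.max (2^31 - 1).
.substreamSeed <- function(seed, component) {
  off <- .substreamOffsets[[component]]
  base <- abs(as.integer(seed)) %% 2147480L
  base * 1000L + off
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.rowVars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}
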
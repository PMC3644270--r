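# Independent oracles and small fixtures used across the test files.
# These deliberately re-derive results by the most transparent route
# available (element-wise loops, direct formulas) so they stay independent
# of the package's implementations.

# Brute-force weighted KS running sum: walk the list one gene at a time.
bruteRunningSum <- function(scores, isHit, weightExponent) {
  N <- length(scores)
  k <- sum(isHit)
  w <- abs(scores[isHit])^weightExponent
  if (sum(w) == 0) w <- rep(1, k)
  rs <- numeric(N)
  acc <- 0
  hi <- 0
  for (j in seq_len(N)) {
    if (isHit[j]) {
      hi <- hi + 1
      acc <- acc + w[hi] / sum(w)
    } else {
      acc <- acc - 1 / (N - k)
    }
    rs[j] <- acc
  }
  mx <- max(rs)
  mn <- min(rs)
  # same stable tie rule as the package: positive extremum unless the
  # negative is larger beyond floating-point noise
  list(runningSum = rs, es = if (mx + mn >= -1e-12) mx else mn)
}

# Step-up BH computed literally from its definition.
manualBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- seq(i, m)
    q[ord[i]] <- min(1, min(p[ord[js]] * m / js))
  }
  q
}

# Negative log-likelihood of the two-parameter logistic model, for use
# with a generic optimizer as an independent maximum-likelihood check.
logisticNegLogLik <- function(par, y, x) {
  eta <- par[1] + par[2] * x
  -sum(y * eta - log1p(exp(eta)))
}

# Top-i overlap computed by direct set intersection.
bruteTopOverlap <- function(a, b, i) {
  length(intersect(a[seq_len(i)], b[seq_len(i)]))
}

# A tiny deterministic statistics table for DEG-selection tests.
toyStats <- function() {
  data.frame(
    gene = c("g1", "g2", "g3"),
    n_A = 5L, n_B = 5L,
    t_stat = c(5, 2.5, 1.2),
    t_p = c(0.001, 0.02, 0.2),
    log2fc = c(1.5, 0.5, 3.0),
    snr = c(2, 1, 0.5),
    sam_d = c(4.5, 2.2, 1.1),
    sam_p = c(1 / 252, 10 / 252, 60 / 252),
    stringsAsFactors = FALSE
  )
}

# A small two-condition study with a fixed seed, shared by io/deg tests.
toyStudy <- function(nGenes = 40, reps = 5, seed = 42) {
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(nGenes))
  samples <- paste0("P_1_", rep(c("A", "B"), each = reps), "_",
                    rep(seq_len(reps), 2))
  vals <- matrix(rnorm(nGenes * 2 * reps, 8, 0.5), nGenes, 2 * reps,
                 dimnames = list(genes, samples))
  des <- data.frame(sample_id = samples, platform = "P", site = "1",
                    condition = rep(c("A", "B"), each = reps),
                    replicate = rep(seq_len(reps), 2),
                    stringsAsFactors = FALSE)
  ExpressionStudy(vals, des)
}
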
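# shared fixtures: built in code, small enough for fast unit tests

small_design <- function() stage_design(11, 3)

# feature table with given per-stage relative means and multiplicative noise
toy_table <- function(means_list, layer = "metabolome", noise = 0,
                      seed = 1, design = small_design(), class_of = NULL) {
  set.seed(seed)
  vals <- t(vapply(means_list, function(m) {
    rep(m, each = design$replicates) *
      exp(stats::rnorm(length(m) * design$replicates, 0, noise))
  }, numeric(length(design$stages) * design$replicates)))
  rownames(vals) <- names(means_list)
  colnames(vals) <- design$sample_ids
  feature_table(vals, layer, design, class_of = class_of)
}

# site table for one or more samples from a position/level specification
toy_sites <- function(pos0, meth, unmeth, context = "CHH", strand = "+",
                      stage = "S1", rep = 1L, chrom = "ChrSim") {
  data.table::data.table(chrom = chrom, pos0 = as.integer(pos0),
                         strand = strand, context = context,
                         meth = as.integer(meth),
                         unmeth = as.integer(unmeth),
                         stage = stage, rep = as.integer(rep))
}

# small but complete synthetic dataset reused across test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_multiomics(simulation_config(
        seed = 101, n_metabolites = 80, n_genes = 400, n_proteins = 160,
        n_planted_edges = 40, n_planted_dmrs = 30))
    cache
  }
})

# brute-force BH step-up oracle (independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(ps[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# two-pass Pearson oracle with explicit sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# Fisher two-sided p oracle by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}
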
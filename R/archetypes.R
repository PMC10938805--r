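#' Metabolite trend archetypes I-VIII
#'
#' Eight archetypal stage-series shapes on the z scale, one per trend
#' cluster of the developmental series:
#' \itemize{
#'   \item I, II, IV: monotone-decreasing variants (high at early stages) —
#'     linear decline, fast early decay, and a late sigmoid drop;
#'   \item VII: peaked at stage 7; VIII: broad peak at stage 6;
#'   \item III, V, VI: increasing variants (high at the final two stages) —
#'     linear rise, late exponential rise, and a late sigmoid rise.
#' }
#' Each archetype is z-standardized (mean 0, sample sd 1) across stages.
#'
#' @param n_stages Number of stages (>= 3; default 11).
#' @return Numeric matrix 8 x `n_stages`, rownames `I`..`VIII`.
#' @export
make_archetypes <- function(n_stages = 11L) {
  n_stages <- as.integer(n_stages)
  if (is.na(n_stages) || n_stages < 3L)
    stop("n_stages must be at least 3")
  t <- seq_len(n_stages)
  n <- n_stages
  # peak positions scale with the series so shapes stay meaningful off 11
  p7 <- round(7 * n / 11); p6 <- round(6 * n / 11)
  shapes <- rbind(
    I    = -t,
    II   = exp(-0.45 * (t - 1)),
    III  = t,
    IV   = 1 / (1 + exp(3 * (t - 0.7 * n))),
    V    = exp(0.45 * (t - n)),
    VI   = 1 / (1 + exp(-3 * (t - 0.5 * n))),
    VII  = exp(-0.5 * ((t - p7) / 1.3)^2),
    VIII = exp(-0.5 * ((t - p6) / 2.2)^2)
  )
  z <- t(apply(shapes, 1, function(x) (x - mean(x)) / stats::sd(x)))
  colnames(z) <- paste0("S", t)
  z
}

#' Ordered archetype labels
#' @return Character vector `c("I", ..., "VIII")`.
#' @export
archetype_labels <- function() c("I", "II", "III", "IV", "V", "VI", "VII",
                                 "VIII")
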
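# Independent oracles used across the suite. These deliberately avoid
# the package's root-finding path: the coexistence state is located by
# a dense-grid scan of the nullcline residual with local linear
# interpolation, refined by zooming the grid.

# Medusa-nullcline M(P), written out independently of the package.
oracle_medusa_nullcline <- function(rp, P) {
  (-rp$d + sqrt(rp$d^2 + 4 * rp$b2 * rp$c * P)) / (2 * rp$b2)
}

# Dense-grid intersection of the two nullclines on (0, l].
oracle_estar <- function(rp, n = 4000L, zooms = 4L) {
  l <- (abs(rp$a) * rp$d + rp$b * rp$c) / (rp$b1 * rp$d)
  g <- function(P) rp$a * P + rp$b * oracle_medusa_nullcline(rp, P) -
    rp$b1 * P^2
  lo <- l * 1e-12
  hi <- l * (1 + 1e-9)
  for (z in seq_len(zooms)) {
    P <- seq(lo, hi, length.out = n)
    s <- g(P)
    idx <- which(s[-n] > 0 & s[-1] <= 0)
    if (length(idx) == 0L) return(NULL)
    i <- idx[1]
    lo <- P[i]
    hi <- P[i + 1]
  }
  # linear interpolation across the final bracket
  glo <- g(lo); ghi <- g(hi)
  Pstar <- lo + (hi - lo) * glo / (glo - ghi)
  c(P = Pstar, M = oracle_medusa_nullcline(rp, Pstar))
}

# Random valid reduced parameter sets; optionally conditioned on a
# regime (draws near the saddle-node threshold are rejected so that
# finite-horizon convergence surrogates are well conditioned).
random_reduced_params <- function(regime = NULL, min_disc = 1e-3) {
  repeat {
    rp <- reduced_params(
      a = stats::runif(1, -0.15, 0.15),
      b = stats::runif(1, 0, 3),
      c = stats::runif(1, 0, 0.2),
      d = stats::runif(1, 0.004, 0.5),
      b1 = 10^stats::runif(1, -4, -1),
      b2 = 10^stats::runif(1, -4, -1))
    if (is.null(regime)) return(rp)
    disc <- rp$a * rp$d + rp$b * rp$c
    got <- if (disc < -min_disc) "GLOBAL_EXTINCTION"
    else if (disc > min_disc && rp$c > 1e-6) "COEXISTENCE_GAS"
    else next
    if (got == regime) return(rp)
  }
}

# Uniform random state strictly inside the invariant box.
random_state_in_omega <- function(rp) {
  reg <- invariant_region(rp)
  c(P = stats::runif(1, 1e-6 * reg$l, (1 - 1e-6) * reg$l),
    M = stats::runif(1, 1e-6 * reg$M_bound, (1 - 1e-6) * reg$M_bound))
}
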
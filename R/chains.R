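# Analytic solution of a linear decay chain (Bateman problem) by partial
# fractions with multiplicity, so nearly degenerate rates are handled by the
# exact confluent (t^m exp) limit instead of diverging amplitudes.
#
# For a chain x_1 -> x_2 -> ... -> x_n with decay rates lambda_1..lambda_n
# and x_1(0) = 1, the occupancy of the last state has Laplace transform
#   X_n(s) = prod_{l<n} lambda_l / prod_l (s + lambda_l),
# i.e. a sum over pole groups g (rate mu_g, multiplicity r_g) of terms
# c_{g,m} t^m exp(-mu_g t), m = 0..r_g-1. A trailing rate of 0 turns the
# last state into the absorbing sink (time-integral of the feed).

CHAIN_DEGENERACY_RTOL <- 1e-9

# Group rates that agree to relative CHAIN_DEGENERACY_RTOL.
# Returns list(mu = group rates, r = multiplicities, pref = prod of feed rates).
chain_poles <- function(rates) {
  n <- length(rates)
  pref <- if (n > 1) prod(rates[-n]) else 1
  ord <- order(rates)
  mu <- numeric(0)
  r <- integer(0)
  members <- list()
  for (lam in rates[ord]) {
    g <- length(mu)
    if (g > 0 && (lam - mu[g]) <= CHAIN_DEGENERACY_RTOL * max(lam, mu[g])) {
      members[[g]] <- c(members[[g]], lam)
      mu[g] <- mean(members[[g]])
      r[g] <- r[g] + 1L
    } else {
      members[[g + 1L]] <- lam
      mu <- c(mu, lam)
      r <- c(r, 1L)
    }
  }
  list(mu = mu, r = r, pref = pref)
}

# Partial-fraction coefficients: for each group g return A_{g,m}, m = 1..r_g,
# with 1/prod_g (s+mu_g)^{r_g} = sum_g sum_m A_{g,m}/(s+mu_g)^m.
# A_{g,m} = phi_g^{(r_g - m)}(-mu_g) / (r_g - m)! with
# phi_g(s) = prod_{h != g} (s+mu_h)^{-r_h}; derivatives of phi via the
# log-derivative recursion (derivatives of log phi_g at -mu_g are
# d_j = (-1)^j (j-1)! sum_{h != g} r_h / (mu_h - mu_g)^j).
chain_pf_coefs <- function(mu, r) {
  ng <- length(mu)
  lapply(seq_len(ng), function(g) {
    rg <- r[g]
    others <- setdiff(seq_len(ng), g)
    phi0 <- if (length(others)) prod((mu[others] - mu[g])^(-r[others])) else 1
    if (rg == 1L) return(phi0)
    maxd <- rg - 1L
    d <- vapply(seq_len(maxd), function(j) {
      (-1)^j * factorial(j - 1) * sum(r[others] / (mu[others] - mu[g])^j)
    }, numeric(1))
    phi <- numeric(maxd + 1L)   # phi^(0..maxd)
    phi[1L] <- phi0
    for (m in seq_len(maxd)) {
      js <- seq_len(m)
      phi[m + 1L] <- sum(choose(m - 1, js - 1) * d[js] * phi[m - js + 1L])
    }
    # A_{g,m} for m = 1..rg uses phi^{(rg-m)} / (rg-m)!
    vapply(seq_len(rg), function(m) {
      phi[rg - m + 1L] / factorial(rg - m)
    }, numeric(1))
  })
}

# Occupancy of the last state of the chain on `times`. If sigma is NULL the
# bare causal solution is returned; otherwise each t^m exp(-mu t) H(t) term
# is replaced by its closed-form convolution with a unit-area Gaussian
# (width sigma, centre t0).
chain_occupancy <- function(rates, times, sigma = NULL, t0 = 0) {
  if (any(rates < 0) || any(!is.finite(rates))) {
    abort("chain rates must be finite and >= 0 (Inf tau maps to rate 0).")
  }
  p <- chain_poles(rates)
  if (p$pref == 0) return(numeric(length(times)))
  A <- chain_pf_coefs(p$mu, p$r)
  out <- numeric(length(times))
  for (g in seq_along(p$mu)) {
    rg <- p$r[g]
    # inverse Laplace of A_m/(s+mu)^m -> A_m t^{m-1} e^{-mu t}/(m-1)!
    cf <- A[[g]] / factorial(seq_len(rg) - 1L)
    basis <- if (is.null(sigma)) {
      T_ <- times - t0
      pos <- T_ >= 0
      e <- ifelse(pos, exp(-p$mu[g] * pmax(T_, 0)), 0)
      vapply(seq_len(rg) - 1L, function(m) T_^m * e, numeric(length(times)))
    } else {
      emg_moments(times, p$mu[g], sigma, t0, order = rg - 1L)
    }
    out <- out + drop(basis %*% cf)
  }
  p$pref * out
}
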
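# Internal numerical helpers.

# Scaled complementary error function, stable for large positive arguments.
# pracma::erfcx evaluates exp(x^2)*erfc(x) directly and returns NaN once
# exp(x^2) overflows (x > ~26.6); beyond that the asymptotic expansion
# erfcx(x) ~ 1/(x*sqrt(pi)) * sum_n (-1)^n (2n-1)!!/(2x^2)^n converges to
# machine precision in a few terms.
erfcx_stable <- function(x) {
  out <- numeric(length(x))
  big <- x >= 25
  if (any(!big)) out[!big] <- pracma::erfcx(x[!big])
  if (any(big)) {
    xb <- x[big]
    inv2x2 <- 1 / (2 * xb^2)
    # (-1)^n (2n-1)!! / (2x^2)^n, n = 0..4; next term < 1e-17 for x >= 25
    s <- 1 - inv2x2 * (1 - 3 * inv2x2 * (1 - 5 * inv2x2 * (1 - 7 * inv2x2)))
    out[big] <- s / (xb * sqrt(pi))
  }
  out
}

stopifnot_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (finite && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

is_fraction <- function(q) is.numeric(q) && length(q) == 1L && !is.na(q) &&
  q >= 0 && q <= 1

# tau may be Inf (explicit non-decaying sentinel); rate is then 0
tau_to_rate <- function(tau) if (is.infinite(tau)) 0 else 1 / tau
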
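#' Gaussian instrument response function
#'
#' The effective temporal resolution of a pump-probe experiment is modelled as
#' a single Gaussian of standard deviation `sigma` centred at the zero-delay
#' offset `t0`, shared by all probe channels. Independent broadening
#' contributions (pulse durations, group-velocity mismatch in the sample,
#' arrival-time jitter) may be attached as `components` for quadrature
#' book-keeping; they are not used in any kinetic computation.
#'
#' @param sigma Gaussian standard deviation in ps. Must be > 0.
#' @param t0 Zero-delay offset in ps (default 0).
#' @param components Optional named or unnamed numeric vector of individual
#'   broadening widths (ps) whose quadrature sum is expected to be near
#'   `sigma`.
#' @return An object of class `irf_model`.
#' @seealso [irf_quadrature_width()], [exp_gauss()]
#' @examples
#' irf_model(0.087)
#' @export
irf_model <- function(sigma, t0 = 0, components = NULL) {
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  stopifnot_scalar(t0, "t0")
  if (!is.null(components)) {
    if (!is.numeric(components) || length(components) == 0 ||
        any(!is.finite(components)) || any(components <= 0)) {
      abort("`components` must be positive finite widths (ps).")
    }
  }
  structure(list(sigma = sigma, t0 = t0, components = components),
            class = "irf_model")
}

#' @export
print.irf_model <- function(x, ...) {
  cat(sprintf("Gaussian IRF: sigma = %g ps (FWHM %.3g ps), t0 = %g ps\n",
              x$sigma, 2 * sqrt(2 * log(2)) * x$sigma, x$t0))
  if (!is.null(x$components)) {
    cat(sprintf("  quadrature budget: %s -> %g ps\n",
                paste(signif(x$components, 3), collapse = " + "),
                signif(irf_quadrature_width(x$components), 3)))
  }
  invisible(x)
}

#' Quadrature sum of independent IRF broadening contributions
#'
#' Independent Gaussian broadening mechanisms add in quadrature: the total
#' width is the square root of the sum of squared component widths. Typical
#' contributions are the X-ray and laser pulse durations, group-velocity
#' mismatch over the sample, and pump-probe timing jitter.
#'
#' @param components Numeric vector of component widths (same unit, > 0).
#' @return Total width, same unit as the inputs.
#' @examples
#' # 20 fs x-ray, 45 fs laser, 65 fs velocity mismatch, 30 fs jitter
#' irf_quadrature_width(c(0.020, 0.045, 0.065, 0.030)) # ~0.087 ps
#' @export
irf_quadrature_width <- function(components) {
  if (!is.numeric(components) || length(components) == 0) {
    abort("`components` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(components)) || any(components <= 0)) {
    abort("all IRF components must be positive and finite.")
  }
  sqrt(sum(components^2))
}

#' Exponential decay convolved with a Gaussian IRF
#'
#' Closed form of a unit-amplitude causal exponential `exp(-(t-t0)/tau)`
#' convolved with a unit-area Gaussian of width `sigma` (the exponentially
#' modified Gaussian):
#' \deqn{\frac12 \exp\!\Big(\frac{\sigma^2}{2\tau^2}-\frac{t-t_0}{\tau}\Big)
#'   \mathrm{erfc}\!\Big(\frac{\sigma/\tau-(t-t_0)/\sigma}{\sqrt2}\Big)}
#' evaluated through the scaled complementary error function so it stays
#' finite for any `sigma/tau` ratio. `tau = Inf` gives the Gaussian
#' cumulative step (the convolved Heaviside), `sigma = 0` the bare
#' exponential times the step function.
#'
#' @param t Numeric vector of times (ps).
#' @param tau Decay time constant (ps); `Inf` for a non-decaying step.
#' @param sigma Gaussian IRF standard deviation (ps), >= 0.
#' @param t0 Zero-time offset (ps).
#' @return Numeric vector, same length as `t`.
#' @examples
#' exp_gauss(seq(-0.5, 2, 0.25), tau = 0.41, sigma = 0.087)
#' @export
exp_gauss <- function(t, tau, sigma, t0 = 0) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      (!is.infinite(tau) && tau <= 0)) {
    abort("`tau` must be a positive time constant or Inf.")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    abort("`sigma` must be >= 0.")
  }
  k <- tau_to_rate(tau)
  drop(emg_moments(t, k, sigma, t0, order = 0))
}

# Convolutions g_m(t) of t'^m * exp(-k t') * H(t') with a unit-area Gaussian
# of width sigma centred at t0, for m = 0..order; returned as a length(t) x
# (order+1) matrix. Needed for confluent (repeated-rate) cascade terms.
#
# With T = t - t0, E(k) = g_0 obeys dE/dk = (sigma^2 k - T) E - G where
# G = sigma/sqrt(2*pi) * exp(-T^2/(2 sigma^2)) is k-independent, and
# E^(m+1) = m sigma^2 E^(m-1) + (sigma^2 k - T) E^(m), g_m = (-1)^m E^(m).
emg_moments <- function(t, k, sigma, t0, order = 0) {
  T_ <- t - t0
  out <- matrix(0, length(t), order + 1L)
  if (sigma == 0) {
    pos <- T_ >= 0
    e <- numeric(length(t))
    e[pos] <- exp(-k * T_[pos])
    for (m in 0:order) out[, m + 1L] <- T_^m * e * pos
    return(out)
  }
  z <- sigma * k - T_ / sigma
  E <- numeric(length(t))
  neg <- z <= 0
  if (any(neg)) {
    u <- sigma^2 * k^2 / 2 - k * T_[neg]   # <= 0 on this branch
    E[neg] <- 0.5 * exp(u) * pracma::erfc(z[neg] / sqrt(2))
  }
  if (any(!neg)) {
    E[!neg] <- 0.5 * erfcx_stable(z[!neg] / sqrt(2)) *
      exp(-T_[!neg]^2 / (2 * sigma^2))
  }
  out[, 1L] <- E
  if (order >= 1) {
    G <- sigma / sqrt(2 * pi) * exp(-T_^2 / (2 * sigma^2))
    a <- sigma^2 * k - T_
    Eprev <- E                      # E^(0)
    Ecur <- a * E - G               # E^(1)
    out[, 2L] <- -Ecur
    if (order >= 2) {
      for (m in 1:(order - 1)) {
        Enext <- m * sigma^2 * Eprev + a * Ecur
        out[, m + 2L] <- (-1)^(m + 1) * Enext
        Eprev <- Ecur
        Ecur <- Enext
      }
    }
  }
  out
}
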
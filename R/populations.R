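# Species populations of the branching recombination scheme.
#
# Each sub-ensemble (i = thiyl recombination channel, j = hot-parent fate)
# is a linear cascade N1 -> N2i -> N3j -> (N4j ->) sink fed at full rate;
# the branching yields enter only the weighted sums over sub-ensembles.

# rates extracted once per evaluation
.kp_rates <- function(kp) {
  list(
    k1 = tau_to_rate(kp$tau1),
    k2 = c(tau_to_rate(kp$tau21), tau_to_rate(kp$tau22), tau_to_rate(kp$tau23)),
    k31 = tau_to_rate(kp$tau31),
    k32 = tau_to_rate(kp$tau32),
    k4 = c(tau_to_rate(kp$tau41), tau_to_rate(kp$tau42))
  )
}

# Core evaluation: matrix with columns N1, N2, N3, N4, N0, Nexc on `times`.
# sigma = NULL -> IRF-free causal solution; otherwise Gaussian-convolved.
.solve_pop_core <- function(kp, times, sigma = NULL, t0 = 0) {
  r <- .kp_rates(kp)
  q2 <- c(kp$q21, kp$q22, kp$q23)
  q3 <- c(kp$q31, kp$q32)
  q4 <- c(kp$q41, kp$q42)
  k3 <- c(r$k31, r$k32)

  occ <- function(rates) chain_occupancy(rates, times, sigma, t0)

  N1 <- occ(r$k1)
  Nexc <- occ(0)
  N2 <- numeric(length(times))
  N3 <- numeric(length(times))
  N4 <- numeric(length(times))
  N0 <- numeric(length(times))

  for (i in 1:3) {
    if (q2[i] == 0) next
    N2 <- N2 + q2[i] * occ(c(r$k1, r$k2[i]))
    if (r$k2[i] == 0) next  # nothing flows past a frozen thiyl sub-ensemble
    for (j in 1:2) {
      if (q3[j] > 0) {
        N3 <- N3 + q3[j] * q2[i] * occ(c(r$k1, r$k2[i], k3[j]))
      }
    }
    # ground-state recovery via vibrational relaxation
    if (kp$q31 > 0) {
      N0 <- N0 + kp$q31 * q2[i] * occ(c(r$k1, r$k2[i], r$k31, 0))
    }
    # perthiyl branch: fed through the C-S cleavage channel (rate k32)
    if (kp$q32 > 0 && r$k32 > 0) {
      for (j in 1:2) {
        if (q4[j] == 0) next
        N4 <- N4 + q4[j] * kp$q32 * q2[i] * occ(c(r$k1, r$k2[i], r$k32, r$k4[j]))
        N0 <- N0 + q4[j] * kp$q32 * q2[i] * occ(c(r$k1, r$k2[i], r$k32, r$k4[j], 0))
      }
    }
  }
  cbind(N1 = N1, N2 = N2, N3 = N3, N4 = N4, N0 = N0, Nexc = Nexc)
}

#' Solve the branching rate-equation system analytically
#'
#' Evaluates all species populations as weighted sums of analytic cascade
#' (Bateman) solutions: the excited parent N1, thiyl radicals N2, the
#' vibrationally excited recombined parent N3, perthiyl radicals N4 and the
#' recovered ground state N0, per unit initial excitation. With an
#' [irf_model] every exponential term is replaced by its closed-form
#' convolution with the Gaussian instrument response, which is what a
#' pump-probe experiment observes. Cascade rates that agree to a relative
#' 1e-9 are treated as exactly degenerate and solved with the confluent
#' `t^m exp` limit, so near-coincident time constants never produce
#' catastrophic cancellation.
#'
#' @param params A [kinetic_parameters] object.
#' @param times Sorted numeric vector of delays (ps).
#' @param irf Optional [irf_model]. `NULL` gives the bare causal solution
#'   with time zero at `t = 0`.
#' @return A tibble with columns `time`, `N1`, `N2`, `N3`, `N4`, `N0`
#'   (class `population_trajectory`).
#' @seealso [ode_populations()] for the numerical-integration cross-check,
#'   [recombined_fraction()], [asymptotic_recovery()]
#' @examples
#' cp <- cystine_parameters()
#' solve_populations(cp$params, c(0.1, 1, 10, 100, 1000))
#' @export
solve_populations <- function(params, times, irf = NULL) {
  if (!inherits(params, "kinetic_parameters")) {
    abort("`params` must be a `kinetic_parameters` object.")
  }
  if (!is.numeric(times) || is.unsorted(times)) {
    abort("`times` must be a sorted numeric vector (ps).")
  }
  sigma <- if (is.null(irf)) NULL else irf$sigma
  t0 <- if (is.null(irf)) 0 else irf$t0
  m <- .solve_pop_core(params, times, sigma, t0)
  out <- tibble(time = times,
                N1 = unname(m[, "N1"]), N2 = unname(m[, "N2"]),
                N3 = unname(m[, "N3"]), N4 = unname(m[, "N4"]),
                N0 = unname(m[, "N0"]))
  class(out) <- c("population_trajectory", class(out))
  out
}

#' Integrate the rate equations numerically
#'
#' Direct stiff numerical integration (deSolve, `lsoda`) of the full
#' sub-ensemble system, aggregated with the branching yields exactly as in
#' [solve_populations()]. This is the verification twin of the analytic
#' solver: slower, but independent of the partial-fraction algebra. Used by
#' the test-suite; exported because an independent cross-check is useful to
#' have at hand.
#'
#' @inheritParams solve_populations
#' @param atol,rtol Integration tolerances (defaults 1e-10).
#' @return A tibble like [solve_populations()] (IRF-free).
#' @export
ode_populations <- function(params, times, atol = 1e-10, rtol = 1e-10) {
  if (!inherits(params, "kinetic_parameters")) {
    abort("`params` must be a `kinetic_parameters` object.")
  }
  r <- .kp_rates(params)
  q2 <- c(params$q21, params$q22, params$q23)
  q3 <- c(params$q31, params$q32)
  q4 <- c(params$q41, params$q42)
  k3 <- c(r$k31, r$k32)

  # state: N1, N2i (3), N3ji (2x3), N4ji (2x3), N031i (3), N04ji (2x3)
  i3 <- function(j, i) 4L + (i - 1L) * 2L + j
  i4 <- function(j, i) 10L + (i - 1L) * 2L + j
  i031 <- function(i) 16L + i
  i04 <- function(j, i) 19L + (i - 1L) * 2L + j

  deriv <- function(t, y, parms) {
    dy <- numeric(25L)
    dy[1] <- -r$k1 * y[1]
    for (i in 1:3) {
      dy[1L + i] <- r$k1 * y[1] - r$k2[i] * y[1L + i]
      for (j in 1:2) {
        dy[i3(j, i)] <- r$k2[i] * y[1L + i] - k3[j] * y[i3(j, i)]
        dy[i4(j, i)] <- r$k32 * y[i3(2L, i)] - r$k4[j] * y[i4(j, i)]
        dy[i04(j, i)] <- r$k4[j] * y[i4(j, i)]
      }
      dy[i031(i)] <- r$k31 * y[i3(1L, i)]
    }
    list(dy)
  }

  tpos <- sort(unique(c(0, times[times > 0])))
  y0 <- c(1, numeric(24L))
  sol <- tryCatch(
    deSolve::lsoda(y0, tpos, deriv, parms = NULL, atol = atol, rtol = rtol),
    warning = function(w) abort(sprintf(
      "ODE integration failed for tau1=%g, tau21=%g, tau22=%g, tau23=%g: %s",
      params$tau1, params$tau21, params$tau22, params$tau23, conditionMessage(w)))
  )
  y <- sol[, -1, drop = FALSE]

  agg <- function(row) {
    N2 <- sum(q2 * row[2:4])
    N3 <- sum(vapply(1:2, function(j)
      q3[j] * sum(q2 * vapply(1:3, function(i) row[i3(j, i)], 0)), 0))
    N4 <- sum(vapply(1:2, function(j)
      q4[j] * params$q32 * sum(q2 * vapply(1:3, function(i) row[i4(j, i)], 0)), 0))
    N0 <- params$q31 * sum(q2 * vapply(1:3, function(i) row[i031(i)], 0)) +
      sum(vapply(1:2, function(j)
        q4[j] * params$q32 * sum(q2 * vapply(1:3, function(i) row[i04(j, i)], 0)), 0))
    c(row[1], N2, N3, N4, N0)
  }
  aggmat <- t(apply(y, 1, agg))

  out <- matrix(0, length(times), 5L)
  pos <- times > 0
  idx <- match(times[pos], tpos)
  out[pos, ] <- aggmat[idx, , drop = FALSE]
  out[times == 0, 1] <- 1
  tibble(time = times, N1 = out[, 1], N2 = out[, 2], N3 = out[, 3],
         N4 = out[, 4], N0 = out[, 5])
}

#' Fraction of formed thiyl radicals that have recombined by time t
#'
#' All excited molecules pass through the thiyl state, so the fraction of
#' the (eventually formed) thiyl population that has left it by delay `t`
#' is `1 - N1(t) - N2(t)`, evaluated IRF-free. It is 0 at `t = 0` and rises
#' towards `q21 + q22` (the two recombining sub-ensembles) once formation
#' and both finite recombination channels are complete.
#'
#' @param params A [kinetic_parameters] object.
#' @param t Delays (ps), >= 0; vectorized.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' recombined_fraction(cystine_parameters()$params, 20) # about 0.85
#' @export
recombined_fraction <- function(params, t) {
  if (!inherits(params, "kinetic_parameters")) {
    abort("`params` must be a `kinetic_parameters` object.")
  }
  if (any(t < 0)) abort("`t` must be >= 0.")
  ord <- order(t)
  m <- .solve_pop_core(params, t[ord], sigma = NULL, t0 = 0)
  out <- unname(1 - m[, "N1"] - m[, "N2"])
  out[order(ord)]
}

#' Asymptotic ground-state recovery
#'
#' Closed-form `N0(Inf)`: the fraction of photoexcited molecules that
#' eventually return to the ground-state parent. Only thiyl sub-ensembles
#' with finite recombination times feed the recovery, which then splits
#' between direct vibrational relaxation (`q31`) and the perthiyl detour
#' (`q32 * q41`, counting only perthiyl branches with finite
#' recombination times).
#'
#' @param params A [kinetic_parameters] object.
#' @return A single fraction.
#' @examples
#' asymptotic_recovery(cystine_parameters()$params) # about 0.69
#' @export
asymptotic_recovery <- function(params) {
  if (!inherits(params, "kinetic_parameters")) {
    abort("`params` must be a `kinetic_parameters` object.")
  }
  if (is.infinite(params$tau1)) return(0)
  thiyl_feed <- params$q21 * is.finite(params$tau21) +
    params$q22 * is.finite(params$tau22) +
    params$q23 * is.finite(params$tau23)
  perthiyl_back <- params$q41 * is.finite(params$tau41) +
    params$q42 * is.finite(params$tau42)
  relax <- params$q31 * is.finite(params$tau31)
  cleave <- params$q32 * is.finite(params$tau32)
  thiyl_feed * (relax + cleave * perthiyl_back)
}
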
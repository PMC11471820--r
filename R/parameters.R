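#' Kinetic parameters of the branching recombination scheme
#'
#' Parameterizes the sequential branching rate-equation model for disulfide
#' photolysis: the photoexcited parent (population N1) decays with `tau1`
#' into thiyl radical pairs (N2), split into three sub-ensembles with yields
#' `q21`, `q22`, `q23 = 1 - q21 - q22` and recombination time constants
#' `tau21`, `tau22`, `tau23` (the third sub-ensemble is non-decaying within
#' the observation window, `tau23 = Inf`). Recombination passes through a
#' vibrationally excited parent state (N3) that either relaxes to the ground
#' state (yield `q31`, time `tau31`) or undergoes C-S bond cleavage to a
#' perthiyl radical (yield `q32 = 1 - q31`, time `tau32`, population N4).
#' Perthiyl radicals recombine with yield `q41` and time `tau41`; the
#' remainder (`q42 = 1 - q41`, `tau42 = Inf`) persists. `N0` is the
#' recovered ground-state parent.
#'
#' All times are picoseconds; `Inf` is the explicit sentinel for
#' "non-decaying", never a large float. Populations are per unit initial
#' excitation (`N1(0) = 1`).
#'
#' @param tau1 Excited-state decay / thiyl formation time (ps).
#' @param q21,tau21 Yield and time constant of the fast geminate
#'   recombination sub-ensemble.
#' @param q22,tau22 Yield and time constant of the slower (rotational
#'   diffusion limited) recombination sub-ensemble.
#' @param tau23 Time constant of the cage-escape sub-ensemble
#'   (yield `1 - q21 - q22`); default `Inf`.
#' @param q31,tau31 Yield and time constant of vibrational relaxation of the
#'   recombined parent back to the ground state.
#' @param tau32 Time constant of C-S cleavage forming the perthiyl radical
#'   (yield `1 - q31`).
#' @param q41,tau41 Yield and time constant of perthiyl recombination.
#' @param tau42 Time constant of the persistent perthiyl fraction
#'   (yield `1 - q41`); default `Inf`.
#' @return An object of class `kinetic_parameters` (a named list with the
#'   derived complements `q23`, `q32`, `q42` filled in).
#' @seealso [cystine_parameters()] for the published optimized values,
#'   [solve_populations()] for the resulting populations.
#' @examples
#' kinetic_parameters(
#'   tau1 = 0.14, q21 = 0.67, tau21 = 0.41, q22 = 0.19, tau22 = 5.66,
#'   q31 = 0.66, tau31 = 0.63, tau32 = 0.45, q41 = 0.42, tau41 = 268
#' )
#' @export
kinetic_parameters <- function(tau1,
                               q21, tau21,
                               q22, tau22,
                               tau23 = Inf,
                               q31, tau31,
                               tau32,
                               q41, tau41,
                               tau42 = Inf) {
  taus <- list(tau1 = tau1, tau21 = tau21, tau22 = tau22, tau23 = tau23,
               tau31 = tau31, tau32 = tau32, tau41 = tau41, tau42 = tau42)
  for (nm in names(taus)) {
    x <- taus[[nm]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (!is.infinite(x) && x <= 0)) {
      abort(sprintf("`%s` must be a positive time constant (ps) or Inf.", nm))
    }
  }
  for (nm in c("q21", "q22", "q31", "q41")) {
    if (!is_fraction(get(nm))) {
      abort(sprintf("`%s` must be a fraction in [0, 1].", nm))
    }
  }
  if (q21 + q22 > 1 + 1e-12) {
    abort("thiyl yields must close a simplex: q21 + q22 <= 1.")
  }
  out <- list(
    tau1 = tau1,
    q21 = q21, tau21 = tau21,
    q22 = q22, tau22 = tau22,
    q23 = max(0, 1 - q21 - q22), tau23 = tau23,
    q31 = q31, tau31 = tau31,
    q32 = 1 - q31, tau32 = tau32,
    q41 = q41, tau41 = tau41,
    q42 = 1 - q41, tau42 = tau42
  )
  structure(out, class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Branching recombination scheme (times in ps):\n")
  cat(sprintf("  thiyl formation        tau1  = %g\n", x$tau1))
  cat(sprintf("  thiyl sub-ensembles    q21 = %.3g (tau21 = %g), q22 = %.3g (tau22 = %g), q23 = %.3g (tau23 = %g)\n",
              x$q21, x$tau21, x$q22, x$tau22, x$q23, x$tau23))
  cat(sprintf("  hot-parent branching   q31 = %.3g (tau31 = %g) relax | q32 = %.3g (tau32 = %g) perthiyl\n",
              x$q31, x$tau31, x$q32, x$tau32))
  cat(sprintf("  perthiyl recombination q41 = %.3g (tau41 = %g), persistent q42 = %.3g\n",
              x$q41, x$tau41, x$q42))
  invisible(x)
}

#' @export
as_tibble.kinetic_parameters <- function(x, ...) {
  tibble(parameter = names(unclass(x)), value = unlist(unclass(x), use.names = FALSE))
}

#' Published optimized parameter set for aqueous L-cystine photolysis
#'
#' Returns the globally fitted kinetic parameters and IRF width for
#' 267-nm photolysis of aqueous L-cystine probed at the sulfur K-edge:
#' thiyl formation in 0.14 ps; geminate recombination sub-ensembles
#' 0.67 at 0.41 ps and 0.19 at 5.66 ps with a 0.14 persistent fraction;
#' hot-parent relaxation 0.66 at 0.63 ps versus perthiyl formation 0.34 at
#' 0.45 ps; perthiyl recombination 0.42 at 268 ps; Gaussian IRF width
#' 0.087 ps.
#'
#' @return A list with elements `params` ([kinetic_parameters]) and
#'   `irf` ([irf_model]).
#' @examples
#' cystine_parameters()$params
#' @export
cystine_parameters <- function() {
  list(
    params = kinetic_parameters(
      tau1 = 0.14,
      q21 = 0.67, tau21 = 0.41,
      q22 = 0.19, tau22 = 5.66,
      tau23 = Inf,
      q31 = 0.66, tau31 = 0.63,
      tau32 = 0.45,
      q41 = 0.42, tau41 = 268,
      tau42 = Inf
    ),
    irf = irf_model(sigma = 0.087, t0 = 0,
                    components = c(x_ray = 0.020, laser = 0.045,
                                   gvm = 0.065, jitter = 0.030))
  )
}
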
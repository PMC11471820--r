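# Shared fixtures for the test suite. Everything is generated in code.

# Random valid parameter set: time constants log-uniform on [0.05, 500] ps,
# yield triple uniform on the simplex.
random_params <- function() {
  rtau <- function(n = 1) exp(runif(n, log(0.05), log(500)))
  q <- -log(runif(3)); q <- q / sum(q)   # uniform on the 2-simplex
  kinetic_parameters(
    tau1 = rtau(),
    q21 = q[1], tau21 = rtau(),
    q22 = q[2], tau22 = rtau(),
    tau23 = if (runif(1) < 0.5) Inf else rtau(),
    q31 = runif(1), tau31 = rtau(),
    tau32 = rtau(),
    q41 = runif(1), tau41 = rtau(),
    tau42 = if (runif(1) < 0.5) Inf else rtau()
  )
}

# Small, fast experiment layout used by the fitting tests (49 delay points
# per channel instead of the full 91).
coarse_design <- function(...) {
  experiment_design(dt = 0.25, n_log = 12, ...)
}

published_init <- function() {
  list(tau1 = 0.14, tau21 = 0.41, tau22 = 5.66, tau31 = 0.63, tau32 = 0.45,
       tau41 = 268, q21 = 0.67, q22 = 0.19, q31 = 0.66, q41 = 0.42,
       sigma_irf = 0.087, t0 = 0,
       amp_thiyl = 0.26, amp_perthiyl = 0.18, amp_bleach = 0.20)
}

# One standard noisy coarse-grid fit, computed once and shared by the
# fitting/report tests.
.fixture_env <- new.env()
standard_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    cp <- cystine_parameters()
    tr <- simulate_traces(cp$params, cp$irf, coarse_design(), seed = 101)
    .fixture_env$fit <- global_fit(tr, fit_spec())
    .fixture_env$traces <- tr
  }
  .fixture_env$fit
}
standard_traces <- function() {
  invisible(standard_fit())
  .fixture_env$traces
}
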
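cp <- cystine_parameters()

test_that("populations conserve the initial excitation and stay in [0,1]", {
  set.seed(42)
  times <- c(0, 10^seq(-2, 2.7, length.out = 40))
  for (i in 1:30) {
    p <- random_params()
    tr <- solve_populations(p, times)
    total <- tr$N1 + tr$N2 + tr$N3 + tr$N4 + tr$N0
    expect_lt(max(abs(total - 1)), 1e-9)
    expect_true(all(as.matrix(tr[, -1]) >= -1e-12))
    expect_true(all(as.matrix(tr[, -1]) <= 1 + 1e-9))
  }
})

test_that("N1 is non-increasing, N0 and the recombined fraction non-decreasing", {
  set.seed(7)
  times <- c(0, 10^seq(-2, 2.7, length.out = 60))
  for (i in 1:10) {
    p <- random_params()
    tr <- solve_populations(p, times)
    expect_true(all(diff(tr$N1) <= 1e-12))
    expect_true(all(diff(tr$N0) >= -1e-12))
    expect_true(all(diff(recombined_fraction(p, times)) >= -1e-12))
  }
})

test_that("analytic solver agrees with stiff ODE integration on random schemes", {
  set.seed(123)
  times <- seq(0, 50, length.out = 51)
  worst <- 0
  for (i in 1:100) {
    p <- random_params()
    an <- solve_populations(p, times)
    od <- ode_populations(p, times)
    worst <- max(worst, max(abs(as.matrix(an[, -1]) - as.matrix(od[, -1]))))
  }
  expect_lt(worst, 1e-6)
})

test_that("ODE integrator reproduces the textbook two-step chain", {
  # A -> B -> C with all branching routed through one sub-ensemble
  p <- kinetic_parameters(tau1 = 1, q21 = 1, tau21 = 3, q22 = 0, tau22 = 10,
                          q31 = 1, tau31 = 1e5, tau32 = 1e5, q41 = 0.5,
                          tau41 = 1e5)
  t <- seq(0, 10, 0.5)
  od <- ode_populations(p, t)
  k1 <- 1; k2 <- 1 / 3
  bateman <- k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t))
  expect_equal(od$N2, bateman, tolerance = 1e-7)
  expect_equal(od$N1, exp(-t), tolerance = 1e-8)
})

test_that("zero-rate chains hold their populations", {
  p <- kinetic_parameters(tau1 = Inf, q21 = 0.5, tau21 = 1, q22 = 0.3,
                          tau22 = 2, q31 = 0.5, tau31 = 1, tau32 = 1,
                          q41 = 0.5, tau41 = 1)
  tr <- ode_populations(p, c(0, 1, 10, 100))
  expect_equal(tr$N1, rep(1, 4))
  expect_equal(tr$N2 + tr$N3 + tr$N4 + tr$N0, rep(0, 4))
})

test_that("IRF-convolved populations equal the discrete convolution oracle", {
  # integrate over the causal support only: the IRF-free solution vanishes
  # for t < 0 and trapezoid across its jump at 0 would dominate the error
  fine <- seq(0, 25, by = 0.001)
  free <- solve_populations(cp$params, fine)
  irf <- irf_model(sigma = 0.087, t0 = 0)
  eval_at <- seq(-0.5, 20, by = 0.5)
  conv <- solve_populations(cp$params, eval_at, irf)
  for (sp in c("N1", "N2", "N3", "N4", "N0")) {
    oracle <- vapply(eval_at, function(t) {
      kern <- dnorm(t - fine, 0, irf$sigma)
      pracma::trapz(fine, free[[sp]] * kern)
    }, numeric(1))
    expect_lt(max(abs(conv[[sp]] - oracle)), 1e-5)
  }
})

test_that("solutions are continuous across rate degeneracies", {
  times <- seq(0, 20, 0.25)
  base <- kinetic_parameters(tau1 = 0.5, q21 = 0.6, tau21 = 0.5, q22 = 0.3,
                             tau22 = 5, q31 = 0.7, tau31 = 0.5, tau32 = 0.5,
                             q41 = 0.4, tau41 = 50)
  pert <- base
  pert$tau21 <- base$tau21 * (1 + 1e-10)
  a <- solve_populations(base, times)
  b <- solve_populations(pert, times)
  expect_lt(max(abs(as.matrix(a[, -1]) - as.matrix(b[, -1]))), 1e-6)
  expect_true(all(is.finite(as.matrix(a[, -1]))))
  # exact triple degeneracy also stays finite and matches the ODE oracle
  trip <- kinetic_parameters(tau1 = 1, q21 = 1, tau21 = 1, q22 = 0, tau22 = 2,
                             q31 = 0.5, tau31 = 1, tau32 = 1, q41 = 0.5,
                             tau41 = 1)
  an <- solve_populations(trip, times)
  od <- ode_populations(trip, times)
  expect_lt(max(abs(as.matrix(an[, -1]) - as.matrix(od[, -1]))), 1e-6)
})

test_that("frozen thiyl radicals accumulate and nothing recombines", {
  p <- kinetic_parameters(tau1 = 0.14, q21 = 0.5, tau21 = Inf, q22 = 0.3,
                          tau22 = Inf, tau23 = Inf, q31 = 0.66, tau31 = 0.63,
                          tau32 = 0.45, q41 = 0.42, tau41 = 268)
  tr <- solve_populations(p, c(10, 1000))
  expect_equal(tr$N2[2], 1, tolerance = 1e-9)
  expect_equal(tr$N0, c(0, 0))
  expect_equal(recombined_fraction(p, c(0, 5, 1000)), rep(0, 3),
               tolerance = 1e-9)
  expect_equal(asymptotic_recovery(p), 0)
})

test_that("published parameters give the headline recovery numbers", {
  tr <- solve_populations(cp$params, 1000)
  expect_equal(tr$N0, 0.69, tolerance = 0.01)        # 70% recovered at 1 ns
  rf20 <- recombined_fraction(cp$params, 20)
  expect_gte(rf20, 0.80)                              # >80% within 20 ps
  expect_equal(rf20, cp$params$q21 + cp$params$q22, tolerance = 0.01)
  expect_equal(recombined_fraction(cp$params, 0), 0)
  # closed-form asymptote: (q21+q22) * (q31 + q32*q41)
  expect_equal(asymptotic_recovery(cp$params),
               0.86 * (0.66 + 0.34 * 0.42), tolerance = 1e-12)
})

test_that("asymptotic recovery closed form handles edge topologies", {
  p <- kinetic_parameters(tau1 = 0.2, q21 = 0.6, tau21 = 1, q22 = 0.2,
                          tau22 = 5, q31 = 1, tau31 = 0.5, tau32 = 0.5,
                          q41 = 0.3, tau41 = 10)
  expect_equal(asymptotic_recovery(p), 0.8)          # q21 + q22, q31 = 1
  sink_only <- kinetic_parameters(tau1 = 0.2, q21 = 1, tau21 = Inf, q22 = 0,
                                  tau22 = 1, q31 = 0.5, tau31 = 1,
                                  tau32 = 1, q41 = 0.5, tau41 = 1)
  expect_equal(asymptotic_recovery(sink_only), 0)
  long <- solve_populations(p, 5000)
  expect_equal(long$N0, 0.8, tolerance = 1e-8)
})

test_that("parameter validation rejects invalid schemes", {
  expect_error(kinetic_parameters(tau1 = -1, q21 = 0.5, tau21 = 1, q22 = 0.2,
                                  tau22 = 1, q31 = 0.5, tau31 = 1, tau32 = 1,
                                  q41 = 0.5, tau41 = 1), "positive")
  expect_error(kinetic_parameters(tau1 = 1, q21 = 0.8, tau21 = 1, q22 = 0.4,
                                  tau22 = 1, q31 = 0.5, tau31 = 1, tau32 = 1,
                                  q41 = 0.5, tau41 = 1), "simplex")
  expect_error(kinetic_parameters(tau1 = 1, q21 = 1.2, tau21 = 1, q22 = 0,
                                  tau22 = 1, q31 = 0.5, tau31 = 1, tau32 = 1,
                                  q41 = 0.5, tau41 = 1), "fraction")
})

test_that("published parameter fixture carries the printed values", {
  p <- cp$params
  expect_identical(p$q21, 0.67)
  expect_identical(p$tau22, 5.66)
  expect_equal(p$q23, 0.14, tolerance = 1e-12)    # simplex closure
  expect_identical(p$tau23, Inf)
  expect_identical(cp$irf$sigma, 0.087)
})
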
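cp <- cystine_parameters()

test_that("noise-free traces return the generating parameters", {
  des <- coarse_design(noise_sd = 0)
  tr <- simulate_traces(cp$params, cp$irf, des, seed = 1)
  tr$sigma <- 1e-4   # uniform weights; dA carries no noise
  fit <- global_fit(tr, fit_spec())
  expect_true(fit$converged)
  truth <- c(tau1 = 0.14, tau21 = 0.41, tau22 = 5.66, tau31 = 0.63,
             tau32 = 0.45, tau41 = 268, q21 = 0.67, q22 = 0.19, q31 = 0.66,
             q41 = 0.42, sigma_irf = 0.087,
             amp_thiyl = 0.268, amp_perthiyl = 0.18, amp_bleach = 0.20)
  rel <- abs(fit$estimates[names(truth)] - truth) / truth
  expect_lt(max(rel), 1e-3)
  expect_lt(abs(fit$estimates[["t0"]]), 1e-4)
})

test_that("kinetic estimates are invariant under a common data/σ rescaling", {
  tr <- standard_traces()
  fit1 <- standard_fit()
  tr10 <- tr
  tr10$dA <- 10 * tr$dA
  tr10$sigma <- 10 * tr$sigma
  fit10 <- global_fit(tr10, fit_spec())
  kin <- c("tau1", "tau21", "tau22", "tau31", "tau32", "tau41",
           "q21", "q22", "q31", "q41", "sigma_irf", "t0")
  expect_equal(fit10$estimates[kin], fit1$estimates[kin], tolerance = 1e-4)
  amps <- c("amp_thiyl", "amp_perthiyl", "amp_bleach")
  expect_equal(fit10$estimates[amps], 10 * fit1$estimates[amps],
               tolerance = 1e-4)
  expect_equal(fit10$reduced_chi2, fit1$reduced_chi2, tolerance = 1e-6)
})

test_that("recovered yields always close their simplexes", {
  fit <- standard_fit()
  q <- fit$estimates
  expect_equal(q[["q21"]] + q[["q22"]] + fit$params$q23, 1, tolerance = 1e-12)
  expect_true(all(c(q[["q21"]], q[["q22"]], q[["q31"]], q[["q41"]]) >= 0))
  expect_true(all(c(q[["q21"]], q[["q22"]], q[["q31"]], q[["q41"]]) <= 1))
  expect_equal(fit$params$q32, 1 - q[["q31"]], tolerance = 1e-12)
})

test_that("fitting data simulated at the generating parameters gives chi2_red near 1", {
  fit <- standard_fit()
  expect_gt(fit$reduced_chi2, 0.7)
  expect_lt(fit$reduced_chi2, 1.4)
  expect_true(fit$converged)
})

test_that("standard errors are finite, positive and roughly calibrated", {
  fit <- standard_fit()
  free <- c("tau1", "q21", "sigma_irf", "amp_thiyl")
  expect_true(all(is.finite(fit$se[free])))
  expect_true(all(fit$se[free] > 0))
  # the tau1 estimate should sit within ~3 SE of the generating value
  expect_lt(abs(fit$estimates[["tau1"]] - 0.14), 3 * fit$se[["tau1"]] + 0.02)
})

test_that("the degenerate single-exponential case matches textbook regression", {
  set.seed(77)
  t <- seq(1, 40, length.out = 60)
  tau_true <- 6; A_true <- 0.3
  sig <- 0.005
  y <- A_true * exp(-t / tau_true) + rnorm(length(t), 0, sig)
  tr <- tibble::tibble(probe_energy = 2466.8, delay_ps = t, dA = y,
                       sigma = sig)
  ch <- list(thiyl = channel_model(2466.8, c(N2 = 1), 0.2))
  spec <- fit_spec(
    channels = ch,
    init = list(tau1 = 0.002, q21 = 1, q22 = 0, q31 = 0.5, q41 = 0.5,
                sigma_irf = 0.005, t0 = 0, tau22 = 10, tau31 = 1, tau32 = 1,
                tau41 = 100, tau21 = 5, amp_thiyl = 0.25),
    fixed = c("tau1", "q21", "q22", "q31", "q41", "sigma_irf", "t0",
              "tau22", "tau31", "tau32", "tau41"),
    bounds = list(tau21 = c(0.1, 30), tau1 = c(1e-3, 1),
                  sigma_irf = c(1e-3, 0.5))
  )
  fit <- global_fit(tr, spec)
  ref <- stats::nls(y ~ A * exp(-t / tau), start = list(A = 0.25, tau = 5),
                    weights = rep(1 / sig^2, length(t)))
  expect_equal(fit$estimates[["tau21"]], coef(ref)[["tau"]], tolerance = 1e-3)
  expect_equal(fit$estimates[["amp_thiyl"]], coef(ref)[["A"]], tolerance = 1e-3)
})

test_that("bootstrap intervals are reproducible and collapse without noise", {
  fit <- standard_fit()
  b1 <- bootstrap_uncertainties(fit, n_replicates = 6, seed = 3)
  b2 <- bootstrap_uncertainties(fit, n_replicates = 6, seed = 3)
  expect_identical(b1, b2)
  expect_true(all(b1$upper >= b1$lower))

  # covariance-based and bootstrap scales agree within a factor of ~2
  # for the well-identified parameters
  cmp <- c("tau1", "q21", "q31", "amp_thiyl", "amp_bleach", "sigma_irf")
  ratio <- b1$se_boot[match(cmp, b1$term)] / fit$se[cmp]
  expect_true(all(ratio > 0.3 & ratio < 3))

  des0 <- coarse_design(noise_sd = 0)
  tr0 <- simulate_traces(cp$params, cp$irf, des0, seed = 2)
  tr0$sigma <- 1e-5
  fit0 <- suppressWarnings(global_fit(tr0, fit_spec(init = published_init())))
  b0 <- suppressWarnings(bootstrap_uncertainties(fit0, n_replicates = 4, seed = 4))
  expect_lt(max((b0$upper - b0$lower) / pmax(abs(b0$estimate), 1e-3)), 1e-4)
})

test_that("a single-seed recovery study reports one replicate per parameter", {
  des <- coarse_design()
  rs <- parameter_recovery_study(cp$params, cp$irf, des, fit_spec(),
                                 n_seeds = 1, seed = 42,
                                 intervals = c(tau1 = 0.05, q21 = 0.06))
  expect_equal(rs$n_failed, 0)
  expect_equal(nrow(rs$estimates), sum(fit_spec()$par_table$vary))
  expect_true(all(rs$summary$n == 1))
  expect_true(all(c("bias", "rmse", "coverage") %in% names(rs$summary)))
})

test_that("fit_spec validates its inputs", {
  expect_error(fit_spec(init = list(bogus = 1)), "unknown")
  expect_error(fit_spec(fixed = "bogus"), "unknown")
  expect_error(fit_spec(init = list(tau1 = 99)), "outside bounds")
  expect_error(global_fit(tibble::tibble(x = 1), fit_spec()), "columns")
  tr <- standard_traces()
  bad <- tr
  bad$sigma[1] <- 0
  expect_error(global_fit(bad, fit_spec()), "sigma")
})
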
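test_that("a unit-area Lorentzian peaks at 2/(pi*FWHM)", {
  fwhm <- 0.6
  m <- spectrum_model(spectral_line(2466.9, 1, lorentz_fwhm = fwhm))
  grid <- seq(2460, 2474, 0.001)
  s <- compose_spectrum(m, grid)
  expect_equal(max(s), 2 / (pi * fwhm), tolerance = 1e-6)
  expect_equal(grid[which.max(s)], 2466.9)
})

test_that("vanishing Gaussian width reduces the pseudo-Voigt to a Lorentzian", {
  grid <- seq(2465, 2469, 0.01)
  lor <- compose_spectrum(
    spectrum_model(spectral_line(2467, 1, lorentz_fwhm = 0.6)), grid)
  pv <- compose_spectrum(
    spectrum_model(spectral_line(2467, 1, lorentz_fwhm = 0.6,
                                 gauss_sigma = 1e-9)), grid)
  expect_lt(max(abs(pv - lor)), 1e-6)
})

test_that("exact Voigt matches brute-force convolution; pseudo-Voigt is close", {
  gam <- 0.3; sig <- 0.2
  x <- seq(-3, 3, 0.1)
  oracle <- vapply(x, function(xi) {
    stats::integrate(function(u) gam / pi / (u^2 + gam^2) * dnorm(xi - u, 0, sig),
                     lower = -Inf, upper = Inf, rel.tol = 1e-10)$value
  }, numeric(1))
  exact <- cystinetics:::.voigt_profile(x, 2 * gam, sig, "voigt")
  approx <- cystinetics:::.voigt_profile(x, 2 * gam, sig, "pseudo_voigt")
  expect_lt(max(abs(exact - oracle)), 1e-8)
  expect_lt(max(abs(approx - oracle)) / max(oracle), 0.015)
})

test_that("two parent lines 1.5 eV apart over the edge stay resolvable", {
  lines <- dplyr::bind_rows(
    spectral_line(2471.7, 0.8, lorentz_fwhm = 0.6, gauss_sigma = 0.25),
    spectral_line(2473.2, 0.9, lorentz_fwhm = 0.6, gauss_sigma = 0.25)
  )
  m <- spectrum_model(lines, edge = list(position = 2475, width = 1, height = 1))
  grid <- seq(2468, 2478, 0.01)
  s <- compose_spectrum(m, grid)
  interior <- which(diff(sign(diff(s))) == -2) + 1
  peaks <- grid[interior]
  expect_equal(sum(peaks > 2470 & peaks < 2475), 2)
})

test_that("composed line area equals the sum of amplitudes", {
  # graded grid: dense near the lines, wide wings to capture Lorentzian tails
  lines <- dplyr::bind_rows(
    spectral_line(0, 0.7, lorentz_fwhm = 0.5, gauss_sigma = 0.3),
    spectral_line(1.2, 0.3, lorentz_fwhm = 0.5)
  )
  m <- spectrum_model(lines)
  grid <- sort(unique(c(seq(-4000, 4000, 5), seq(-200, 200, 0.1),
                        seq(-5, 6, 0.01))))
  s <- compose_spectrum(m, grid)
  expect_equal(pracma::trapz(grid, s), 1.0, tolerance = 1e-4)
})

test_that("spectra are equivariant under a common energy shift", {
  lines <- spectral_line(2466.9, 1, lorentz_fwhm = 0.6, gauss_sigma = 0.2)
  grid <- seq(2460, 2474, 0.05)
  base <- compose_spectrum(spectrum_model(lines), grid)
  # +52.09 eV theory-to-experiment offset applied via the shift field
  shifted <- compose_spectrum(
    spectrum_model(dplyr::mutate(lines, center = center - 52.09),
                   energy_shift = 52.09), grid)
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("a parent differenced against itself gives zero", {
  parent <- spectrum_model(
    spectral_line(2472, 1, lorentz_fwhm = 0.6, gauss_sigma = 0.3),
    edge = list(position = 2475, width = 1, height = 1))
  grid <- seq(2465, 2480, 0.05)
  d <- differential_spectrum(parent, list(list(model = parent, population = 0.1)),
                             excitation_fraction = 0.1, grid)
  expect_equal(d, rep(0, length(grid)))
})

test_that("a thiyl-only differential shows product absorption plus bleach", {
  parent <- spectrum_model(
    dplyr::bind_rows(
      spectral_line(2471.7, 0.8, lorentz_fwhm = 0.6, gauss_sigma = 0.25,
                    species = "parent"),
      spectral_line(2473.2, 0.9, lorentz_fwhm = 0.6, gauss_sigma = 0.25,
                    species = "parent")))
  thiyl <- spectrum_model(
    spectral_line(2466.9, 0.9, lorentz_fwhm = 0.6, species = "thiyl"))
  grid <- seq(2464, 2476, 0.02)
  d <- differential_spectrum(parent, list(list(model = thiyl, population = 0.15)),
                             excitation_fraction = 0.15, grid)
  expect_gt(d[which.min(abs(grid - 2466.9))], 0)
  expect_lt(d[which.min(abs(grid - 2472))], 0)
  expect_error(
    differential_spectrum(parent, list(list(model = thiyl, population = 0.5)),
                          excitation_fraction = 0.15, grid),
    "populations")
})

test_that("decomposition round-trips composed spectra exactly without noise", {
  lines <- dplyr::bind_rows(
    spectral_line(2466.9, 0.35, lorentz_fwhm = 0.6, species = "thiyl"),
    spectral_line(2468.2, 0.12, lorentz_fwhm = 0.7, species = "perthiyl"),
    spectral_line(2472.0, -0.4, lorentz_fwhm = 0.6, gauss_sigma = 0.25,
                  species = "bleach")
  )
  m <- spectrum_model(lines)
  grid <- seq(2463, 2476, 0.02)
  obs <- tibble::tibble(energy = grid, dA = compose_spectrum(m, grid))
  template <- spectrum_model(dplyr::mutate(lines, amplitude = 1))
  fit <- decompose_spectrum(obs, template)
  expect_lt(max(abs(fit$coefficients$estimate - lines$amplitude)), 1e-6)
  expect_false(fit$rank_deficient)
  # freeing widths keeps the round trip exact
  fit_w <- decompose_spectrum(obs, template, free_widths = TRUE)
  expect_lt(max(abs(fit_w$lines$amplitude - lines$amplitude)), 1e-4)
  expect_lt(max(abs(fit_w$lines$lorentz_fwhm - lines$lorentz_fwhm)), 1e-4)
})

test_that("amplitude recovery from 1% noise is essentially unbiased", {
  lines <- dplyr::bind_rows(
    spectral_line(2466.9, 0.35, lorentz_fwhm = 0.6),
    spectral_line(2472.0, -0.4, lorentz_fwhm = 0.6, gauss_sigma = 0.25)
  )
  m <- spectrum_model(lines)
  grid <- seq(2463, 2476, 0.02)
  clean <- compose_spectrum(m, grid)
  noise_sd <- 0.01 * max(abs(clean))
  template <- spectrum_model(dplyr::mutate(lines, amplitude = 1))
  set.seed(11)
  recovered <- replicate(20, {
    obs <- tibble::tibble(energy = grid, dA = clean + rnorm(length(grid), 0, noise_sd),
                          sigma = noise_sd)
    decompose_spectrum(obs, template)$coefficients$estimate
  })
  bias <- abs(rowMeans(recovered) - lines$amplitude) / abs(lines$amplitude)
  expect_lt(max(bias), 0.02)
})

test_that("strongly overlapping lines inflate uncertainties and condition number", {
  grid <- seq(2465, 2470, 0.01)
  sep <- function(d) {
    lines <- dplyr::bind_rows(
      spectral_line(2467.0, 0.5, lorentz_fwhm = 0.6),
      spectral_line(2467.0 + d, 0.5, lorentz_fwhm = 0.6)
    )
    m <- spectrum_model(lines)
    obs <- tibble::tibble(energy = grid, dA = compose_spectrum(m, grid),
                          sigma = 0.01)
    decompose_spectrum(obs, spectrum_model(dplyr::mutate(lines, amplitude = 1)))
  }
  far <- sep(2.0)
  near <- sep(0.05)
  expect_gt(near$condition_number, 10 * far$condition_number)
  expect_gt(mean(near$coefficients$std.error), 5 * mean(far$coefficients$std.error))
})

test_that("degenerate spectral inputs are handled explicitly", {
  expect_warning(compose_spectrum(spectrum_model(), seq(0, 1, 0.1)), "empty")
  expect_error(spectral_line(1, 1, lorentz_fwhm = 0, gauss_sigma = 0), "widths")
  expect_error(compose_spectrum(spectrum_model(spectral_line(1, 1, 0.5)),
                                c(2, 1)), "increasing")
  obs <- tibble::tibble(energy = seq(2465, 2470, 0.1), dA = 0)
  tmpl <- spectrum_model(spectral_line(2480, 1, lorentz_fwhm = 0.5))
  expect_error(decompose_spectrum(obs, tmpl), "cover")
})
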
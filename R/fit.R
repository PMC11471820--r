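# Global weighted nonlinear least squares for multi-channel delay scans.
#
# All kinetic parameters, the IRF width and t0 are shared across channels;
# each channel has its own amplitude. Internally the optimizer works on a
# transformed parameter vector: log for time constants and the IRF width
# (strictly positive, spanning decades), stick-breaking logits for the
# three-way thiyl yield simplex (q21, q22, q23), plain logits for q31 and
# q41, linear for t0 and amplitudes. Box bounds are applied on the
# transformed scale, so any optimizer iterate maps to a valid scheme.

.sb_eps <- 1e-12

# parameter table ----------------------------------------------------------

.fit_par_table <- function(channels) {
  amp_names <- paste0("amp_", names(channels))
  amp_init <- vapply(channels, function(ch) ch$amplitude, numeric(1))
  tibble(
    name = c("tau1", "tau21", "tau22", "tau31", "tau32", "tau41",
             "q21", "q22", "q31", "q41", "sigma_irf", "t0", "contam",
             amp_names),
    init = c(0.1, 0.3, 8, 0.5, 0.5, 150,
             0.5, 0.25, 0.5, 0.5, 0.1, 0, 0.08,
             unname(amp_init)),
    lower = c(0.01, 0.05, 1, 0.05, 0.05, 20,
              0, 0, 0, 0, 0.02, -0.5, 0,
              rep(1e-6, length(channels))),
    upper = c(1, 3, 50, 5, 5, 2000,
              1, 1, 1, 1, 0.5, 0.5, 1,
              rep(5, length(channels))),
    vary = c(rep(TRUE, 12), FALSE, rep(TRUE, length(channels))),
    trans = c(rep("log", 6), "sb1", "sb2", "logit", "logit", "log",
              "linear", "logit", rep("linear", length(channels))),
    # amplitudes default to data-driven starts/bounds unless the user
    # overrides them: the data scale is arbitrary (normalization choice)
    auto = c(rep(FALSE, 13), rep(TRUE, length(channels)))
  )
}

#' Specify a global fit
#'
#' Builds the parameter table (initial values, bounds, free/fixed flags)
#' and optimizer settings for [global_fit()]. Defaults: all kinetic time
#' constants, the three-way thiyl yield simplex, the branching yields, the
#' IRF width, t0 and the per-channel amplitudes are free; the 8 % spectral
#' contamination (`contam`) is fixed, since it is known from the static
#' lineshapes rather than the kinetics. Initial time constants default to
#' the geometric mid-point of their bounds.
#'
#' @param channels Named list of [channel_model]s the fit will use.
#' @param init Named list overriding initial values (natural scale).
#' @param fixed Character vector of parameter names to hold at their
#'   initial values (use e.g. `fixed = "sigma_irf"` to freeze the IRF).
#' @param free Character vector of parameters to release (e.g. `"contam"`).
#' @param bounds Named list of `c(lower, upper)` overrides (natural scale).
#' @param n_starts Number of optimizer starts; starts beyond the first
#'   jitter the free initial values within bounds (seeded, reproducible).
#' @param start_seed Seed for the multi-start jitter.
#' @param ftol,ptol Cost and parameter convergence tolerances passed to the
#'   Levenberg-Marquardt optimizer.
#' @param max_iter Iteration cap per start.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(channels = default_channels(), init = list(),
                     fixed = character(), free = character(),
                     bounds = list(), n_starts = 1, start_seed = 1,
                     ftol = 1e-10, ptol = 1e-8, max_iter = 200) {
  pt <- .fit_par_table(channels)
  # geometric mid-bound starts for the log-scale parameters
  logidx <- pt$trans == "log"
  pt$init[logidx] <- sqrt(pt$lower[logidx] * pt$upper[logidx])
  for (nm in names(init)) {
    if (!nm %in% pt$name) abort(sprintf("unknown fit parameter `%s`.", nm))
    pt$init[pt$name == nm] <- init[[nm]]
    pt$auto[pt$name == nm] <- FALSE
  }
  for (nm in names(bounds)) {
    if (!nm %in% pt$name) abort(sprintf("unknown fit parameter `%s`.", nm))
    pt$lower[pt$name == nm] <- bounds[[nm]][1]
    pt$upper[pt$name == nm] <- bounds[[nm]][2]
    pt$auto[pt$name == nm] <- FALSE
  }
  bad <- pt$init < pt$lower | pt$init > pt$upper
  if (any(bad)) {
    abort(sprintf("initial values outside bounds for: %s",
                  paste(pt$name[bad], collapse = ", ")))
  }
  for (nm in fixed) {
    if (!nm %in% pt$name) abort(sprintf("unknown fit parameter `%s`.", nm))
    pt$vary[pt$name == nm] <- FALSE
  }
  for (nm in free) {
    if (!nm %in% pt$name) abort(sprintf("unknown fit parameter `%s`.", nm))
    pt$vary[pt$name == nm] <- TRUE
  }
  structure(list(channels = channels, par_table = pt,
                 n_starts = n_starts, start_seed = start_seed,
                 ftol = ftol, ptol = ptol, max_iter = max_iter),
            class = "fit_spec")
}

# transforms ---------------------------------------------------------------

.to_internal <- function(pt) {
  z <- numeric(nrow(pt))
  zlo <- numeric(nrow(pt))
  zhi <- numeric(nrow(pt))
  q21 <- pt$init[pt$name == "q21"]
  for (r in seq_len(nrow(pt))) {
    x <- pt$init[r]
    switch(pt$trans[r],
      log = {
        z[r] <- log(x); zlo[r] <- log(pt$lower[r]); zhi[r] <- log(pt$upper[r])
      },
      logit = {
        z[r] <- qlogis(min(max(x, .sb_eps), 1 - .sb_eps))
        zlo[r] <- -8; zhi[r] <- 8
      },
      sb1 = {
        z[r] <- qlogis(min(max(x, .sb_eps), 1 - .sb_eps))
        zlo[r] <- -8; zhi[r] <- 8
      },
      sb2 = {
        frac <- x / max(1 - q21, .sb_eps)
        z[r] <- qlogis(min(max(frac, .sb_eps), 1 - .sb_eps))
        zlo[r] <- -8; zhi[r] <- 8
      },
      linear = {
        z[r] <- x; zlo[r] <- pt$lower[r]; zhi[r] <- pt$upper[r]
      }
    )
  }
  list(z = z, lower = zlo, upper = zhi)
}

# full internal vector -> named natural list (fixed entries keep their
# natural initial values)
.from_internal <- function(zfull, pt) {
  nat <- setNames(numeric(nrow(pt)), pt$name)
  q21 <- NA_real_
  for (r in seq_len(nrow(pt))) {
    if (!pt$vary[r]) {
      nat[r] <- pt$init[r]
      if (pt$name[r] == "q21") q21 <- nat[r]
      next
    }
    switch(pt$trans[r],
      log = nat[r] <- exp(zfull[r]),
      logit = nat[r] <- plogis(zfull[r]),
      sb1 = {
        nat[r] <- plogis(zfull[r]); q21 <- nat[r]
      },
      sb2 = nat[r] <- (1 - q21) * plogis(zfull[r]),
      linear = nat[r] <- zfull[r]
    )
  }
  # fixed q22 must still respect the simplex against a fitted q21
  if (!pt$vary[pt$name == "q22"]) {
    nat["q22"] <- min(nat[["q22"]], 1 - nat[["q21"]])
  }
  nat
}

.nat_to_model <- function(nat, channels) {
  kp <- kinetic_parameters(
    tau1 = nat[["tau1"]],
    q21 = nat[["q21"]], tau21 = nat[["tau21"]],
    q22 = nat[["q22"]], tau22 = nat[["tau22"]],
    q31 = nat[["q31"]], tau31 = nat[["tau31"]],
    tau32 = nat[["tau32"]],
    q41 = nat[["q41"]], tau41 = nat[["tau41"]]
  )
  chans <- channels
  for (nm in names(chans)) {
    chans[[nm]]$amplitude <- nat[[paste0("amp_", nm)]]
    if (!is.null(chans[[nm]]$contamination)) {
      chans[[nm]]$contamination$fraction <- nat[["contam"]]
    }
  }
  list(kp = kp, sigma = nat[["sigma_irf"]], t0 = nat[["t0"]], channels = chans)
}

# fast predictor: channels evaluated from one population matrix per grid
.predict_stack <- function(nat, channels, grids) {
  mdl <- .nat_to_model(nat, channels)
  # channels usually share one grid: solve each distinct grid once
  ug <- list()
  gidx <- integer(length(grids))
  for (ii in seq_along(grids)) {
    found <- 0L
    for (uu in seq_along(ug)) {
      if (identical(ug[[uu]], grids[[ii]])) { found <- uu; break }
    }
    if (!found) { ug[[length(ug) + 1L]] <- grids[[ii]]; found <- length(ug) }
    gidx[ii] <- found
  }
  pops <- lapply(ug, function(g) .solve_pop_core(mdl$kp, g, mdl$sigma, mdl$t0))
  base <- lapply(seq_along(channels), function(ii) {
    .channel_base(pops[[gidx[ii]]], mdl$channels[[ii]])
  })
  names(base) <- names(channels)
  for (nm in names(channels)) {
    cont <- mdl$channels[[nm]]$contamination
    if (!is.null(cont)) {
      src <- NULL
      for (snm in names(channels)) {
        if (isTRUE(all.equal(channels[[snm]]$probe_energy, cont$source))) src <- snm
      }
      if (is.null(src)) abort("contamination source channel not defined.")
      base[[nm]] <- base[[nm]] + cont$fraction * base[[src]]
    }
  }
  base
}

.match_traces <- function(traces, channels) {
  req <- c("probe_energy", "delay_ps", "dA", "sigma")
  if (!all(req %in% names(traces))) {
    abort("`traces` needs columns probe_energy, delay_ps, dA, sigma.")
  }
  if (any(traces$sigma <= 0)) abort("all `sigma` must be > 0.")
  out <- lapply(channels, function(ch) {
    df <- traces[abs(traces$probe_energy - ch$probe_energy) < 1e-6, ]
    if (nrow(df) == 0) {
      abort(sprintf("no trace rows for probe energy %s.", ch$probe_energy))
    }
    df[order(df$delay_ps), ]
  })
  names(out) <- names(channels)
  out
}

# fitting ------------------------------------------------------------------

#' Global fit of the kinetic model to transient-absorption traces
#'
#' Minimizes the sigma-weighted sum of squared residuals over all channels
#' simultaneously (Levenberg-Marquardt with box bounds on the transformed
#' parameter scale). Kinetic time constants, yields, the IRF width and t0
#' are shared across channels; amplitudes are per channel. Standard errors
#' come from the Gauss-Newton covariance at the optimum scaled by the
#' reduced chi-square, propagated to the natural scale by the delta method.
#' A non-converged optimizer is reported in the result (`converged`,
#' `message`), never silently.
#'
#' @param traces Tidy trace table (columns `probe_energy`, `delay_ps`,
#'   `dA`, `sigma`), e.g. from [simulate_traces()] or [read_traces()].
#' @param spec A [fit_spec()].
#' @return An object of class `cystine_fit` with elements `estimates`
#'   (natural-scale named vector), `se`, `cov`, `params`
#'   ([kinetic_parameters]), `irf`, `channels`, `residuals` (tibble),
#'   `reduced_chi2`, `n_obs`, `n_free`, `converged`, `message`, `starts`.
#'   Methods: [tidy()], [glance()], [augment()], `autoplot()`, `print()`.
#' @examples
#' cp <- cystine_parameters()
#' tr <- simulate_traces(cp$params, cp$irf,
#'                       experiment_design(dt = 0.25, n_log = 12), seed = 7)
#' \donttest{
#' fit <- global_fit(tr, fit_spec())
#' tidy(fit)
#' }
#' @export
global_fit <- function(traces, spec = fit_spec()) {
  if (!inherits(spec, "fit_spec")) abort("`spec` must come from fit_spec().")
  channels <- spec$channels
  pt <- spec$par_table
  chunks <- .match_traces(traces, channels)
  grids <- lapply(chunks, function(df) df$delay_ps)
  # data-driven amplitude starts: the peak |dA| of a channel is its
  # amplitude times an order-one population factor
  for (nm in names(channels)) {
    row <- match(paste0("amp_", nm), pt$name)
    if (isTRUE(pt$auto[row])) {
      peak <- max(abs(chunks[[nm]]$dA))
      pt$init[row] <- peak / 0.6
      pt$upper[row] <- max(pt$upper[row], 20 * peak)
    }
  }
  obs <- unlist(lapply(chunks, function(df) df$dA), use.names = FALSE)
  wts <- unlist(lapply(chunks, function(df) 1 / df$sigma), use.names = FALSE)

  internal <- .to_internal(pt)
  free <- which(pt$vary)
  if (length(free) == 0) abort("at least one parameter must be free.")
  zfull0 <- internal$z

  resid_fn <- function(zfree) {
    zfull <- zfull0
    zfull[free] <- zfree
    nat <- .from_internal(zfull, pt)
    pred <- unlist(.predict_stack(nat, channels, grids), use.names = FALSE)
    (obs - pred) * wts
  }

  starts <- list(internal$z[free])
  if (spec$n_starts > 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(spec$start_seed))
    for (s in 2:spec$n_starts) {
      starts[[s]] <- runif(length(free), internal$lower[free], internal$upper[free])
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }

  best <- NULL
  start_costs <- numeric(0)
  for (z0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = z0, fn = resid_fn,
        lower = internal$lower[free], upper = internal$upper[free],
        control = minpack.lm::nls.lm.control(
          ftol = spec$ftol, ptol = spec$ptol, maxiter = spec$max_iter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    start_costs <- c(start_costs, fit$deviance)
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    abort("optimizer failed from every start; check traces and fit_spec bounds.")
  }

  zfull <- zfull0
  zfull[free] <- best$par
  nat <- .from_internal(zfull, pt)
  mdl <- .nat_to_model(nat, channels)
  n_obs <- length(obs)
  n_free <- length(free)
  redchi2 <- best$deviance / max(n_obs - n_free, 1)
  converged <- best$info %in% 1:3

  # covariance on the internal scale, scaled by reduced chi-square
  cov_nat <- NULL
  se_nat <- setNames(rep(NA_real_, nrow(pt)), pt$name)
  cov_z <- tryCatch(solve(best$hessian) * redchi2, error = function(e) NULL)
  if (!is.null(cov_z) && all(is.finite(cov_z))) {
    G <- .nat_jacobian(zfull, pt, free)
    cov_nat <- G %*% cov_z %*% t(G)
    dimnames(cov_nat) <- list(pt$name, pt$name)
    se_nat[] <- sqrt(pmax(diag(cov_nat), 0))
  } else {
    warn("Jacobian is degenerate at the optimum; standard errors unavailable.")
  }

  pred <- .predict_stack(nat, channels, grids)
  resid_tbl <- purrr::imap_dfr(chunks, function(df, nm) {
    tibble(channel = nm, probe_energy = df$probe_energy,
           delay_ps = df$delay_ps, dA = df$dA, sigma = df$sigma,
           fitted = pred[[nm]],
           residual = df$dA - pred[[nm]],
           std_residual = (df$dA - pred[[nm]]) / df$sigma)
  })

  structure(list(
    estimates = nat,
    se = se_nat,
    cov = cov_nat,
    params = mdl$kp,
    irf = irf_model(mdl$sigma, mdl$t0),
    channels = mdl$channels,
    residuals = resid_tbl,
    reduced_chi2 = redchi2,
    n_obs = n_obs, n_free = n_free,
    converged = converged,
    message = best$message,
    info = best$info,
    niter = best$niter,
    starts = length(start_costs),
    start_costs = start_costs,
    spec = spec
  ), class = "cystine_fit")
}

# finite-difference jacobian of the natural parameter vector w.r.t. the
# free internal parameters (rows: all natural params; cols: free internal)
.nat_jacobian <- function(zfull, pt, free, h = 1e-6) {
  base <- .from_internal(zfull, pt)
  G <- matrix(0, nrow(pt), length(free))
  for (jj in seq_along(free)) {
    zp <- zfull; zp[free[jj]] <- zp[free[jj]] + h
    zm <- zfull; zm[free[jj]] <- zm[free[jj]] - h
    G[, jj] <- (.from_internal(zp, pt) - .from_internal(zm, pt)) / (2 * h)
  }
  rownames(G) <- pt$name
  G
}
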
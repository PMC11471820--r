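#' @export
print.cystine_fit <- function(x, ...) {
  cat(sprintf("Global kinetic fit: %d points, %d free parameters, %d channel(s)\n",
              x$n_obs, x$n_free, length(x$channels)))
  cat(sprintf("  converged: %s (%s)\n", x$converged, trimws(x$message)))
  cat(sprintf("  reduced chi-square: %.4g\n", x$reduced_chi2))
  pt <- x$spec$par_table
  est <- x$estimates[pt$name[pt$vary]]
  se <- x$se[pt$name[pt$vary]]
  for (nm in names(est)) {
    cat(sprintf("  %-10s %10.4g +/- %.3g\n", nm, est[[nm]], se[[nm]]))
  }
  invisible(x)
}

#' Tidy a global kinetic fit
#'
#' @param x A `cystine_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `std.error`, and whether the parameter was `fixed`.
#' @export
tidy.cystine_fit <- function(x, ...) {
  pt <- x$spec$par_table
  tibble(term = pt$name,
         estimate = unname(x$estimates[pt$name]),
         std.error = unname(x$se[pt$name]),
         fixed = !pt$vary)
}

#' One-row summary of a global kinetic fit
#'
#' Includes the derived headline quantities of the recombination scheme:
#' the 20-ps thiyl recombined fraction and the asymptotic ground-state
#' recovery.
#'
#' @inheritParams tidy.cystine_fit
#' @return A one-row tibble.
#' @export
glance.cystine_fit <- function(x, ...) {
  tibble(
    n_obs = x$n_obs,
    n_free = x$n_free,
    reduced_chi2 = x$reduced_chi2,
    converged = x$converged,
    n_starts = x$starts,
    recombined_20ps = recombined_fraction(x$params, 20),
    recovery_asymptotic = asymptotic_recovery(x$params)
  )
}

#' @export
augment.cystine_fit <- function(x, ...) x$residuals

#' Fitted model curves of a global fit
#'
#' @param fit A `cystine_fit`.
#' @param delays Optional delay grid (ps); defaults to the fitted data's
#'   grids.
#' @return A tibble `channel`, `probe_energy`, `delay_ps`, `dA`.
#' @export
fitted_traces <- function(fit, delays = NULL) {
  if (is.null(delays)) {
    return(dplyr::select(fit$residuals, "channel", "probe_energy",
                         "delay_ps", dA = "fitted"))
  }
  predict_channels(fit$params, fit$irf, fit$channels, delays)
}

#' Plot a global fit: data, model curves and residuals
#'
#' @param object A `cystine_fit`.
#' @param ... Unused.
#' @return A ggplot object (delay on a pseudo-log axis).
#' @export
autoplot.cystine_fit <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delay_ps)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$dA - .data$sigma,
                                        ymax = .data$dA + .data$sigma),
                           colour = "grey60", width = 0) +
    ggplot2::geom_point(ggplot2::aes(y = .data$dA), size = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#b03030") +
    ggplot2::facet_wrap(~ .data$channel + .data$probe_energy, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_x_continuous(trans = "pseudo_log") +
    ggplot2::labs(x = "delay (ps)", y = expression(Delta * A ~ "(edge-normalized)"))
}

#' Residual-resampling bootstrap uncertainties
#'
#' Resamples the standardized residuals of a converged global fit with
#' replacement, rebuilds synthetic data sets `fitted + sigma * r*`, refits
#' each (starting from the original estimates), and summarizes the spread
#' of the re-estimated parameters. Reproducible for a given seed; replicate
#' fits that fail to converge are counted and excluded from the intervals.
#'
#' @param fit A `cystine_fit` from [global_fit()].
#' @param n_replicates Number of bootstrap replicates (>= 2).
#' @param seed Integer RNG seed (required).
#' @param level Interval coverage (default 0.95).
#' @return A tibble with `term`, `estimate`, `se_boot`, `lower`, `upper`,
#'   plus attributes `n_failed` and `n_replicates`.
#' @export
bootstrap_uncertainties <- function(fit, n_replicates, seed, level = 0.95) {
  if (missing(seed)) abort("`seed` is required.")
  if (n_replicates < 2) abort("`n_replicates` must be >= 2.")
  res <- fit$residuals
  spec <- fit$spec
  # restart every replicate from the fitted optimum
  pt <- spec$par_table
  spec$par_table$init <- unname(fit$estimates[pt$name])
  spec$n_starts <- 1

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)

  free_names <- pt$name[pt$vary]
  draws <- matrix(NA_real_, n_replicates, length(free_names),
                  dimnames = list(NULL, free_names))
  n_failed <- 0L
  for (b in seq_len(n_replicates)) {
    rstar <- sample(res$std_residual, nrow(res), replace = TRUE)
    boot <- res
    boot$dA <- res$fitted + res$sigma * rstar
    bf <- tryCatch(global_fit(boot, spec), error = function(e) NULL)
    if (is.null(bf) || !bf$converged) {
      n_failed <- n_failed + 1L
      next
    }
    draws[b, ] <- bf$estimates[free_names]
  }
  ok <- stats::complete.cases(draws)
  a <- (1 - level) / 2
  out <- tibble(
    term = free_names,
    estimate = unname(fit$estimates[free_names]),
    se_boot = apply(draws[ok, , drop = FALSE], 2, sd),
    lower = apply(draws[ok, , drop = FALSE], 2, quantile, probs = a),
    upper = apply(draws[ok, , drop = FALSE], 2, quantile, probs = 1 - a)
  )
  attr(out, "n_failed") <- n_failed
  attr(out, "n_replicates") <- n_replicates
  out
}

#' Simulation-based parameter recovery study
#'
#' Generates synthetic experiments from known parameters across many seeds,
#' fits each globally, and reports how well every free parameter is
#' recovered: per-seed estimates plus per-parameter bias, RMSE, and (when
#' reference half-widths are supplied) the fraction of seeds within
#' `truth +/- interval`. Failed fits are recorded per seed, not fatal.
#'
#' @param params,irf Generating [kinetic_parameters] and [irf_model].
#' @param design An [experiment_design].
#' @param spec A [fit_spec()]; its channels should match the design's.
#' @param n_seeds Number of replicates.
#' @param seed Base seed; replicate `s` uses `seed + s - 1`.
#' @param intervals Optional named numeric vector of +/- half-widths for
#'   coverage accounting (e.g. `c(tau1 = 0.05, q21 = 0.02)`).
#' @return An object of class `recovery_study`: list with `estimates`
#'   (tibble seed x parameter), `summary` (tibble per parameter), `truth`,
#'   `n_failed`.
#' @export
parameter_recovery_study <- function(params, irf, design, spec,
                                     n_seeds, seed, intervals = NULL) {
  if (missing(seed)) abort("`seed` is required.")
  pt <- spec$par_table
  free_names <- pt$name[pt$vary]
  truth_all <- c(
    tau1 = params$tau1, tau21 = params$tau21, tau22 = params$tau22,
    tau31 = params$tau31, tau32 = params$tau32, tau41 = params$tau41,
    q21 = params$q21, q22 = params$q22, q31 = params$q31, q41 = params$q41,
    sigma_irf = irf$sigma, t0 = irf$t0, contam = NA_real_
  )
  amp_truth <- setNames(
    vapply(design$channels, function(ch) ch$amplitude, numeric(1)),
    paste0("amp_", names(design$channels)))
  truth_all <- c(truth_all, amp_truth)
  for (nm in names(design$channels)) {
    cont <- design$channels[[nm]]$contamination
    if (!is.null(cont)) truth_all[["contam"]] <- cont$fraction
  }

  rows <- list()
  n_failed <- 0L
  for (s in seq_len(n_seeds)) {
    sd_s <- as.integer(seed) + s - 1L
    tr <- simulate_traces(params, irf, design, seed = sd_s)
    ft <- tryCatch(global_fit(tr, spec), error = function(e) NULL)
    if (is.null(ft)) {
      n_failed <- n_failed + 1L
      rows[[s]] <- tibble(seed = sd_s, term = free_names,
                          estimate = NA_real_, converged = FALSE)
      next
    }
    rows[[s]] <- tibble(seed = sd_s, term = free_names,
                        estimate = unname(ft$estimates[free_names]),
                        converged = ft$converged)
  }
  est <- dplyr::bind_rows(rows)

  smry <- est |>
    dplyr::filter(!is.na(.data$estimate)) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      truth = truth_all[[unique(.data$term)]],
      n = dplyr::n(),
      median = median(.data$estimate),
      mean = mean(.data$estimate),
      sd = sd(.data$estimate),
      bias = mean(.data$estimate) - truth_all[[unique(.data$term)]],
      rmse = sqrt(mean((.data$estimate - truth_all[[unique(.data$term)]])^2)),
      .groups = "drop"
    )
  if (!is.null(intervals)) {
    smry$coverage <- vapply(smry$term, function(nm) {
      if (!nm %in% names(intervals)) return(NA_real_)
      e <- est$estimate[est$term == nm & !is.na(est$estimate)]
      mean(abs(e - truth_all[[nm]]) <= intervals[[nm]])
    }, numeric(1))
  }
  structure(list(estimates = est, summary = smry,
                 truth = truth_all[free_names], n_failed = n_failed,
                 n_seeds = n_seeds),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter recovery study: %d seeds (%d failed fits)\n",
              x$n_seeds, x$n_failed))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @export
autoplot.recovery_study <- function(object, ...) {
  est <- dplyr::filter(object$estimates, !is.na(.data$estimate))
  truth <- tibble(term = names(object$truth),
                  truth = unname(object$truth))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(data = truth[!is.na(truth$truth), ],
                        ggplot2::aes(xintercept = .data$truth),
                        colour = "#b03030", linetype = 2) +
    ggplot2::facet_wrap(~ .data$term, scales = "free") +
    ggplot2::labs(x = "recovered estimate", y = "seeds")
}
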
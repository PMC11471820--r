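#' Design of a synthetic transient-absorption experiment
#'
#' Describes the measurement layout used to generate synthetic delay scans:
#' the probe channels, a delay grid that is linear through the pulse overlap
#' region and logarithmic out to the longest delay (mirroring how such scans
#' are recorded and plotted, with the axis turning logarithmic after 5 ps),
#' and the noise model. Two noise modes are supported: `"per_point"` adds
#' Gaussian noise of standard deviation `noise_sd` to each point and
#' reports that value as the point uncertainty; `"shots"` simulates
#' `shots` independent acquisitions of per-shot standard deviation
#' `shot_sd` per delay point, stores their mean as the signal and their
#' sample standard deviation as the uncertainty column (the convention used
#' for error bars computed from repeated shot measurements). An optional
#' seeded random-walk drift emulates slow variations of experimental
#' conditions; it is off by default.
#'
#' @param channels Named list of [channel_model]s.
#' @param t_min,t_lin_max,dt Linear delay segment: start, end, step (ps).
#' @param t_max End of the logarithmic segment (ps).
#' @param n_log Number of logarithmic points after `t_lin_max`.
#' @param noise One of `"per_point"` or `"shots"`.
#' @param noise_sd Per-point Gaussian noise SD (parent-edge-normalized
#'   dA units); may be a single value or one per channel.
#' @param shots,shot_sd Shot-level mode: number of shots averaged per delay
#'   point and the per-shot SD.
#' @param drift_sd Per-step SD of an optional additive random-walk drift
#'   along the scan (0 disables).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(channels = default_channels(),
                              t_min = -1, t_lin_max = 5, dt = 0.1,
                              t_max = 800, n_log = 30,
                              noise = c("per_point", "shots"),
                              noise_sd = 0.004,
                              shots = 600, shot_sd = 0.2,
                              drift_sd = 0) {
  noise <- match.arg(noise)
  if (t_min >= t_lin_max || t_lin_max >= t_max || dt <= 0 || n_log < 1) {
    abort("delay grid spec must satisfy t_min < t_lin_max < t_max, dt > 0, n_log >= 1.")
  }
  if (noise == "shots" && (shots < 1 || shot_sd <= 0)) {
    abort("shot-level noise needs shots >= 1 and shot_sd > 0.")
  }
  if (any(noise_sd < 0) || drift_sd < 0) {
    abort("noise SDs must be >= 0.")
  }
  if (!length(noise_sd) %in% c(1L, length(channels))) {
    abort("`noise_sd` must have length 1 or one value per channel.")
  }
  lin <- seq(t_min, t_lin_max, by = dt)
  lg <- exp(seq(log(t_lin_max), log(t_max), length.out = n_log + 1L))[-1L]
  grid <- c(lin, lg)
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("delay grid must be strictly increasing.")
  }
  structure(list(channels = channels, grid = grid, noise = noise,
                 noise_sd = noise_sd, shots = shots, shot_sd = shot_sd,
                 drift_sd = drift_sd),
            class = "experiment_design")
}

#' Generate synthetic transient-absorption traces
#'
#' Predicts noise-free differential-absorption traces for every channel via
#' the observable model and adds noise according to the design. A seed is
#' mandatory: synthetic data are only meaningful when reproducible, so no
#' silent clock seeding is allowed. Identical seeds give bit-identical
#' traces.
#'
#' @param params A [kinetic_parameters] object.
#' @param irf An [irf_model].
#' @param design An [experiment_design].
#' @param seed Integer RNG seed (required).
#' @return A tibble with columns `channel`, `probe_energy`, `delay_ps`,
#'   `dA`, `sigma` — one block per probe channel (class `transient_traces`).
#' @examples
#' cp <- cystine_parameters()
#' simulate_traces(cp$params, cp$irf, experiment_design(), seed = 1)
#' @export
simulate_traces <- function(params, irf, design = experiment_design(), seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed)) {
    abort("`seed` is required for synthetic data generation.")
  }
  if (!inherits(design, "experiment_design")) {
    abort("`design` must be an `experiment_design` object.")
  }
  clean <- predict_channels(params, irf, design$channels, design$grid)
  nsd <- rep(design$noise_sd, length.out = length(design$channels))
  names(nsd) <- names(design$channels)

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    expr
  }

  out <- withr_seed({
    purrr::imap_dfr(split(clean, factor(clean$channel, levels = unique(clean$channel))),
                    function(df, nm) {
      n <- nrow(df)
      if (design$noise == "per_point") {
        s <- rep(nsd[[nm]], n)
        dA <- df$dA + rnorm(n, 0, nsd[[nm]])
      } else {
        # draw the individual shot measurements: the point value is their
        # mean, the reported uncertainty their sample standard deviation
        shots <- matrix(rnorm(n * design$shots, mean = df$dA,
                              sd = design$shot_sd),
                        nrow = n)
        dA <- rowMeans(shots)
        s <- apply(shots, 1L, sd)
      }
      if (design$drift_sd > 0) {
        dA <- dA + cumsum(rnorm(n, 0, design$drift_sd))
      }
      df$dA <- dA
      df$sigma <- pmax(s, .Machine$double.eps)
      df
    })
  })
  class(out) <- c("transient_traces", class(out))
  out
}
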
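#' Map species populations to a differential-absorption channel
#'
#' A probe channel is a linear readout of the species populations at one
#' probe energy: `dA = amplitude * sum(weights * N_species)`, optionally
#' plus a fixed fraction of another channel's predicted signal (spectral
#' cross-contamination, e.g. the tail of the thiyl line under the perthiyl
#' probe energy). The parent bleach is expressed through the transient
#' populations (`-(N1+N2+N3+N4)`), which is `-(1 - N0)` scaled by the
#' convolved excitation step and therefore causal also with an IRF.
#'
#' @param probe_energy Probe energy label (eV), used to identify channels.
#' @param weights Named numeric vector of response coefficients over
#'   `c("N1","N2","N3","N4")` (unlisted species contribute 0).
#' @param amplitude Channel amplitude on the parent-edge-normalized
#'   differential-absorption scale.
#' @param contamination Optional `list(source = <probe energy>, fraction =
#'   <in \[0,1\]>)`: adds `fraction` times the predicted signal of the source
#'   channel.
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(probe_energy, weights, amplitude,
                          contamination = NULL) {
  stopifnot_scalar(probe_energy, "probe_energy")
  stopifnot_scalar(amplitude, "amplitude")
  if (!is.numeric(weights) || is.null(names(weights)) ||
      !all(names(weights) %in% c("N1", "N2", "N3", "N4"))) {
    abort("`weights` must be named over species N1, N2, N3, N4.")
  }
  if (!is.null(contamination)) {
    if (!is.list(contamination) ||
        !all(c("source", "fraction") %in% names(contamination)) ||
        !is_fraction(contamination$fraction)) {
      abort("`contamination` must be list(source=, fraction=) with fraction in [0,1].")
    }
  }
  structure(list(probe_energy = probe_energy, weights = weights,
                 amplitude = amplitude, contamination = contamination),
            class = "channel_model")
}

#' Default three-channel sulfur K-edge probe set
#'
#' The standard probe configuration for disulfide photolysis: the thiyl
#' radical line at 2466.8 eV, the perthiyl radical shoulder at 2468.2 eV
#' (which also picks up 8 % of the thiyl lineshape's maximum), and the
#' parent bleach at 2472.0 eV. The excited parent N1 and the vibrationally
#' excited parent N3 carry no product response; every transient species
#' depletes the parent absorption equally.
#'
#' Default amplitudes put the thiyl peak at 17 % of the parent K-edge jump
#' (with the published kinetic parameters) and give bleach/perthiyl
#' signals of comparable visual magnitude to measured scans.
#'
#' @param a_thiyl,a_perthiyl,a_bleach Channel amplitudes (parent-edge
#'   normalized).
#' @param thiyl_contamination Fraction of the thiyl channel appearing under
#'   the perthiyl probe energy (default 0.08).
#' @return A named list of three [channel_model] objects.
#' @export
default_channels <- function(a_thiyl = 0.268, a_perthiyl = 0.18,
                             a_bleach = 0.20, thiyl_contamination = 0.08) {
  list(
    thiyl = channel_model(2466.8, c(N2 = 1), a_thiyl),
    perthiyl = channel_model(2468.2, c(N4 = 1), a_perthiyl,
                             contamination = list(source = 2466.8,
                                                  fraction = thiyl_contamination)),
    bleach = channel_model(2472.0, c(N1 = -1, N2 = -1, N3 = -1, N4 = -1),
                           a_bleach)
  )
}

# population matrix (.solve_pop_core output) -> raw channel signal without
# contamination
.channel_base <- function(popmat, channel) {
  sig <- numeric(nrow(popmat))
  for (sp in names(channel$weights)) {
    sig <- sig + channel$weights[[sp]] * popmat[, sp]
  }
  channel$amplitude * sig
}

#' Predict one channel's differential absorption
#'
#' @param trajectory A `population_trajectory` from [solve_populations()],
#'   evaluated on the channel's delay grid.
#' @param channel A [channel_model].
#' @param all_channels Channel list providing the contamination source
#'   (only needed when `channel` has a contamination term).
#' @return Numeric vector of differential absorption values.
#' @export
predict_channel <- function(trajectory, channel, all_channels = NULL) {
  popmat <- as.matrix(trajectory[, c("N1", "N2", "N3", "N4")])
  sig <- .channel_base(popmat, channel)
  if (!is.null(channel$contamination)) {
    src <- NULL
    for (ch in all_channels) {
      if (isTRUE(all.equal(ch$probe_energy, channel$contamination$source))) {
        src <- ch
      }
    }
    if (is.null(src)) {
      abort(sprintf("contamination source channel %s not defined.",
                    format(channel$contamination$source)))
    }
    sig <- sig + channel$contamination$fraction * .channel_base(popmat, src)
  }
  sig
}

#' Predict all channels of a transient-absorption experiment
#'
#' Solves the populations (with IRF) on each channel's delay grid and
#' applies every channel readout, returning one tidy table of noise-free
#' model traces. Deterministic: identical inputs give identical outputs.
#'
#' @param params A [kinetic_parameters] object.
#' @param irf An [irf_model] (or `NULL` for the IRF-free limit).
#' @param channels Named list of [channel_model]s, e.g. [default_channels()].
#' @param delays Either one numeric vector used for every channel or a list
#'   of vectors, one per channel (same order/names as `channels`).
#' @return A tibble with columns `channel`, `probe_energy`, `delay_ps`, `dA`.
#' @examples
#' cp <- cystine_parameters()
#' predict_channels(cp$params, cp$irf, default_channels(), seq(-1, 5, 0.5))
#' @export
predict_channels <- function(params, irf, channels, delays) {
  if (!is.list(delays)) {
    delays <- rep(list(delays), length(channels))
  }
  if (length(delays) != length(channels)) {
    abort("`delays` must have one grid per channel (or a single shared grid).")
  }
  purrr::imap_dfr(channels, function(ch, nm) {
    grid <- delays[[match(nm, names(channels))]]
    if (!is.numeric(grid) || is.unsorted(grid)) {
      abort(sprintf("delay grid for channel %s must be sorted numeric.", nm))
    }
    traj <- solve_populations(params, grid, irf)
    tibble(channel = nm, probe_energy = ch$probe_energy, delay_ps = grid,
           dA = predict_channel(traj, ch, channels))
  })
}
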
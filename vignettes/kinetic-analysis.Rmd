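---
title: "Methods: branching recombination kinetics from transient X-ray absorption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branching recombination kinetics from transient X-ray absorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystinetics)
```

## The kinetic model and its assumptions

`cystinetics` models the photocycle of an aqueous disulfide after UV
excitation as a branching sequential compartment system. One photon
promotes a parent molecule to a dissociative state ($N_1$, decay time
$\tau_1$) that cleaves the S–S bond into a thiyl radical pair ($N_2$).
The thiyl population is a mixture of three sub-ensembles that recombine
on distinct timescales: a dominant in-cage channel ($q_{21}$, $\tau_{21}$,
sub-picosecond), a rotational-diffusion-limited channel ($q_{22}$,
$\tau_{22}$, tens of picoseconds), and a cage-escape fraction
($q_{23} = 1 - q_{21} - q_{22}$) that does not recombine within the
sub-nanosecond observation window. Recombination proceeds through a
vibrationally excited parent ($N_3$) that either relaxes to the cold
ground state ($q_{31}$, $\tau_{31}$) or cleaves a C–S bond to form a
perthiyl radical ($N_4$; $q_{32} = 1 - q_{31}$, $\tau_{32}$). Perthiyl
radicals recombine to the parent with yield $q_{41}$ ($\tau_{41}$,
hundreds of picoseconds); the remainder persists.

Assumptions inherited from this structure:

* **First-order kinetics.** Every step is a unimolecular exponential;
  diffusive re-encounters beyond the solvent cage are outside the window
  and absorbed into the non-decaying fractions.
* **Non-decaying sub-ensembles are exactly frozen.** The cage-escape
  thiyl fraction and the persistent perthiyl fraction are modelled with
  rate 0 (`tau = Inf` as an explicit sentinel, never a large float).
  Their true recombination times are only bounded from below
  (≫ observation window), so any finite choice would be arbitrary; rate 0
  is the limit consistent with the data and keeps the asymptotics exact.
* **Sub-ensemble-independent branching.** Every thiyl sub-ensemble feeds
  the two hot-parent fates with the same $q_{3j}$; the model provides no
  mechanism for the branching to remember which recombination channel
  produced the hot parent. (The index structure of the governing
  equations admits the same simplification, and nothing in the data
  distinguishes the alternatives.)
* **A single shared Gaussian IRF.** One width $\sigma_{\mathrm{IRF}}$ and
  one time-zero $t_0$ apply to all probe channels, as appropriate for
  channels recorded on the same pump and probe pulses.

Populations are normalized per unit initial excitation ($N_1(0) = 1$);
the absolute excitation fraction is carried by the per-channel amplitudes
of the observable model.

## From populations to observed channels

Three probe channels are modelled (energies in eV label the channels and
carry no other physics):

| channel | energy | readout |
|---|---|---|
| thiyl | 2466.8 | $A_2 N_2$ |
| perthiyl | 2468.2 | $A_4 N_4 + c\,(A_2 N_2)$, $c = 0.08$ |
| bleach | 2472.0 | $-A_0\,(N_1 + N_2 + N_3 + N_4)$ |

The excited parent $N_1$ and the hot parent $N_3$ are spectroscopically
silent in the product channels. Two deliberate choices:

* **Bleach as the sum of transient populations.** Algebraically
  $-(1 - N_0)$ scaled by the excitation step; writing it through the
  transient populations makes the signal exactly causal under IRF
  convolution. This treats the hot parent as bleaching like any other
  transient — the alternative (hot parent partially absorbing at the cold
  parent energy) cannot be separated from amplitude scaling here, so the
  simpler convention is the default.
* **The 8 % thiyl contamination of the perthiyl channel is a fixed
  constant** (`contam` in the fit table), because it derives from the
  static lineshapes, not from the kinetics. It can be released with
  `fit_spec(free = "contam")`.

## Tunable parameters

All times in picoseconds, yields dimensionless, amplitudes on the
parent-edge-normalized ΔA scale. Defaults in `fit_spec()`:

* time-constant bounds: $\tau_1 \in [0.01, 1]$, $\tau_{21} \in [0.05, 3]$,
  $\tau_{22} \in [1, 50]$, $\tau_{31}, \tau_{32} \in [0.05, 5]$,
  $\tau_{41} \in [20, 2000]$ — one decade or more around the physically
  expected scales of formation (~0.1 ps), in-cage recombination (~0.5 ps),
  rotational diffusion (~5 ps) and perthiyl recombination (~300 ps);
  initial values are the geometric mid-points.
* $\sigma_{\mathrm{IRF}} \in [0.02, 0.5]$ ps (covering X-ray/laser
  cross-correlations from well-compressed to badly drifting), $t_0 \in
  [-0.5, 0.5]$ ps.
* amplitudes: initialized from the data (peak |ΔA| of the channel divided
  by an order-one population factor) unless the user supplies values —
  the data scale is a normalization choice and must not require retuning.

## Numerical choices

* **Closed-form cascades via partial fractions with multiplicity.** Each
  sub-ensemble chain is a Bateman problem; its Laplace-domain poles are
  grouped when two rates agree to a relative $10^{-9}$, and grouped poles
  are expanded in confluent $t^m e^{-kt}$ terms. Below the grouping
  tolerance a perturbation maps to the identical grouping, so outputs are
  continuous across degeneracies by construction and partial-fraction
  amplitudes can never blow up.
* **IRF convolution through the scaled complementary error function.**
  The exponentially modified Gaussian is evaluated as
  $\tfrac12\,\mathrm{erfcx}(z/\sqrt2)\,e^{-T^2/2\sigma^2}$ on the branch
  where the naive form overflows; erfcx itself switches to its asymptotic
  series beyond argument 25 where the library routine returns NaN.
  Convolutions of $t^m e^{-kt}$ (needed for confluent terms) come from an
  analytic derivative recursion of that closed form, not finite
  differences.
* **Optimizer.** Levenberg–Marquardt (`minpack.lm::nls.lm`) with box
  bounds on a transformed scale: log for times and the IRF width,
  stick-breaking logits for the thiyl yield simplex (two free logits give
  $q_{21}, q_{22}, q_{23}$ that always close to 1 — box bounds alone
  cannot enforce a sum constraint), plain logits for $q_{31}$ and
  $q_{41}$. Cost tolerance $10^{-10}$, parameter tolerance $10^{-8}$,
  200 iterations per start. Multi-start (`n_starts`) jitters initial
  values uniformly within bounds under a fixed seed; the default is a
  single start, which suffices at the default noise level, while the
  0.41/0.45/0.63 ps time-constant cluster can trap the optimizer when the
  data are substantially noisier.
* **Uncertainties.** Gauss–Newton covariance at the optimum scaled by the
  reduced chi-square, mapped to the natural scale by the delta method; a
  residual-resampling bootstrap (`bootstrap_uncertainties()`) is the
  cross-check. A degenerate Jacobian flags the errors as unavailable
  rather than fabricating them.
* **Degenerate inputs.** Infinite time constants are explicit sentinels;
  chains containing an intermediate zero rate contribute exactly zero
  downstream; `sigma = 0` IRF reduces to the bare causal exponential.
* **Spectra.** Pseudo-Voigt in the Thompson–Cox–Hastings parameterization
  (~1 % of peak height accuracy, ample for eV-scale linewidths) by
  default; the exact Voigt via Weideman's 24-term Faddeeva expansion
  behind `profile = "voigt"`. The default Lorentzian FWHM for sulfur
  K-edge lines in the CLI line-list reader is 0.6 eV, a configuration
  value representing the natural core-hole linewidth scale, not a fitted
  claim. Line amplitude is integrated area, so a pure Lorentzian of
  area 1 peaks at $2/(\pi\,\mathrm{FWHM})$.

## The synthetic-data generator

`experiment_design()` emulates the structure of measured delay scans:
three channels at 2466.8/2468.2/2472.0 eV, a delay grid linear from −1 ps
to 5 ps (0.1 ps steps) then logarithmic to 800 ps (30 points), Gaussian
per-point noise, and optionally a shot-level mode in which each delay
point is the mean of 600 simulated shot measurements and the reported
uncertainty is their sample standard deviation. A seeded random-walk
drift term (off by default) mimics slow experimental parameter drift.
Seeds are mandatory; identical seeds give bit-identical traces.

**Noise calibration.** The measured scans' point uncertainties are not
published numerically, so the default per-point noise (`noise_sd = 0.004`
on the edge-normalized ΔA scale, equal for all channels) was calibrated
once against the published parameter uncertainties: at this level the
Fisher-information (expected) standard errors of the default design match
the published ± values closely — τ₁: 0.017 vs 0.02, q₂₁: 0.019 vs 0.02,
τ₂₂: 0.7 vs 0.5, σ_IRF: 0.005 vs 0.006 ps — i.e. the synthetic experiment
carries the same information content as the real one. Amplitude defaults
put the thiyl channel peak at 17 % of the parent edge jump, its reported
magnitude.

What the generator does **not** emulate: photon statistics and detector
response (noise is phenomenological Gaussian), channel-dependent noise
(supported but defaulted equal), long-term drift (off by default), and
any spectral overlap beyond the single 8 % scalar. Passing recovery tests
therefore demonstrates that the estimator is unbiased and correctly
calibrated *under the stated noise model* — not that every systematic
effect of a beamline measurement is handled.

## Problem sizes in the shipped tests

The test-suite fits use either the full default design (273 points,
3 × 91 delays) or a coarse variant (147 points) where only estimator
mechanics are probed; the acceptance study runs 50 seeded replicates of
the full design, chosen so the median estimate is stable to well within
the published uncertainty of every parameter. The analytic solver is
cross-validated against direct stiff ODE integration (`deSolve::lsoda`,
tolerances $10^{-10}$) on 100 random schemes with time constants spanning
0.05–500 ps.

## Known limitations

* The model topology is fixed; no model selection across alternative
  reaction schemes is provided.
* Covariance-based errors are symmetric-Gaussian approximations; for
  weakly identified parameters (notably $\tau_{41}$ when the perthiyl
  signal is shallow) the bootstrap or the recovery study is the honest
  instrument.
* The spectral decomposition is a generic weighted lineshape fit; it does
  not replicate any particular published lineshape-analysis protocol.
* Populations are linear in excitation fraction: multi-photon effects and
  excitation-density dependence are out of scope.
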
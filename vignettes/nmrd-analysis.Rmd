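---
title: "Decomposing NMRD profiles of soft matter: model, fitting strategy and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing NMRD profiles of soft matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdfit)
```

## The model

Fast field-cycling (FFC) relaxometry measures the proton spin-lattice
relaxation rate $R_1$ as a function of Larmor frequency $\nu$, here over
10 kHz–10 MHz. For $^1$H-rich soft matter the dominant relaxation channel
is the fluctuating $^1$H–$^1$H dipole–dipole interaction, and each
motional process with correlation time $\tau$ contributes a Lorentzian
spectral-density term. `nmrdfit` fits

$$R_1(\nu) \;=\; \sum_{k} C_k^{DD}\left[
\frac{\tau_k}{1 + (\omega\tau_k)^2} +
\frac{4\tau_k}{1 + (2\omega\tau_k)^2}\right] \; + \; A,
\qquad \omega = 2\pi\nu,$$

with 1–4 components $k$. $C_k^{DD}$ (Hz²) is a dipolar relaxation
constant — a structural prefactor proportional to the amount of protons
relaxing through that motion — and $\tau_k$ (s) the correlation time of
the motion. $A$ (s⁻¹) absorbs relaxation by motions much faster than the
window probed (sub-nanosecond internal dynamics): within the window their
Lorentzians are flat, so only an offset is identifiable. For gelatin-based
jelly candies three components suffice, conventionally labelled *slow*
($\tau \sim 10^{-6}$ s, macromolecular tumbling and network-bound water),
*intermediate* ($\tau \sim 10^{-7}$ s, water confined in the gel matrix)
and *fast* ($\tau \sim 10^{-8}$ s, loosely bound water).

Useful closed forms, used as test oracles throughout:
$R_1(0) = 5\sum_k C_k\tau_k + A$ exactly; $R_1$ is strictly non-increasing
in $\nu$; and $R_1 \to A$ as $\nu \to \infty$ with the residual bounded by
$5\sum_k C_k \tau_k / (\omega \tau_{\min})^2$.

Public interfaces take $\nu$ in Hz and convert to angular frequency
internally, once. All quantities are carried in base SI-derived units
(Hz² for $C^{DD}$, s for $\tau$, s⁻¹ for $R_1$ and $A$); there is no unit
conversion layer.

## From recovery curves to R1 points

Each $R_1(\nu)$ point comes from a magnetization-recovery curve fitted
with the three-parameter single exponential
$M(t) = M_{eq} + (M_{init} - M_{eq})e^{-R_1 t}$, which covers both
saturation and inversion recovery without a sign constraint. Points
inside the field-switching (dead) time — 3 ms by default, configurable —
are discarded; at least six must survive.

Two flags accompany every fit:

* **Measurability.** During the dead time nothing is observed, so when
  `exp(-R1 * dead_time)` falls below `1 - loss_threshold` (default: 95%
  of the recovery lost) the rate is declared unmeasurable. This is the
  mechanism behind missing low-frequency points when relaxation is very
  fast; the instrument literature states no sharp cutoff, so the 95%
  convention is a documented package choice. With the default 3 ms it
  corresponds to $R_1 \gtrsim 10^3$ s⁻¹.
* **Mono-exponentiality.** A Wald–Wolfowitz runs test on the signed
  residuals (normal approximation, reject at $p < 0.01$) combined with a
  residual-RMS-versus-noise ratio (fail above 5×, noise estimated from
  first differences of the residuals). Thresholds were calibrated on
  synthetic curves: single exponentials with 1% noise pass in ≥ 95% of
  seeds; an equal-amplitude bi-exponential with rates 10 and 1000 s⁻¹
  fails in all of them. When only the tail of a fast recovery is
  detected the fitted rate may be biased; the package flags, it does not
  correct.

The reported $R_1$ uncertainty is the 1σ covariance estimate with the
residual variance floored at $(10^{-8}\,\Delta M)^2$, so that even
noise-free fits report the geometry of information loss (the uncertainty
grows monotonically as early points are truncated away).

## Fitting dispersion profiles

Weighted least squares with Levenberg–Marquardt (via `minpack.lm`).
Design choices that matter:

* **Log-parameterization.** All $C$ and $\tau$ are optimized in log10
  space — they are positive and span 10⁷–10⁹ Hz² and 10⁻⁹–10⁻⁶ s — with
  generous bounds (log10 C in [2, 13], log10 τ in [−11, −3]); $A$ stays
  linear with a lower bound of 0.
* **Weighting.** $1/\sigma^2$ with supplied uncertainties, else
  relative weighting $1/R_1^2$: profiles span two decades in $R_1$ and
  FFC noise is close to multiplicative.
* **Initialization and multi-start.** $\tau$ starts on the decades the
  window covers ($10^{-6}, 10^{-7}, 10^{-8}$ s for three components),
  $A$ at 80% of the high-frequency plateau, and each $C$ sized so the
  components reproduce the low-frequency rate. Five starts by default,
  the first unjittered, the rest jittered by 0.4 decades under the
  caller's seed. In multi-profile fits each profile is first prefit
  individually and the global optimization starts from those solutions —
  markedly more reliable than starting a 30-parameter problem from the
  raw heuristic. Component labels are rank conventions (slow →
  longest τ), so fits are relabelled canonically whenever no component
  parameter is fixed.
* **Constraints.** A `constraint_map()` declares every
  (parameter × profile) slot free, fixed at a value, or shared within a
  named group; shared groups take a single optimizer slot, so members
  are bit-identical in the result, and fixed slots never enter the
  optimizer. Over-constrained maps evaluate without fitting (with a
  warning); under-determined ones warn about rank deficiency.
  `catalog_constraint_map()` derives the packaged catalog's own scenario
  from its fixed flags and repeated value ± uncertainty entries.
* **Uncertainties.** 1σ from the residual-variance-scaled Gauss–Newton
  covariance, transformed back to linear scale. The catalog's source
  tables do not state how their uncertainties were estimated; these
  covariance-based values are this package's convention and need not
  coincide.
* **Degeneracy.** Correlation times of adjacent components within a
  factor of 3 trigger a merge-suggestion warning rather than silent
  acceptance.

**Component-count selection** fits $k = 1 \dots k_\max$ and minimizes
$\mathrm{AIC} = n\log(\chi^2/n) + 2p$; models within 2 AIC units of the
minimum resolve to the smallest $k$. On noise-free three-component
profiles this selects $k = 3$ deterministically: the third component
improves $\chi^2$ by orders of magnitude while a fourth only pays the
parameter penalty.

**The parsimony search** formalizes the strategy of explaining a
temperature pair with as few free parameters as possible. Starting from
the fully-shared fit it frees blocks in the fixed order
(C_i, τ_i) → τ_s → C_f → C_s → A, keeping a block only when AIC drops by
at least 10 (a decisive-evidence threshold; configurable). The
intermediate block leads because temperature predominantly depletes the
confined-water fraction, the dominant effect observed in this system.
Each trial is warm-started from the incumbent solution, so freeing a
block can never increase $\chi^2$ and the trace is monotone.

## Fingerprint comparison

Authentication-style comparisons reduce a pair of profiles to the mean
absolute difference of $\log_{10} R_1$ over a common grid (24 log-spaced
points on the intersection of uncensored spans; log-log linear
interpolation, never extrapolation). A distance of 0.01 ≈ 2.3% relative
difference in $R_1$. Profiles are grouped by single-linkage clustering
cut at 0.03 (≈ 7%), a threshold calibrated so that independent 2%-noise
realizations of one generator co-group (their expected distance is
≈ 0.01) while the closest distinct parameter rows in the catalog stay
apart (≥ 0.04 between noise-free curves). The visual-overlap judgement
this replaces is inherently qualitative; the threshold is a documented
convention, not a claim about how the original groupings were drawn.

## The synthetic-data generator

`make_profile()` evaluates a model on a grid (default: 32 log-spaced
points, 10 kHz–10 MHz — the stated experimental range) and applies
independent multiplicative Gaussian noise, 2% by default, a typical FFC
instrument specification; the deposited raw data were not used, so the
noise level is a convention. Censoring is applied from the *true* rate
through the measurability rule, which keeps the mechanism exactly
consistent between generator and analysis. `make_recovery()` adds
additive noise scaled to the recovery amplitude. Everything is seeded
and byte-reproducible; per-profile seeds derive from one top-level seed.

`make_dataset()` emits one profile per catalog row: 12 Haribo profiles
(six jellies × two temperatures, with bear/phantasia and
tropifruity/color-rado sharing parameter rows), six Vidal profiles at
323 K, and — because no 298 K Vidal parameters exist (at room
temperature the low-frequency relaxation was too fast to measure) — six
*emulated* 298 K Vidal profiles, produced by reusing the 323 K
parameters with all correlation times doubled. The emulation is a
synthetic-only convention, flagged `emulated = TRUE`; it exists so the
censoring mechanism has something realistic to act on, and it reproduces
the qualitative picture of missing low-frequency Vidal points.

What the generator does *not* emulate: field-switching transients,
spin–spin-relaxation limits on detectability, temperature drift,
multi-exponential recovery, or correlated noise. Passing recovery tests
therefore demonstrate the estimator's behaviour under the assumed noise
model, not robustness to instrumental systematics.

## Study designs used by the tests

Problem sizes were chosen to characterize the estimators at desk scale:

* *Parameter recovery*: 50 seeds, 32-point profiles at 2% noise,
  fitted under the catalog scenario (`catalog_constraint_map()`), one
  global fit per brand per seed; profiles generated uncensored
  (`dead_time = 0`), since the measured Haribo data span the full range
  and censoring is exercised separately. Noise-free round trips recover
  every catalog row to better than 0.1%.
* *Identifiability limit*: the slow component of Vidal cherry (and, less
  severely, watermelon) is weakly determined by a single 32-point 2%
  profile — the catalog itself quotes ±27% on cherry's $C_s^{DD}$ and
  ±21% on its $\tau_s$. The acceptance suite's recovery medians for
  those slots sit near 19–26%, which is the information content of the
  data, not an optimizer deficiency: the fitted $\chi^2$ falls below the
  $\chi^2$ at the generating truth in essentially every seed.
* *Recovery-curve precision*: 48 delays spanning $7/R_1$ at 2% additive
  noise give a median $R_1$ error below 2%; sparser 16–32-point curves
  cannot reach that figure for a three-parameter exponential at this
  noise level, so the denser acquisition is the package's stated design.
* *Model selection and parsimony*: 20 seeds each; *grouping*: 20 seeds
  plus a deterministic noise-free check.

## Known limitations

* The Lorentzian form assumes isotropic exponentially-correlated
  fluctuations; translational-diffusion spectral densities, quadrupole
  peaks and Arrhenius temperature laws are out of scope.
* Censored points are excluded, never imputed; no bias correction is
  applied to tail-only recovery fits.
* The parsimony search is greedy in a fixed, physically motivated block
  order; it does not explore all $2^5$ sharing patterns.
* AIC is used throughout; with ~30 points per profile the small-sample
  correction (AICc) would penalize the fourth component slightly harder,
  but the selection outcomes here are far from that margin.
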
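---
title: "Multi-exponential backbone dynamics and 15N relaxation back-calculation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-exponential backbone dynamics and 15N relaxation back-calculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ls3relax)
```

## The model

The quantity that couples molecular motion to amide ¹⁵N relaxation is the
rank-2 (second Legendre) autocorrelation of the H–N bond unit vector,

$$C(t) = \langle P_2(\mu(0)\cdot\mu(t))\rangle, \qquad P_2(x) = \tfrac{1}{2}(3x^2-1).$$

For a folded protein this factorizes into internal motion times overall
tumbling. A disordered chain offers no such factorization: segmental
motions and chain reorientation overlap in timescale, and the pragmatic
description is a small sum of exponentials fitted to the *total* (lab-frame)
correlation function,

$$C(t) = \sum_{i=1}^{n} a_i\, e^{-t/\tau_i}, \qquad \sum_i a_i = 1,\quad
a_i \ge 0,\quad n \in \{2,3,4\}.$$

With $n = 3$ (the LS3 decomposition) the terms separate into fast
librational (\(a_1, \tau_1\sim\) ps), intermediate segmental
(\(a_2, \tau_2\sim\) hundreds of ps) and slow tumbling-like
(\(a_3, \tau_3\sim\) ns) motion. The normalization \(\sum a_i = 1\) encodes
\(C(0) = 1\), exact for a normalized rank-2 autocorrelation, so the fit has
\(2n-1\) free parameters.

Because a sum of exponentials transforms term by term, the spectral density
is analytic:

$$J(\omega) = \frac{2}{5}\sum_i \frac{a_i\,\tau_i}{1+(\omega\tau_i)^2},$$

with the conventional 2/5 factor of rank-2 reorientation kept in
\(J(\omega)\) (never in \(C(t)\)), so the rigid-rotor limit is
\(J(0) = \tfrac{2}{5}\tau_m\). The standard dipolar + CSA expressions then
give the observables at a stated field:

$$R_1 = \tfrac{d^2}{4}\left[J(\omega_H-\omega_N) + 3J(\omega_N) +
6J(\omega_H+\omega_N)\right] + c^2 J(\omega_N),$$
$$R_2 = \tfrac{d^2}{8}\left[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
6J(\omega_H) + 6J(\omega_H+\omega_N)\right] +
\tfrac{c^2}{6}\left[4J(0) + 3J(\omega_N)\right],$$
$$\mathrm{NOE} = 1 + \frac{\gamma_H}{\gamma_N}\,\frac{d^2}{4}\,
\frac{6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)}{R_1},$$

with \(d = (\mu_0/4\pi)\hbar\gamma_H|\gamma_N|/r_{NH}^3\) and
\(c = |\omega_N \Delta\sigma|/\sqrt{3}\). No chemical-exchange (\(R_{ex}\))
term is included anywhere: the model describes pure reorientational
relaxation.

### Assumptions

* Isotropic reorientation statistics per residue; no anisotropic or axially
  symmetric diffusion tensors.
* The multi-exponential form is a description, not a mechanism: its
  timescale classes are only as distinct as the fitted \(\tau_i\) are
  separated.
* ACF points are treated as independent observations in least squares and
  in the F-test degrees of freedom \(D = N_{points} - (2n-1)\); serial
  correlation between lags is ignored, which makes the nominal F-test
  significance optimistic. The test is used as a parsimony heuristic, not
  an exact inference.

## Fitting and model selection

`fit_multiexp()` minimizes weighted squared residuals with
Levenberg–Marquardt (analytic Jacobian), parametrizing \(n-1\) free
amplitudes on the simplex (the last is \(1-\sum\)) and \(\log\tau\) within
bounds \([0.01\,\mathrm{ps}, 1\,\mu s]\). Multi-start initialization uses
\(\tau\) log-spaced over the fit window with equal amplitudes, 8 jittered
restarts; the best sum of squares wins, ties broken by the
lexicographically smaller \(\tau\) vector. When fits are run in ascending
\(n\) (as `select_model()` does), the previous solution extended by a
near-zero term is an additional start, which makes the achieved sum of
squares non-increasing in \(n\).

Numerical edge cases:

* **Fit window.** Long-lag ACF estimates from a trajectory average over few
  time origins and are noise-dominated, so the default window runs to 1/5
  of the originating trajectory span when the series carries one (ACFs from
  `compute_p2_acf()` do), otherwise to the last lag. Configurable via
  `options$window_ps`.
* **Near-degenerate timescales.** If two fitted \(\tau\) agree within 5%
  the terms are merged (amplitude-weighted geometric mean) and the fit is
  reflagged as the smaller model; four-exponential fits of three-timescale
  data routinely collapse this way.
* **Non-decaying input.** A \(\tau\) pinned at the upper bound with
  non-negligible amplitude flags the fit as not converged rather than
  returning a silently meaningless timescale.

`compare_models()` implements the nested F-test
\(F = \frac{(SS_i-SS_j)/(D_i-D_j)}{SS_j/D_j}\); a larger model that fits
*worse* (possible with independent restarts) is reported as \(F = 0\) with
a flag. `select_model()` accepts the larger model only when
\(\alpha > 0\) and \(p \le \alpha\), so `alpha = 0` degenerates to the
smallest candidate; the default \(\alpha = 0.05\) is a conventional choice
— the selection outcome for well-separated timescales is insensitive to it
over a wide range.

## Rotating-frame conversion and tumbling times

Off-resonance rotating-frame rates mix \(R_1\) and \(R_2\) through the
effective-field tilt \(\theta\) with \(\tan\theta = B_{SL}/\Delta\omega\)
(\(\theta = \pi/2\) on resonance):
\(R_{1\rho} = R_1\cos^2\theta + R_2\sin^2\theta\). `r2_from_r1rho()` applies
the exact inverse; only the first-order tilted-frame relation is used, with
no higher-order off-resonance corrections — adequate for
\(B_{SL} = 1.5\) kHz spin locks and the offset ranges of amide spectra, and
the convention under which the conversion is its own exact inverse.
First-order error propagation gives
\(\sigma_{R_2}^2 = (\sigma_{R_{1\rho}}/\sin^2\theta)^2 +
(\sigma_{R_1}\cos^2\theta/\sin^2\theta)^2\), which makes the off-resonance
error amplification explicit.

`estimate_tauc()` solves the rigid-rotor (single-exponential, \(S^2 = 1\))
ratio \(R_2(\tau_m)/R_1(\tau_m) = \) observed on the bracket
\([0.05, 200]\) ns. Beyond extreme narrowing the ratio is strictly
increasing in \(\tau_m\) (asserted on a grid in the test suite), so the
root is unique; ratios at or below the extreme-narrowing floor raise an
error reporting the floor rather than returning a boundary value.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `field_mhz` | 600 | MHz | proton frequency of the instrument modeled |
| `gamma_h`, `gamma_n` | 2.6752218744e8, −2.71261804e7 | rad s⁻¹ T⁻¹ | conventional amide model-free values |
| `r_nh_angstrom` | 1.02 | Å | effective N–H distance; rates scale as \(r^{-6}\) |
| `csa_ppm` | −172 | ppm | amide ¹⁵N CSA; enters squared |
| `tau_bounds_ps` | 0.01–1e6 | ps | sub-resolution to beyond any tumbling time |
| `restarts` | 8 | — | multi-start count; noiseless recovery is exact, noisy fits stable |
| `alpha` | 0.05 | — | F-test level for accepting a larger model |
| `b_sl_hz` | 1500 | Hz | spin-lock field of the rotating-frame experiment |
| crowding `scale` | user (1.86 for 160 g/L Ficoll 70) | — | tumbling-time ratio of a rigid reference protein |

Units follow a fixed convention: correlation times in ps inside models,
seconds inside \(J(\omega)\); interface frequencies in Hz, angular
frequencies in rad/s internally.

## The crowding transform

`apply_crowding()` multiplies the slow correlation times — by default every
term but the fastest, matching the view that microviscosity retards
segmental and tumbling-like motion while leaving ps librations untouched —
by a common factor, and optionally replaces the fast amplitude (e.g.
\(a_1 = 0.20\) for a highly crowded state). The replaced amplitude's
complement is redistributed over the remaining terms *proportionally*: the
relative weights of intermediate and slow motion are left unchanged because
nothing in the forward model constrains how they would rebalance. This is
the one genuinely open choice in the transform; any alternative (e.g.
loading the difference entirely onto one term) is a one-line variant of the
same operation.

## Synthetic data: what it emulates, and what it does not

Every pipeline input can be generated with known ground truth and a fixed
seed (all generators are bit-reproducible):

* `gen_multiexp_acf()` — model ACF plus i.i.d. Gaussian noise (none at lag
  0). Real trajectory ACF noise is serially correlated and grows with lag;
  the i.i.d. fixture isolates the fitter from the estimator.
* `gen_rotdiff_trajectory()` — small-step isotropic rotational Brownian
  motion: each step rotates the vector about a uniformly random
  perpendicular axis by a Gaussian angle of variance \(4D_r\Delta t\), the
  mean-square angular displacement of a direction diffusing on the sphere,
  giving \(C_2(t) = e^{-6D_r t}\) exactly in the small-step limit. Steps
  with \(6D_r\Delta t > 0.1\) warn, \(> 0.5\) error.
* `gen_cone_tumbling_trajectory()` — wobble in a cone (reflecting boundary)
  riding on an isotropically tumbling frame; the ACF decays to a plateau
  near \(S^2\) with \(S = \cos\theta_0(1+\cos\theta_0)/2\) before the
  global decay.
* `gen_intensity_decays()` — exponential peak-intensity decays on the
  standard amide schedules (10–640 ms for \(R_1\), 10–150 ms for
  \(R_{1\rho}\)) with relative Gaussian noise.
* `gen_residue_ensemble()` — per-residue three-term models drawn around the
  population values \(\tau = 7\pm9, 419\pm454, 3400\pm5700\) ps and
  \(a = 0.37\pm0.09, 0.36\pm0.12, 0.27\pm0.17\).

Two distributional choices in the ensemble generator deserve explanation.
Correlation times are drawn from **moment-matched lognormals** rather than
truncated normals: with SDs exceeding the means (7±9 ps!), a normal over a
positive variable cannot reproduce the stated moments — truncation rejects
a quarter of the mass and shifts the mean by a third — whereas the
lognormal matches mean and SD exactly and carries the heavy right skew such
fit populations imply (most residues below the mean, a few far above).
Amplitudes, whose SDs are comfortably below their means, stay truncated
normal (at \(\ge 0.01\), renormalized to the simplex). Ordering
\(\tau_1<\tau_2<\tau_3\) is enforced by **resampling whole draws**, not by
sorting, so each marginal keeps its own distribution.

What passing tests on these fixtures do *not* show about real data: no MD
force-field realism, no chain connectivity (residues are drawn
independently, so joint \(a_i/\tau_i\) correlations along a real chain are
absent), no crowder physics beyond the single viscosity factor, no
spectral-processing artifacts in the intensity fixtures.

## Problem sizes and stochastic test design

The test suite fixes its own problem sizes. Fits use a mixed lag grid
(1 ps steps to 20 ps, coarsening to 50 ps steps at 20 ns; ~500 points) that
resolves all three Table-level timescales; the noiseless recovery check
uses 1 ps sampling over 50 ns. Selection frequency is measured over 100
seeds at noise sd 0.005. For the trajectory oracle, a single 20,000-frame
(200 ns) record of a 5 ns process carries sampling error in an ACF-fitted
\(\tau\) on the order of \(\sqrt{2\tau/T}\), i.e. tens of percent — an
intrinsic property of the path statistics, not of the estimator — so the oracle test averages the P₂ ACF over 16
independently seeded vectors before fitting, the same per-residue ensemble
averaging used on real trajectories, bringing sampling error within a few
percent; a deliberately loose single-trajectory check documents the scatter.

Monte-Carlo uncertainties in `fit_decay()` (500 residual-resamples by
default) are seeded and bit-reproducible; covariance-matrix standard errors
are available as an option.

## Known limitations

* Forward-only: the package back-calculates rates from dynamic models; it
  does not fit experimental \(R_1/R_2\)/NOE to extract model parameters.
* Isotropic reorientation only; no reduced spectral-density mapping, no
  cross-correlated relaxation, no \(R_{ex}\).
* The F-test inherits the independence approximation discussed above.
* Under viscosity scaling, \(R_2\) rises for every model with slow-term
  weight (a \(J(0)\) statement, proved as a property test), but \(R_1\) and
  the NOE need not: \(J(\omega_N)\) peaks at \(\tau \approx 1/\omega_N\)
  (~2.6 ns at 600 MHz), so residues whose slow times already exceed the
  turnover see \(R_1\) *fall* when those times are scaled up. Ensembles
  drawn independently from the population moments above place substantial
  \(\tau_3\) mass beyond the turnover, so a uniform rise of all three
  observables across a whole synthetic ensemble is not a property of this
  generator — only of particular per-residue parameter sets.
* Binary trajectory formats (XTC/TRR/DCD) are out of scope; vectors arrive
  as text.
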
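---
title: "Models and methods behind nirsmotor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirsmotor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nirsmotor` implements a complete analysis chain for continuous-wave fNIRS
recordings of the primary motor cortex under three paradigms — a blocked
finger-tapping task, a single walking bout, and an eyes-closed resting
state — together with a forward simulator that generates recordings with
known ground truth.  This vignette explains the models, the tunable
parameters, the numerical choices, and what the validation on simulated
cohorts does and does not establish.

## The measurement model

A channel is a source–detector pair on the scalp.  The montage
(`default_probe()`) has 10 sources and 8 detectors forming 20 long channels
(30 mm separation, 10 per hemisphere) over bilateral motor cortex and 2
short channels (15 mm, one per hemisphere) that sample mostly scalp
hemodynamics.  Channels separated by less than 20 mm are classified as
short; every long channel has a declared contralateral mirror homolog.
Dual-wavelength LEDs at 757 and 843 nm sample at 25 Hz.

Light attenuation follows the modified Beer–Lambert law.  With intensities
$I_\lambda(t)$ and a baseline reference $I^0_\lambda$, the optical-density
change is $\Delta OD_\lambda = -\log_{10}(I_\lambda / I^0_\lambda)$, and

$$\Delta OD_\lambda(t) = \varepsilon_{\lambda,HbO}\,\Delta HbO(t) +
  \varepsilon_{\lambda,HbR}\,\Delta HbR(t),$$

with a partial pathlength factor of 1 at both wavelengths, so concentration
changes carry units of µM·mm.  The bundled extinction coefficients are
interpolated at 757/843 nm from the standard compiled hemoglobin
absorption spectrum used across the field; they can be overridden.  Solving
the 2×2 system per sample gives HbO and HbR; HbT is their exact sum.

One numerical caveat is inherent to CW fNIRS: with the conventional
temporal-mean reference, absolute concentration offsets are not
identifiable, only changes.  `intensity_to_od()` therefore accepts an
explicit baseline reference; when the simulator's true baseline is
supplied, the conversion is the exact inverse of the forward model (the
package's round-trip tests exercise this at better than $10^{-10}$
relative error).

## Preprocessing

The task chain is prune → OD → motion detection → spline correction →
wavelet correction → trial rejection → 0.01–3 Hz band-pass → Beer–Lambert;
the resting-state chain replaces the last stages with the connectivity band
(0.009–0.08 Hz).  Stage functions check the recording kind, so the order
cannot be violated accidentally.

* **Pruning** keeps a channel when its mean raw intensity lies in
  $[10^{-7}, 10^{7}]$ a.u., its SNR (temporal mean/sd) reaches 2 at both
  wavelengths, and its separation lies in the configured range.  The range
  is expressed in meters (default upper bound 0.45 m), which for this probe
  imposes no effective separation limit — 0.45 in mm or cm would prune
  every channel.
* **Motion detection** slides a 1 s window per channel and wavelength; a
  window triggers when its max–min change exceeds 0.5 OD or its sd exceeds
  15× the channel's median windowed sd.  The median is the robust baseline
  for the fold-change rule; 1 s of data around the excursion is masked, and
  a sample flagged at either wavelength is flagged for the channel.  The
  flagged set grows monotonically as the amplitude threshold is lowered.
* **Spline correction** replaces each artifact segment by its residual
  around a smoothing-spline fit, re-leveled to the adjacent clean segment
  means (a single neighbor at record boundaries).  The smoothing parameter
  $p = 0.99$ follows the fidelity-versus-roughness convention in which
  $p \to 1$ approaches interpolation; it maps to the penalty
  $\lambda = (1-p)/p$.  Implementations normalize this trade-off
  differently; the mapping preserves the intent (a nearly interpolating
  fit whose residual keeps the physiological high-frequency content).
* **Wavelet correction** uses a periodized orthogonal Daubechies-5
  transform, implemented in the package (decomposition depth
  $\min(\lfloor\log_2 n\rfloor - 4,\ 8)$).  At each detail level,
  coefficients outside the Tukey fences (1.5×IQR) are zeroed.  Periodic
  boundary handling makes the analysis operator orthogonal, so
  reconstruction is exact to machine precision when nothing is zeroed.
* **Trial rejection** drops any trial with a masked sample on a kept
  channel within −2 to 10 s around onset.
* **Filtering** is a zero-phase (forward–backward) order-3 Butterworth
  band-pass.  Measured responses: the connectivity band passes 0.05 Hz
  with gain > 0.94 and attenuates the 1.1 Hz cardiac line by far more
  than 20 dB; the task band passes 0.1–1 Hz with gain > 0.99.

## HRF estimation

Per channel and chromophore, the concentration series is regressed on:

* a train of Gaussians (sd 0.5 s, so roughly 1 s wide) centered every 1 s
  across the −2 to 25 s window, placed at each accepted onset of each
  condition (28 basis columns per condition);
* orthogonalized polynomial drift terms of order 0–3 over the record
  (Legendre-style, for conditioning);
* one short-channel nuisance series per long channel — the short channel
  with the largest absolute Pearson correlation with that channel,
  computed on the same chromophore over clean samples.  Largest $|r|$ and
  smallest p coincide at fixed n, so the "most significant" short channel
  is the most correlated one.

Ordinary least squares gives the weights; the estimated HRF is the basis
expansion on the window grid.  The walking bout uses the same machinery as
a single trial.  Five scalar features summarize each curve over
$t \in [0, 25]$ s: the signed extremum of largest magnitude (so HbR
deactivations keep their sign), its time (time-to-peak), the trapezoidal
area under the curve, the time average, and the least-squares slope from
onset to the peak.  A flat curve yields the degenerate convention
peak = time-to-peak = slope = 0, flagged.  Features are computed per
subject, on subject-level curves, and AUC/mean use the full 0–25 s window
(configurable); the 0–10 s task-only alternative changes AUC and mean by a
scale factor but not the group contrasts in simulation.

## Superficial-signal removal and connectivity

For connectivity, the short channels are averaged,
$s(t) = \tfrac1n \sum_i y_i(t)$, and regressed out of every channel with a
Tikhonov-regularized estimator

$$\beta_g = [s^\top s + \lambda^2 I]^{-1} s^\top Y, \qquad
  \lambda = 0.001\,\max\{\mathrm{diag}(s^\top s)\},$$

fitted on motion-free samples only; the residual $Y' = Y - s\,\beta_g$
feeds the channel-by-channel Pearson correlation matrix (pairwise over
jointly clean samples, minimum 30 per pair).  With a single mean short
series $s^\top s$ is scalar, so the policy reduces to
$\lambda = 0.001\,s^\top s$, and the estimator uses $\lambda^2$ exactly as
written; at $\lambda = 0$ it is ordinary least squares.  Correlations are
Fisher-transformed, $z = \tfrac12\ln[(1+r)/(1-r)]$, after clamping to
$\pm(1 - 10^{-6})$ so perfect correlations map to a finite sentinel.

The interhemispheric index is the mean $z$ over the 10 homolog pairs; the
intrahemispheric indices average the 45 within-hemisphere long-channel
pairs per side (long channels only, no self-pairs; short channels never
enter).  Regression and correlation operate on hemoglobin series (after
Beer–Lambert), consistent with the stage order of the resting-state
chain.  The same machinery applies to the walking bout band-passed to the
connectivity band.

## The statistical layer

Channel activation uses a paired t-test of task-window versus
baseline-window means across subjects.  Group contrasts use the two-sided
Wilcoxon–Mann–Whitney test — exact enumeration when the pooled sample is
at most 20 without ties, the tie-corrected normal approximation otherwise
— applied to HRF features and, for connectivity, to the Fisher-z indices.
A Shapiro–Wilk gate records normality per feature and forces the
nonparametric branch.  Clinical correlations are Spearman's rho over PD
subjects, restricted to channels passing the group-difference gate, with
Benjamini–Hochberg adjustment inside explicitly declared families; every
test result carries its `family_id`, so no comparison leaves the module
without a declared multiplicity context.  Families are kept separate per
(condition × chromophore × feature) for feature contrasts, per chromophore
for connectivity, and pooled across the gated channel set for clinical
correlations; this mirrors per-contrast reporting and is configurable.
Partial correlations rank-transform all variables, residualize feature and
clinical ranks on the control ranks (age, education) by least squares
within side-of-onset strata, and use the t approximation with
$n - 2 - k$ degrees of freedom.

## The simulator

The generator is first-class, tested code; its defaults are the study
conditions the analysis assumes.

* **Paradigms.** Task: 20 tapping blocks of 10 s (10 per hand, seeded
  random order) with rests uniform on 20–24 s, ~11 min total.  Walk: 20 s
  standing baseline, one 2-min bout.  Rest: 6 min.
* **Evoked model.** The per-block response is a difference-of-gammas curve
  (main lobe peaking at 6 s, undershoot near 16 s at 1/6 depth) normalized
  to a configurable peak amplitude; latency shifts translate the curve
  exactly and width scales stretch it.  The block response is modeled
  directly by this family rather than as an impulse response convolved
  with the 10-s boxcar: with a fixed block length the two
  parameterizations span the same curve shapes, but the direct form makes
  the amplitude and latency parameters identical to the ground-truth peak
  and time-to-peak, so recovery error is measurable without deconvolution
  conventions entering the comparison.  The hemisphere contralateral to
  the tapping hand receives the full amplitude, the ipsilateral side a
  0.25 fraction.  HbR is −1/3 of the evoked HbO component plus independent
  noise.  Disease-like defaults: dominant-hand amplitude ×0.6, latency
  +2 s; non-dominant ×1.4, +2 s; per-subject lognormal amplitude scatter
  (sd 0.1) and Gaussian latency scatter (sd 0.3 s).
* **Physiology and noise.** A shared low-pass-filtered superficial process
  (sd 0.3 µM·mm) enters every channel with channel-specific gains — the
  short channels sense it nearly cleanly — plus sinusoidal systemic
  components (cardiac 1.1 Hz, respiratory 0.25 Hz, Mayer 0.1 Hz at
  0.10/0.05/0.05 µM·mm with random phases) and white noise (0.05 µM·mm).
  The superficial and systemic components carry a smaller HbR fraction
  (−0.1) than the evoked response, reflecting their predominantly
  oxygenation-driven origin; this also keeps the scalp signal optically
  visible at both wavelengths instead of near-cancelling at 757 nm.
* **Resting-state coupling.** Long-channel latent signals are white noise
  colored by a matrix square root (eigendecomposition, so exactly
  representable semidefinite targets such as perfect homolog coupling are
  allowed; indefinite targets are rejected) of a target correlation matrix
  with homolog pairs at `rho_inter`, within-hemisphere pairs at
  `rho_intra`, and non-homolog cross pairs at their product, then
  band-limited to 0.009–0.08 Hz and scaled to 0.5 µM·mm.  Defaults: 0.6/0.5
  for controls, 0.3/0.4 for the disease-like group.
* **Motion artifacts.** Poisson-timed (0.5/min) spikes (half-cosine,
  ≤ 1 s) and transient baseline shifts (2–6 s), with OD magnitudes drawn
  log-uniformly in 2–10× the 0.5 OD detection scale, applied
  multiplicatively to both wavelengths and logged.  Shifts are transient
  rather than persistent so that re-leveling the corrected segment to its
  clean neighbors is well-defined on both sides.
* **Clinical table.** Demographics and disease scales are drawn with the
  cohort's published group-level moments; the MoCA score of disease-group
  subjects is coupled negatively (3 points/s) to their evoked latency so
  the correlation stage has a recoverable signal.

Everything is deterministic given the configuration and master seed;
per-subject and per-paradigm seeds are derived arithmetically, and
regenerating any session reproduces it bit-for-bit.

## What the simulations establish — and what they do not

The validation suite shows, on simulated cohorts: exact forward/inverse
consistency of the optical model; recovery of evoked timing within the
basis resolution and of amplitude within a few percent; strict improvement
from short-channel regression when superficial contamination is present;
recovery of interhemispheric coupling in {0.2, 0.4, 0.6} to within ±0.05;
detection of a 0.3 coupling deficit and of a 2 s latency delay with high
power at n = 20 per group; nominal type-I level of the activation, group
and correlation tests and of the BH procedure under the null; and ≥95%
motion-artifact detection with ≥50% artifact-variance reduction.

The generator emulates the statistical structure the analysis assumes — it
is not a biophysical model.  It does not simulate photon transport through
layered tissue, spatially varying sensitivity, optode-scalp coupling
drift, serial correlations in the measurement noise, or non-sinusoidal
systemic waveforms.  Passing these tests therefore demonstrates the
estimators' correctness and calibration under the assumed signal model,
not performance bounds on any particular real dataset.

Problem sizes in the validation runs are chosen for a laptop-class single
core: the full cohorts use the complete 22-channel montage, while the
replicated power studies use a reduced montage of the same construction
(2 long pairs + 2 shorts) — per-channel statistics are unaffected by the
montage width, and the replication counts (50–100) follow the study's
design.

## Known limitations

* With CW measurements the absolute concentration baseline is
  unidentifiable; all quantities are changes relative to a reference.
* The Tikhonov policy is implemented exactly as printed
  ($\lambda^2$ in the normal equation with $\lambda$ proportional to
  $s^\top s$); because the policy scales with signal power, the effective
  shrinkage is mild.  The `lambda` argument exposes the scalar for
  sensitivity analyses.
* Spline and wavelet correction run back-to-back, as in the processing
  chain this package follows; each is individually switchable, and their
  relative contribution is data-dependent.
* Homolog pairing must be declared for real probes; mirror-symmetry
  inference (`infer_homologs()`) is a convenience for simulated or
  symmetric layouts, not a registration method.
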
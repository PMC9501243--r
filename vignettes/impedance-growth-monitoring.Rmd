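---
title: "Monitoring bacterial growth from impedance spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring bacterial growth from impedance spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eisgrowth)
```

## The measurement and the model

Electrochemical impedance spectroscopy applies a small sinusoidal voltage
across an electrode pair immersed in the culture and records the resulting
current over a frequency sweep (here 10 Hz–1 MHz). The complex impedance
Z = V/I at each frequency is converted from polar to rectangular form, and
only its imaginary part — the reactance X, in Ω — is modelled: suspended
ions and bacterial cells act predominantly as *reactive* elements, and
standard Randles-circuit fits describe such cultures poorly.

The reactance model is a sum of fractional-order Laplace-domain elements
evaluated at s = jω on the principal branch, (jω)^p = ω^p e^{jpπ/2}:

$$X(\omega) = a_0 + b_0\,\omega^{p_1}\sin(p_1\pi/2)
            + c_0\,\omega^{-1/2}\sin(-\pi/4)
            + d_0\,\omega^{p_2}\sin(p_2\pi/2).$$

* **a0** (Ω) — a constant reactive offset, associated with the ill-defined
  high-frequency semicircle of the Nyquist trace. It is deliberately kept
  *inside* the fitted reactance (not treated as a pure resistance excluded
  from the imaginary part): the parameter time-courses report −a0 with
  replicate error bars, which is only meaningful if a0 participates in the
  reactance fit.
* **b0** (exponent p1, default −1.5) — the fractional "supercapacitor".
  Note on units: a coefficient multiplying s^−1.5 is not a capacitance in
  Farad in the SI sense even though supercapacitor language is used for it;
  `eisgrowth` stores b0 as a raw coefficient with pseudo-units
  Ω·(rad/s)^1.5 and reports −b0 for plotting.
* **c0** (exponent fixed at −0.5) — the Warburg diffusion element. Its
  complex form is Z_W = A_W ω^{−1/2}(1 − j): constant −45° phase at every
  frequency, the 45° straight line in the low-frequency Nyquist region.
  The −0.5 exponent is never freed; diffusion physics pins it.
* **d0** (H, exponent p2, default +1) — series inductance from the wiring,
  typically of order 10⁻⁵ H. It is small but cannot be frozen at a nonzero
  constant without destabilising the fit, so it is always estimated (an
  option fixes d0 = 0, which is viable for rise-and-decline cultures whose
  fits are insensitive to it).

A structural caveat: the composite model is assembled from the element
definitions (capacitor 1/(k1 s), inductor k2 s, Warburg) with the Warburg
exponent fixed at −0.5 and p1, p2 the only free exponents. Degenerate
settings reproduce the ideal elements exactly, and the test-suite asserts
these limits against direct complex-arithmetic oracles.

## Fitting

**Fixed-exponent stage.** With p1 and p2 pinned the model is linear in
(a0, b0, c0, d0). The fit is therefore an exact linear least-squares solve
on the design matrix
[1, ω^{p1} sin(p1π/2), ω^{−1/2} sin(−π/4), ω^{p2} sin(p2π/2)]. The raw
columns span ~14 orders of magnitude across a 10 Hz–1 MHz sweep, so the
solver equilibrates columns to unit norm before a pivoted QR; agreement
with a naive closed-form solve is at the 10⁻¹³ relative level, far inside
the 10⁻⁸ the test suite demands. Rank deficiency (frequencies that cannot
separate the terms) is a hard error.

**Free-exponent stage.** Releasing p1 ∈ [−3, −0.01] and p2 ∈ [0.01, 2]
makes the problem nonlinear. `eisgrowth` uses variable projection: the
optimizer searches only (p1, p2) — L-BFGS-B within the box, iteration cap
50,000 per start — and the four coefficients are profiled out by the exact
linear solve at each candidate pair. This has the same optimum as a joint
six-parameter nonlinear fit but a two-dimensional, smooth, well-scaled
search space. A fixed, deterministic multi-start list ((−1.5, 1) plus four
spread-out pairs) guards the nonconvex landscape; no randomness enters the
fit, so identical inputs give bit-identical results. If every start fails
the best-effort parameters are returned flagged `converged = FALSE` rather
than raising.

**Loss.** The minimised quantity is the plain sum of squared *signed*
reactance residuals. Unweighted is the minimal defensible choice when the
acquisition noise model is unknown; 1/|X| and 1/|Z| weightings are exposed
in `fit_config()` for heteroscedastic data. The fitted quantity is X
itself; negation to −a0 … −d0 happens only in reporting
(`negated_report`), matching the plotting convention.

**Replicates.** Each reactor is fit independently; parameters are then
summarised per (condition, hour) by the mean and *sample* standard
deviation across the (default three) reactors. The dispersion statistic
across replicates is not uniquely dictated by convention (SD vs SEM vs
range); sample SD was chosen and is propagated downstream.

**Identifiability limit worth knowing.** The ω^{−1.5} and ω^{−0.5} columns
are nearly collinear over a five-decade sweep, so the *free* exponent p1 is
weakly identified under noise: at 1 % relative reactance noise its estimate
scatters by several hundredths even though the optimizer demonstrably finds
the global minimum. Exponent freeing is therefore a model-selection tool
for clean or averaged spectra; routine tracking should use the fixed-exponent
stage, which is immune to this (the coefficients remain well determined).

## From parameters to biology

"CFU count" always means log10(CFU/mL). Plate counts convert as
log10(count/(dilution × plated volume)); the plated volume is rarely
recorded alongside, so it defaults to the standard spread-plate 0.1 mL and
only shifts the additive constant. A zero count is reported as a finite
below-detection sentinel (one log below the single-colony concentration of
that dilution), never −∞.

During exponential growth −b0 tracks the CFU count approximately linearly.
`correlate_supercap_cfu()` regresses the replicate-mean −b0 (y) on the CFU
count (x) inside the exponential window — manual by default (0–6 h for a
riser culture), or automatic as the longest contiguous run of per-step
log-CFU slopes above half the maximum slope. Fit times match CFU times by
nearest neighbour within 0.5 h (hourly sampling implies aligned clocks, but
alignment is never guaranteed, so the tolerance is explicit and
configurable).

The slope's standard error is obtained by propagating the replicate spread
(b0 SD / √n, pooled across the window's points) through the OLS slope
weights. The naive residual-based SE has only n − 2 ≈ 4 degrees of freedom
in an hourly window and is badly unstable; the pooled estimator carries
roughly twelve and was verified (60-seed calibration) to cover the
generating slope at the nominal 3-SE rate. The residual SE remains the
fallback when no replicate spread is available.

Pb(II) presence is classified by a threshold on log10|b0|: the midpoint of
the two class means. A query exactly on the threshold is called absent —
ties break toward the smaller-magnitude class so that only clear
enlargement of |b0| flags lead. The classifier is monotone in the query.
Residual Pb(II) series are carried as observational context; no uptake
kinetics are fit.

## The synthetic experiment

The generator emulates the study design end to end: two conditions (with /
without an 80 mg/L Pb(II) dose), three replicate reactors, hourly samples
over 1–10 h, 61-point log-spaced sweeps (12 points/decade, enough to
resolve all four terms).

* **Growth.** Two presets. `kpneumoniae_like`: saturating rise in log-CFU
  space, L(t) = K − (K − n0)e^{−rt/(K−n0)}, leaving the inoculum
  (n0 = 6) at slope r = 0.5 log-units/h and levelling at K = 9 — slope
  exactly r far below capacity, since exponential growth is linear in log
  counts. `pbifermentans_like`: the same rise (r = 0.6) up to a 9 h peak,
  then linear decline at 0.15 log-units/h. Reactor-to-reactor variation
  enters as a N(0, 0.05) jitter on the initial CFU count.
* **Pb(II) depletion.** Stepwise uptake proportional to the current CFU
  count with a hard floor: C(t+Δ) = max(floor, C(t) − uptake·L(t)·Δ),
  from 80 mg/L down to a 5 mg/L floor; the decline-strain preset depletes
  faster, mirroring its early exhaustion. Non-increasing by construction.
* **Linkage.** Each coefficient is an affine function of the CFU count
  during growth; −b0 decreases strictly as the culture grows. Condition
  contrast is a ×30 multiplier on b0 and c0 with Pb — at least the order
  of magnitude the measured data show (the published time-courses need log
  scales for −b0 and −c0), and enough that |b0| classes never overlap. The
  absolute anchor magnitudes (a0 ≈ −4 Ω, |b0| ~ 10⁴–10⁵, |c0| ~ 10²–10⁴,
  d0 = 2×10⁻⁵ H) follow the only legible scale cues (d0 of order 10⁻⁵ H)
  and are otherwise plausible rather than authoritative.
* **Noise.** X_obs = X + ε_abs + ε_rel·|X| with independent Gaussian
  draws; the default σ_rel = 0.01 is an SNR of 100 per point. The real
  channel is filled with a constant 50 Ω series-resistance stub so Nyquist
  plots are drawable; the fit never consumes it, and no real-part physics
  is invented. Every stream derives deterministically from one master seed,
  so datasets are byte-identical across reruns.

What the generator does *not* emulate — and hence what green tests do not
certify about laboratory data: electrode double-layer and biofouling
dynamics, suspended elemental-Pb scattering after heavy precipitation,
Gram-positive vs Gram-negative charge interactions, drifting series
resistance, or non-Gaussian instrument noise. The generator's linkage is
exactly affine, so end-to-end recovery tests validate the estimation
chain, not the biology.

## Numerical and interface choices

* Phase is degrees in files and interfaces, radians internally, wrapped to
  (−180, 180]; capacitive reactance is stored negative and Nyquist plots
  use −X (first-quadrant convention).
* Spectra CSVs are long-format with explicit reactor/time/condition columns
  (grouping keys for replicate averaging), in either polar
  (`z_mag_ohm`, `z_phase_deg`) or rectangular (`z_real_ohm`, `z_imag_ohm`)
  dialects; condition labels are exactly `with_pb` / `without_pb`. Values
  round-trip through write-then-read to better than 10⁻⁹ relative.
* ω = 0 is rejected wherever a negative exponent would diverge; duplicate
  or non-ascending frequencies are parse errors, not warnings.
* Pipeline configurations (R list or YAML) reject unknown keys by name.
* Solution-preparation arithmetic uses atomic masses Pb 207.2, N 14.007,
  O 15.999; reactor dosing is nominal (added volume not counted in the
  denominator), reproducing the 10,000 mg/L stock (2 s.f.) and 80 mg/L
  dose figures.

## Problem sizes used in the tests

The suite runs in well under a minute on one core: 61-point sweeps
(10⁴ points only for the noise-calibration check), 100-instance
linear-oracle sweeps, 200–500-rep Monte-Carlo oracles for replicate and
slope recovery, and six-seed end-to-end pipeline calibration batches.
These sizes were chosen to give the Monte-Carlo assertions comfortable
statistical margins while staying desk-scale.

## Known limitations

* The free-exponent stage's p1 is weakly identified under noise (above);
  its acceptance-grade use is on noiseless or replicate-averaged spectra.
* Only the reactance is modelled; the real part of the measured impedance
  is ignored by design, so solution-resistance information is discarded.
* The exponential window must be supplied or detected from CFU data; the
  package does not infer it from the impedance alone.
* Correlation results are descriptive (slope, intercept, R², SE); no
  hypothesis tests are attached, as none are defined for this design.
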
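---
title: "Methods: RAFF2 pulse physics, simulation and TRAFF2 estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RAFF2 pulse physics, simulation and TRAFF2 estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raffmap)
```

This vignette is the package's account of the science it implements: the
RAFF2 preparation, the signal model and its estimator, what the synthetic
data emulate, and the numerical and design choices made where the method
itself leaves them open.

## The RAFF2 preparation

A RAFF2 pulse is an amplitude- and frequency-modulated RF pulse operating
deliberately *below* the adiabatic limit:

$$\omega_1(t) = \omega_{1max}\,\lvert\sin(\omega_{1max} t + \varphi_0)\rvert,
\qquad
\Delta\omega(t) = \omega_{1max}\,\cos(\omega_{1max} t + \varphi_0),$$

with the frequency modulation realized as a phase ramp
$\varphi(t)=\int_0^t \Delta\omega\,dt'$. On resonance the effective field in
the first rotating frame has constant magnitude $\omega_{1max}$ and its tilt
angle sweeps at the constant rate $\omega_{1max}$. Because the sweep is fast
(sub-adiabatic), transforming into the frame following the sweep introduces
a fictitious field of the same magnitude: the second-rotating-frame
effective field is *stationary* with magnitude $\sqrt{2}\,\omega_{1max}$,
tilted 45 degrees. Magnetization precesses about this fixed axis, and the
mono-exponential decay time of the locked component — TRAFF2 — is the
quantitative parameter.

Three conventions are configurable but have motivated defaults:

* **Pulse duration** defaults to $\sqrt{2}/f_{1max}$, the unique value for
  which precession about the $\sqrt 2 f_{1max}$ second-frame field
  accumulates exactly $4\pi$ — two full revolutions — per pulse. At the
  reference 625 Hz this is 2.2627 ms, i.e. the protocol's printed 2.26 ms
  at two decimals. Protocol train totals (22.98/46.66/70.34 ms for 8/16/24
  pulses with 0.7 ms spoilers) are reproduced exactly when the pulse is
  configured at the printed 2.26 ms.
* **Initial phase** $\varphi_0$ defaults to 0; it only shifts the starting
  point of the sweep.
* **Spoilers** sit strictly *between* consecutive pulses
  ($n_{pulses}-1$ gaps), the unique convention consistent with the printed
  totals.

B1 transmit miscalibration ($\eta_1$, `b1_scale`) multiplies the amplitude
modulation only: a gain error scales the realized B1 field, while the phase
ramp is synthesized digitally and is immune to it.

## Bloch simulation

The propagator uses the hard-pulse approximation: piecewise-constant
rotations over each waveform sampling interval, with the field evaluated at
the interval midpoint, followed by an exact (closed-form) relaxation step.
This splitting is unconditionally norm-preserving for the rotation part and
reproduces the free-recovery and continuous-wave spin-lock limits exactly,
which makes it directly testable against analytic expressions. A guard
refuses propagation when the rotation per step at peak field exceeds 0.1
rad; the default 256 samples per pulse give about 0.035 rad per step.

Three generative modes serve different purposes:

* **`forward_model`** evaluates $S(T_p)=A e^{-T_p/T_{RAFF2}}+B$ directly;
  it is the reference for estimator validation.
* **`phenomenological`** tracks the magnetization history (rest-period T1
  recovery, saturation efficiency) while decaying the locked component at
  the ground-truth $1/T_{RAFF2}$ across the *entire* preparation block,
  spoiler gaps included. The abscissa of the signal model is the total
  preparation time including spoiling, so letting the phenomenological
  decay span the whole block keeps simulation and model consistent; with
  T1 recovery confined to the 4 s rest periods this mode matches the
  forward model to well under 1% on resonance.
* **`bloch`** propagates every pulse with tissue T1/T2 only. Since no
  exchange or dipolar relaxation pathways are modeled, *absolute* fitted
  values in this mode reflect T1/T2 physics, not tissue TRAFF2; the mode
  exists for physics sanity checks and for inhomogeneity *trend* analysis.

### Train phase scheme

How successive RAFF2 pulses are phased is not fixed by the waveform
equations, and it matters. Numerically, a train of *identical* pulses with
ideal spoiling between all of them retains only $|M_z|\approx 0.07$ per
pulse at $\eta_1 = 0.4$: the rectified-sine pulse is not self-refocusing at
reduced amplitude, the signal collapses within one train, and the fitted
time is grossly *under*estimated at low B1 — the opposite of what the
physical experiment shows (progressive overestimation, up to several
hundred percent at $\eta_1=0.4$). A coherent sign-alternated pair —
$P(\varphi)$ followed by $P(\varphi+\pi)$, which concatenates into the
continuous, unrectified sine sweep of the classic RAFF packet construction
— retains $M_z \approx 1.000$ at all $\eta_1$ while still degrading
monotonically with off-resonance. The Bloch simulator therefore defaults to
`pairing = "alternating"`: coherent pairs, ideal spoiling between pairs,
with the spoiler time of the timing budget lumped into the inter-pair gaps
(at 0.7 ms versus second-scale T1 the placement is negligible for
relaxation, but coherence within the pair is essential). The
`"identical"` option preserves the naive scheme for comparison, and
`assemble_prep_train()` exposes a general `phase_cycle_rad` hook.

One consequence worth knowing: the sine/cosine sweep has a handedness, so
the response to off-resonance is not symmetric in the sign of
$\Delta\omega_0$ at small offsets; sensitivity analyses in this package
therefore average the two signs per $|\Delta\omega_0|$ before asserting
monotone behaviour.

### Readout

The default readout is ideal: the acquired magnitude is
$|M_z \sin\alpha|$ at the central k-space line. An optional simplified
bSSFP mode propagates a linearly-ordered train (70 degrees, TR 3.0 ms, 73
segments, alpha/2 catalyzation) and samples the transverse magnitude at the
partial-Fourier center segment (`round(73 - 73/(6/8)/2)` = 24). Readout
fidelity is deliberately not a validation target: the $A$ and $B$
parameters of the signal model absorb readout effects by construction.

## Phantoms and noise

`make_vial_phantom()` renders nine discs on a 3x3 grid with T1 spanning
297.8–1421.6 ms and T2 spanning 40.1–194.4 ms — the measured ranges of the
physical nine-vial agarose/NiCl2 phantom. Per-vial TRAFF2 ground truths are
*synthetic fixtures* spanning 101.7–550.8 ms: rotating-frame decay of the
physical vials is not derivable from T1/T2 alone, so these defaults are
placeholders that let estimator tests cover the relevant dynamic range, not
claims about the physical phantom. The default B0 field is a smooth linear
+ Gaussian-bump map scaled to a 50 Hz peak; the default relative B1 is a
constant 1.05.

`make_sax_phantom()` builds an annular left-ventricular myocardium
(default ground truth 79.1 ms, a healthy mid-myocardial value) around a
blood pool, marks the RV insertion on the outer boundary as the angular
origin for AHA segmentation, and can embed a wedge lesion with elevated
TRAFF2 for 2SD-masking experiments.

Noise is Gaussian or Rician (`|S + n_1 + i n_2|`), seeded and reproducible.
The Rician floor at low SNR biases the fitted offset $B$ upward — a
documented property (and test), not something the estimator corrects.

What the synthetic data do *not* emulate: anatomy, cardiac and respiratory
motion, coil sensitivities, k-space reconstruction artifacts, and — most
importantly — the exchange/dipolar relaxation physics that makes tissue
TRAFF2 what it is. Passing tests therefore validate the *estimation
machinery and trend directions*, not absolute in-vivo accuracy.

## Estimation

`fit_traff2()` solves, per voxel, bounded nonlinear least squares for
$(A, B, T_{RAFF2})$ with a Levenberg–Marquardt trust-region engine
(`minpack.lm`), analytic Jacobian, bounds $T_{RAFF2}\in[1, 2000]$ ms and
$A, B \ge 0$, at most 200 iterations and relative tolerance $10^{-8}$.
Initialization: $B_0$ from the saturation image (else the series minimum),
$A_0 = S(0)-B_0$, and $T_0$ from a log-linear regression of $S-B_0$ over
the finite preparation times, clipped to bounds. The saturation image
enters the model as $S = B$ exactly ($e^{-\infty}=0$). A Gaussian
likelihood on magnitude data is assumed. Degenerate voxels (all-zero or
constant series) are flagged `insufficient_signal`; estimates pinned at a
bound are flagged `at_bound` and not counted as converged. Voxels are
independent — no spatial regularization.

The SD map is the per-voxel standard error of the $T_{RAFF2}$ estimate
from the fit residuals, $\sqrt{\hat\sigma^2 [(J^\top J)^{-1}]_{TT}}$ with
$\hat\sigma^2 = SSR/(n-3)$.

**A small-sample caveat.** With the five-point protocol the residual
variance has only two degrees of freedom, so the per-voxel SD estimate is
proportional to a chi-distributed scale whose *median* is
$\sqrt{\chi^2_{2,0.5}/2} = 0.833$ of the truth: the median SD-map value
sits systematically about 17% below the Monte-Carlo dispersion of the
estimates even though the estimator is variance-unbiased (the *mean* ratio
is about 0.89). This is a property of any residual-based standard error at
two degrees of freedom, not an implementation artifact; users comparing SD
maps to empirical replicate scatter should expect it.

## Cohort statistics

For each AHA segment (basal 1–6, mid 7–12, apical 13–16, angular origin at
the anterior RV insertion, counterclockwise, with a chirality flag):

* precision $wCV$: mean over (subject, repetition) of
  100 x segment SD-map mean / segment TRAFF2 mean;
* reproducibility $\overline{wCV}$: mean over subjects of
  100 x SD(repetition means) / subject mean;
* inter-subject variability $\overline{CV}$: 100 x SD(subject means) /
  grand mean.

The averaging order (average of per-subject CVs, then across segments) is
pinned here and in the tests; the sample $(n-1)$ SD is used throughout.
`simulate_segment_cohort()` generates a two-level hierarchical cohort
(defaults: 7 subjects, 3 repetitions, population mean 79.1 ms,
between-subject CV 10%, within-subject CV 1%, SD-map level 7.6%) for
generative-parameter recovery checks; with 16 segments averaged, the
estimators recover the generative CVs well within +/-3 points (between)
and +/-0.5 points (within) across seeds.

Agreement analysis (`pearson_and_bland_altman()`) reports the least-squares
line, $R^2$, bias and 1.96-SD limits of agreement; `scar_mask_2sd()`
thresholds at remote mean + 2 SD.

## Problem sizes and runtime choices

The validation suite uses sizes chosen to make the statistics stable while
keeping a laptop-scale run: $10^4$ voxels for the bias/efficiency check at
1% noise (estimator SD agrees with the Cramér–Rao bound to a few percent),
500 replicates per decay time for the SD-map comparison, 96–128 pixel
grids for phantoms, 256 waveform samples per pulse for Bloch propagation
(0.035 rad per step), and 20 seeds for the cohort-statistics coverage
check.

## Known limitations

* Bloch mode predicts trends, not tissue values: without exchange and
  dipolar mechanisms the on-resonance fitted time for T1 = 1200 ms / T2 =
  45 ms tissue is about 73 ms of mixed T1/T2 origin, not a physiological
  TRAFF2.
* The B0 response is asymmetric in the offset sign at small offsets (sweep
  handedness); only the |offset|-averaged behaviour is monotone.
* Magnitude-data fitting uses a Gaussian likelihood; the Rician noise floor
  biases $B$ at low SNR.
* The median SD-map value is ~17% low at two residual degrees of freedom
  (see above).
* ECG timing, motion and registration are outside the model; voxels are
  static and independent.
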
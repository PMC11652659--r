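# raffmap

Quantitative myocardial relaxometry with **RAFF2** — Relaxation Along a
Fictitious Field in the 2nd rotating frame — as a fully simulated, tested
toolkit: RAFF2 pulse synthesis, Bloch simulation of the five-contrast
preparation sequence under B0/B1 imperfections, digital phantoms, voxel-wise
three-parameter TRAFF2 fitting with SD maps, and the repeatability /
precision / variability statistics with AHA 16-segment reporting.

## The problem

Rotating-frame relaxation times such as T1ρ are sensitive to slow molecular
motion and show promise for detecting myocardial infarction without
gadolinium contrast, but continuous-wave spin locking is hard to use at 3 T:
it is SAR-intensive and fragile against B0 and B1+ inhomogeneity. RAFF2
replaces the continuous lock with a sub-adiabatic amplitude- and
frequency-modulated pulse whose effective field is *stationary in the doubly
rotating frame*; magnetization precesses about this fixed effective field,
and the relaxation time of the locked component — TRAFF2 — becomes the
quantitative contrast. This package is for sequence developers and
relaxometry methodologists who need an end-to-end executable model of the
mapping experiment: waveforms, spin dynamics, fitting and cohort statistics.

## The model

A single RAFF2 pulse is defined by

    omega_1(t)     = omega_1max * |sin(omega_1max * t + phi_0)|      (AM)
    delta_omega(t) = omega_1max *  cos(omega_1max * t + phi_0)       (FM)
    phi(t)         = integral_0^t delta_omega(t') dt'                (PM)

with peak RF frequency `omega_1max / 2pi` (625 Hz in the reference
protocol). On resonance the first-rotating-frame effective field has
constant magnitude `f1max` and sweeps at rate `omega_1max`, so the
second-frame effective field is constant at `sqrt(2) * f1max`; the default
pulse duration `sqrt(2) / f1max` (= 2.26 ms at 625 Hz) makes the
magnetization complete exactly two revolutions (4 pi) about it per pulse.
Trains of 8/16/24 pulses with 0.7 ms spoiler gaps give the protocol
preparation totals 22.98 / 46.66 / 70.34 ms.

The mapping sequence acquires five single-shot images: no preparation,
three RAFF2-weighted, and one saturation-prepared (an effectively infinite
preparation). Maps are produced by voxel-wise nonlinear least squares of the
three-parameter model

    S(Tp) = A * exp(-Tp / TRAFF2) + B

where the saturation image enters as `S = B` exactly, and per-voxel SD maps
are derived from the fit residuals,
`SD = sqrt(SSR/(n-3) * [(J'J)^-1]_TT)`.

## Worked example

Simulate the nine-vial phantom experiment with Rician noise, fit it, and
compare per-vial estimates with the ground truth:

```r
library(raffmap)

p <- make_raff2_pulse(raff2_config(625, duration_s = 2.26e-3))
assemble_prep_train(p, 8, 0.7e-3)
#> RAFF2 preparation train: 8 x 2.26 ms pulses, 0.7 ms spoilers, total 22.98 ms

ph  <- make_vial_phantom(96)
ser <- simulate_series(ph, sequence_protocol(), raff2_config(),
                       mode = "forward_model", noise_sigma = 0.005,
                       noise_model = "rician", seed = 1)
fit <- fit_traff2(ser)
summary(fit)
#> TRAFF2 fit summary
#>   preparations (ms):  0.00000, 23.00193, 46.70387, 70.40580, sat
#>   converged 4581 | at bound 0 | insufficient 0
#>   TRAFF2 mean 327.12 ms, SD 146.72 ms, median 326.85 ms
#>   median SD-map value 9.913 ms

sapply(1:9, function(v) mean(fit$traff2_map[ph$label_map == v], na.rm = TRUE))
#> 101.9 158.0 214.4 270.4 328.3 383.7 440.7 495.2 551.7   # truth: 101.7 ... 550.8
```

The fitted values track the per-vial ground truths (synthetic fixtures
spanning 101.7–550.8 ms) to within the noise level; the `summary` line
reports the residual-based SD map, the per-voxel precision estimate.

Inhomogeneity sensitivity, here the B1 branch of the sweep — reduced
transmit amplitude progressively overestimates TRAFF2:

```r
subset(b0_b1_sweep(tissue_params(1, 1200, 45)), sweep == "b1")
#>    sweep value traff2_ms deviation_pct
#> 10    b1   0.4     107.8          48.4
#> 11    b1   0.6      82.6          13.7
#> 12    b1   0.8      78.2           7.7
#> 13    b1   1.0      72.6           0.0
```

A thin command-line interface wraps the same functions
(`phantom | simulate | fit | sweep | stats | demo`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli","raffmap.R",package="raffmap"))') \
    demo --seed 7 --grid 96 --out demo_out
```

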
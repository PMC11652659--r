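#' Tissue relaxation parameters
#'
#' @param m0 Equilibrium magnetization (arbitrary units, positive).
#' @param t1_ms Longitudinal relaxation time in ms.
#' @param t2_ms Transverse relaxation time in ms (a warning is issued if
#'   `t2_ms > t1_ms`, which is unphysical).
#' @param traff2_ms Optional phenomenological rotating-frame decay time in ms;
#'   required by the `"phenomenological"` and `"forward_model"` simulation
#'   modes.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(m0 = 1, t1_ms = 1000, t2_ms = 45,
                          traff2_ms = NULL) {
  if (m0 <= 0 || t1_ms <= 0 || t2_ms <= 0)
    stop("'m0', 't1_ms' and 't2_ms' must be positive", call. = FALSE)
  if (t2_ms > t1_ms)
    warning("t2_ms > t1_ms is unphysical", call. = FALSE)
  if (!is.null(traff2_ms) && traff2_ms <= 0)
    stop("'traff2_ms' must be positive", call. = FALSE)
  structure(list(m0 = m0, t1_ms = t1_ms, t2_ms = t2_ms,
                 traff2_ms = traff2_ms),
            class = "tissue_params")
}

#' Acquisition protocol for the five-contrast TRAFF2 sequence
#'
#' Describes the preparation scheme of the mapping sequence: one image with
#' no preparation (fully recovered magnetization), one RAFF2-weighted image
#' per entry of `n_pulses`, and optionally one image directly after a
#' saturation module, which mimics an infinitely long preparation. Each
#' prepared image is preceded by a rest period for magnetization recovery.
#'
#' @param n_pulses Integer vector of RAFF2 pulse repetitions per weighted
#'   image (default `c(8, 16, 24)`).
#' @param spoiler_ms Gradient spoiler gap between consecutive pulses, ms.
#' @param rest_period_s Rest period before each prepared acquisition, s.
#' @param saturation_efficiency Fraction of longitudinal magnetization
#'   destroyed by the saturation module, in \[0, 1\] (1 = ideal).
#' @param include_saturation Acquire the saturation-prepared image?
#' @param readout `"ideal"` (sample Mz scaled by `sin(flip)`) or `"bssfp"`
#'   (propagate a linearly-ordered balanced SSFP segment train and sample the
#'   transverse magnitude at the central k-space line).
#' @param flip_deg Readout flip angle, degrees.
#' @param tr_ms bSSFP repetition time, ms.
#' @param segments Number of acquired bSSFP segments.
#' @param partial_fourier Partial-Fourier fraction (the central line index is
#'   `round(segments - segments / partial_fourier / 2)`).
#' @param pairing RF phase scheme of the train used by the Bloch simulator:
#'   `"alternating"` (default) plays consecutive pulses as coherent
#'   sign-alternated pairs — the second pulse of each pair has its RF phase
#'   shifted by pi, so the pair reconstructs the continuous (unrectified)
#'   sine sweep and refocuses the magnetization to the longitudinal axis
#'   even at reduced B1 amplitude; `"identical"` plays every pulse with the
#'   same phase and full spoiling between all pulses. The phenomenological
#'   and forward-model modes are unaffected.
#' @return An object of class `sequence_protocol`.
#' @export
sequence_protocol <- function(n_pulses = c(8L, 16L, 24L), spoiler_ms = 0.7,
                              rest_period_s = 4, saturation_efficiency = 1,
                              include_saturation = TRUE,
                              readout = c("ideal", "bssfp"), flip_deg = 70,
                              tr_ms = 3.0, segments = 73L,
                              partial_fourier = 6 / 8,
                              pairing = c("alternating", "identical")) {
  readout <- match.arg(readout)
  pairing <- match.arg(pairing)
  if (rest_period_s < 0) stop("'rest_period_s' must be >= 0", call. = FALSE)
  if (saturation_efficiency < 0 || saturation_efficiency > 1)
    stop("'saturation_efficiency' must lie in [0, 1]", call. = FALSE)
  if (any(n_pulses < 1)) stop("'n_pulses' entries must be >= 1",
                              call. = FALSE)
  structure(
    list(n_pulses = as.integer(n_pulses), spoiler_ms = spoiler_ms,
         rest_period_s = rest_period_s,
         saturation_efficiency = saturation_efficiency,
         include_saturation = isTRUE(include_saturation), readout = readout,
         flip_deg = flip_deg, tr_ms = tr_ms, segments = as.integer(segments),
         partial_fourier = partial_fourier, pairing = pairing),
    class = "sequence_protocol")
}

#' @export
print.sequence_protocol <- function(x, ...) {
  cat("TRAFF2 mapping protocol\n")
  cat(sprintf("  weighted images: no-prep + %d RAFF2 trains (%s pulses)%s\n",
              length(x$n_pulses), paste(x$n_pulses, collapse = "/"),
              if (x$include_saturation) " + saturation" else ""))
  cat(sprintf("  spoilers %.3g ms, rest %.3g s, readout %s (flip %g deg)\n",
              x$spoiler_ms, x$rest_period_s, x$readout, x$flip_deg))
  invisible(x)
}

# concatenate copies of a pulse with per-copy RF phase offsets into one
# coherent waveform (duplicate boundary samples dropped)
concat_waveforms <- function(pulse, phase_offsets) {
  k <- length(phase_offsets)
  t <- unlist(lapply(seq_len(k), function(i)
    pulse$t + (i - 1) * pulse$duration_s))
  omega1 <- rep(pulse$omega1, k)
  phase <- unlist(lapply(phase_offsets, function(ph) pulse$phase + ph))
  keep <- !duplicated(t)
  out <- pulse
  out$t <- t[keep]; out$omega1 <- omega1[keep]; out$phase <- phase[keep]
  out$delta_omega <- rep(pulse$delta_omega, k)[keep]
  out$duration_s <- k * pulse$duration_s
  out
}

# preparation abscissae (ms) implied by a protocol and a pulse duration
protocol_prep_ms <- function(protocol, pulse_duration_s) {
  d_ms <- pulse_duration_s * 1000
  totals <- protocol$n_pulses * d_ms +
    (protocol$n_pulses - 1L) * protocol$spoiler_ms
  c(0, totals, if (protocol$include_saturation) Inf)
}

# --- Bloch propagation core -------------------------------------------------
#
# Hard-pulse approximation: piecewise-constant rotation over each waveform
# sampling interval, field evaluated at the interval midpoint, followed by an
# exact relaxation step (operator splitting). Rotations are norm-preserving
# by construction; relaxation steps use the closed-form exponentials, so the
# free-recovery and spin-lock limits are reproduced exactly.
#
# M: n x 3 matrix (rows = voxels). In the frame rotating at the RF carrier
# the field is (omega1 cos(phi), omega1 sin(phi), 2*pi*b0): the frequency
# modulation is realized as phase modulation, so only the static offset
# appears along z.
bloch_run <- function(M, wf, t1_s, t2_s, m0, b0_hz, b1, relax = TRUE,
                      dt_max = NULL) {
  n <- length(wf$t)
  dt <- diff(wf$t)
  w1 <- (wf$omega1[-1] + wf$omega1[-n]) / 2
  ph <- (wf$phase[-1] + wf$phase[-n]) / 2
  peak <- sqrt((max(b1) * max(wf$omega1))^2 + (2 * pi * max(abs(b0_hz)))^2)
  max_rot <- peak * max(dt)
  limit <- if (is.null(dt_max)) 0.1 else peak * dt_max
  if (max_rot > limit + 1e-12)
    stop(sprintf(paste0(
      "waveform sampling too coarse for stable propagation: peak rotation ",
      "per step is %.3f rad (limit %.3f); increase 'n_samples' in the pulse ",
      "configuration"), max_rot, limit), call. = FALSE)
  wz <- 2 * pi * b0_hz              # per-voxel, constant over the pulse
  cph <- cos(ph); sph <- sin(ph)
  for (i in seq_len(n - 1L)) {
    wx <- b1 * (w1[i] * cph[i])
    wy <- b1 * (w1[i] * sph[i])
    wmag <- sqrt(wx^2 + wy^2 + wz^2)
    th <- wmag * dt[i]
    nz <- wmag > 0
    ux <- ifelse(nz, wx / wmag, 0)
    uy <- ifelse(nz, wy / wmag, 0)
    uz <- ifelse(nz, wz / wmag, 1)
    ct <- cos(th); st <- sin(th); vt <- 1 - ct
    mx <- M[, 1]; my <- M[, 2]; mz <- M[, 3]
    dot <- ux * mx + uy * my + uz * mz
    # rotation of M about u by angle -th (dM/dt = M x w convention)
    M[, 1] <- mx * ct - (uy * mz - uz * my) * st + ux * dot * vt
    M[, 2] <- my * ct - (uz * mx - ux * mz) * st + uy * dot * vt
    M[, 3] <- mz * ct - (ux * my - uy * mx) * st + uz * dot * vt
    if (relax) {
      e2 <- exp(-dt[i] / t2_s)
      e1 <- exp(-dt[i] / t1_s)
      M[, 1] <- M[, 1] * e2
      M[, 2] <- M[, 2] * e2
      M[, 3] <- m0 + (M[, 3] - m0) * e1
    }
  }
  M
}

as_mag_matrix <- function(m) {
  if (is.matrix(m)) {
    if (ncol(m) != 3L) stop("magnetization matrix must have 3 columns",
                            call. = FALSE)
    m
  } else {
    if (length(m) != 3L)
      stop("magnetization must be a length-3 vector (mx, my, mz)",
           call. = FALSE)
    matrix(m, 1L, 3L)
  }
}

#' Propagate magnetization through a single pulse
#'
#' Solves the Bloch equations for a magnetization state under a sampled
#' RF waveform with static B0 off-resonance, using piecewise-constant
#' rotations (hard-pulse approximation) with exact relaxation steps.
#'
#' In `"bloch"` mode relaxation uses the tissue T1/T2. In
#' `"phenomenological"` mode the pulse is treated as an ideal RAFF2 locking
#' block: over one complete pulse the magnetization returns to its initial
#' axis (two full revolutions about the stationary second-rotating-frame
#' field) while the locked component decays mono-exponentially with the
#' ground-truth TRAFF2, so the state is simply scaled by
#' `exp(-duration / traff2)`.
#'
#' @param m Magnetization: length-3 vector `c(mx, my, mz)` or an n x 3
#'   matrix of voxel states, in units of `m0`.
#' @param wf A `raff2_pulse` waveform.
#' @param tissue A [tissue_params()] object.
#' @param delta_omega0_hz Static off-resonance in Hz.
#' @param mode `"bloch"` or `"phenomenological"`.
#' @param relax Apply relaxation? (`FALSE` isolates the rotation dynamics;
#'   the norm is then conserved to machine precision.)
#' @param dt_max Optional upper bound on the sampling interval in seconds;
#'   propagation refuses (with guidance) when the rotation per step at peak
#'   field exceeds 0.1 rad or the interval exceeds `dt_max`.
#' @return Magnetization in the same shape as `m`.
#' @export
propagate_pulse <- function(m, wf, tissue, delta_omega0_hz = 0,
                            mode = c("bloch", "phenomenological"),
                            relax = TRUE, dt_max = NULL) {
  mode <- match.arg(mode)
  M <- as_mag_matrix(m)
  if (mode == "phenomenological") {
    if (is.null(tissue$traff2_ms))
      stop("phenomenological mode requires 'traff2_ms' in the tissue",
           call. = FALSE)
    out <- M * exp(-wf$duration_s / (tissue$traff2_ms / 1000))
  } else {
    out <- bloch_run(M, wf,
                     t1_s = tissue$t1_ms / 1000, t2_s = tissue$t2_ms / 1000,
                     m0 = tissue$m0, b0_hz = delta_omega0_hz, b1 = 1,
                     relax = relax, dt_max = dt_max)
  }
  if (is.matrix(m)) out else drop(out)
}

#' Ideal gradient spoiler with T1 recovery
#'
#' Sets the transverse magnetization to zero (ideal spoiling) and lets the
#' longitudinal component relax toward equilibrium over the gap.
#'
#' @inheritParams propagate_pulse
#' @param gap_s Spoiler gap duration in seconds (non-negative).
#' @return Magnetization in the same shape as `m`.
#' @export
apply_spoiler <- function(m, gap_s, tissue) {
  if (gap_s < 0) stop("'gap_s' must be >= 0", call. = FALSE)
  M <- as_mag_matrix(m)
  M[, 1] <- 0
  M[, 2] <- 0
  e1 <- exp(-gap_s / (tissue$t1_ms / 1000))
  M[, 3] <- tissue$m0 + (M[, 3] - tissue$m0) * e1
  if (is.matrix(m)) M else drop(M)
}

#' Parametric saturation module
#'
#' Models the WET-style saturation prepulse as a single efficiency: the
#' longitudinal magnetization is scaled by `1 - efficiency` and the
#' transverse components are destroyed.
#'
#' @inheritParams propagate_pulse
#' @param efficiency Fraction of Mz destroyed, in \[0, 1\].
#' @return Magnetization in the same shape as `m`.
#' @export
apply_saturation <- function(m, efficiency = 1) {
  if (efficiency < 0 || efficiency > 1)
    stop("'efficiency' must lie in [0, 1]", call. = FALSE)
  M <- as_mag_matrix(m)
  M[, 1] <- 0
  M[, 2] <- 0
  M[, 3] <- (1 - efficiency) * M[, 3]
  if (is.matrix(m)) M else drop(M)
}

# simplified linearly-ordered bSSFP readout: alternating +/- flip about x,
# free precession + relaxation over TR between pulses; returns |Mxy| after
# the central k-space segment (partial-Fourier center index).
bssfp_readout <- function(mz, protocol, t1_s, t2_s, m0, b0_hz) {
  n_center <- max(1L, round(protocol$segments -
                              protocol$segments / protocol$partial_fourier / 2))
  fa <- protocol$flip_deg * pi / 180
  tr <- protocol$tr_ms / 1000
  M <- cbind(0, 0, mz)
  e1 <- exp(-tr / t1_s); e2 <- exp(-tr / t2_s)
  phi <- 2 * pi * b0_hz * tr
  cphi <- cos(phi); sphi <- sin(phi)
  # alpha/2 catalyzation
  a <- fa / 2
  M <- cbind(M[, 1], M[, 2] * cos(a) + M[, 3] * sin(a),
             -M[, 2] * sin(a) + M[, 3] * cos(a))
  sgn <- -1
  for (k in seq_len(n_center)) {
    a <- sgn * fa
    ca <- cos(a); sa <- sin(a)
    M <- cbind(M[, 1], M[, 2] * ca + M[, 3] * sa,
               -M[, 2] * sa + M[, 3] * ca)
    if (k == n_center) break
    mx <- M[, 1] * cphi - M[, 2] * sphi
    my <- M[, 1] * sphi + M[, 2] * cphi
    M <- cbind(mx * e2, my * e2, m0 + (M[, 3] - m0) * e1)
    sgn <- -sgn
  }
  sqrt(M[, 1]^2 + M[, 2]^2)
}

#' Simulate the five-contrast weighted image series
#'
#' Produces one magnitude image per preparation abscissa of the protocol:
#' no-prep, one per RAFF2 train, and (optionally) saturation. Voxels are
#' simulated independently (single-shot acquisition, no spatial encoding
#' artifacts); rest periods restore Mz by T1 recovery between acquisitions.
#'
#' Three generative modes are available:
#' \describe{
#'   \item{`"forward_model"`}{signals follow the three-parameter model
#'     directly: `S(Tp) = m0 * (a_frac * exp(-Tp / traff2) + b_frac)`, with
#'     the saturation image at `m0 * b_frac`. No sequence physics.}
#'   \item{`"phenomenological"`}{the magnetization history is tracked; during
#'     a preparation block the locked component decays mono-exponentially
#'     with the ground-truth TRAFF2 over the whole block (pulses and spoiler
#'     gaps), and rest periods recover Mz with T1. On-resonance this
#'     reproduces the forward model closely.}
#'   \item{`"bloch"`}{full Bloch propagation through every RAFF2 pulse with
#'     the tissue T1/T2, ideal spoilers between pulses, and per-voxel B0/B1.
#'     Absolute fitted values reflect T1/T2 physics only (no exchange or
#'     dipolar mechanisms), so this mode serves physics sanity checks and
#'     inhomogeneity trend analysis, not tissue TRAFF2 prediction.}
#' }
#'
#' @param tissue A [tissue_params()] object (single voxel) or a
#'   `tissue_maps` object from [make_vial_phantom()] / [make_sax_phantom()].
#' @param protocol A [sequence_protocol()].
#' @param pulse_config A [raff2_config()]; the per-voxel B1 map (if any)
#'   multiplies the configured `b1_scale`.
#' @param mode Generative mode, see Details.
#' @param a_frac,b_frac Forward-model signal fractions (defaults 0.8 / 0.2).
#' @param delta_omega0_hz Additional global off-resonance in Hz, added to any
#'   per-voxel B0 map.
#' @param noise_sigma Optional absolute noise level passed to [add_noise()].
#' @param noise_model `"gaussian"` or `"rician"` (used when
#'   `noise_sigma > 0`).
#' @param seed Integer seed for the noise generator.
#' @return A [weighted_series()] with one image per preparation duration.
#' @export
simulate_series <- function(tissue, protocol = sequence_protocol(),
                            pulse_config = raff2_config(),
                            mode = c("forward_model", "phenomenological",
                                     "bloch"),
                            a_frac = 0.8, b_frac = 0.2,
                            delta_omega0_hz = 0, noise_sigma = 0,
                            noise_model = c("gaussian", "rician"),
                            seed = NULL) {
  mode <- match.arg(mode)
  noise_model <- match.arg(noise_model)
  single <- inherits(tissue, "tissue_params")
  if (single) {
    shape <- c(1L, 1L)
    m0 <- tissue$m0; t1 <- tissue$t1_ms; t2 <- tissue$t2_ms
    traff2 <- if (is.null(tissue$traff2_ms)) NA_real_ else tissue$traff2_ms
    b0 <- 0; b1 <- 1
    active <- TRUE
  } else if (inherits(tissue, "tissue_maps") ||
             inherits(tissue, "sax_phantom")) {
    maps <- if (inherits(tissue, "sax_phantom")) tissue$maps else tissue
    shape <- dim(maps$m0_map)
    active <- maps$label_map > 0
    m0 <- maps$m0_map[active]; t1 <- maps$t1_map[active]
    t2 <- maps$t2_map[active]; traff2 <- maps$traff2_map[active]
    b0 <- maps$b0_map[active]; b1 <- maps$b1_map[active]
  } else {
    stop("'tissue' must be tissue_params, tissue_maps or sax_phantom",
         call. = FALSE)
  }
  if (mode %in% c("phenomenological", "forward_model") &&
      any(is.na(traff2)))
    stop(sprintf("mode '%s' requires ground-truth traff2 values", mode),
         call. = FALSE)

  pulse <- make_raff2_pulse(pulse_config)
  prep_ms <- protocol_prep_ms(protocol, pulse$duration_s)
  nvox <- length(m0)
  fa <- protocol$flip_deg * pi / 180
  signals <- matrix(0, nvox, length(prep_ms))

  if (mode == "forward_model") {
    for (j in seq_along(prep_ms)) {
      tp <- prep_ms[j]
      dec <- if (is.infinite(tp)) 0 else exp(-tp / traff2)
      signals[, j] <- m0 * (a_frac * dec + b_frac)
    }
  } else if (mode == "phenomenological") {
    mz <- m0
    for (j in seq_along(prep_ms)) {
      if (j > 1L)
        mz <- m0 + (mz - m0) * exp(-protocol$rest_period_s / (t1 / 1000))
      tp <- prep_ms[j]
      if (is.infinite(tp)) {
        mz <- (1 - protocol$saturation_efficiency) * mz
      } else if (tp > 0) {
        mz <- mz * exp(-tp / traff2)
      }
      signals[, j] <- abs(mz * sin(fa))
    }
  } else { # bloch
    t1s <- t1 / 1000; t2s <- t2 / 1000
    b0v <- b0 + delta_omega0_hz
    M <- cbind(0, 0, m0)
    for (j in seq_along(prep_ms)) {
      if (j > 1L) {
        rp <- protocol$rest_period_s
        M[, 1] <- M[, 1] * exp(-rp / t2s)
        M[, 2] <- M[, 2] * exp(-rp / t2s)
        M[, 3] <- m0 + (M[, 3] - m0) * exp(-rp / t1s)
      }
      tp <- prep_ms[j]
      if (is.infinite(tp)) {
        M[, 1] <- 0; M[, 2] <- 0
        M[, 3] <- (1 - protocol$saturation_efficiency) * M[, 3]
      } else if (tp > 0) {
        n_p <- protocol$n_pulses[j - 1L]
        # packets: coherent sign-alternated pairs (default) or single pulses
        if (protocol$pairing == "alternating") {
          pair <- concat_waveforms(pulse, c(0, pi))
          packets <- c(rep(list(pair), n_p %/% 2L),
                       if (n_p %% 2L) list(pulse))
        } else {
          packets <- rep(list(pulse), n_p)
        }
        n_pk <- length(packets)
        # total spoiler time spread over the inter-packet gaps
        gap_s <- if (n_pk > 1L)
          (n_p - 1L) * protocol$spoiler_ms / 1000 / (n_pk - 1L) else 0
        for (k in seq_len(n_pk)) {
          M <- bloch_run(M, packets[[k]], t1s, t2s, m0, b0v, b1)
          M[, 1] <- 0; M[, 2] <- 0
          if (k < n_pk)
            M[, 3] <- m0 + (M[, 3] - m0) * exp(-gap_s / t1s)
        }
      }
      signals[, j] <- if (protocol$readout == "bssfp")
        bssfp_readout(M[, 3], protocol, t1s, t2s, m0, b0v)
      else abs(M[, 3] * sin(fa))
    }
  }

  images <- array(0, c(shape, length(prep_ms)))
  for (j in seq_along(prep_ms)) {
    img <- matrix(0, shape[1], shape[2])
    img[active] <- signals[, j]
    images[, , j] <- img
  }
  series <- weighted_series(images, prep_ms,
                            mask = matrix(active, shape[1], shape[2]))
  if (noise_sigma > 0)
    series <- add_noise(series, noise_sigma, model = noise_model, seed = seed)
  series
}

#' B0 / B1 inhomogeneity sweep
#'
#' Simulates and fits the full five-contrast experiment across a grid of B0
#' off-resonances (at nominal B1) and of relative B1 scalings (on-resonance),
#' reporting for each grid point the fitted TRAFF2 and its percent deviation
#' from the reference point (`delta_omega0 = 0` Hz, `eta1 = 1`). The grids
#' default to the phantom-experiment values
#' `c(-150, -100, -50, -25, 0, 25, 50, 100, 150)` Hz and
#' `c(0.4, 0.6, 0.8, 1.0)`.
#'
#' @param tissue A [tissue_params()] object.
#' @param protocol A [sequence_protocol()].
#' @param pulse_config A [raff2_config()].
#' @param delta_omega0_hz B0 offset grid in Hz; must contain 0.
#' @param eta1 Relative B1 scaling grid; must contain 1.
#' @param mode Simulation mode passed to [simulate_series()] (default
#'   `"bloch"`; the phenomenological and forward modes have no B0/B1
#'   sensitivity by construction).
#' @return A data frame with columns `sweep` (`"b0"` or `"b1"`), `value`,
#'   `traff2_ms` and `deviation_pct`.
#' @export
b0_b1_sweep <- function(tissue, protocol = sequence_protocol(),
                        pulse_config = raff2_config(),
                        delta_omega0_hz = c(-150, -100, -50, -25, 0,
                                            25, 50, 100, 150),
                        eta1 = c(0.4, 0.6, 0.8, 1.0),
                        mode = "bloch") {
  if (!any(delta_omega0_hz == 0))
    stop("'delta_omega0_hz' must contain the on-resonance reference 0",
         call. = FALSE)
  if (!any(eta1 == 1))
    stop("'eta1' must contain the nominal-amplitude reference 1.0",
         call. = FALSE)
  fit_one <- function(b0, b1) {
    cfg <- raff2_config(pulse_config$f1max_hz, pulse_config$phi0,
                        pulse_config$duration_s, pulse_config$n_samples,
                        b1_scale = pulse_config$b1_scale * b1)
    ser <- simulate_series(tissue, protocol, cfg, mode = mode,
                           delta_omega0_hz = b0)
    fit <- fit_traff2(ser)
    fit$traff2_map[1, 1]
  }
  t_b0 <- vapply(delta_omega0_hz, fit_one, numeric(1), b1 = 1)
  t_b1 <- vapply(eta1, fit_one, numeric(1), b0 = 0)
  ref_b0 <- t_b0[delta_omega0_hz == 0][1]
  ref_b1 <- t_b1[eta1 == 1][1]
  rbind(
    data.frame(sweep = "b0", value = delta_omega0_hz, traff2_ms = t_b0,
               deviation_pct = 100 * (t_b0 - ref_b0) / ref_b0),
    data.frame(sweep = "b1", value = eta1, traff2_ms = t_b1,
               deviation_pct = 100 * (t_b1 - ref_b1) / ref_b1))
}
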
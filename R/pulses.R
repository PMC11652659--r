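#' RAFF2 pulse configuration
#'
#' Bundles the parameters that define a single RAFF2 radio-frequency pulse:
#' the peak RF pulse frequency \eqn{\omega_{1max}/2\pi} in Hz, the initial
#' phase \eqn{\varphi_0}, the single-pulse duration, the sampling density and
#' a dimensionless B1 transmit scaling \eqn{\eta_1} applied to the amplitude
#' modulation only.
#'
#' If `duration_s` is `NULL` the canonical duration convention
#' \eqn{T_p = \sqrt{2}/f_{1max}} is applied: the effective field in the doubly
#' rotating frame has magnitude \eqn{\sqrt{2}\,\omega_{1max}} and completes
#' exactly two full revolutions (\eqn{4\pi} of precession) in that time. At
#' 625 Hz this gives 2.26 ms (to two decimals).
#'
#' @param f1max_hz Peak RF pulse frequency \eqn{\omega_{1max}/2\pi} in Hz
#'   (must be positive).
#' @param phi0 Initial phase \eqn{\varphi_0} in radians. Default 0.
#' @param duration_s Single-pulse duration in seconds, or `NULL` for the
#'   \eqn{\sqrt{2}/f_{1max}} convention.
#' @param n_samples Number of waveform samples per pulse (integer, at least
#'   16; at least 64 recommended when field trajectories are differentiated).
#' @param b1_scale Dimensionless \eqn{\eta_1} multiplier on the amplitude
#'   modulation, in (0, 2].
#' @return An object of class `raff2_config`.
#' @seealso [make_raff2_pulse()], [assemble_prep_train()]
#' @examples
#' cfg <- raff2_config(625)
#' round(cfg$duration_s * 1000, 2)  # 2.26 ms
#' @export
raff2_config <- function(f1max_hz = 625, phi0 = 0, duration_s = NULL,
                         n_samples = 256L, b1_scale = 1) {
  if (!is.numeric(f1max_hz) || length(f1max_hz) != 1L || f1max_hz <= 0)
    stop("'f1max_hz' must be a single positive number", call. = FALSE)
  if (is.null(duration_s)) duration_s <- sqrt(2) / f1max_hz
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("'duration_s' must be a single positive number", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 16L)
    stop("'n_samples' must be an integer >= 16", call. = FALSE)
  if (!is.numeric(b1_scale) || length(b1_scale) != 1L ||
      b1_scale <= 0 || b1_scale > 2)
    stop("'b1_scale' must lie in (0, 2]", call. = FALSE)
  structure(
    list(f1max_hz = f1max_hz, phi0 = phi0, duration_s = duration_s,
         n_samples = n_samples, b1_scale = b1_scale),
    class = "raff2_config")
}

#' @export
print.raff2_config <- function(x, ...) {
  cat("RAFF2 pulse configuration\n")
  cat(sprintf("  f1max:    %.6g Hz\n", x$f1max_hz))
  cat(sprintf("  phi0:     %.6g rad\n", x$phi0))
  cat(sprintf("  duration: %.6g ms (%d samples)\n",
              x$duration_s * 1000, x$n_samples))
  cat(sprintf("  b1 scale: %.6g\n", x$b1_scale))
  invisible(x)
}

# cumulative trapezoid integral, y over x, starting at 0
cumtrapz1 <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

# cumulative integral on a uniform grid, 4th-order accurate: composite
# Simpson increments for even strides, Adams-type three-point rule for the
# odd in-between points; falls back to trapezoid off uniform grids
cumquad1 <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(cumtrapz1(x, y))
  h <- diff(x)
  if (diff(range(h)) > 1e-9 * mean(h)) return(cumtrapz1(x, y))
  h <- mean(h)
  out <- numeric(n)
  for (i in seq(1L, n - 2L, by = 2L)) {
    out[i + 1L] <- out[i] + h / 12 * (5 * y[i] + 8 * y[i + 1L] - y[i + 2L])
    out[i + 2L] <- out[i] + h / 3 * (y[i] + 4 * y[i + 1L] + y[i + 2L])
  }
  if (n %% 2L == 0L)  # last interval via the mirrored three-point rule
    out[n] <- out[n - 1L] +
      h / 12 * (-y[n - 2L] + 8 * y[n - 1L] + 5 * y[n])
  out
}

# central-difference gradient with one-sided edges
grad1 <- function(y, x) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2)
    g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g
}

#' Synthesize a RAFF2 waveform
#'
#' Builds the sampled sine/cosine amplitude- and frequency-modulated RAFF2
#' pulse. The amplitude modulation is
#' \eqn{\omega_1(t) = \eta_1\,\omega_{1max}\,|\sin(\omega_{1max} t + \varphi_0)|}
#' and the frequency modulation is
#' \eqn{\Delta\omega(t) = \omega_{1max}\cos(\omega_{1max} t + \varphi_0)},
#' converted to a phase modulation by cumulative (trapezoid) integration with
#' \eqn{\varphi(0) = 0}. Both AM and FM operate in the sub-adiabatic regime,
#' creating a stationary effective field in the doubly rotating frame around
#' which magnetization precesses.
#'
#' The B1 scaling `b1_scale` multiplies the amplitude function only: a
#' transmit-gain miscalibration scales the realized B1 amplitude, while the
#' phase ramp is synthesized digitally and is unaffected.
#'
#' @param config A [raff2_config()] object.
#' @return An object of class `raff2_pulse`: a list with components `t`
#'   (seconds, `t[1] = 0`), `omega1` (rad/s, non-negative), `delta_omega`
#'   (rad/s), `phase` (radians, `phase[1] = 0`), plus the generating
#'   parameters.
#' @examples
#' wf <- make_raff2_pulse(raff2_config(625, n_samples = 1024))
#' max(abs(wf$phase))  # ~1 rad for phi0 = 0
#' @export
make_raff2_pulse <- function(config) {
  if (!inherits(config, "raff2_config"))
    config <- do.call(raff2_config, as.list(config))
  w1max <- 2 * pi * config$f1max_hz
  t <- seq(0, config$duration_s, length.out = config$n_samples)
  theta <- w1max * t + config$phi0
  omega1 <- config$b1_scale * w1max * abs(sin(theta))
  delta_omega <- w1max * cos(theta)
  phase <- cumquad1(t, delta_omega)
  structure(
    list(t = t, omega1 = omega1, delta_omega = delta_omega, phase = phase,
         f1max_hz = config$f1max_hz, phi0 = config$phi0,
         b1_scale = config$b1_scale, duration_s = config$duration_s),
    class = "raff2_pulse")
}

#' @export
print.raff2_pulse <- function(x, ...) {
  cat(sprintf(
    "RAFF2 pulse: f1max %.6g Hz, duration %.4g ms, %d samples, b1 scale %.3g\n",
    x$f1max_hz, x$duration_s * 1000, length(x$t), x$b1_scale))
  invisible(x)
}

#' Constant-amplitude (continuous-wave) waveform
#'
#' Convenience constructor for a spin-lock style continuous-wave pulse:
#' constant amplitude at `f1_hz`, zero frequency/phase modulation. Used for
#' closed-form Bloch checks and RF-power comparisons against RAFF2.
#'
#' @param f1_hz RF amplitude in Hz.
#' @param duration_s Duration in seconds.
#' @param n_samples Samples (integer, at least 16).
#' @return A `raff2_pulse`-classed waveform with constant `omega1`.
#' @export
cw_pulse <- function(f1_hz, duration_s, n_samples = 256L) {
  if (f1_hz < 0 || duration_s <= 0) stop("invalid CW pulse parameters",
                                         call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (n_samples < 16L) stop("'n_samples' must be >= 16", call. = FALSE)
  t <- seq(0, duration_s, length.out = n_samples)
  structure(
    list(t = t, omega1 = rep(2 * pi * f1_hz, n_samples),
         delta_omega = rep(0, n_samples), phase = rep(0, n_samples),
         f1max_hz = f1_hz, phi0 = 0, b1_scale = 1, duration_s = duration_s),
    class = "raff2_pulse")
}

#' Assemble a RAFF2 preparation train
#'
#' Concatenates `n_pulses` identical copies of a RAFF2 pulse with gradient
#' spoiler gaps strictly between consecutive pulses (`n_pulses - 1` gaps).
#' The total preparation duration — the abscissa of the three-parameter
#' signal model — is
#' `n_pulses * pulse_duration + (n_pulses - 1) * spoiler_duration`.
#' With a 2.26 ms pulse and 0.7 ms spoilers this reproduces the protocol
#' totals 22.98, 46.66 and 70.34 ms for 8, 16 and 24 repetitions.
#'
#' @param pulse A `raff2_pulse` waveform.
#' @param n_pulses Number of pulse repetitions (integer, at least 1).
#' @param spoiler_s Spoiler gap in seconds between consecutive pulses
#'   (non-negative).
#' @param phase_cycle_rad Optional per-pulse RF phase offsets in radians
#'   (recycled over the train), e.g. `c(0, pi)` for sign-alternated pairs;
#'   `NULL` (default) plays identical copies.
#' @return An object of class `raff2_train` with components `pulse`,
#'   `n_pulses`, `spoiler_s`, `phase_cycle_rad` and `total_duration_s`.
#' @examples
#' p <- make_raff2_pulse(raff2_config(625, duration_s = 2.26e-3))
#' assemble_prep_train(p, 8, 0.7e-3)$total_duration_s * 1000  # 22.98
#' @export
assemble_prep_train <- function(pulse, n_pulses, spoiler_s = 0.7e-3,
                                phase_cycle_rad = NULL) {
  if (!inherits(pulse, "raff2_pulse"))
    stop("'pulse' must be a raff2_pulse waveform", call. = FALSE)
  n_pulses <- as.integer(n_pulses)
  if (is.na(n_pulses) || n_pulses < 1L)
    stop("'n_pulses' must be an integer >= 1", call. = FALSE)
  if (spoiler_s < 0) stop("'spoiler_s' must be non-negative", call. = FALSE)
  structure(
    list(pulse = pulse, n_pulses = n_pulses, spoiler_s = spoiler_s,
         phase_cycle_rad = phase_cycle_rad,
         total_duration_s =
           n_pulses * pulse$duration_s + (n_pulses - 1L) * spoiler_s),
    class = "raff2_train")
}

#' @export
print.raff2_train <- function(x, ...) {
  cat(sprintf(
    "RAFF2 preparation train: %d x %.4g ms pulses, %.3g ms spoilers, total %.4g ms\n",
    x$n_pulses, x$pulse$duration_s * 1000, x$spoiler_s * 1000,
    x$total_duration_s * 1000))
  invisible(x)
}

# reflection-aware phase unwrapping: atan2(omega1 >= 0, .) folds the tilt
# angle into [0, pi]; continue it across the omega1 = 0 reflection points by
# linear extrapolation over the sign/2pi candidates
unwrap_reflect <- function(a) {
  n <- length(a)
  out <- numeric(n)
  out[1] <- a[1]
  for (i in 2:n) {
    pred <- if (i == 2L) out[1] else 2 * out[i - 1] - out[i - 2]
    c1 <- a[i] + 2 * pi * round((pred - a[i]) / (2 * pi))
    c2 <- -a[i] + 2 * pi * round((pred + a[i]) / (2 * pi))
    out[i] <- if (abs(c1 - pred) <= abs(c2 - pred)) c1 else c2
  }
  out
}

#' Rotating-frame field geometry of a waveform
#'
#' Computes, per time sample, the magnitude of the effective field in the
#' first rotating frame, the (unwrapped, continuous) tilt angle of that field
#' from the z-axis, the numerical sweep rate \eqn{d\alpha/dt}, and the
#' magnitude of the effective field in the second rotating frame, which adds
#' the fictitious-field component generated by the sweep:
#' \deqn{|B_{eff}|(t) = \sqrt{\omega_1^2 + (\Delta\omega + 2\pi\Delta\omega_0)^2}/2\pi,\qquad
#'       |E|(t) = \sqrt{(2\pi |B_{eff}|)^2 + (d\alpha/dt)^2}/2\pi.}
#' For an on-resonance RAFF2 pulse both are constant: \eqn{|B_{eff}| = f_{1max}}
#' and \eqn{|E| = \sqrt{2} f_{1max}} — the stationary effective and fictitious
#' fields of the doubly rotating frame.
#'
#' @param wf A `raff2_pulse` waveform (at least 64 samples recommended so the
#'   numerical differentiation of the tilt angle is stable).
#' @param delta_omega0_hz Static B0 off-resonance in Hz. Default 0.
#' @return A data frame of class `raff2_field` with columns `t` (s),
#'   `b_eff_mag` (Hz), `alpha` (rad, unwrapped), `sweep_rate` (rad/s) and
#'   `e_field_mag` (Hz).
#' @export
field_trajectory <- function(wf, delta_omega0_hz = 0) {
  if (!inherits(wf, "raff2_pulse"))
    stop("'wf' must be a raff2_pulse waveform", call. = FALSE)
  wz <- wf$delta_omega + 2 * pi * delta_omega0_hz
  b_eff <- sqrt(wf$omega1^2 + wz^2) / (2 * pi)
  alpha <- unwrap_reflect(atan2(wf$omega1, wz))
  sweep <- grad1(alpha, wf$t)
  e_mag <- sqrt((2 * pi * b_eff)^2 + sweep^2) / (2 * pi)
  structure(
    data.frame(t = wf$t, b_eff_mag = b_eff, alpha = alpha,
               sweep_rate = sweep, e_field_mag = e_mag),
    class = c("raff2_field", "data.frame"))
}

#' Relative RF power of a waveform
#'
#' Time-averaged \eqn{(\omega_1(t)/\omega_{1max})^2} over the pulse, with
#' \eqn{\omega_{1max}} the nominal (unscaled) peak amplitude. This is the
#' B1-power part of the SAR comparison between a RAFF2 train and a
#' continuous-wave train of equal duration and equal peak RF frequency: a
#' continuous-wave pulse gives 1, a rectified-sine amplitude modulation
#' averages to 0.5 over integer half-periods.
#'
#' @param wf A `raff2_pulse` waveform.
#' @param f1max_hz Nominal peak frequency in Hz used for normalization;
#'   defaults to the waveform's stored `f1max_hz`.
#' @return Dimensionless mean power fraction (0 for an all-zero waveform).
#' @export
rf_power_fraction <- function(wf, f1max_hz = wf$f1max_hz) {
  if (!inherits(wf, "raff2_pulse"))
    stop("'wf' must be a raff2_pulse waveform", call. = FALSE)
  if (all(wf$omega1 == 0)) return(0)
  w1max <- 2 * pi * f1max_hz
  y <- (wf$omega1 / w1max)^2
  # time average by trapezoid rule
  n <- length(wf$t)
  sum((y[-1] + y[-n]) / 2 * diff(wf$t)) / (wf$t[n] - wf$t[1])
}

#' Export a waveform as CSV
#'
#' Writes the scanner-agnostic 3-column exchange format: time in seconds,
#' RF amplitude in Hz, and phase in radians.
#'
#' @param wf A `raff2_pulse` waveform.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_waveform_csv <- function(wf, path) {
  if (!inherits(wf, "raff2_pulse"))
    stop("'wf' must be a raff2_pulse waveform", call. = FALSE)
  utils::write.csv(
    data.frame(t_s = wf$t, omega1_hz = wf$omega1 / (2 * pi),
               phase_rad = wf$phase),
    path, row.names = FALSE)
  invisible(path)
}
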
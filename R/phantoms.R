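#' Per-voxel tissue parameter maps
#'
#' Container for the ground-truth maps a simulation consumes: equilibrium
#' magnetization, T1, T2, TRAFF2, B0 offset (Hz), relative B1 scaling, and
#' an integer label map (0 = background). All maps share one 2-D shape and
#' R's native 1-based (row, column) matrix indexing is used throughout.
#'
#' @param m0_map,t1_map,t2_map,traff2_map Numeric matrices (ms for times).
#' @param b0_map Off-resonance in Hz per voxel.
#' @param b1_map Dimensionless relative B1 per voxel.
#' @param label_map Integer region labels, 0 for background.
#' @return An object of class `tissue_maps`.
#' @export
tissue_maps <- function(m0_map, t1_map, t2_map, traff2_map, b0_map,
                        b1_map, label_map) {
  maps <- list(m0_map = m0_map, t1_map = t1_map, t2_map = t2_map,
               traff2_map = traff2_map, b0_map = b0_map, b1_map = b1_map,
               label_map = label_map)
  shp <- dim(m0_map)
  for (nm in names(maps))
    if (!identical(dim(maps[[nm]]), shp))
      stop(sprintf("'%s' does not match the grid shape", nm), call. = FALSE)
  lab <- label_map > 0
  for (nm in c("m0_map", "t1_map", "t2_map"))
    if (any(!is.finite(maps[[nm]][lab]) | maps[[nm]][lab] <= 0))
      stop(sprintf("labeled voxels must have finite positive '%s'", nm),
           call. = FALSE)
  structure(c(maps, list(shape = shp)), class = "tissue_maps")
}

#' @export
print.tissue_maps <- function(x, ...) {
  cat(sprintf("tissue_maps: %d x %d grid, %d labeled voxels (%d regions)\n",
              x$shape[1], x$shape[2], sum(x$label_map > 0),
              length(setdiff(unique(as.vector(x$label_map)), 0))))
  invisible(x)
}

#' Default nine-vial parameter set
#'
#' Ground-truth parameters for the nine-vial relaxometry phantom: T1 values
#' span 297.8-1421.6 ms and T2 values span 40.1-194.4 ms (the measured
#' ranges of the physical agarose/nickel-chloride phantom). The per-vial
#' TRAFF2 ground truths are synthetic fixture values spanning the measured
#' phantom range 101.7-550.8 ms; the physical vials' rotating-frame decay is
#' not derivable from T1/T2 alone, so these are placeholders, not claims
#' about the physical phantom.
#'
#' @return A list of nine [tissue_params()] objects with `traff2_ms` set.
#' @export
default_vial_params <- function() {
  t1 <- seq(297.8, 1421.6, length.out = 9)
  t2 <- seq(40.1, 194.4, length.out = 9)
  traff2 <- seq(101.7, 550.8, length.out = 9)
  lapply(seq_len(9), function(i)
    tissue_params(m0 = 1, t1_ms = t1[i], t2_ms = t2[i],
                  traff2_ms = traff2[i]))
}

# smooth linear + Gaussian-bump field, scaled so max |field| = peak_hz
default_b0_field <- function(shape, peak_hz = 50) {
  r <- matrix(seq(-1, 1, length.out = shape[1]), shape[1], shape[2])
  cc <- matrix(seq(-1, 1, length.out = shape[2]), shape[1], shape[2],
               byrow = TRUE)
  f <- 0.5 * cc + 0.3 * r +
    exp(-((r - 0.35)^2 + (cc - 0.25)^2) / (2 * 0.25^2))
  if (peak_hz == 0) return(f * 0)
  f / max(abs(f)) * peak_hz
}

#' Nine-vial digital phantom
#'
#' Lays `vial_params` out as filled discs on a 3 x 3 grid, emulating a
#' multi-vial relaxometry phantom. Defaults: the nine-vial parameter set of
#' [default_vial_params()], a smooth linear-plus-bump B0 field with a
#' configurable peak (default 50 Hz), and a constant relative B1 of 1.05.
#'
#' @param grid_size Side of the square grid in voxels (at least 64).
#' @param vial_params List of 1-9 [tissue_params()] objects.
#' @param vial_radius Disc radius in voxels; defaults to 40% of the 3 x 3
#'   cell spacing. Radii that make neighbouring vials overlap are refused.
#' @param b0_peak_hz Peak absolute off-resonance of the default B0 field.
#' @param b1_value Constant relative B1 value.
#' @param seed Unused placeholder for interface symmetry (the phantom is
#'   deterministic); kept so configuration files can carry one seed.
#' @return A `tissue_maps` object; vial i has label i.
#' @export
make_vial_phantom <- function(grid_size = 128, vial_params = NULL,
                              vial_radius = NULL, b0_peak_hz = 50,
                              b1_value = 1.05, seed = NULL) {
  if (grid_size < 64) stop("'grid_size' must be at least 64", call. = FALSE)
  if (is.null(vial_params)) vial_params <- default_vial_params()
  nv <- length(vial_params)
  if (nv < 1 || nv > 9) stop("between 1 and 9 vials supported",
                             call. = FALSE)
  spacing <- grid_size / 3
  if (is.null(vial_radius)) vial_radius <- 0.4 * spacing
  if (vial_radius >= spacing / 2)
    stop(sprintf(paste0("vial radius %.1f overlaps neighbouring vials ",
                        "(max %.1f for this grid)"),
                 vial_radius, spacing / 2), call. = FALSE)
  shp <- c(grid_size, grid_size)
  zero <- matrix(0, grid_size, grid_size)
  m0 <- zero; t1 <- zero; t2 <- zero; tr <- zero; lab <- zero
  centers <- expand.grid(r = spacing * (0:2) + spacing / 2,
                         c = spacing * (0:2) + spacing / 2)
  rows <- matrix(seq_len(grid_size), grid_size, grid_size)
  cols <- t(rows)
  for (i in seq_len(nv)) {
    inside <- (rows - centers$r[i])^2 + (cols - centers$c[i])^2 <=
      vial_radius^2
    p <- vial_params[[i]]
    m0[inside] <- p$m0; t1[inside] <- p$t1_ms; t2[inside] <- p$t2_ms
    tr[inside] <- if (is.null(p$traff2_ms)) NA_real_ else p$traff2_ms
    lab[inside] <- i
  }
  tissue_maps(m0, t1, t2, tr, default_b0_field(shp, b0_peak_hz),
              matrix(b1_value, grid_size, grid_size), lab)
}

#' Short-axis left-ventricle annulus phantom
#'
#' Builds an annular myocardium around a blood pool, with the right-ventricle
#' insertion point marked on the outer boundary (the angular origin of the
#' AHA segmentation), and optionally a focal wedge lesion with elevated
#' TRAFF2 inside the annulus.
#'
#' @param grid_size Side of the square grid in voxels.
#' @param radii Inner and outer myocardial radii in voxels,
#'   `c(inner, outer)` with `inner < outer`; defaults scale with the grid.
#' @param traff2_myocardium_ms Ground-truth myocardial TRAFF2 in ms
#'   (default 79.1 ms, a healthy mid-myocardial value).
#' @param traff2_blood_ms Ground-truth blood-pool TRAFF2 in ms.
#' @param lesion Optional lesion specification:
#'   `list(angle_deg =, width_deg =, traff2_ms =)` — a wedge of the annulus
#'   centred at `angle_deg` (measured from the RV insertion,
#'   counterclockwise) spanning `width_deg`, with its own TRAFF2.
#' @param rv_angle_deg Angular position of the RV insertion on the outer
#'   boundary, degrees (image convention of [aha16_label()]).
#' @param seed Unused placeholder (deterministic construction).
#' @return An object of class `sax_phantom`: `maps` (a `tissue_maps`),
#'   `lv_center`, `rv_insertion` (1-based (row, col)), `myocardium_mask`,
#'   `blood_mask` and `lesion_mask`. Labels: 1 myocardium, 2 blood,
#'   3 lesion.
#' @export
make_sax_phantom <- function(grid_size = 128, radii = NULL,
                             traff2_myocardium_ms = 79.1,
                             traff2_blood_ms = 150,
                             lesion = NULL, rv_angle_deg = 150,
                             seed = NULL) {
  if (is.null(radii)) radii <- grid_size * c(0.20, 0.34)
  if (radii[1] >= radii[2])
    stop("inner radius must be smaller than outer radius", call. = FALSE)
  ctr <- c(grid_size, grid_size) / 2 + 0.5
  rows <- matrix(seq_len(grid_size), grid_size, grid_size)
  cols <- t(rows)
  rr <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  myo <- rr >= radii[1] & rr <= radii[2]
  blood <- rr < radii[1]
  theta <- atan2(-(rows - ctr[1]), cols - ctr[2]) # CCW, x = col, y = -row
  rv_theta <- rv_angle_deg * pi / 180
  rv <- c(round(ctr[1] - radii[2] * sin(rv_theta)),
          round(ctr[2] + radii[2] * cos(rv_theta)))
  lesion_mask <- matrix(FALSE, grid_size, grid_size)
  if (!is.null(lesion)) {
    off <- (theta - rv_theta - lesion$angle_deg * pi / 180) %% (2 * pi)
    half <- lesion$width_deg / 2 * pi / 180
    lesion_mask <- myo & (off <= half | off >= 2 * pi - half)
    if (!any(lesion_mask))
      stop("lesion specification selects no voxels inside the annulus",
           call. = FALSE)
  }
  zero <- matrix(0, grid_size, grid_size)
  m0 <- zero; t1 <- zero; t2 <- zero; tr <- zero; lab <- zero
  m0[myo] <- 1; t1[myo] <- 1200; t2[myo] <- 45
  tr[myo] <- traff2_myocardium_ms; lab[myo] <- 1
  m0[blood] <- 1; t1[blood] <- 1900; t2[blood] <- 180
  tr[blood] <- traff2_blood_ms; lab[blood] <- 2
  if (any(lesion_mask)) {
    tr[lesion_mask] <- lesion$traff2_ms
    lab[lesion_mask] <- 3
  }
  maps <- tissue_maps(m0, t1, t2, tr, default_b0_field(dim(zero), 0),
                      matrix(1, grid_size, grid_size), lab)
  structure(list(maps = maps, lv_center = ctr, rv_insertion = rv,
                 myocardium_mask = myo, blood_mask = blood,
                 lesion_mask = lesion_mask),
            class = "sax_phantom")
}

#' @export
print.sax_phantom <- function(x, ...) {
  cat(sprintf(
    "sax_phantom: %d x %d grid, %d myocardial voxels%s\n",
    x$maps$shape[1], x$maps$shape[2], sum(x$myocardium_mask),
    if (any(x$lesion_mask))
      sprintf(", lesion of %d voxels", sum(x$lesion_mask)) else ""))
  invisible(x)
}

#' Add seeded noise to a weighted series
#'
#' Gaussian noise adds independent N(0, sigma^2) to every voxel of every
#' contrast. Rician noise replaces each magnitude S by
#' `|S + n1 + i n2|` with independent `n1, n2 ~ N(0, sigma^2)`, the
#' magnitude-image noise model; at S = 0 it reduces to a Rayleigh
#' distribution with mean `sigma * sqrt(pi / 2)`, the noise floor that
#' biases the offset parameter of the signal model upward at low SNR.
#'
#' @param series A [weighted_series()].
#' @param sigma Absolute noise standard deviation (non-negative).
#' @param model `"gaussian"` or `"rician"`.
#' @param seed Integer seed; identical seeds give identical realizations.
#' @return A new `weighted_series` with noisy images.
#' @export
add_noise <- function(series, sigma, model = c("gaussian", "rician"),
                      seed = NULL) {
  model <- match.arg(model)
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  if (sigma == 0) return(series)
  if (!is.null(seed)) set.seed(seed)
  x <- series$images
  if (model == "gaussian") {
    x <- x + stats::rnorm(length(x), 0, sigma)
  } else {
    x <- sqrt((x + stats::rnorm(length(x), 0, sigma))^2 +
                stats::rnorm(length(x), 0, sigma)^2)
  }
  weighted_series(x, series$prep_ms, series$mask)
}
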
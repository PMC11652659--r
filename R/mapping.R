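#' Contrast-weighted image series
#'
#' A stack of magnitude images with one preparation duration per image. The
#' abscissa vector `prep_ms` may contain a `0` (no preparation) and at most
#' one `Inf`, the saturation sentinel: the saturation image mimics an
#' infinitely long preparation and enters the signal model as `S = B`
#' exactly.
#'
#' @param images 3-D array `(rows, cols, contrasts)`, a matrix interpreted
#'   as a single image row of voxels, or a plain numeric vector interpreted
#'   as a single voxel.
#' @param prep_ms Numeric vector of preparation durations in ms, `Inf`
#'   allowed once.
#' @param mask Optional logical matrix restricting analysis.
#' @return An object of class `weighted_series`.
#' @export
weighted_series <- function(images, prep_ms, mask = NULL) {
  if (is.vector(images) && is.numeric(images))
    images <- array(images, c(1L, 1L, length(images)))
  if (length(dim(images)) == 2L)
    images <- array(images, c(dim(images)[1], 1L, dim(images)[2]))
  if (length(dim(images)) != 3L)
    stop("'images' must be a (rows, cols, contrasts) array", call. = FALSE)
  nc <- dim(images)[3]
  if (length(prep_ms) != nc)
    stop(sprintf(
      "contrast-count mismatch: %d images but %d preparation durations",
      nc, length(prep_ms)), call. = FALSE)
  if (sum(is.infinite(prep_ms)) > 1L)
    stop("at most one saturation (infinite) preparation entry is allowed",
         call. = FALSE)
  if (any(prep_ms < 0)) stop("preparation durations must be >= 0",
                             call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, dim(images)[1], dim(images)[2])
  structure(list(images = images, prep_ms = as.numeric(prep_ms),
                 mask = mask),
            class = "weighted_series")
}

#' @export
print.weighted_series <- function(x, ...) {
  p <- ifelse(is.infinite(x$prep_ms), "sat", format(x$prep_ms))
  cat(sprintf("weighted_series: %d x %d voxels, %d contrasts (prep ms: %s)\n",
              dim(x$images)[1], dim(x$images)[2], dim(x$images)[3],
              paste(p, collapse = ", ")))
  invisible(x)
}

# decay factors exp(-Tp/T) with the saturation sentinel mapped to 0
decay_factors <- function(prep_ms, traff2_ms) {
  e <- exp(-prep_ms / traff2_ms)
  e[is.infinite(prep_ms)] <- 0
  e
}

# model Jacobian d S / d (A, B, T) at (a, b, t); sat rows are (0, 1, 0)
model_jacobian <- function(prep_ms, a, t) {
  e <- decay_factors(prep_ms, t)
  tp <- ifelse(is.infinite(prep_ms), 0, prep_ms)
  cbind(e, 1, a * tp / t^2 * e)
}

#' Log-linear initializer for exponential decay
#'
#' Closed-form starting values for mono-exponential fitting: subtract the
#' offset estimate, take logs, and regress over the finite preparation
#' durations. On noiseless offset-free data the slope equals `-1/T` exactly.
#'
#' @param s Signal vector.
#' @param prep_ms Preparation durations (ms), `Inf` allowed.
#' @param b0 Offset estimate subtracted before the log (default 0).
#' @return Named vector `c(a0 =, t0 =)`; `t0` is `NA` when fewer than two
#'   usable points remain.
#' @export
loglin_decay_init <- function(s, prep_ms, b0 = 0) {
  fin <- is.finite(prep_ms)
  y <- s[fin] - b0
  tp <- prep_ms[fin]
  ok <- y > max(s) * 1e-9
  if (sum(ok) < 2L) return(c(a0 = max(s[1] - b0, 0), t0 = NA_real_))
  fit <- stats::lm.fit(cbind(1, tp[ok]), log(y[ok]))
  slope <- fit$coefficients[2]
  t0 <- if (is.finite(slope) && slope < 0) -1 / slope else NA_real_
  c(a0 = unname(exp(fit$coefficients[1])), t0 = unname(t0))
}

# single-voxel three-parameter fit; returns estimates, SSR, flags, SE
fit_voxel <- function(s, prep_ms, lower, upper, maxit = 200L, tol = 1e-8) {
  n <- length(s)
  out <- list(a = NA_real_, b = NA_real_, t = NA_real_, ssr = NA_real_,
              sd = NA_real_, resid = rep(NA_real_, n),
              converged = FALSE, at_bound = FALSE,
              insufficient_signal = FALSE)
  if (max(s) <= 0 || diff(range(s)) < 1e-12 * max(max(s), 1)) {
    out$insufficient_signal <- TRUE
    return(out)
  }
  has_sat <- any(is.infinite(prep_ms))
  b0 <- if (has_sat) mean(s[is.infinite(prep_ms)]) else min(s)
  a0 <- max(s[which.min(ifelse(is.infinite(prep_ms), Inf, prep_ms))] - b0,
            1e-6 * max(s))
  ini <- loglin_decay_init(s, prep_ms, b0)
  t0 <- ini["t0"]
  if (!is.finite(t0)) t0 <- sqrt(lower[3] * upper[3])
  t0 <- min(max(t0, lower[3]), upper[3])
  res_fn <- function(p) s - (p[1] * decay_factors(prep_ms, p[3]) + p[2])
  jac_fn <- function(p) -model_jacobian(prep_ms, p[1], p[3])
  fit <- try(minpack.lm::nls.lm(
    par = c(a0, b0, t0), lower = lower, upper = upper,
    fn = res_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = maxit, ftol = tol, ptol = tol)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    out$insufficient_signal <- TRUE
    return(out)
  }
  p <- fit$par
  out$a <- p[1]; out$b <- p[2]; out$t <- p[3]
  out$resid <- res_fn(p)
  out$ssr <- sum(out$resid^2)
  out$converged <- fit$info %in% 1:4
  rel <- function(x, y) abs(x - y) <= 1e-6 * max(abs(y), 1)
  out$at_bound <- rel(p[3], lower[3]) || rel(p[3], upper[3])
  if (out$at_bound) out$converged <- FALSE
  if (n > 3L && out$converged) {
    J <- model_jacobian(prep_ms, p[1], p[3])
    jtj <- crossprod(J)
    cv <- try(solve(jtj), silent = TRUE)
    if (!inherits(cv, "try-error") && cv[3, 3] > 0)
      out$sd <- sqrt(out$ssr / (n - 3L) * cv[3, 3])
  }
  out
}

#' Voxel-wise three-parameter TRAFF2 fitting
#'
#' Fits the signal model \deqn{S(T_p) = A\,e^{-T_p/T_{RAFF2}} + B} to every
#' masked voxel of a weighted series by nonlinear least squares
#' (Levenberg-Marquardt with analytic Jacobian, parameter bounds
#' \eqn{T_{RAFF2} \in} `t_bounds_ms`, \eqn{A, B \ge 0}). The saturation
#' image enters the residual as `S = B` exactly. Initialization: `B` from
#' the saturation image (else the series minimum), `A` from the no-prep
#' image, and `TRAFF2` from a log-linear regression, clipped to bounds.
#' A Gaussian likelihood on the magnitude data is assumed; the Rician noise
#' floor at low SNR biases `B` upward and is not corrected.
#'
#' Per-voxel standard errors of the TRAFF2 estimate — the SD map — are
#' derived from the fit residuals:
#' \eqn{SD = \sqrt{SSR/(n-3)\,[(J^T J)^{-1}]_{TT}}}.
#'
#' Non-converged voxels are flagged (`converged`, `at_bound`,
#' `insufficient_signal`), never silently filled.
#'
#' @param series A [weighted_series()] with at least 3 distinct preparation
#'   durations (0 and the saturation sentinel count).
#' @param mask Optional logical matrix; defaults to the series mask.
#' @param t_bounds_ms Lower/upper TRAFF2 bounds in ms (default
#'   `c(1, 2000)`).
#' @param maxit,tol Optimizer iteration cap and relative tolerance.
#' @return An object of class `traff2_fit` with matrices `traff2_map`,
#'   `a_map`, `b_map`, `sd_map`, `rss_map`, a residual array, and logical
#'   flag matrices. Supports `print`, `summary`, `coef`, `predict`,
#'   `residuals` and `plot`.
#' @examples
#' s <- weighted_series(0.8 * exp(-c(0, 22.98, 46.66, 70.34) / 80) + 0.2,
#'                      c(0, 22.98, 46.66, 70.34))
#' fit <- fit_traff2(s)
#' coef(fit)
#' @export
fit_traff2 <- function(series, mask = NULL, t_bounds_ms = c(1, 2000),
                       maxit = 200L, tol = 1e-8) {
  if (!inherits(series, "weighted_series"))
    stop("'series' must be a weighted_series", call. = FALSE)
  prep <- series$prep_ms
  if (length(unique(prep)) < 3L)
    stop("at least 3 distinct preparation durations are required for a ",
         "three-parameter fit", call. = FALSE)
  dims <- dim(series$images)
  if (is.null(mask)) mask <- series$mask
  lower <- c(0, 0, t_bounds_ms[1])
  upper <- c(Inf, Inf, t_bounds_ms[2])
  nam <- matrix(NA_real_, dims[1], dims[2])
  fl <- matrix(FALSE, dims[1], dims[2])
  out <- list(traff2_map = nam, a_map = nam, b_map = nam, sd_map = nam,
              rss_map = nam,
              residuals = array(NA_real_, dims),
              flags = list(converged = fl, at_bound = fl,
                           insufficient_signal = fl),
              prep_ms = prep, series = series, t_bounds_ms = t_bounds_ms,
              call = match.call())
  idx <- which(mask)
  nxy <- dims[1] * dims[2]
  for (v in idx) {
    s <- series$images[v + nxy * (seq_len(dims[3]) - 1L)]
    f <- fit_voxel(s, prep, lower, upper, maxit, tol)
    out$traff2_map[v] <- f$t
    out$a_map[v] <- f$a
    out$b_map[v] <- f$b
    out$sd_map[v] <- f$sd
    out$rss_map[v] <- f$ssr
    out$residuals[v + nxy * (seq_len(dims[3]) - 1L)] <- f$resid
    out$flags$converged[v] <- f$converged
    out$flags$at_bound[v] <- f$at_bound
    out$flags$insufficient_signal[v] <- f$insufficient_signal
  }
  class(out) <- "traff2_fit"
  out
}

#' @export
print.traff2_fit <- function(x, ...) {
  ok <- x$flags$converged
  cat("Voxel-wise TRAFF2 fit (three-parameter exponential)\n")
  cat(sprintf("  voxels fitted: %d converged, %d at bound, %d insufficient\n",
              sum(ok), sum(x$flags$at_bound),
              sum(x$flags$insufficient_signal)))
  if (any(ok))
    cat(sprintf("  TRAFF2: median %.1f ms (range %.1f-%.1f ms)\n",
                stats::median(x$traff2_map[ok]), min(x$traff2_map[ok]),
                max(x$traff2_map[ok])))
  invisible(x)
}

#' @export
summary.traff2_fit <- function(object, ...) {
  ok <- object$flags$converged
  s <- list(
    n_converged = sum(ok),
    n_at_bound = sum(object$flags$at_bound),
    n_insufficient = sum(object$flags$insufficient_signal),
    traff2_mean = mean(object$traff2_map[ok]),
    traff2_sd = stats::sd(object$traff2_map[ok]),
    traff2_median = stats::median(object$traff2_map[ok]),
    sd_map_median = stats::median(object$sd_map[ok], na.rm = TRUE),
    prep_ms = object$prep_ms)
  class(s) <- "summary.traff2_fit"
  s
}

#' @export
print.summary.traff2_fit <- function(x, ...) {
  cat("TRAFF2 fit summary\n")
  p <- ifelse(is.infinite(x$prep_ms), "sat", format(x$prep_ms))
  cat(sprintf("  preparations (ms): %s\n", paste(p, collapse = ", ")))
  cat(sprintf("  converged %d | at bound %d | insufficient %d\n",
              x$n_converged, x$n_at_bound, x$n_insufficient))
  if (x$n_converged > 0) {
    cat(sprintf("  TRAFF2 mean %.2f ms, SD %.2f ms, median %.2f ms\n",
                x$traff2_mean, x$traff2_sd, x$traff2_median))
    cat(sprintf("  median SD-map value %.3f ms\n", x$sd_map_median))
  }
  invisible(x)
}

#' @export
coef.traff2_fit <- function(object, ...) {
  if (prod(dim(object$traff2_map)) == 1L)
    return(c(A = object$a_map[1], B = object$b_map[1],
             TRAFF2 = object$traff2_map[1]))
  list(a = object$a_map, b = object$b_map, traff2 = object$traff2_map)
}

#' @export
predict.traff2_fit <- function(object, prep_ms = object$prep_ms, ...) {
  dims <- c(dim(object$traff2_map), length(prep_ms))
  out <- array(NA_real_, dims)
  for (j in seq_along(prep_ms)) {
    e <- if (is.infinite(prep_ms[j])) 0 else
      exp(-prep_ms[j] / object$traff2_map)
    out[, , j] <- object$a_map * e + object$b_map
  }
  if (prod(dims[1:2]) == 1L) drop(out) else out
}

#' @export
residuals.traff2_fit <- function(object, ...) object$residuals

#' @export
plot.traff2_fit <- function(x, which = c("traff2", "sd"), zlim = NULL, ...) {
  which <- match.arg(which)
  m <- if (which == "traff2") x$traff2_map else x$sd_map
  if (prod(dim(m)) == 1L) {
    tp <- x$prep_ms
    s <- drop(x$series$images)
    tpl <- ifelse(is.infinite(tp), max(tp[is.finite(tp)]) * 1.3, tp)
    graphics::plot(tpl, s, xlab = "preparation duration [ms]",
                   ylab = "signal", pch = 19, ...)
    tt <- seq(0, max(tpl), length.out = 200)
    graphics::lines(tt, x$a_map[1] * exp(-tt / x$traff2_map[1]) + x$b_map[1])
    graphics::abline(h = x$b_map[1], lty = 3)
    return(invisible(x))
  }
  if (is.null(zlim))
    zlim <- range(m[is.finite(m)], na.rm = TRUE)
  graphics::image(t(m)[, nrow(m):1], zlim = zlim, axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = if (which == "traff2") "TRAFF2 [ms]" else
                    "SD [ms]", ...)
  invisible(x)
}

#' SD map from fit residuals
#'
#' Recomputes the spatially-resolved standard deviation of the TRAFF2
#' estimate from the fit residuals: per converged voxel,
#' \eqn{SD = \sqrt{\hat\sigma^2 \,[(J^T J)^{-1}]_{TT}}} with
#' \eqn{\hat\sigma^2 = SSR/(n-3)}. Voxels with `n <= 3` contrasts have no
#' residual degrees of freedom and return `NA`.
#'
#' @param fit A `traff2_fit` object.
#' @param series The series it was fitted to (defaults to the stored one).
#' @return Matrix of per-voxel SD values in ms.
#' @export
sd_map_from_residuals <- function(fit, series = fit$series) {
  prep <- series$prep_ms
  n <- length(prep)
  out <- matrix(NA_real_, nrow(fit$traff2_map), ncol(fit$traff2_map))
  if (n <= 3L) return(out)
  idx <- which(fit$flags$converged)
  nxy <- prod(dim(fit$traff2_map))
  for (v in idx) {
    r <- fit$residuals[v + nxy * (seq_len(n) - 1L)]
    J <- model_jacobian(prep, fit$a_map[v], fit$traff2_map[v])
    cv <- try(solve(crossprod(J)), silent = TRUE)
    if (!inherits(cv, "try-error") && cv[3, 3] > 0)
      out[v] <- sqrt(sum(r^2) / (n - 3L) * cv[3, 3])
  }
  out
}

#' Cramer-Rao lower bound for the TRAFF2 estimate
#'
#' Analytic lower bound on the standard deviation of the TRAFF2 estimator
#' under i.i.d. Gaussian noise of standard deviation `sigma`:
#' \eqn{\sigma \sqrt{[(J^T J)^{-1}]_{TT}}} with the model Jacobian evaluated
#' at the true parameters.
#'
#' @param a,b,traff2_ms True model parameters.
#' @param prep_ms Preparation durations (ms), `Inf` allowed.
#' @param sigma Noise standard deviation (signal units).
#' @return Standard-deviation bound in ms.
#' @export
traff2_crb <- function(a, b, traff2_ms, prep_ms, sigma) {
  J <- model_jacobian(prep_ms, a, traff2_ms)
  sigma * sqrt(solve(crossprod(J))[3, 3])
}

#' Generic mono-exponential decay fitting
#'
#' Two- or three-parameter exponential fitting with the same engine as
#' [fit_traff2()]: `S = A exp(-Tp/T)` or `S = A exp(-Tp/T) + B`. Provided
#' as plumbing for reference relaxometry (e.g. T2-prepared series at 0, 25
#' and 50 ms).
#'
#' @param series A [weighted_series()].
#' @param n_params 2 or 3.
#' @param t_bounds_ms Decay-time bounds in ms.
#' @return List of matrices `t_map`, `a_map` and (3-parameter) `b_map`,
#'   plus a `converged` flag matrix.
#' @export
fit_monoexp_decay <- function(series, n_params = 2, t_bounds_ms = c(1, 5000)) {
  if (!n_params %in% c(2, 3)) stop("'n_params' must be 2 or 3",
                                   call. = FALSE)
  prep <- series$prep_ms
  if (length(unique(prep)) < n_params)
    stop(sprintf("at least %d distinct preparation durations required",
                 n_params), call. = FALSE)
  dims <- dim(series$images)
  nam <- matrix(NA_real_, dims[1], dims[2])
  t_map <- nam; a_map <- nam; b_map <- nam
  conv <- matrix(FALSE, dims[1], dims[2])
  nxy <- dims[1] * dims[2]
  lower <- c(0, if (n_params == 3) 0, t_bounds_ms[1])
  upper <- c(Inf, if (n_params == 3) Inf, t_bounds_ms[2])
  for (v in which(series$mask)) {
    s <- series$images[v + nxy * (seq_len(dims[3]) - 1L)]
    if (max(s) <= 0) next
    if (n_params == 3) {
      f <- fit_voxel(s, prep, lower, upper)
      t_map[v] <- f$t; a_map[v] <- f$a; b_map[v] <- f$b
      conv[v] <- f$converged
    } else {
      ini <- loglin_decay_init(s, prep)
      t0 <- ini["t0"]; if (!is.finite(t0)) t0 <- 50
      t0 <- min(max(t0, lower[2]), upper[2])
      fit <- try(minpack.lm::nls.lm(
        par = c(ini["a0"], t0), lower = lower, upper = upper,
        fn = function(p) s - p[1] * decay_factors(prep, p[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200L)),
        silent = TRUE)
      if (!inherits(fit, "try-error")) {
        t_map[v] <- fit$par[2]; a_map[v] <- fit$par[1]
        conv[v] <- fit$info %in% 1:4
      }
    }
  }
  c(list(t_map = t_map, a_map = a_map, converged = conv),
    if (n_params == 3) list(b_map = b_map))
}
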
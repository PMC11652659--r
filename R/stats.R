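#' Coefficient of variation in percent
#'
#' `100 * sample SD / mean`. Scale-invariant and non-negative; the sample
#' (n - 1) standard deviation is used, as everywhere in this package.
#'
#' @param values Numeric vector, at least two finite values, nonzero mean.
#' @return CV in percent.
#' @examples
#' cv_percent(c(95, 100, 105))  # 5
#' @export
cv_percent <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop("at least two finite values are required", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("CV is undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Per-segment measurement table
#'
#' Tidy table keyed by (subject, repetition, slice, segment) holding the
#' segment-mean TRAFF2 and segment-mean SD-map values. Segment indices
#' follow the AHA 16-segment convention: basal 1-6, mid-ventricular 7-12,
#' apical 13-16.
#'
#' @param subject,repetition Identifiers (coerced to character/integer).
#' @param slice One of `"basal"`, `"mid"`, `"apical"` per row.
#' @param segment Integer 1-16 per row, consistent with the slice.
#' @param mean_ms,sd_ms Segment means of the TRAFF2 map and of the SD map.
#' @return A data frame of class `segment_table`.
#' @export
segment_table <- function(subject, repetition, slice, segment, mean_ms,
                          sd_ms = NA_real_) {
  slice <- as.character(slice)
  if (!all(slice %in% c("basal", "mid", "apical")))
    stop("'slice' must be basal, mid or apical", call. = FALSE)
  segment <- as.integer(segment)
  rng <- list(basal = 1:6, mid = 7:12, apical = 13:16)
  bad <- !mapply(function(sl, sg) sg %in% rng[[sl]], slice, segment)
  if (any(bad))
    stop("segment indices inconsistent with the AHA slice convention",
         call. = FALSE)
  structure(
    data.frame(subject = as.character(subject),
               repetition = as.integer(repetition), slice = slice,
               segment = segment, mean_ms = mean_ms, sd_ms = sd_ms),
    class = c("segment_table", "data.frame"))
}

#' Precision, reproducibility and inter-subject variability
#'
#' Per AHA segment, three coefficient-of-variation statistics:
#' \describe{
#'   \item{precision `wcv`}{mean over (subject, repetition) cells of
#'     `100 * segment SD-map mean / segment TRAFF2 mean` — the
#'     residual-based single-measurement precision.}
#'   \item{reproducibility `wcv_bar`}{mean over subjects of
#'     `100 * SD(across that subject's repetition means) / subject mean` —
#'     test-retest dispersion.}
#'   \item{inter-subject variability `cv_bar`}{`100 * SD(across subjects of
#'     per-subject means) / grand mean` — between-subject dispersion of the
#'     repetition-averaged values.}
#' }
#' All use the sample (n - 1) SD. Missing (subject, repetition) cells are
#' refused with an explicit listing.
#'
#' @param table A [segment_table()] with at least 2 repetitions and, for
#'   `cv_bar`, at least 2 subjects.
#' @return List with a per-segment data frame (`per_segment`) and global
#'   averages `wcv`, `wcv_bar`, `cv_bar` (means across segments).
#' @export
precision_reproducibility_intersubject <- function(table) {
  subjects <- unique(table$subject)
  reps <- unique(table$repetition)
  if (length(reps) < 2L)
    stop("at least two repetitions are required", call. = FALSE)
  if (length(subjects) < 2L)
    stop("inter-subject variability is undefined for a single subject",
         call. = FALSE)
  segs <- sort(unique(table$segment))
  grid <- expand.grid(subject = subjects, repetition = reps,
                      segment = segs, stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject, d$repetition, d$segment)
  missing <- grid[!(key(grid) %in% key(table)), , drop = FALSE]
  if (nrow(missing) > 0L)
    stop("missing (subject, repetition) cells: ",
         paste(sprintf("(%s, %d, seg %d)", missing$subject,
                       missing$repetition, missing$segment),
               collapse = ", "), call. = FALSE)
  per_seg <- do.call(rbind, lapply(segs, function(sg) {
    d <- table[table$segment == sg, ]
    wcv <- mean(100 * d$sd_ms / d$mean_ms)
    subj_means <- tapply(d$mean_ms, d$subject, mean)
    subj_wcv <- tapply(d$mean_ms, d$subject,
                       function(x) 100 * stats::sd(x) / mean(x))
    data.frame(segment = sg, wcv = wcv, wcv_bar = mean(subj_wcv),
               cv_bar = 100 * stats::sd(subj_means) / mean(subj_means))
  }))
  list(per_segment = per_seg,
       wcv = mean(per_seg$wcv), wcv_bar = mean(per_seg$wcv_bar),
       cv_bar = mean(per_seg$cv_bar))
}

#' Simulate a hierarchical segment cohort
#'
#' Generates a complete [segment_table()] for a healthy cohort under a
#' two-level model: per segment, subject means are drawn around `mean_ms`
#' with between-subject CV `between_cv` (percent), and repetition values
#' around the subject mean with within-subject CV `within_cv` (percent).
#' The SD-map column is `precision_cv` percent of the repetition value.
#' Used for generative-parameter recovery checks of the variability
#' estimators.
#'
#' @param n_subjects,n_reps Cohort size (default 7 subjects, 3 repetitions).
#' @param mean_ms Population mean TRAFF2 in ms (default 79.1).
#' @param between_cv,within_cv,precision_cv Generative CVs in percent
#'   (defaults 10, 1, 7.6).
#' @param seed Integer seed.
#' @return A `segment_table` covering 16 segments, all subjects and
#'   repetitions (basal 1-6, mid 7-12, apical 13-16).
#' @export
simulate_segment_cohort <- function(n_subjects = 7, n_reps = 3,
                                    mean_ms = 79.1, between_cv = 10,
                                    within_cv = 1, precision_cv = 7.6,
                                    seed = 1) {
  set.seed(seed)
  slices <- c(rep("basal", 6), rep("mid", 6), rep("apical", 4))
  rows <- list()
  for (sg in 1:16) {
    subj_mean <- mean_ms * (1 + stats::rnorm(n_subjects, 0,
                                             between_cv / 100))
    for (su in seq_len(n_subjects)) {
      vals <- subj_mean[su] * (1 + stats::rnorm(n_reps, 0, within_cv / 100))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", su), repetition = seq_len(n_reps),
        slice = slices[sg], segment = sg, mean_ms = vals,
        sd_ms = vals * precision_cv / 100)
    }
  }
  d <- do.call(rbind, rows)
  segment_table(d$subject, d$repetition, d$slice, d$segment, d$mean_ms,
                d$sd_ms)
}

#' Pearson correlation and Bland-Altman agreement
#'
#' Least-squares line and coefficient of determination between paired ROI
#' means, plus Bland-Altman statistics: mean difference (bias) and the
#' limits of agreement `bias +/- 1.96 * SD(differences)`.
#'
#' @param x,y Paired numeric vectors (at least 3 points; `x` must vary).
#' @return List with `r2`, `slope`, `intercept`, `bias`, `loa_low`,
#'   `loa_high`.
#' @export
pearson_and_bland_altman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must be paired with at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("R^2 is undefined when x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  d <- y - x
  sdd <- stats::sd(d)
  list(r2 = if (stats::sd(y) == 0) 1 else unname(stats::cor(x, y)^2),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       bias = mean(d),
       loa_low = mean(d) - 1.96 * sdd,
       loa_high = mean(d) + 1.96 * sdd)
}

#' Two-standard-deviation scar mask
#'
#' Voxels whose map value exceeds the remote-region mean plus two remote
#' standard deviations — the 2SD segmentation method for hyperintense scar.
#'
#' @param map_img Numeric matrix (parametric map).
#' @param remote_roi Logical matrix marking the remote (reference) region.
#' @param search_mask Optional logical matrix restricting the search
#'   (e.g. the myocardium); defaults to everywhere.
#' @return Logical matrix of supra-threshold voxels, with the threshold in
#'   attribute `"threshold"`.
#' @export
scar_mask_2sd <- function(map_img, remote_roi, search_mask = NULL) {
  if (!any(remote_roi)) stop("'remote_roi' is empty", call. = FALSE)
  vals <- map_img[remote_roi]
  thr <- mean(vals) + 2 * stats::sd(vals)
  if (stats::sd(vals) == 0)
    warning("remote SD is zero: degenerate 2SD threshold", call. = FALSE)
  out <- map_img > thr
  if (!is.null(search_mask)) out <- out & search_mask
  attr(out, "threshold") <- thr
  out
}

#' AHA 16-segment labelling of a short-axis slice
#'
#' Partitions a myocardial mask into the AHA segments of one slice level by
#' angular position around the LV center, starting at the anterior RV
#' insertion and proceeding counterclockwise: 6 segments of 60 degrees for
#' basal (labels 1-6) and mid-ventricular (7-12) slices, 4 segments of 90
#' degrees for apical (13-16). Every myocardial voxel receives exactly one
#' label. Angles use image coordinates with `x = column`,
#' `y = -row` (so "counterclockwise" matches the on-screen convention);
#' set `clockwise = TRUE` for flipped data.
#'
#' @param mask Logical myocardium matrix, or a `sax_phantom` (whose mask,
#'   center and insertion are then used).
#' @param lv_center,rv_insertion Numeric `(row, col)` coordinates (1-based);
#'   ignored when a phantom is supplied.
#' @param slice_level `"basal"`, `"mid"` or `"apical"`.
#' @param clockwise Chirality flag for flipped acquisitions.
#' @return Integer matrix of labels (0 outside the mask).
#' @export
aha16_label <- function(mask, lv_center = NULL, rv_insertion = NULL,
                        slice_level = c("mid", "basal", "apical"),
                        clockwise = FALSE) {
  slice_level <- match.arg(slice_level)
  if (inherits(mask, "sax_phantom")) {
    lv_center <- mask$lv_center
    rv_insertion <- mask$rv_insertion
    mask <- mask$myocardium_mask
  }
  if (is.null(lv_center) || is.null(rv_insertion))
    stop("'lv_center' and 'rv_insertion' are required", call. = FALSE)
  if (all(abs(rv_insertion - lv_center) < .Machine$double.eps * 4))
    stop("RV insertion coincides with the LV center: angle undefined",
         call. = FALSE)
  nseg <- if (slice_level == "apical") 4L else 6L
  base <- switch(slice_level, basal = 0L, mid = 6L, apical = 12L)
  rows <- matrix(seq_len(nrow(mask)), nrow(mask), ncol(mask))
  cols <- t(matrix(seq_len(ncol(mask)), ncol(mask), nrow(mask)))
  ang <- atan2(-(rows - lv_center[1]), cols - lv_center[2])
  ang0 <- atan2(-(rv_insertion[1] - lv_center[1]),
                rv_insertion[2] - lv_center[2])
  off <- if (clockwise) (ang0 - ang) %% (2 * pi) else
    (ang - ang0) %% (2 * pi)
  seg <- pmin(floor(off / (2 * pi / nseg)), nseg - 1L) + 1L + base
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seg[mask]
  lab
}

#' Bullseye summary of a segment table
#'
#' Per-segment means (across subjects and repetitions), per-slice means
#' (unweighted averages of the slice's segment means) and the global mean,
#' for the TRAFF2 and SD columns. Optionally renders an AHA bullseye.
#'
#' @param table A [segment_table()].
#' @param plot Draw the bullseye (base graphics)?
#' @param value `"mean_ms"` or `"sd_ms"` — which column to summarize in the
#'   plot.
#' @return List with `per_segment` (data frame), `per_slice` and `global`
#'   means of both columns.
#' @export
bullseye_summary <- function(table, plot = FALSE, value = "mean_ms") {
  segs <- sort(unique(table$segment))
  per_segment <- do.call(rbind, lapply(segs, function(sg) {
    d <- table[table$segment == sg, ]
    data.frame(segment = sg, slice = d$slice[1],
               mean_ms = mean(d$mean_ms), sd_ms = mean(d$sd_ms))
  }))
  per_slice <- do.call(rbind, lapply(
    unique(per_segment$slice), function(sl) {
      d <- per_segment[per_segment$slice == sl, ]
      data.frame(slice = sl, mean_ms = mean(d$mean_ms),
                 sd_ms = mean(d$sd_ms))
    }))
  global <- list(mean_ms = mean(per_segment$mean_ms),
                 sd_ms = mean(per_segment$sd_ms))
  if (plot) plot_bullseye(per_segment, value = value)
  list(per_segment = per_segment, per_slice = per_slice, global = global)
}

#' Draw an AHA 16-segment bullseye
#'
#' Three concentric rings (outer = basal 1-6, middle = mid 7-12, inner =
#' apical 13-16) coloured by the chosen per-segment value, with the value
#' printed in each segment.
#'
#' @param per_segment Data frame with columns `segment` and the value
#'   column (as produced by [bullseye_summary()]).
#' @param value Column name to display.
#' @param main Plot title.
#' @return Invisibly, the per-segment data frame.
#' @export
plot_bullseye <- function(per_segment, value = "mean_ms",
                          main = "AHA 16-segment bullseye") {
  v <- per_segment[[value]]
  pal <- grDevices::hcl.colors(64, "viridis")
  col_of <- function(x) pal[pmax(1, pmin(64, round(
    1 + 63 * (x - min(v)) / max(diff(range(v)), 1e-12))))]
  graphics::plot.new()
  graphics::plot.window(c(-1.1, 1.1), c(-1.1, 1.1), asp = 1)
  graphics::title(main)
  rings <- list(basal = c(2 / 3, 1), mid = c(1 / 3, 2 / 3),
                apical = c(0, 1 / 3))
  nsegs <- c(basal = 6, mid = 6, apical = 4)
  base <- c(basal = 0, mid = 6, apical = 12)
  for (sl in names(rings)) {
    n <- nsegs[[sl]]
    for (k in seq_len(n)) {
      sg <- base[[sl]] + k
      th <- seq((k - 1) * 2 * pi / n, k * 2 * pi / n, length.out = 30) +
        pi / 2
      r0 <- rings[[sl]][1]; r1 <- rings[[sl]][2]
      xx <- c(r1 * cos(th), rev(r0 * cos(th)))
      yy <- c(r1 * sin(th), rev(r0 * sin(th)))
      val <- v[per_segment$segment == sg]
      if (length(val) == 0L) {  # segment absent (e.g. single-slice table)
        graphics::polygon(xx, yy, col = "grey90", border = "white")
        next
      }
      graphics::polygon(xx, yy, col = col_of(val), border = "white")
      tm <- mean(range(th)); rm <- mean(c(r0, r1))
      graphics::text(rm * cos(tm), rm * sin(tm), sprintf("%.1f", val),
                     cex = 0.7)
    }
  }
  invisible(per_segment)
}

#' Segment-wise map statistics for one slice
#'
#' Applies [aha16_label()] to a mask and aggregates a TRAFF2 map (and
#' optionally an SD map) into segment means, returning [segment_table()]
#' rows for one (subject, repetition, slice).
#'
#' @param traff2_map,sd_map Numeric matrices (the SD map may be `NULL`).
#' @param mask,lv_center,rv_insertion As in [aha16_label()].
#' @param slice_level Slice level string.
#' @param subject,repetition Identifiers for the output rows.
#' @return A `segment_table` with one row per segment present.
#' @export
segment_map_stats <- function(traff2_map, sd_map = NULL, mask, lv_center,
                              rv_insertion, slice_level = "mid",
                              subject = "S01", repetition = 1L) {
  lab <- aha16_label(mask, lv_center, rv_insertion, slice_level)
  segs <- sort(setdiff(unique(as.vector(lab)), 0L))
  rows <- lapply(segs, function(sg) {
    sel <- lab == sg
    data.frame(subject = subject, repetition = repetition,
               slice = slice_level, segment = sg,
               mean_ms = mean(traff2_map[sel], na.rm = TRUE),
               sd_ms = if (is.null(sd_map)) NA_real_ else
                 mean(sd_map[sel], na.rm = TRUE))
  })
  d <- do.call(rbind, rows)
  segment_table(d$subject, d$repetition, d$slice, d$segment, d$mean_ms,
                d$sd_ms)
}
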
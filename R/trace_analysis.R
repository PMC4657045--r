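#' Filament centerline trace
#'
#' An ordered polyline of centerline coordinates for one filament imaged at
#' one applied substrate strain, with condition metadata. Coordinates are in
#' micrometres with `x` along the compression axis.
#'
#' @param x,y Coordinates in um (equal length, >= 2 points).
#' @param strain Applied substrate compression strain as a fraction.
#' @param strain_rate Strain rate in %/s (optional metadata).
#' @param kinesin_nM Kinesin concentration in nM (optional metadata).
#' @param filament_id Identifier string.
#' @return An object of class `filament_trace`.
#' @export
filament_trace <- function(x, y, strain, strain_rate = NA_real_,
                           kinesin_nM = NA_real_, filament_id = "MT1") {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 2) stop("a trace needs at least 2 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("trace coordinates must be finite", call. = FALSE)
  }
  if (!is.finite(strain) || strain < 0) {
    stop("`strain` must be a non-negative fraction", call. = FALSE)
  }
  # orient along +x so the chord coordinate increases with point order
  if (x[length(x)] < x[1]) { x <- rev(x); y <- rev(y) }
  structure(
    list(points = data.frame(x = x, y = y), strain = strain,
         strain_rate = strain_rate, kinesin_nM = kinesin_nM,
         filament_id = as.character(filament_id)),
    class = "filament_trace"
  )
}

#' @export
print.filament_trace <- function(x, ...) {
  cat(sprintf("<filament_trace> %s: %d points, strain %.3g%%, kinesin %g nM\n",
              x$filament_id, nrow(x$points), 100 * x$strain, x$kinesin_nM))
  invisible(x)
}

#' Contour length, end-to-end distance and orientation of a trace
#'
#' @param trace A [filament_trace()].
#' @return `contour_length()`/`end_to_end()`: um. `orientation_deg()`: angle
#'   between the end-to-end vector and the compression (x) axis, degrees in
#'   \[0, 90\].
#' @export
contour_length <- function(trace) {
  p <- trace$points
  sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
}

#' @rdname contour_length
#' @export
end_to_end <- function(trace) {
  p <- trace$points
  n <- nrow(p)
  sqrt((p$x[n] - p$x[1])^2 + (p$y[n] - p$y[1])^2)
}

#' @rdname contour_length
#' @export
orientation_deg <- function(trace) {
  p <- trace$points
  n <- nrow(p)
  ang <- abs(atan2(p$y[n] - p$y[1], p$x[n] - p$x[1])) * 180 / pi
  min(ang, 180 - ang)
}

#' Strain series of one filament
#'
#' @param traces A list of [filament_trace()] objects for one filament at
#'   strictly increasing strains.
#' @param substrate_initial_length Initial (fully elongated) substrate length
#'   in mm; the strain reference length.
#' @return An object of class `strain_series`.
#' @export
strain_series <- function(traces, substrate_initial_length = 8.0) {
  if (length(traces) == 0) stop("empty strain series", call. = FALSE)
  if (!all(vapply(traces, inherits, logical(1), "filament_trace"))) {
    stop("all elements must be filament_trace objects", call. = FALSE)
  }
  ids <- vapply(traces, function(t) t$filament_id, character(1))
  if (length(unique(ids)) != 1) {
    stop("all traces in a series must share one filament_id", call. = FALSE)
  }
  strains <- vapply(traces, function(t) t$strain, numeric(1))
  traces <- traces[order(strains)]
  strains <- sort(strains)
  if (any(diff(strains) <= 0)) {
    stop("strains must be strictly increasing", call. = FALSE)
  }
  check_positive(substrate_initial_length, "substrate_initial_length")
  structure(list(traces = traces, strains = strains,
                 substrate_initial_length = substrate_initial_length),
            class = "strain_series")
}

#' Applied compression strain of the substrate
#'
#' Strain is referenced to the fully elongated substrate length (8.0 mm in
#' the standard geometry): `(L0 - L) / L0`.
#'
#' @param initial_length Elongated substrate length (reference), any unit.
#' @param current_length Substrate length after compression, same unit.
#' @return Compression strain as a fraction.
#' @examples
#' applied_strain(8.0, 7.0)  # 0.125
#' @export
applied_strain <- function(initial_length, current_length) {
  check_positive(initial_length, "initial_length")
  check_positive(current_length, "current_length")
  if (any(current_length > initial_length)) {
    stop("current_length exceeds initial_length: extension, not compression",
         call. = FALSE)
  }
  (initial_length - current_length) / initial_length
}

# Chord-frame profile of a trace: coordinate t along the end-to-end chord and
# signed transverse deviation d, resampled onto a uniform grid. Tolerates
# small backtracking in t (localization noise) via ties = mean.
.chord_profile <- function(trace) {
  p <- trace$points
  n <- nrow(p)
  v <- c(p$x[n] - p$x[1], p$y[n] - p$y[1])
  len <- sqrt(sum(v^2))
  if (len == 0) stop("degenerate trace: zero end-to-end distance",
                     call. = FALSE)
  u <- v / len
  dx <- p$x - p$x[1]; dy <- p$y - p$y[1]
  t <- dx * u[1] + dy * u[2]
  d <- -dx * u[2] + dy * u[1]
  step <- (max(t) - min(t)) / (n - 1)
  grid <- seq(min(t), max(t), length.out = n)
  d_u <- stats::approx(t, d, xout = grid, ties = mean, rule = 2)$y
  # cumulative polyline arc length as a function of t (for contour lengths)
  arc <- c(0, cumsum(sqrt(diff(p$x)^2 + diff(p$y)^2)))
  ord <- order(t)
  list(t = grid, d = d_u, step = step,
       arc_t = t[ord], arc = arc[ord])
}

.sg_smooth <- function(d, step, window, order = 3) {
  n <- length(d)
  w <- max(order + 2, round(window / step))
  if (w %% 2 == 0) w <- w + 1
  if (w > n) w <- if (n %% 2 == 1) n else n - 1
  if (w <= order + 1) return(d)
  as.numeric(signal::sgolayfilt(d, p = order, n = w))
}

# indices of strict local extrema of a numeric vector
.local_extrema <- function(v) {
  dv <- diff(v)
  s <- sign(dv)
  # carry sign through flat runs
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  which(diff(s) != 0) + 1
}

# thresholded, sign-alternating extrema of a detrended profile
.extrema_pass <- function(d_detr, step, window, smooth_order, thr) {
  d_s <- .sg_smooth(d_detr, step, window, smooth_order)
  ext <- .local_extrema(d_s)
  ext <- ext[abs(d_s[ext]) > thr]
  if (length(ext) == 0) return(list(idx = integer(0), smooth = d_s))
  sgn <- sign(d_s[ext])
  runs <- rle(sgn)
  keep <- integer(0)
  pos0 <- 1
  for (r in seq_along(runs$lengths)) {
    idx <- ext[pos0:(pos0 + runs$lengths[r] - 1)]
    keep <- c(keep, idx[which.max(abs(d_s[idx]))])
    pos0 <- pos0 + runs$lengths[r]
  }
  list(idx = keep, smooth = d_s)
}

# Full crest analysis of a trace. Baseline handling is two-pass: first the
# profile is detrended against its least-squares line; if that finds at
# least two crests, the baseline is re-estimated jointly with a sinusoid at
# the crest-implied wave number (linear fit in a, b, sin, cos) and only the
# line part is subtracted before re-detection. The joint fit stops the
# baseline from absorbing part of the buckle on traces only one or two
# wavelengths long, which would pull the detected extrema inward.
.crest_analysis <- function(trace, noise_sigma = 0.05, window = 1,
                            amplitude_floor = 0.15, prominence_factor = 3,
                            smooth_order = 3, detrend = "line") {
  check_positive(noise_sigma, "noise_sigma", allow_zero = TRUE)
  prof <- .chord_profile(trace)
  t <- prof$t
  thr <- max(amplitude_floor, prominence_factor * noise_sigma)
  if (identical(detrend, "none")) {
    # the chord is the known buckling axis (e.g. simulator output with both
    # ends on the substrate line): use the raw chord-frame deviation
    p0 <- .extrema_pass(prof$d, prof$step, window, smooth_order, thr)
    return(list(prof = prof, d = prof$d, smooth = p0$smooth, idx = p0$idx,
                axis_intercept = 0, axis_slope = 0))
  }
  line0 <- stats::lm.fit(cbind(1, t), prof$d)
  d1 <- line0$residuals
  p1 <- .extrema_pass(d1, prof$step, window, smooth_order, thr)
  d_detr <- d1; pass <- p1; coef <- line0$coefficients
  if (length(p1$idx) >= 2) {
    q0 <- pi / mean(diff(t[p1$idx]))
    for (iter in 1:5) {
      X <- cbind(1, t, sin(q0 * t), cos(q0 * t))
      fit <- stats::lm.fit(X, prof$d)
      baseline <- X[, 1:2, drop = FALSE] %*% fit$coefficients[1:2]
      d2 <- prof$d - as.numeric(baseline)
      p2 <- .extrema_pass(d2, prof$step, window, smooth_order, thr)
      if (length(p2$idx) < 1) break
      d_detr <- d2; pass <- p2; coef <- fit$coefficients[1:2]
      if (length(p2$idx) < 2) break
      q_new <- pi / mean(diff(t[p2$idx]))
      if (abs(q_new - q0) <= 1e-4 * q0) { q0 <- q_new; break }
      q0 <- q_new
    }
  }
  list(prof = prof, d = d_detr, smooth = pass$smooth, idx = pass$idx,
       axis_intercept = coef[[1]], axis_slope = coef[[2]])
}

#' Detect buckling crests along a filament trace
#'
#' Detrends the trace against its end-to-end chord, smooths the transverse
#' deviation with a Savitzky-Golay filter, and returns alternating-sign local
#' extrema whose magnitude exceeds
#' `max(amplitude_floor, prominence_factor * noise_sigma)`. Extremum
#' positions are refined by parabolic interpolation; the reported deviation
#' is a local average of the raw (unsmoothed) deviation so that smoothing
#' attenuation does not bias amplitudes.
#'
#' @param trace A [filament_trace()].
#' @param noise_sigma Coordinate noise scale in um (default 0.05, the
#'   diffraction-limited localization scale).
#' @param window Smoothing window in um (default 1).
#' @param amplitude_floor Minimum crest deviation in um (default 0.15).
#' @param prominence_factor Threshold multiple of `noise_sigma` (default 3).
#' @param smooth_order Savitzky-Golay polynomial order (default 3).
#' @param detrend Baseline handling: `"line"` (default) fits the filament
#'   axis to the trace (least squares, refined jointly with a sinusoid); use
#'   `"none"` when the chord between the endpoints is the known buckling
#'   axis, e.g. for simulator shapes whose ends sit on the substrate line.
#' @return A data frame with one row per crest: `position` (um along the
#'   chord), `sign` (+1 crest up / -1 down), `deviation` (signed um).
#'   Zero rows for an unbuckled filament.
#' @export
detect_crests <- function(trace, noise_sigma = 0.05, window = 1,
                          amplitude_floor = 0.15, prominence_factor = 3,
                          smooth_order = 3, detrend = c("line", "none")) {
  stopifnot(inherits(trace, "filament_trace"))
  ca <- .crest_analysis(trace, noise_sigma, window, amplitude_floor,
                        prominence_factor, smooth_order, match.arg(detrend))
  .crest_table(ca)
}

.crest_table <- function(ca) {
  keep <- ca$idx
  if (length(keep) == 0) {
    return(data.frame(position = numeric(0), sign = numeric(0),
                      deviation = numeric(0)))
  }
  d_s <- ca$smooth
  n <- length(d_s)
  pos <- dev <- numeric(length(keep))
  for (i in seq_along(keep)) {
    j <- keep[i]
    # parabolic refinement of the extremum position on the smoothed profile
    delta <- 0
    if (j > 1 && j < n) {
      den <- d_s[j - 1] - 2 * d_s[j] + d_s[j + 1]
      if (abs(den) > .Machine$double.eps) {
        delta <- 0.5 * (d_s[j - 1] - d_s[j + 1]) / den
        delta <- max(-0.5, min(0.5, delta))
      }
    }
    pos[i] <- ca$prof$t[j] + delta * ca$prof$step
    # amplitude from the raw detrended profile so smoothing attenuation
    # does not bias it
    nb <- max(1, j - 2):min(n, j + 2)
    dev[i] <- mean(ca$d[nb])
  }
  # project crest positions onto the fitted filament axis: the chord frame
  # is tilted by the baseline slope, and raw chord-frame gaps pick up an
  # alternating amplitude term (about 2 A sin(tilt)) that the projection
  # removes
  b <- ca$axis_slope
  d_raw <- ca$axis_intercept + b * pos + dev
  pos <- (pos + b * d_raw) / sqrt(1 + b^2)
  data.frame(position = pos, sign = sign(d_s[keep]), deviation = dev)
}

# Trace-level wavelength by fitting baseline + sinusoid with free wave
# number (grid search over wavelength, linear least squares in the other
# four parameters). Used where the crest-gap convention runs out of crests
# (traces shorter than ~1.5 buckle wavelengths).
.fit_wavelength <- function(t, d, lam0 = NULL) {
  span <- max(t) - min(t)
  step <- span / (length(t) - 1)
  lo <- max(6 * step, if (is.null(lam0)) 0 else 0.4 * lam0)
  hi <- if (is.null(lam0)) 4 * span else min(4 * span, 2.5 * lam0)
  if (hi <= lo) return(NA_real_)
  rss <- function(lam) {
    q <- 2 * pi / lam
    sum(stats::lm.fit(cbind(1, t, sin(q * t), cos(q * t)), d)$residuals^2)
  }
  grid <- exp(seq(log(lo), log(hi), length.out = 80))
  vals <- vapply(grid, rss, numeric(1))
  i <- which.min(vals)
  bracket <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  stats::optimize(rss, bracket)$minimum
}

#' Measure buckling metrics of a trace
#'
#' Per-crest buckling wavelength, amplitude, radius of curvature and crest
#' contour length, plus trace-level averages. The measurement convention is:
#' wavelength = twice the axial distance between adjacent opposite-sign
#' extrema; amplitude = half the transverse peak-to-valley distance of
#' adjacent extrema; radius of curvature from [radius_of_curvature()]; crest
#' contour length = polyline arc length between the zero crossings of the
#' detrended profile flanking each crest (extended to the trace ends where
#' no crossing exists).
#'
#' @inheritParams detect_crests
#' @return An object of class `buckle_metrics`: a list with `crests` (the
#'   [detect_crests()] table with `crest_contour_length` added), `per_crest`
#'   (one row per adjacent extremum pair: `wavelength`, `amplitude`,
#'   `radius`), and trace-averaged fields `wavelength`, `amplitude`,
#'   `wavenumber`, `radius`, `crest_contour_length`, `n_crests`. Averages are
#'   `NA` where undefined (wavelength needs >= 2 crests; a single crest still
#'   yields an amplitude).
#' @export
measure_buckle <- function(trace, noise_sigma = 0.05, window = 1,
                           amplitude_floor = 0.15, prominence_factor = 3,
                           smooth_order = 3, detrend = c("line", "none")) {
  ca <- .crest_analysis(trace, noise_sigma, window, amplitude_floor,
                        prominence_factor, smooth_order, match.arg(detrend))
  cr <- .crest_table(ca)
  prof <- ca$prof
  d_s <- ca$smooth

  # crest contour lengths from flanking zero crossings
  if (nrow(cr) > 0) {
    sgn <- sign(d_s); sgn[sgn == 0] <- 1
    zc <- which(diff(sgn) != 0)
    zc_t <- (prof$t[zc] + prof$t[zc + 1]) / 2
    arc_of <- function(tv) {
      stats::approx(prof$arc_t, prof$arc, xout = tv, ties = mean,
                    rule = 2)$y
    }
    ccl <- vapply(cr$position, function(p) {
      left <- zc_t[zc_t < p]
      right <- zc_t[zc_t > p]
      t_l <- if (length(left)) max(left) else prof$t[1]
      t_r <- if (length(right)) min(right) else prof$t[length(prof$t)]
      arc_of(t_r) - arc_of(t_l)
    }, numeric(1))
    cr$crest_contour_length <- ccl
  } else {
    cr$crest_contour_length <- numeric(0)
  }

  if (nrow(cr) >= 2) {
    i <- seq_len(nrow(cr) - 1)
    wl <- 2 * (cr$position[i + 1] - cr$position[i])
    amp <- (abs(cr$deviation[i]) + abs(cr$deviation[i + 1])) / 2
    per <- data.frame(wavelength = wl, amplitude = amp,
                      radius = 1 / (amp * (2 * pi / wl)^2))
  } else {
    per <- data.frame(wavelength = numeric(0), amplitude = numeric(0),
                      radius = numeric(0))
  }

  wavelength <- if (nrow(per)) mean(per$wavelength) else NA_real_
  if (nrow(cr) >= 2 && nrow(cr) <= 3) {
    # fewer than ~1.5 periods visible: refine the trace-level estimate by a
    # sinusoid-plus-baseline fit, anchored to the crest-based value
    wl_fit <- .fit_wavelength(prof$t, prof$d, lam0 = wavelength)
    if (is.finite(wl_fit)) wavelength <- wl_fit
  }
  amplitude <- if (nrow(per)) mean(per$amplitude)
               else if (nrow(cr)) mean(abs(cr$deviation)) else NA_real_
  structure(
    list(
      crests = cr, per_crest = per,
      wavelength = wavelength,
      amplitude = amplitude,
      wavenumber = if (is.na(wavelength)) NA_real_ else 2 * pi / wavelength,
      radius = if (nrow(per)) mean(per$radius) else NA_real_,
      crest_contour_length = if (nrow(cr)) mean(cr$crest_contour_length)
                             else NA_real_,
      n_crests = nrow(cr)
    ),
    class = "buckle_metrics"
  )
}

#' @export
print.buckle_metrics <- function(x, ...) {
  cat(sprintf(
    "<buckle_metrics> %d crests: lambda = %.3g um, A = %.3g um, R = %.3g um\n",
    x$n_crests, x$wavelength, x$amplitude, x$radius))
  invisible(x)
}

#' Critical strain of a strain series
#'
#' The smallest applied strain at which the filament first shows a buckling
#' crest; `NA` if the filament never buckles within the series (short
#' filaments may not buckle even at 50% strain).
#'
#' @param series A [strain_series()].
#' @param ... Crest-detection parameters passed to [detect_crests()].
#' @return Strain fraction, or `NA_real_`.
#' @export
critical_strain <- function(series, ...) {
  stopifnot(inherits(series, "strain_series"))
  for (tr in series$traces) {
    if (nrow(detect_crests(tr, ...)) >= 1) return(tr$strain)
  }
  NA_real_
}

#' Experiment dataset
#'
#' A collection of filament traces spanning kinesin-concentration and strain
#' conditions, optionally with generator ground truth.
#'
#' @param traces List of [filament_trace()] objects.
#' @param ground_truth Optional data frame of per-trace ground truth.
#' @param conditions Optional data frame of per-condition parameters.
#' @return An object of class `experiment_dataset`.
#' @export
experiment_dataset <- function(traces, ground_truth = NULL,
                               conditions = NULL) {
  if (!all(vapply(traces, inherits, logical(1), "filament_trace"))) {
    stop("all elements of `traces` must be filament_trace objects",
         call. = FALSE)
  }
  structure(list(traces = traces, ground_truth = ground_truth,
                 conditions = conditions),
            class = "experiment_dataset")
}

#' @export
print.experiment_dataset <- function(x, ...) {
  cat(sprintf("<experiment_dataset> %d traces\n", length(x$traces)))
  invisible(x)
}

#' Aggregate buckling metrics for one condition
#'
#' Selects the traces matching a kinesin concentration and strain, excludes
#' filaments whose end-to-end vector deviates from the compression axis by
#' more than `orientation_tol_deg` (only filaments aligned with the
#' compression axis are comparable), measures each, and returns the mean and
#' sample SD of the per-trace mean wavelength, amplitude and radius.
#'
#' @param dataset An [experiment_dataset()].
#' @param kinesin_nM,strain Condition selectors.
#' @param orientation_tol_deg Maximum end-to-end misalignment, degrees
#'   (default 15).
#' @param strain_tol Absolute tolerance for strain matching.
#' @param ... Passed to [measure_buckle()].
#' @return A one-row data frame with columns `kinesin_nM`, `strain`,
#'   `n_traces`, `n_buckled`, and `*_mean`/`*_sd` for wavelength, amplitude
#'   and radius (um).
#' @export
aggregate_condition <- function(dataset, kinesin_nM, strain,
                                orientation_tol_deg = 15,
                                strain_tol = 1e-6, ...) {
  stopifnot(inherits(dataset, "experiment_dataset"))
  sel <- Filter(function(tr) {
    isTRUE(tr$kinesin_nM == kinesin_nM) &&
      abs(tr$strain - strain) <= strain_tol
  }, dataset$traces)
  if (length(sel) == 0) {
    stop(sprintf("no traces for kinesin %g nM at strain %g", kinesin_nM,
                 strain), call. = FALSE)
  }
  sel <- Filter(function(tr) orientation_deg(tr) <= orientation_tol_deg, sel)
  if (length(sel) == 0) {
    stop("no traces aligned with the compression axis for this condition",
         call. = FALSE)
  }
  mets <- lapply(sel, measure_buckle, ...)
  wl <- vapply(mets, function(m) m$wavelength, numeric(1))
  am <- vapply(mets, function(m) m$amplitude, numeric(1))
  ra <- vapply(mets, function(m) m$radius, numeric(1))
  msd <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) c(NA_real_, NA_real_)
    else c(mean(v), if (length(v) > 1) stats::sd(v) else 0)
  }
  w <- msd(wl); a <- msd(am); r <- msd(ra)
  data.frame(
    kinesin_nM = kinesin_nM, strain = strain,
    n_traces = length(sel),
    n_buckled = sum(vapply(mets, function(m) m$n_crests > 0, logical(1))),
    wavelength_mean = w[1], wavelength_sd = w[2],
    amplitude_mean = a[1], amplitude_sd = a[2],
    radius_mean = r[1], radius_sd = r[2]
  )
}
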
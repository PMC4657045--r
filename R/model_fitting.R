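#' Two-segment breakpoint fit of wavelength against strain
#'
#' The buckling wavelength falls steeply with applied strain up to a
#' "transitional strain" (about 15% in kinesin-supported microtubule
#' experiments) and much more slowly beyond it. This fit objectivizes the
#' two-straight-lines construction: candidate breakpoints are the midpoints
#' between consecutive observed strains with at least two points on each
#' side; ordinary least squares lines are fitted on both sides; the
#' candidate minimizing the total SSE wins, with ties broken towards the
#' smallest breakpoint. The transitional wavelength is read off at the
#' intersection of the two lines.
#'
#' @param strain Applied strains (fractions), length >= 5.
#' @param wavelength Buckling wavelengths (um).
#' @return An object of class `breakpoint_fit`: `breakpoint_strain`,
#'   `below_slope`/`above_slope` (um per strain fraction),
#'   `below_intercept`/`above_intercept`, `intersection_strain`,
#'   `intersection_wavelength` (um), `sse`, `single_line_sse`, and flags
#'   `no_distinct_transition` (two-line fit no better than one line) and
#'   `parallel` (slopes equal; the wavelength falls back to the fitted value
#'   at the breakpoint strain).
#' @export
transitional_strain_fit <- function(strain, wavelength) {
  if (length(strain) != length(wavelength)) {
    stop("`strain` and `wavelength` must have equal length", call. = FALSE)
  }
  if (length(strain) < 5) {
    stop("need at least 5 points for a breakpoint fit", call. = FALSE)
  }
  ord <- order(strain)
  x <- strain[ord]; y <- wavelength[ord]
  n <- length(x)

  line_sse <- function(xx, yy) {
    f <- stats::lm.fit(cbind(1, xx), yy)
    sum(f$residuals^2)
  }
  single_fit <- stats::lm(y ~ x)
  single_sse <- sum(stats::residuals(single_fit)^2)

  splits <- 2:(n - 2)               # left gets 1..i, right gets (i+1)..n
  sses <- vapply(splits, function(i) {
    line_sse(x[1:i], y[1:i]) + line_sse(x[(i + 1):n], y[(i + 1):n])
  }, numeric(1))
  # ties (within floating noise) break towards the smallest breakpoint
  tol <- 1e-9 * max(sum((y - mean(y))^2), .Machine$double.xmin)
  best <- splits[which(sses <= min(sses) + tol)][1]
  bp <- (x[best] + x[best + 1]) / 2

  f1 <- stats::lm(y1 ~ x1, data = list(x1 = x[1:best], y1 = y[1:best]))
  f2 <- stats::lm(y2 ~ x2, data = list(x2 = x[(best + 1):n],
                                       y2 = y[(best + 1):n]))
  b1 <- stats::coef(f1)[[1]]; m1 <- stats::coef(f1)[[2]]
  b2 <- stats::coef(f2)[[1]]; m2 <- stats::coef(f2)[[2]]

  scale <- max(abs(c(m1, m2)), 1e-300)
  parallel <- abs(m1 - m2) <= 1e-10 * scale
  if (parallel) {
    xi <- bp
    yi <- b1 + m1 * bp
  } else {
    xi <- (b2 - b1) / (m1 - m2)
    yi <- b1 + m1 * xi
  }
  sse <- min(sses)
  structure(
    list(breakpoint_strain = bp, below_slope = m1, above_slope = m2,
         below_intercept = b1, above_intercept = b2,
         intersection_strain = xi, intersection_wavelength = yi,
         sse = sse, single_line_sse = single_sse,
         no_distinct_transition = (single_sse - sse) <=
           1e-8 * max(single_sse, .Machine$double.eps),
         parallel = parallel),
    class = "breakpoint_fit"
  )
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("<breakpoint_fit>\n")
  cat(sprintf("  transitional strain = %.3g%% (wavelength %.4g um)\n",
              100 * x$breakpoint_strain, x$intersection_wavelength))
  cat(sprintf("  slopes: %.4g (below) / %.4g (above) um per strain\n",
              x$below_slope, x$above_slope))
  if (x$no_distinct_transition) cat("  note: no distinct transition\n")
  if (x$parallel) cat("  note: parallel segments, intersection undefined\n")
  invisible(x)
}

#' Log-log slope of a power-law relation
#'
#' Ordinary least squares of `log(y)` on `log(x)`: the exponent of an exact
#' power law is recovered to floating precision, and the straight-line
#' log-log presentation matches how quarter-power wavelength/spacing
#' relations are reported.
#'
#' @param x,y Positive numeric vectors, length >= 3.
#' @return A list with `slope`, `intercept` (natural-log scale), and `se`
#'   (standard error of the slope).
#' @export
loglog_slope <- function(x, y) {
  check_positive(x, "x")
  check_positive(y, "y")
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  lx <- log(x); ly <- log(y)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  n <- length(x)
  sxx <- sum((lx - mean(lx))^2)
  se <- sqrt(sum(fit$residuals^2) / (n - 2) / sxx)
  list(slope = fit$coefficients[[2]], intercept = fit$coefficients[[1]],
       se = se)
}

#' Power-law exponent of critical force versus kinesin spacing
#'
#' Magnitude of the log-log slope of the critical buckling force against the
#' kinesin spacing. The unmodified elastic foundation model predicts 1/2;
#' experiments on kinesin-softened microtubules report much steeper
#' dependences.
#'
#' @param spacing Kinesin spacings (positive, length >= 2).
#' @param critical_force Critical buckling forces (positive).
#' @return Absolute exponent (dimensionless).
#' @export
powerlaw_exponent_fc <- function(spacing, critical_force) {
  check_positive(spacing, "spacing")
  check_positive(critical_force, "critical_force")
  if (length(spacing) != length(critical_force)) {
    stop("`spacing` and `critical_force` must have equal length",
         call. = FALSE)
  }
  if (length(spacing) < 2) stop("need at least 2 observations", call. = FALSE)
  if (length(spacing) == 2) {
    abs(log(critical_force[2] / critical_force[1]) /
          log(spacing[2] / spacing[1]))
  } else {
    abs(loglog_slope(spacing, critical_force)$slope)
  }
}

#' Fit the softening-modified foundation model to wavelength summaries
#'
#' Extracts the kinesin spring constant from per-condition (spacing,
#' wavelength) summaries via [spring_constant_from_fit()], and tabulates the
#' observed wavelengths against the predictions of the unmodified model
#' (constant bare modulus) and the modified model (spacing-dependent
#' modulus), both evaluated at the fitted spring constant.
#'
#' @param spacing Kinesin spacings, m (length >= 2).
#' @param wavelength Observed buckling wavelengths, m.
#' @param softening A [softening_model()].
#' @param second_moment Second moment of area `I`, m^4.
#' @return A list with `k_spring` (N/m), `per_point` (pointwise spring
#'   constants), and `comparison` (data frame: spacing, observed, modified
#'   and unmodified predictions, residuals in log wavelength).
#' @export
fit_modified_model <- function(spacing, wavelength, softening,
                               second_moment) {
  if (length(spacing) < 2) stop("need at least 2 summaries", call. = FALSE)
  fit <- spring_constant_from_fit(softening, second_moment, spacing,
                                  wavelength)
  k <- fit$k_spring
  lam_mod <- modified_wavelength(softening, second_moment, k, spacing)
  mech0 <- filament_mechanics(softening$bare_modulus, second_moment)
  lam_unmod <- vapply(spacing, function(s) combined_wavelength(mech0, k, s),
                      numeric(1))
  list(
    k_spring = k,
    per_point = fit$per_point,
    comparison = data.frame(
      spacing = spacing,
      observed = wavelength,
      modified = lam_mod,
      unmodified = lam_unmod,
      residual_log_modified = log(wavelength) - log(lam_mod),
      residual_log_unmodified = log(wavelength) - log(lam_unmod)
    )
  )
}
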
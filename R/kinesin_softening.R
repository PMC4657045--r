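#' Kinesin-spacing-dependent softening of the Young's modulus
#'
#' Bound kinesin softens microtubules: the effective Young's modulus falls
#' towards zero as the spacing `L_d` between bound motors shrinks below a
#' critical spacing `L_d*`, and saturates at the bare-filament modulus
#' `E_MT^0` for sparse decoration. Three saturating families are provided:
#'
#' * `hill` (default, exponent `n`): `E(L) = E0 L^n / (L^n + L*^n)`
#' * `exp_saturation`: `E(L) = E0 (1 - exp(-L / L*))`
#' * `gaussian_saturation` (exponent `n`): `E(L) = E0 (1 - exp(-(L / L*)^n))`
#'
#' All are continuous, strictly increasing in `L`, bounded by `E0`, and tend
#' to 0 as `L -> 0`. For the default hill family `E(L*) = E0 / 2`, so a
#' filament is drastically softened once `L_d < L_d*`.
#'
#' @param bare_modulus Bare-filament Young's modulus `E_MT^0`, Pa.
#' @param critical_spacing Critical kinesin spacing `L_d*`, m.
#' @param family One of `"hill"`, `"exp_saturation"`, `"gaussian_saturation"`.
#' @param shape_exponent Dimensionless exponent for the hill and gaussian
#'   families (default 2).
#' @return An object of class `softening_model`.
#' @examples
#' mod <- softening_model(MPa(64), nm(51))
#' as_MPa(softened_modulus(mod, nm(c(18, 95, 1e6))))
#' @export
softening_model <- function(bare_modulus, critical_spacing,
                            family = c("hill", "exp_saturation",
                                       "gaussian_saturation"),
                            shape_exponent = 2) {
  check_positive(bare_modulus, "bare_modulus")
  check_positive(critical_spacing, "critical_spacing")
  family <- match.arg(family)
  check_positive(shape_exponent, "shape_exponent")
  structure(
    list(bare_modulus = bare_modulus, critical_spacing = critical_spacing,
         family = family, shape_exponent = shape_exponent),
    class = "softening_model"
  )
}

#' @export
print.softening_model <- function(x, ...) {
  cat("<softening_model>\n")
  cat(sprintf("  family = %s (n = %g)\n", x$family, x$shape_exponent))
  cat(sprintf("  E_MT^0 = %.4g MPa\n", as_MPa(x$bare_modulus)))
  cat(sprintf("  L_d*   = %.4g nm\n", as_nm(x$critical_spacing)))
  cal <- attr(x, "calibration")
  if (!is.null(cal)) {
    cat(sprintf("  calibrated to %d anchors, max |rel residual| = %.3g\n",
                nrow(cal), max(abs(cal$rel_residual))))
  }
  invisible(x)
}

# saturation factor g(s) in [0, 1), E = E0 * g(spacing / critical_spacing)
.soften_g <- function(family, s, n) {
  switch(family,
    hill = s^n / (1 + s^n),
    exp_saturation = 1 - exp(-s),
    gaussian_saturation = 1 - exp(-(s^n))
  )
}

#' Softened Young's modulus at a given kinesin spacing
#'
#' @param model A [softening_model()].
#' @param spacing Kinesin spacing, m (vectorized).
#' @return Young's modulus in Pa.
#' @export
softened_modulus <- function(model, spacing) {
  stopifnot(inherits(model, "softening_model"))
  check_positive(spacing, "spacing")
  model$bare_modulus *
    .soften_g(model$family, spacing / model$critical_spacing,
              model$shape_exponent)
}

# Largest modulus ratio E(s1)/E(s2), s1 > s2, attainable by a family as the
# critical spacing grows without bound.
.family_ceiling <- function(family, ratio_s, n) {
  switch(family,
    hill = ratio_s^n,
    exp_saturation = ratio_s,
    gaussian_saturation = ratio_s^n
  )
}

#' Calibrate a softening model to anchor measurements
#'
#' Fits `(E_MT^0, L_d*)` so the model passes through measured
#' (spacing, modulus) anchor pairs: exactly when two anchors are given
#' (matching the two free parameters), by least squares otherwise. Anchor
#' pairs whose modulus ratio exceeds what the chosen family can produce at
#' any critical spacing raise a calibration-failure error naming the bound.
#'
#' @param spacing Anchor spacings, m (at least two, distinct).
#' @param modulus Measured Young's moduli at those spacings, Pa.
#' @inheritParams softening_model
#' @return A [softening_model()] with a `calibration` attribute (data frame
#'   of anchors, fitted values and relative residuals).
#' @examples
#' mod <- calibrate_softening(nm(c(95, 18)), MPa(c(49.75, 7.15)))
#' as_MPa(c(mod$bare_modulus))       # ~63.9
#' as_nm(mod$critical_spacing)       # ~50.7
#' @export
calibrate_softening <- function(spacing, modulus,
                                family = c("hill", "exp_saturation",
                                           "gaussian_saturation"),
                                shape_exponent = 2) {
  family <- match.arg(family)
  check_positive(spacing, "spacing")
  check_positive(modulus, "modulus")
  check_positive(shape_exponent, "shape_exponent")
  if (length(spacing) != length(modulus)) {
    stop("`spacing` and `modulus` must have equal length", call. = FALSE)
  }
  if (length(spacing) < 2 || anyDuplicated(spacing)) {
    stop("need >= 2 anchors with distinct spacings", call. = FALSE)
  }
  ord <- order(spacing, decreasing = TRUE)
  s <- spacing[ord]; y <- modulus[ord]

  # feasibility: the steepest anchor pair must be attainable
  for (i in seq_len(length(s) - 1)) {
    for (j in seq(i + 1, length(s))) {
      req <- y[i] / y[j]
      ceil <- .family_ceiling(family, s[i] / s[j], shape_exponent)
      if (req >= ceil) {
        stop(sprintf(
          paste0("calibration failure: anchors require modulus ratio %.4g ",
                 "between spacings %.3g and %.3g nm, but family '%s' can ",
                 "attain at most %.4g"),
          req, as_nm(s[i]), as_nm(s[j]), family, ceil), call. = FALSE)
      }
      if (req <= 1 && length(s) == 2) {
        stop("calibration failure: anchors are non-increasing in spacing",
             call. = FALSE)
      }
    }
  }

  n <- shape_exponent
  if (family == "hill") {
    # linearization: s^n / y = s^n / E0 + L*^n / E0  (exact for 2 anchors)
    sn <- s^n
    fit <- stats::lm(I(sn / y) ~ sn)
    a <- stats::coef(fit)[["sn"]]; b <- stats::coef(fit)[["(Intercept)"]]
    if (a <= 0 || b <= 0) stop("calibration failure: degenerate hill fit",
                               call. = FALSE)
    e0 <- 1 / a
    lstar <- (b / a)^(1 / n)
  } else {
    g <- function(sv, c) .soften_g(family, sv / c, n)
    if (length(s) == 2) {
      f <- function(lc) {
        c <- exp(lc)
        log(g(s[1], c) / g(s[2], c)) - log(y[1] / y[2])
      }
      lo <- log(min(s)) - 12; hi <- log(max(s)) + 12
      root <- stats::uniroot(f, c(lo, hi), tol = 1e-14)
      lstar <- exp(root$root)
      e0 <- y[1] / g(s[1], lstar)
    } else {
      sn0 <- stats::median(s)
      fit <- minpack.lm::nlsLM(
        y ~ e0 * .soften_g(family, s / lstar, n),
        start = list(e0 = max(y) * 1.2, lstar = sn0),
        lower = c(max(y), min(s) * 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )
      e0 <- stats::coef(fit)[["e0"]]; lstar <- stats::coef(fit)[["lstar"]]
    }
  }
  if (length(s) > 2 && family == "hill") {
    # refine the linearized estimate by least squares in modulus space
    fit <- try(minpack.lm::nlsLM(
      y ~ e0 * .soften_g(family, s / lstar, n),
      start = list(e0 = e0, lstar = lstar),
      control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      e0 <- stats::coef(fit)[["e0"]]; lstar <- stats::coef(fit)[["lstar"]]
    }
  }

  model <- softening_model(e0, lstar, family, shape_exponent)
  fitted <- softened_modulus(model, s)
  attr(model, "calibration") <- data.frame(
    spacing = s, modulus = y, fitted = fitted,
    rel_residual = (y - fitted) / y
  )
  model
}

#' Buckling wavelength under the softening-modified foundation model
#'
#' The unmodified model takes the filament modulus as constant; the modified
#' model lets the modulus itself depend on kinesin spacing, giving
#' `lambda(L_d) = 2 pi (E(L_d) I L_d / k)^(1/4)`. With a spacing-independent
#' model (large `L_d*` limit) this reduces to [combined_wavelength()].
#'
#' @param model A [softening_model()].
#' @param second_moment Second moment of area `I`, m^4.
#' @param k_spring Kinesin spring constant, N/m.
#' @param spacing Kinesin spacing `L_d`, m (vectorized).
#' @return Wavelength in m.
#' @export
modified_wavelength <- function(model, second_moment, k_spring, spacing) {
  check_positive(second_moment, "second_moment")
  check_positive(k_spring, "k_spring")
  e <- softened_modulus(model, spacing)
  2 * pi * (e * second_moment * spacing / k_spring)^0.25
}

#' Extract the kinesin spring constant from wavelength observations
#'
#' Inverts the modified foundation model pointwise,
#' `k_i = (2 pi)^4 E(L_d,i) I L_d,i / lambda_i^4`, and combines the pointwise
#' estimates by their geometric mean (the spring constant enters the
#' wavelength multiplicatively at the fourth power, so estimation noise is
#' log-symmetric).
#'
#' @inheritParams modified_wavelength
#' @param wavelength Observed buckling wavelengths, m (same length as
#'   `spacing`).
#' @return A list with `k_spring` (geometric-mean estimate, N/m) and
#'   `per_point` (data frame of spacings, wavelengths and pointwise `k`).
#' @export
spring_constant_from_fit <- function(model, second_moment, spacing,
                                     wavelength) {
  check_positive(second_moment, "second_moment")
  check_positive(spacing, "spacing")
  check_positive(wavelength, "wavelength")
  if (length(spacing) == 0) stop("no observations", call. = FALSE)
  if (length(spacing) != length(wavelength)) {
    stop("`spacing` and `wavelength` must have equal length", call. = FALSE)
  }
  e <- softened_modulus(model, spacing)
  k_i <- (2 * pi)^4 * e * second_moment * spacing / wavelength^4
  list(
    k_spring = exp(mean(log(k_i))),
    per_point = data.frame(spacing = spacing, wavelength = wavelength,
                           k_spring = k_i)
  )
}
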
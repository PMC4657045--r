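#' Discrete rod-on-springs model
#'
#' A planar discrete elastic rod (n nodes, uniform rest spacing) coupled to a
#' compressed substrate by transverse linear springs placed every
#' `anchor_spacing` along the rod — the discrete counterpart of a filament
#' supported by regularly spaced kinesin molecules. The simulator works in
#' micrometre/piconewton units, which keep all energies of order one for
#' microtubule-scale parameters (`EI` about 16 pN um^2):
#'
#' * bending: `EI / (2 ds) * theta_i^2` per interior node (turning angle
#'   `theta`),
#' * axial stretching: `ka / (2 ds) * (l_j - ds)^2` per segment, where `ka`
#'   is the axial stiffness (force per unit strain, an `EA` surrogate),
#' * foundation: `k_spring / 2 * y_a^2` at each anchor node, measuring the
#'   transverse offset from the anchor's affinely compressed substrate
#'   position (the springs act perpendicular to the filament only).
#'
#' @param length Rod rest length, um (rounded to a whole number of nodes).
#' @param node_spacing Rest distance between adjacent nodes, um.
#' @param EI Flexural rigidity in pN um^2, or a [filament_mechanics()] object
#'   (converted from SI: 1 N m^2 = 1e24 pN um^2).
#' @param k_spring Anchor spring constant, pN/um (1 N/m = 1e6 pN/um).
#' @param anchor_spacing Distance between spring anchors, um.
#' @param axial_stiffness Axial stiffness `ka` in pN per unit strain; default
#'   `1e3 * EI / node_spacing^2` (effectively inextensible).
#' @param boundary `"clamped"` (default; positions and tangents of both ends
#'   follow the substrate) or `"pinned"` (end positions only).
#' @return An object of class `rod_model`.
#' @export
rod_model <- function(length, node_spacing, EI, k_spring, anchor_spacing,
                      axial_stiffness = NULL,
                      boundary = c("clamped", "pinned")) {
  boundary <- match.arg(boundary)
  if (inherits(EI, "filament_mechanics")) EI <- EI$flexural_rigidity * 1e24
  check_positive(length, "length")
  check_positive(node_spacing, "node_spacing")
  check_positive(EI, "EI")
  check_positive(k_spring, "k_spring")
  check_positive(anchor_spacing, "anchor_spacing")
  n_nodes <- round(length / node_spacing) + 1
  if (n_nodes < 10) stop("rod must have at least 10 nodes", call. = FALSE)
  L0 <- (n_nodes - 1) * node_spacing
  if (is.null(axial_stiffness)) {
    axial_stiffness <- 1e3 * EI / node_spacing^2
  }
  check_positive(axial_stiffness, "axial_stiffness")
  anchor_x <- seq(0, L0, by = anchor_spacing)
  anchor_idx <- unique(pmin(n_nodes, round(anchor_x / node_spacing) + 1))
  if (length(anchor_idx) < 2) {
    stop("need at least 2 spring anchors along the rod", call. = FALSE)
  }
  structure(
    list(n_nodes = n_nodes, node_spacing = node_spacing, length = L0,
         EI = EI, k_spring = k_spring, anchor_spacing = anchor_spacing,
         anchor_idx = anchor_idx, axial_stiffness = axial_stiffness,
         boundary = boundary),
    class = "rod_model"
  )
}

#' @export
print.rod_model <- function(x, ...) {
  cat(sprintf(
    "<rod_model> %d nodes / %.3g um, EI = %.3g pN um^2, k = %.3g pN/um every %.3g um, %s\n",
    x$n_nodes, x$length, x$EI, x$k_spring, x$anchor_spacing, x$boundary))
  invisible(x)
}

#' Straight rest shape of a rod model
#'
#' @param model A [rod_model()].
#' @return An `n_nodes x 2` matrix of (x, y) coordinates in um.
#' @export
rest_shape <- function(model) {
  cbind(x = seq(0, model$length, length.out = model$n_nodes), y = 0)
}

# energy and gradient of a full shape matrix; returns list(energy, grad)
.rod_energy_grad <- function(model, shape, want_grad = TRUE) {
  n <- model$n_nodes
  ds <- model$node_spacing
  seg <- shape[2:n, , drop = FALSE] - shape[1:(n - 1), , drop = FALSE]
  len <- sqrt(seg[, 1]^2 + seg[, 2]^2)
  u <- seg / len

  # axial stretching
  tens <- model$axial_stiffness / ds * (len - ds)
  e_stretch <- sum(tens * (len - ds)) / 2

  # bending (turning angles at interior nodes)
  i <- 2:(n - 1)
  ax <- seg[i - 1, 1]; ay <- seg[i - 1, 2]
  bx <- seg[i, 1];     by <- seg[i, 2]
  theta <- atan2(ax * by - ay * bx, ax * bx + ay * by)
  cb <- model$EI / (2 * ds)
  e_bend <- cb * sum(theta^2)

  # foundation
  ya <- shape[model$anchor_idx, 2]
  e_found <- model$k_spring / 2 * sum(ya^2)

  out <- list(energy = e_bend + e_stretch + e_found,
              bend = e_bend, stretch = e_stretch, foundation = e_found)
  if (!want_grad) return(out)

  grad <- matrix(0, n, 2)
  # stretch forces
  f <- tens * u
  grad[2:n, ] <- grad[2:n, ] + f
  grad[1:(n - 1), ] <- grad[1:(n - 1), ] - f
  # bending
  la2 <- ax^2 + ay^2
  lb2 <- bx^2 + by^2
  m <- 2 * cb * theta
  wux <- -ay / la2; wuy <- ax / la2
  wvx <- -by / lb2; wvy <- bx / lb2
  g1 <- cbind(m * wux, m * wuy)            # to node i-1
  g3 <- cbind(m * wvx, m * wvy)            # to node i+1
  grad[1:(n - 2), ] <- grad[1:(n - 2), ] + g1
  grad[i, ] <- grad[i, ] - g1 - g3
  grad[3:n, ] <- grad[3:n, ] + g3
  # foundation
  grad[model$anchor_idx, 2] <- grad[model$anchor_idx, 2] +
    model$k_spring * ya
  out$grad <- grad
  out
}

#' Total elastic energy of a rod shape
#'
#' Sum of discrete bending, axial stretching and foundation-spring energies.
#'
#' @param model A [rod_model()].
#' @param shape An `n_nodes x 2` coordinate matrix (um).
#' @return Energy in pN um (1 pN um = 1e-18 J). The components are attached
#'   as attribute `"components"`.
#' @export
total_energy <- function(model, shape) {
  stopifnot(inherits(model, "rod_model"))
  shape <- as.matrix(shape)
  if (nrow(shape) != model$n_nodes || ncol(shape) != 2) {
    stop(sprintf("shape must be a %d x 2 matrix", model$n_nodes),
         call. = FALSE)
  }
  e <- .rod_energy_grad(model, shape, want_grad = FALSE)
  structure(e$energy, components = c(bend = e$bend, stretch = e$stretch,
                                     foundation = e$foundation))
}

# indices of free y coordinates given the boundary condition
.free_y_idx <- function(model) {
  n <- model$n_nodes
  if (model$boundary == "clamped") 3:(n - 2) else 2:(n - 1)
}

#' Relax a rod to mechanical equilibrium at a given substrate strain
#'
#' Minimizes the total elastic energy over the transverse node deflections.
#' The axial node positions follow the substrate affinely (the kinesin
#' anchors register the filament axially), so compression loads the rod
#' through the segment-stretching term and is relieved by transverse
#' deflection — the standard transverse-deflection discretization of a
#' compressed beam on a foundation. A small seeded transverse perturbation
#' (about `node_spacing / 100`) breaks the symmetry of the straight state so
#' the minimizer can leave the unstable unbuckled branch. Quasi-static
#' energy minimization is used rather than dynamics because the
#' experimental buckling is insensitive to strain rate.
#'
#' Mode selection is physical only when the strain schedule resolves the
#' buckling onset: the onset strain is roughly the critical force divided by
#' the axial stiffness, and strain steps should be no larger than that (far
#' beyond onset a wide band of wavelengths is unstable and a cold-started
#' minimizer can settle into any of them).
#'
#' @param model A [rod_model()].
#' @param strain Substrate compression strain in \[0, 0.5\].
#' @param shape Optional warm-start shape (e.g. the previous equilibrium at
#'   a smaller strain); its x grid is rescaled to the new substrate length.
#' @param seed Integer seed for the symmetry-breaking perturbation.
#' @param perturbation Perturbation amplitude, um.
#' @param maxit Iteration cap per L-BFGS-B attempt.
#' @return A list: `shape` (equilibrium coordinates), `energy` (pN um),
#'   `converged`, `grad_norm` (max |gradient| over free coordinates, pN),
#'   `strain`.
#' @export
relax <- function(model, strain, shape = NULL, seed = 1L,
                  perturbation = model$node_spacing / 100, maxit = 20000L) {
  stopifnot(inherits(model, "rod_model"))
  if (!is.finite(strain) || strain < 0 || strain > 0.5) {
    stop("`strain` must be in [0, 0.5]", call. = FALSE)
  }
  n <- model$n_nodes
  xs <- seq(0, model$length, length.out = n) * (1 - strain)
  y <- if (is.null(shape)) rep(0, n) else as.matrix(shape)[, 2]
  fy <- .free_y_idx(model)
  y[c(1, n)] <- 0
  if (model$boundary == "clamped") y[c(2, n - 1)] <- 0
  if (perturbation > 0) {
    y[fy] <- y[fy] +
      with_seed(seed, stats::runif(length(fy), -perturbation, perturbation))
  }
  build <- function(p) { y[fy] <- p; cbind(xs, y) }
  fn <- function(p) .rod_energy_grad(model, build(p),
                                     want_grad = FALSE)$energy
  gr <- function(p) .rod_energy_grad(model, build(p))$grad[fy, 2]

  grad_tol <- 1e-7 * model$EI / model$node_spacing^2
  par0 <- y[fy]
  res <- NULL
  gnorm <- Inf
  for (attempt in 1:3) {
    res <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 10,
                                       lmm = 30, pgtol = 0))
    par0 <- res$par
    gnorm <- max(abs(gr(res$par)))
    if (gnorm <= grad_tol) break
  }
  if (gnorm > grad_tol) {
    stop(sprintf(
      "relaxation did not converge: grad %.3g pN (tol %.3g), optim code %d",
      gnorm, grad_tol, res$convergence), call. = FALSE)
  }
  list(shape = build(res$par), energy = res$value,
       converged = TRUE, grad_norm = gnorm, strain = strain)
}

#' Dominant buckling wavelength of a shape or transverse profile
#'
#' Detrends the transverse profile against the chord between the endpoints,
#' resamples uniformly, and returns the wavelength of the zero-padded
#' periodogram peak with parabolic interpolation around the peak bin.
#' Returns `NA` when the maximum deviation is below `amplitude_threshold`
#' (no buckle to measure).
#'
#' @param x Either an `n x 2` shape matrix or the axial coordinates (um).
#' @param y Transverse coordinates (um) when `x` is a vector.
#' @param amplitude_threshold Minimum |deviation| in um (default 0.05).
#' @return Wavelength in um, or `NA_real_`.
#' @export
dominant_wavelength <- function(x, y = NULL, amplitude_threshold = 0.05) {
  if (is.matrix(x)) { y <- x[, 2]; x <- x[, 1] }
  n <- length(x)
  if (n < 8) stop("need at least 8 points", call. = FALSE)
  chord <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
  d <- y - chord
  if (max(abs(d)) < amplitude_threshold) return(NA_real_)
  step <- (x[n] - x[1]) / (n - 1)
  grid <- seq(x[1], x[n], length.out = n)
  d <- stats::approx(x, d, xout = grid, ties = mean, rule = 2)$y
  d <- d - mean(d)
  nfft <- 2^ceiling(log2(8 * n))
  p <- Mod(stats::fft(c(d, rep(0, nfft - n))))^2
  half <- p[2:(nfft %/% 2)]
  k <- which.max(half) + 1         # 1-based fft bin, frequency (k-1)/(nfft*step)
  # parabolic interpolation on the power spectrum around the peak
  delta <- 0
  if (k > 2 && k < nfft %/% 2) {
    den <- p[k - 1] - 2 * p[k] + p[k + 1]
    if (abs(den) > 0) delta <- max(-0.5, min(0.5,
      0.5 * (p[k - 1] - p[k + 1]) / den))
  }
  freq <- (k - 1 + delta) / (nfft * step)
  1 / freq
}

#' Quasi-static compression ramp
#'
#' Applies substrate strain in `n_steps` increments up to `max_strain`, each
#' step relaxed to equilibrium warm-started from the previous shape, and
#' records the buckling metrics per step. The step count plays the role of a
#' strain-rate surrogate: because each state is fully equilibrated, the
#' post-onset wavelength is insensitive to it, mirroring the experimental
#' strain-rate insensitivity.
#'
#' @param model A [rod_model()].
#' @param max_strain Final substrate strain (fraction, <= 0.5).
#' @param n_steps Number of strain increments (>= 2).
#' @param seed Integer seed for the symmetry-breaking perturbations.
#' @param amplitude_threshold Amplitude (um) above which the rod counts as
#'   buckled; sets `onset_strain` and gates wavelength reporting.
#' @param ... Passed to [relax()].
#' @return An object of class `simulation_result`: `strain_history`,
#'   `shapes` (list of coordinate matrices), `energy`, `axial_force` (pN,
#'   compression positive), `max_amplitude` (um), `dominant_wavelength`
#'   (um, `NA` below onset), `onset_strain` (`NA` if never buckled).
#' @export
simulate_ramp <- function(model, max_strain, n_steps, seed = 1L,
                          amplitude_threshold = 0.05, ...) {
  stopifnot(inherits(model, "rod_model"))
  if (n_steps < 2) stop("need at least 2 strain steps", call. = FALSE)
  strains <- seq(max_strain / n_steps, max_strain, length.out = n_steps)
  shapes <- vector("list", n_steps)
  energy <- force_ax <- amp <- lam <- numeric(n_steps)
  shape <- NULL
  for (s in seq_len(n_steps)) {
    r <- relax(model, strains[s], shape = shape, seed = seed + s - 1L, ...)
    shape <- r$shape
    shapes[[s]] <- shape
    energy[s] <- r$energy
    seg <- diff(shape)
    len <- sqrt(seg[, 1]^2 + seg[, 2]^2)
    force_ax[s] <- model$axial_stiffness *
      mean(model$node_spacing - len) / model$node_spacing
    amp[s] <- max(abs(shape[, 2]))
    lam[s] <- if (amp[s] > amplitude_threshold) {
      dominant_wavelength(shape, amplitude_threshold = amplitude_threshold)
    } else NA_real_
  }
  onset <- strains[amp > amplitude_threshold][1]
  structure(
    list(model = model, strain_history = strains, shapes = shapes,
         energy = energy, axial_force = force_ax, max_amplitude = amp,
         dominant_wavelength = lam,
         onset_strain = if (is.na(onset)) NA_real_ else onset),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  n <- length(x$strain_history)
  cat(sprintf(
    "<simulation_result> %d steps to %.3g%% strain; onset %.3g%%, final lambda %.3g um\n",
    n, 100 * max(x$strain_history), 100 * x$onset_strain,
    x$dominant_wavelength[n]))
  invisible(x)
}

#' Critical buckling force of a finite rod on an elastic foundation
#'
#' Minimizes `F(m) = EI (m pi / L_e)^2 + E_c (L_e / (m pi))^2` over the
#' integer mode number `m >= 1`, with effective length `L_e = L` for pinned
#' ends and `L / 2` for clamped ends. For long rods the minimum approaches
#' the continuum value `2 sqrt(EI E_c)` from above; short rods pay a
#' finite-size penalty because the admissible wavelengths are quantized,
#' which is why short filaments resist buckling to much larger strains.
#'
#' @param mech A [filament_mechanics()] object or bare `EI` (units free as
#'   long as consistent with `ec` and `length`).
#' @param ec Foundation modulus (force/length^2); may be 0 for the classical
#'   Euler column.
#' @param length Rod length.
#' @param boundary `"clamped"` or `"pinned"`.
#' @return A list with `force` and `mode` (the number of half-waves; ties
#'   broken towards the smaller mode).
#' @export
finite_length_critical_force <- function(mech, ec, length,
                                         boundary = c("clamped", "pinned")) {
  boundary <- match.arg(boundary)
  ei <- .ei(mech)
  if (!is.numeric(ec) || length(ec) != 1 || !is.finite(ec) || ec < 0) {
    stop("`ec` must be a finite scalar >= 0", call. = FALSE)
  }
  check_positive(length, "length")
  le <- if (boundary == "clamped") length / 2 else length
  f_of <- function(m) ei * (m * pi / le)^2 + ec * (le / (m * pi))^2
  if (ec == 0) return(list(force = f_of(1), mode = 1L))
  m_star <- (le / pi) * (ec / ei)^0.25
  cand <- sort(unique(pmax(1L, c(1L, floor(m_star) + (-2:2),
                                 ceiling(m_star)))))
  fv <- vapply(cand, f_of, numeric(1))
  best <- min(fv)
  m <- cand[which(fv <= best * (1 + 1e-12))][1]
  list(force = f_of(m), mode = as.integer(m))
}
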
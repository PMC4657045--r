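#' Default per-condition generator parameters
#'
#' The five standard kinesin conditions (10-200 nM, spacings 95-18 nm) with
#' per-crest wavelength and amplitude distributions at critical strain. The
#' 10 nM and 200 nM rows carry the reported experimental means and SDs
#' (21.14 +/- 5.6 um and 2.16 +/- 0.89 um; 3.11 +/- 1.21 um and 0.72 +/-
#' 0.16 um); intermediate conditions are interpolated with a power law in
#' spacing (exponent set by the two end conditions) and linearly interpolated
#' relative SDs, since only the end-condition distributions are reported.
#' Critical strains anchor at 0.6% (10 nM), 1.2% (50 nM) and 2.0% (200 nM).
#'
#' @param n_filaments Filaments per condition (default 30).
#' @return A data frame with columns `kinesin_nM`, `spacing_nm`,
#'   `wavelength_um`, `wavelength_sd_um`, `amplitude_um`, `amplitude_sd_um`,
#'   `critical_strain`, `n_filaments`.
#' @export
default_conditions <- function(n_filaments = 30) {
  spacing <- c(95, 51, 36, 23, 18)
  frac <- log(95 / spacing) / log(95 / 18)   # 0 at 95 nm, 1 at 18 nm
  p_wl <- log(21.14 / 3.11) / log(95 / 18)
  p_am <- log(2.16 / 0.72) / log(95 / 18)
  wl <- 21.14 * (spacing / 95)^p_wl
  am <- 2.16 * (spacing / 95)^p_am
  wl_rel <- 5.6 / 21.14 + (1.21 / 3.11 - 5.6 / 21.14) * frac
  am_rel <- 0.89 / 2.16 + (0.16 / 0.72 - 0.89 / 2.16) * frac
  cs <- c(0.006, 0.009, 0.012, 0.016, 0.020)
  data.frame(
    kinesin_nM = c(10, 30, 50, 100, 200),
    spacing_nm = spacing,
    wavelength_um = wl, wavelength_sd_um = wl * wl_rel,
    amplitude_um = am, amplitude_sd_um = am * am_rel,
    critical_strain = cs,
    n_filaments = n_filaments
  )
}

#' Synthetic-experiment generator specification
#'
#' Fully determines a synthetic buckling experiment: per-condition wavelength
#' and amplitude distributions, coordinate noise, sampling step, filament
#' length range, strain schedule and seed. The same spec and seed always
#' regenerate bit-identical data.
#'
#' @param conditions Data frame as returned by [default_conditions()].
#' @param coord_noise Gaussian coordinate noise SD in um (default 0.05, an
#'   optical localization surrogate).
#' @param sampling_step Centerline sampling step in um (default 0.1).
#' @param length_range Filament length range in um (default c(20, 50)).
#' @param strains Strain grid applied to every filament (fractions).
#' @param knee_strain Transitional strain of the programmed wavelength
#'   response (default 0.15).
#' @param seed Integer seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(conditions = default_conditions(),
                           coord_noise = 0.05, sampling_step = 0.1,
                           length_range = c(20, 50),
                           strains = c(0, 0.025, 0.05, 0.125, 0.25, 0.5),
                           knee_strain = 0.15, seed = 1L) {
  need <- c("kinesin_nM", "spacing_nm", "wavelength_um", "wavelength_sd_um",
            "amplitude_um", "amplitude_sd_um", "critical_strain",
            "n_filaments")
  miss <- setdiff(need, names(conditions))
  if (length(miss)) stop("conditions missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(conditions$kinesin_nM)) {
    stop("duplicate condition keys (kinesin_nM)", call. = FALSE)
  }
  for (col in c("wavelength_um", "wavelength_sd_um", "amplitude_um",
                "amplitude_sd_um")) {
    check_positive(conditions[[col]], col)
  }
  if (any(conditions$wavelength_sd_um >= conditions$wavelength_um)) {
    stop("wavelength SD must be smaller than its mean", call. = FALSE)
  }
  check_positive(coord_noise, "coord_noise", allow_zero = TRUE)
  check_positive(sampling_step, "sampling_step")
  structure(
    list(conditions = conditions, coord_noise = coord_noise,
         sampling_step = sampling_step, length_range = length_range,
         strains = sort(unique(strains)), knee_strain = knee_strain,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

# truncated-normal draw, lower truncation at 0.1 * mean (rejection sampling)
.rtrunc <- function(n, mean, sd) {
  lo <- 0.1 * mean
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo]
  }
  out
}

# programmed strain response of the per-filament wavelength / amplitude
.strain_response <- function(lambda_c, amp_c, strain, critical_strain,
                             knee_strain, wl_rate = 3.0, wl_rate_late = 0.3,
                             amp_rate = 3.0) {
  d1 <- max(0, min(strain, knee_strain) - critical_strain)
  d2 <- max(0, strain - knee_strain)
  list(
    wavelength = lambda_c * max(0.2, 1 - wl_rate * d1 - wl_rate_late * d2),
    amplitude = amp_c * (1 + amp_rate * max(0, strain - critical_strain))
  )
}

#' Generate one synthetic filament trace
#'
#' Below the condition's critical strain the filament is straight; above it
#' the centerline is a sinusoid whose per-filament wavelength and amplitude
#' are drawn from truncated normal distributions (truncation at a tenth of
#' the mean) around the programmed condition means, with a random phase.
#' Beyond the critical strain the programmed wavelength decreases (steeply up
#' to the transitional strain, slowly after) and the amplitude increases.
#' Gaussian noise of SD `coord_noise` is added to both coordinates.
#'
#' @param condition One row of a conditions data frame (see
#'   [default_conditions()]).
#' @param strain Applied strain fraction.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param coord_noise,sampling_step,length_range,knee_strain See
#'   [generator_spec()].
#' @param filament_id Identifier for the trace.
#' @return A [filament_trace()] with attribute `"ground_truth"`: a list with
#'   the drawn `wavelength`, `amplitude` (um; `NA` below onset),
#'   `critical_strain` and `length`.
#' @export
generate_trace <- function(condition, strain, seed = NULL,
                           coord_noise = 0.05, sampling_step = 0.1,
                           length_range = c(20, 50), knee_strain = 0.15,
                           filament_id = "MT1") {
  if (!is.finite(strain) || strain < 0) {
    stop("`strain` must be >= 0", call. = FALSE)
  }
  gen <- function() {
    len <- stats::runif(1, length_range[1], length_range[2])
    x <- seq(0, len, by = sampling_step)
    buckled <- strain >= condition$critical_strain && strain > 0
    if (buckled) {
      lam_c <- .rtrunc(1, condition$wavelength_um, condition$wavelength_sd_um)
      amp_c <- .rtrunc(1, condition$amplitude_um, condition$amplitude_sd_um)
      resp <- .strain_response(lam_c, amp_c, strain,
                               condition$critical_strain, knee_strain)
      phi <- stats::runif(1, 0, 2 * pi)
      y <- resp$amplitude * sin(2 * pi * x / resp$wavelength + phi)
      truth <- list(wavelength = resp$wavelength,
                    amplitude = resp$amplitude,
                    critical_strain = condition$critical_strain,
                    length = len)
    } else {
      y <- rep(0, length(x))
      truth <- list(wavelength = NA_real_, amplitude = NA_real_,
                    critical_strain = condition$critical_strain,
                    length = len)
    }
    if (coord_noise > 0) {
      x <- x + stats::rnorm(length(x), 0, coord_noise)
      y <- y + stats::rnorm(length(y), 0, coord_noise)
    }
    tr <- filament_trace(x, y, strain = strain,
                         kinesin_nM = condition$kinesin_nM,
                         filament_id = filament_id)
    attr(tr, "ground_truth") <- truth
    tr
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate a full synthetic experiment
#'
#' Full factorial over conditions, filaments and the strain grid, with a
#' persistent per-trace ground-truth ledger for recovery scoring.
#'
#' @param spec A [generator_spec()].
#' @return An [experiment_dataset()] whose `ground_truth` data frame has one
#'   row per trace (`filament_id`, `kinesin_nM`, `spacing_nm`, `strain`,
#'   `true_wavelength`, `true_amplitude`, `critical_strain`, `length`).
#' @export
generate_experiment <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    traces <- list()
    gt <- list()
    for (ci in seq_len(nrow(spec$conditions))) {
      cond <- spec$conditions[ci, ]
      for (f in seq_len(cond$n_filaments)) {
        fid <- sprintf("k%g_f%03d", cond$kinesin_nM, f)
        for (strain in spec$strains) {
          tr <- generate_trace(cond, strain, seed = NULL,
                               coord_noise = spec$coord_noise,
                               sampling_step = spec$sampling_step,
                               length_range = spec$length_range,
                               knee_strain = spec$knee_strain,
                               filament_id = fid)
          truth <- attr(tr, "ground_truth")
          traces[[length(traces) + 1]] <- tr
          gt[[length(gt) + 1]] <- data.frame(
            filament_id = fid, kinesin_nM = cond$kinesin_nM,
            spacing_nm = cond$spacing_nm, strain = strain,
            true_wavelength = truth$wavelength,
            true_amplitude = truth$amplitude,
            critical_strain = truth$critical_strain,
            length = truth$length
          )
        }
      }
    }
    experiment_dataset(traces, ground_truth = do.call(rbind, gt),
                       conditions = spec$conditions)
  })
}

#' Render a trace as a synthetic fluorescence image
#'
#' Deposits the line integral of the polyline onto a pixel grid and convolves
#' with an isotropic Gaussian point-spread surrogate. Intended for generating
#' raster fixtures; pixel-level tracing is out of scope for the analysis
#' pipeline itself.
#'
#' @param trace A [filament_trace()].
#' @param pixel_size Pixel edge in um (default 0.1).
#' @param psf_sigma Gaussian PSF sigma in um (default 0.25).
#' @return A numeric intensity matrix (rows = y, columns = x) with
#'   attributes `origin` (um coordinates of pixel \[1,1\] center) and
#'   `pixel_size`. Values are non-negative and scaled to unit maximum.
#' @export
render_raster <- function(trace, pixel_size = 0.1, psf_sigma = 0.25) {
  stopifnot(inherits(trace, "filament_trace"))
  check_positive(pixel_size, "pixel_size")
  check_positive(psf_sigma, "psf_sigma")
  p <- trace$points
  if (nrow(p) < 2 || contour_length(trace) == 0) {
    stop("degenerate trace", call. = FALSE)
  }
  margin <- 3 * psf_sigma + pixel_size
  x0 <- min(p$x) - margin; x1 <- max(p$x) + margin
  y0 <- min(p$y) - margin; y1 <- max(p$y) + margin
  ncol_ <- ceiling((x1 - x0) / pixel_size) + 1
  nrow_ <- ceiling((y1 - y0) / pixel_size) + 1
  img <- matrix(0, nrow_, ncol_)
  # dense resampling of the polyline, ~4 samples per pixel
  seg_len <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  s <- c(0, cumsum(seg_len))
  ns <- max(2, ceiling(s[length(s)] / (pixel_size / 4)))
  sg <- seq(0, s[length(s)], length.out = ns)
  xs <- stats::approx(s, p$x, xout = sg, ties = mean)$y
  ys <- stats::approx(s, p$y, xout = sg, ties = mean)$y
  ix <- pmin(ncol_, pmax(1, round((xs - x0) / pixel_size) + 1))
  iy <- pmin(nrow_, pmax(1, round((ys - y0) / pixel_size) + 1))
  for (i in seq_along(ix)) img[iy[i], ix[i]] <- img[iy[i], ix[i]] + 1
  # separable Gaussian blur
  half <- ceiling(3 * psf_sigma / pixel_size)
  kern <- stats::dnorm(seq(-half, half) * pixel_size, sd = psf_sigma)
  kern <- kern / sum(kern)
  blur1 <- function(v) {
    out <- stats::convolve(c(rep(0, half), v, rep(0, half)), rev(kern),
                           type = "filter")
    out
  }
  img <- apply(img, 2, blur1)
  img <- t(apply(img, 1, blur1))
  img[img < 0] <- 0
  if (max(img) > 0) img <- img / max(img)
  attr(img, "origin") <- c(x = x0, y = y0)
  attr(img, "pixel_size") <- pixel_size
  img
}
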
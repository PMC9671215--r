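#' Scattering vector magnitude
#'
#' Standard light-scattering geometry: q = 4 pi n sin(theta/2) / lambda, with
#' the wavelength in nm and the result in 1/m. The 633 nm / 90 degree / n =
#' 1.33 default geometry gives q = 1.87e7 1/m.
#'
#' @param wavelength_nm Laser wavelength in vacuo, nm.
#' @param refractive_index Solvent refractive index.
#' @param angle_deg Scattering angle in degrees, in (0, 180).
#' @return q in 1/m.
#' @export
scattering_vector <- function(wavelength_nm = 633, refractive_index = 1.33,
                              angle_deg = 90) {
  .check_positive_scalar(wavelength_nm, "wavelength_nm")
  .check_positive_scalar(refractive_index, "refractive_index")
  if (!is.numeric(angle_deg) || angle_deg <= 0 || angle_deg >= 180)
    .stopf("'angle_deg' must lie strictly between 0 and 180")
  4 * pi * refractive_index * sin(angle_deg * pi / 360) /
    (wavelength_nm * 1e-9)
}

#' Size distribution for DLS simulation
#'
#' A discrete intensity-weighted distribution of diffusing species, given
#' either as diffusion coefficients (m^2/s) or as hydrodynamic diameters (nm,
#' converted through Stokes-Einstein in `medium`). Weights are normalized
#' to 1.
#'
#' @param weights Positive component weights.
#' @param diffusion_coefficients Diffusion coefficients in m^2/s, or `NULL`.
#' @param diameters_nm Hydrodynamic diameters in nm, or `NULL`.
#' @param medium A [solvent_medium()] with viscosity (needed for diameters).
#' @return Object of class `size_distribution` with fields `weights` and
#'   `diffusion` (m^2/s).
#' @export
size_distribution <- function(weights, diffusion_coefficients = NULL,
                              diameters_nm = NULL,
                              medium = water_medium()) {
  if (any(weights <= 0)) .stopf("weights must be positive")
  w <- weights / sum(weights)
  if (is.null(diffusion_coefficients) == is.null(diameters_nm))
    .stopf("give exactly one of diffusion_coefficients or diameters_nm")
  D <- if (!is.null(diffusion_coefficients)) diffusion_coefficients
       else diffusion_from_diameter(diameters_nm, medium)
  if (length(D) != length(w)) .stopf("weights and sizes differ in length")
  if (any(D <= 0)) .stopf("diffusion coefficients must be positive")
  structure(list(weights = w, diffusion = D), class = "size_distribution")
}

#' Aqueous measurement medium default
#'
#' Water at 25 C: relative permittivity 80, viscosity 0.89 mPa s.
#' @return A [solvent_medium()].
#' @export
water_medium <- function() solvent_medium(80, 298.15, 0.89e-3)

#' Stokes-Einstein conversions
#'
#' `diffusion_from_diameter()` maps a hydrodynamic diameter (nm) to the
#' translational diffusion coefficient D = kB T / (3 pi eta d);
#' `hydrodynamic_size()` is the exact inverse, returning the diameter
#' 2 RH = kB T / (3 pi eta D). Both need the medium viscosity.
#'
#' @param diameter_nm Hydrodynamic diameter(s) in nm.
#' @param mean_diffusion Diffusion coefficient(s) in m^2/s.
#' @param medium A [solvent_medium()] with `viscosity` set.
#' @return m^2/s, or nm respectively.
#' @export
diffusion_from_diameter <- function(diameter_nm, medium = water_medium()) {
  medium <- .as_medium(medium)
  if (is.na(medium$viscosity)) .stopf("medium viscosity is required")
  if (any(diameter_nm <= 0)) .stopf("diameters must be positive")
  .const$kB * medium$temperature /
    (3 * pi * medium$viscosity * diameter_nm * 1e-9)
}

#' @rdname diffusion_from_diameter
#' @export
hydrodynamic_size <- function(mean_diffusion, medium = water_medium()) {
  medium <- .as_medium(medium)
  if (is.na(medium$viscosity)) .stopf("medium viscosity is required")
  if (any(mean_diffusion <= 0)) .stopf("diffusion must be positive")
  1e9 * .const$kB * medium$temperature /
    (3 * pi * medium$viscosity * mean_diffusion)
}

#' Simulate an intensity autocorrelation trace
#'
#' Siegert construction: g2(tau) = 1 + beta |sum_i w_i exp(-D_i q^2 tau)|^2,
#' plus additive Gaussian noise of standard deviation `noise_sigma`
#' (deterministic for a given `seed`). Global RNG state is untouched.
#'
#' @param dist A [size_distribution()].
#' @param q Scattering vector in 1/m.
#' @param lags Strictly increasing positive lag times in s.
#' @param beta Coherence factor in (0, 1].
#' @param noise_sigma Gaussian noise sd on g2 (>= 0).
#' @param seed Integer seed (required when `noise_sigma > 0`).
#' @param medium A [solvent_medium()] recorded with the trace.
#' @return Object of class `correlogram_trace` with `lags`, `g2`, `q`,
#'   `beta`, `medium`.
#' @export
simulate_g2 <- function(dist, q, lags, beta = 1, noise_sigma = 0,
                        seed = NULL, medium = water_medium()) {
  stopifnot(inherits(dist, "size_distribution"))
  if (any(diff(lags) <= 0) || any(lags <= 0))
    .stopf("lags must be positive and strictly increasing")
  if (beta <= 0 || beta > 1) .stopf("beta must lie in (0, 1]")
  if (noise_sigma < 0) .stopf("noise_sigma must be >= 0")
  g1 <- vapply(lags, function(tau)
    sum(dist$weights * exp(-dist$diffusion * q^2 * tau)), numeric(1))
  g2 <- 1 + beta * g1^2
  if (noise_sigma > 0) {
    if (is.null(seed)) .stopf("a seed is required for noisy simulation")
    g2 <- g2 + withr::with_seed(as.integer(seed),
                                stats::rnorm(length(lags), 0, noise_sigma))
  }
  structure(list(lags = lags, g2 = g2, q = q, beta = beta, medium = medium),
            class = "correlogram_trace")
}

#' Second-order cumulant analysis of a correlogram
#'
#' Linearized cumulant fit of ln(g2 - 1) = ln(beta) - 2 mu1 tau + mu2 tau^2
#' by weighted least squares (weights proportional to (g2-1)^2), over the lag
#' window where (g2-1)/beta exceeds `window_floor`. Returns the first two
#' cumulants, the mean diffusion coefficient D = mu1/q^2, the
#' Stokes-Einstein hydrodynamic diameter, and the polydispersity index
#' PDI = 1 + mu2/mu1^2 (so 1 means monodisperse). A negative fitted mu2 is
#' clamped to 0 and flagged in `mu2_clamped`. The alternative size-CV form
#' PDI = 1 + sigma_R/RH is reported as `pdi_size_cv`.
#'
#' @param trace A [correlogram_trace()] (or list with `lags`, `g2`, `q`,
#'   optionally `beta`, `medium`).
#' @param beta Coherence factor; `NULL` (default) estimates it from the
#'   tau -> 0 intercept of the fit.
#' @param window_floor Fit-window threshold on (g2-1)/beta (default 0.05).
#' @param medium Medium for Stokes-Einstein sizing (default from the trace).
#' @return Object of class `cumulant_result` with `mu1` (1/s), `mu2` (1/s^2),
#'   `mean_diffusion` (m^2/s), `hydrodynamic_diameter` (nm), `pdi`,
#'   `pdi_size_cv`, `beta`, `mu2_clamped`, `n_points`.
#' @export
cumulant_fit <- function(trace, beta = NULL, window_floor = 0.05,
                         medium = NULL) {
  lags <- trace$lags; g2 <- trace$g2; q <- trace$q
  if (is.null(medium)) medium <- trace$medium
  if (is.null(medium)) medium <- water_medium()
  if (length(lags) < 10L) .stopf("need at least 10 lags")
  amp <- g2 - 1
  if (all(amp <= 0)) .stopf("no signal: g2 <= 1 everywhere")
  beta0 <- if (is.null(beta)) max(amp) else beta
  keep <- which(amp / beta0 > window_floor & amp > 0)
  if (length(keep) < 3L) .stopf("fit window too small (%d points)",
                                length(keep))
  tau <- lags[keep]; a <- amp[keep]
  fit <- stats::lm(log(a) ~ tau + I(tau^2), weights = a^2)
  b <- stats::coef(fit)
  mu1 <- -b[[2]] / 2
  mu2 <- b[[3]]
  beta_hat <- if (is.null(beta)) exp(b[[1]]) else beta
  clamped <- FALSE
  if (mu2 < 0) { mu2 <- 0; clamped <- TRUE }
  if (mu1 <= 0) .stopf("non-physical decay rate (mu1 <= 0); fit failed")
  D <- mu1 / q^2
  dia <- hydrodynamic_size(D, medium)
  pdi <- 1 + mu2 / mu1^2
  # size-CV alternative: sigma_R/RH equals sigma_D/D to first order
  pdi_cv <- 1 + sqrt(mu2) / mu1
  structure(list(mu1 = mu1, mu2 = mu2, mean_diffusion = D,
                 hydrodynamic_diameter = dia, pdi = pdi,
                 pdi_size_cv = pdi_cv, beta = beta_hat,
                 mu2_clamped = clamped, n_points = length(keep)),
            class = "cumulant_result")
}

#' @export
print.cumulant_result <- function(x, ...) {
  cat(sprintf(
    "Cumulant fit: D = %.3e m^2/s, diameter = %.1f nm, PDI = %.3f (n = %d)\n",
    x$mean_diffusion, x$hydrodynamic_diameter, x$pdi, x$n_points))
  invisible(x)
}
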
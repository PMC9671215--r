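#' Lamellar particle presets
#'
#' Ground-truth parameter presets for the three observed particle
#' archetypes, usable both as generator inputs and as classification
#' references: `"A1"` compact multilamellar (D = 5.4 nm, negligible decay
#' and dilation, high compaction alpha = 8), `"A2"` core-shell stratified
#' (D = 7.3 nm, strong radial decay k = 0.05 1/nm, appreciable dilation),
#' and `"B"` hollow lipid-only (D = 5.2 nm, smooth sinusoidal alpha = 1).
#' Amplitude/baseline and the A2 dilation and compaction values are
#' generator choices, flagged under `synthetic_choice`.
#'
#' @param name One of `"A1"`, `"A2"`, `"B"`.
#' @return A [lamellar_model()] with attribute `synthetic_choice` naming the
#'   fields that are generator conventions rather than measured values.
#' @export
lamellar_preset <- function(name = c("A1", "A2", "B")) {
  name <- match.arg(name)
  m <- switch(name,
    A1 = lamellar_model(S0 = 1, k = 0,    D = 5.4, delta = 0,
                        alpha = 8, baseline = 0.1),
    A2 = lamellar_model(S0 = 1, k = 0.05, D = 7.3, delta = 0.1 / 7.3,
                        alpha = 4, baseline = 0.1),
    B  = lamellar_model(S0 = 1, k = 0,    D = 5.2, delta = 0,
                        alpha = 1, baseline = 0.1)
  )
  attr(m, "preset") <- name
  attr(m, "synthetic_choice") <- switch(name,
    A1 = c("S0", "baseline"),
    A2 = c("S0", "baseline", "delta", "alpha"),
    B  = c("S0", "baseline"))
  m
}

# md5 content hash of a numeric vector (little-endian IEEE doubles)
.content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  writeBin(as.double(x), con, endian = "little")
  close(con)
  unname(tools::md5sum(f))
}

.ground_truth <- function(generator, params, seed, artifact_values) {
  list(generator = generator, params = params, seed = seed,
       rng = "Mersenne-Twister (R default)",
       content_hash = .content_hash(artifact_values))
}

# Poisson (signal-dependent) then Gaussian (read) noise. SNR is defined as
# peak model amplitude over the Poisson sd at the peak, giving the gain
# g = peak / snr^2 used by the callers.
.detector_noise <- function(signal, poisson_scale, gaussian_sigma) {
  out <- signal
  if (poisson_scale > 0)
    out <- poisson_scale * stats::rpois(length(signal),
                                        pmax(signal, 0) / poisson_scale)
  if (gaussian_sigma > 0)
    out <- out + stats::rnorm(length(signal), 0, gaussian_sigma)
  pmax(out, 0)
}

#' Synthetic multilamellar particle image
#'
#' Renders a radially symmetric particle from a lamellar structure-factor
#' model: intensity I(r) = S(r) for radii up to `outer_radius_nm` (an
#' optional corona annulus from `corona$start_radius_nm` outward uses
#' `corona$model`), baseline elsewhere, then Poisson (gain
#' `noise$poisson_scale`) and additive Gaussian (`noise$gaussian_sigma`)
#' detector noise. Deterministic for a given seed; the global RNG state is
#' untouched. Intensities are scaled so the noiseless model peak sits at 60%
#' of the unit dynamic range (headroom for noise when writing 8/16-bit
#' files).
#'
#' @param size_px Image side length in pixels (square field).
#' @param pixel_size_nm Pixel size in nm/px.
#' @param model A [lamellar_model()] (e.g. a [lamellar_preset()]).
#' @param outer_radius_nm Particle radius in nm; must fit in the half-field.
#' @param corona Optional list `(start_radius_nm, model)`.
#' @param noise List with `poisson_scale` (gain, >= 0; 0 disables) and
#'   `gaussian_sigma` (a.u. on the unit scale, >= 0).
#' @param center_px Particle centre in pixel coordinates `c(x, y)`; default
#'   the field centre.
#' @param seed Integer seed (mandatory).
#' @return List with `image` (matrix in \[0, 1\]), `pixel_size_nm` and
#'   `ground_truth` (generator record incl. a content hash).
#' @export
make_lamellar_image <- function(size_px = 256, pixel_size_nm = 0.5,
                                model = lamellar_preset("A1"),
                                outer_radius_nm = NULL, corona = NULL,
                                noise = list(poisson_scale = 0,
                                             gaussian_sigma = 0),
                                center_px = NULL, seed) {
  if (missing(seed)) .stopf("'seed' is mandatory for synthetic images")
  .check_positive_scalar(pixel_size_nm, "pixel_size_nm")
  half_nm <- (size_px - 1) / 2 * pixel_size_nm
  if (is.null(outer_radius_nm)) outer_radius_nm <- 0.9 * half_nm
  if (outer_radius_nm > half_nm)
    .stopf("outer radius (%.1f nm) exceeds the half-field (%.1f nm)",
           outer_radius_nm, half_nm)
  if (is.null(center_px)) center_px <- c((size_px + 1) / 2, (size_px + 1) / 2)
  xs <- (seq_len(size_px) - center_px[1]) * pixel_size_nm
  ys <- (seq_len(size_px) - center_px[2]) * pixel_size_nm
  rr <- sqrt(outer(ys^2, xs^2, "+"))   # rows = y, cols = x
  img <- matrix(model$baseline, size_px, size_px)
  core <- rr <= outer_radius_nm
  img[core] <- evaluate_model(model, rr[core])
  if (!is.null(corona)) {
    ann <- rr >= corona$start_radius_nm & rr <= outer_radius_nm
    img[ann] <- evaluate_model(corona$model, rr[ann])
  }
  peak <- model$baseline + model$S0
  img <- img * (0.6 / peak)
  img <- withr::with_seed(as.integer(seed), {
    matrix(.detector_noise(as.vector(img),
                           noise$poisson_scale * (0.6 / peak),
                           noise$gaussian_sigma),
           size_px, size_px)
  })
  img <- pmin(img, 1)
  gt_params <- list(size_px = size_px, pixel_size_nm = pixel_size_nm,
                    model = unclass(model), outer_radius_nm = outer_radius_nm,
                    corona = corona, noise = noise, center_px = center_px,
                    synthetic_choice = attr(model, "synthetic_choice"))
  list(image = img, pixel_size_nm = pixel_size_nm,
       ground_truth = .ground_truth("make_lamellar_image", gt_params, seed,
                                    as.vector(img)))
}

#' Synthetic noisy radial profile
#'
#' One-dimensional counterpart of [make_lamellar_image()]: evaluates a
#' lamellar model on an even radial grid and applies Poisson noise at a
#' stated signal-to-noise ratio (SNR = peak amplitude / Poisson sd at the
#' peak), plus optional Gaussian read noise. Used for fit-recovery studies
#' where rendering a full image is unnecessary.
#'
#' @param model A [lamellar_model()].
#' @param r_max_nm Profile extent in nm.
#' @param dr_nm Radial step in nm.
#' @param snr Peak signal-to-noise ratio (Inf for noise-free).
#' @param gaussian_sigma Additive Gaussian sd (a.u.).
#' @param seed Integer seed (mandatory when noisy).
#' @return List with `profile` (a [radial_profile()]) and `ground_truth`.
#' @export
make_noisy_profile <- function(model, r_max_nm = 6 * model$D, dr_nm = 0.25,
                               snr = Inf, gaussian_sigma = 0, seed = NULL) {
  r <- seq(0, r_max_nm, by = dr_nm)
  y <- evaluate_model(model, r)
  peak <- model$baseline + model$S0
  gain <- if (is.finite(snr)) peak / snr^2 else 0
  if (gain > 0 || gaussian_sigma > 0) {
    if (is.null(seed)) .stopf("'seed' is required for noisy profiles")
    y <- withr::with_seed(as.integer(seed),
                          .detector_noise(y, gain, gaussian_sigma))
  }
  prof <- radial_profile(r, y, provenance = list(pixel_size = dr_nm))
  gt <- .ground_truth("make_noisy_profile",
                      list(model = unclass(model), r_max_nm = r_max_nm,
                           dr_nm = dr_nm, snr = snr,
                           gaussian_sigma = gaussian_sigma),
                      seed, y)
  list(profile = prof, ground_truth = gt)
}

#' DLS instrument presets from the characterization tables
#'
#' Monomodal presets named after the measured fractions: `"pellet"`
#' (mean diameter 172 nm, PDI 1.18), `"supernatant"` (193 nm, PDI 1.22) and
#' `"clodronate"` (400 nm, PDI 1.50).
#'
#' @param name Preset name.
#' @return List with `diameter_nm` and `pdi`.
#' @export
dls_preset <- function(name = c("pellet", "supernatant", "clodronate")) {
  name <- match.arg(name)
  switch(name,
         pellet      = list(diameter_nm = 172, pdi = 1.18),
         supernatant = list(diameter_nm = 193, pdi = 1.22),
         clodronate  = list(diameter_nm = 400, pdi = 1.50))
}

#' Log-normal size distribution matching a mean diameter and PDI
#'
#' Builds a discrete intensity-weighted log-normal diameter distribution
#' whose intensity-weighted mean diffusivity equals the Stokes-Einstein
#' diffusivity of `diameter_nm` and whose diffusivity relative variance
#' equals `pdi - 1` (so a second-order cumulant analysis of the resulting
#' correlogram recovers the stated diameter and PDI). `pdi = 1` gives a
#' monodisperse single component.
#'
#' @param diameter_nm Target cumulant mean diameter in nm.
#' @param pdi Target polydispersity index (>= 1).
#' @param n_components Number of quadrature nodes.
#' @param medium A [solvent_medium()] with viscosity.
#' @return A [size_distribution()].
#' @export
lognormal_size_distribution <- function(diameter_nm, pdi = 1,
                                        n_components = 31,
                                        medium = water_medium()) {
  .check_positive_scalar(diameter_nm, "diameter_nm")
  if (pdi < 1) .stopf("'pdi' must be >= 1")
  if (pdi == 1)
    return(size_distribution(1, diameters_nm = diameter_nm, medium = medium))
  sigma2 <- log(pdi)           # variance of log-diameter
  sigma <- sqrt(sigma2)
  mu <- log(diameter_nm) + sigma2 / 2   # so E[1/d] = 1/diameter_nm
  z <- seq(-4, 4, length.out = n_components)
  d <- exp(mu + sigma * z)
  w <- stats::dnorm(z)
  dist <- size_distribution(w, diameters_nm = d, medium = medium)
  # correct residual discretization bias so the weighted diffusivity mean
  # and relative variance hit the targets exactly
  target_D <- diffusion_from_diameter(diameter_nm, medium)
  m1 <- sum(dist$weights * dist$diffusion)
  v <- sum(dist$weights * (dist$diffusion - m1)^2)
  c_sd <- sqrt((pdi - 1) * target_D^2 / v)
  Dc <- target_D + (dist$diffusion - m1) * c_sd
  if (all(Dc > 0)) dist$diffusion <- Dc
  else dist$diffusion <- dist$diffusion * target_D / m1
  dist
}

#' Synthetic DLS dataset
#'
#' Generates a correlogram for a stated size distribution (or a named
#' preset) via [simulate_g2()], with logarithmically spaced lags spanning
#' the decay and Gaussian detector noise `noise_sigma`.
#'
#' @param preset Optional preset name for [dls_preset()]; overrides
#'   `diameters_nm`/`pdi`.
#' @param diameters_nm Target mean diameter (ignored when `preset` given).
#' @param pdi Target PDI (ignored when `preset` given).
#' @param q Scattering vector in 1/m.
#' @param n_lags Number of lag channels.
#' @param beta Coherence factor.
#' @param noise_sigma Gaussian noise sd on g2.
#' @param seed Integer seed (mandatory when noisy).
#' @param medium A [solvent_medium()] with viscosity.
#' @return List with `trace` (a `correlogram_trace`) and `ground_truth`.
#' @export
make_dls_dataset <- function(preset = NULL, diameters_nm = 172, pdi = 1,
                             q = scattering_vector(), n_lags = 200,
                             beta = 1, noise_sigma = 0, seed = NULL,
                             medium = water_medium()) {
  if (!is.null(preset)) {
    p <- dls_preset(preset)
    diameters_nm <- p$diameter_nm
    pdi <- p$pdi
  }
  dist <- lognormal_size_distribution(diameters_nm, pdi, medium = medium)
  rate <- 2 * sum(dist$weights * dist$diffusion) * q^2
  lags <- exp(seq(log(1e-3 / rate), log(8 / rate), length.out = n_lags))
  trace <- simulate_g2(dist, q, lags, beta = beta,
                       noise_sigma = noise_sigma, seed = seed,
                       medium = medium)
  gt <- .ground_truth("make_dls_dataset",
                      list(preset = preset, diameter_nm = diameters_nm,
                           pdi = pdi, q = q, n_lags = n_lags, beta = beta,
                           noise_sigma = noise_sigma),
                      seed, trace$g2)
  list(trace = trace, ground_truth = gt)
}

#' Synthetic replicate zeta measurements
#'
#' Draws `n` replicate zeta potentials around a true value with Gaussian
#' instrument scatter; `instrument_sigma = 0` returns the true value
#' repeated.
#'
#' @param true_zeta_mV True zeta potential in mV.
#' @param instrument_sigma_mV Replicate scatter sd in mV (>= 0).
#' @param n Number of replicates.
#' @param seed Integer seed (mandatory when `instrument_sigma_mV > 0`).
#' @return List with `values_mV` and `ground_truth`.
#' @export
make_zeta_replicates <- function(true_zeta_mV, instrument_sigma_mV = 0,
                                 n = 5, seed = NULL) {
  if (instrument_sigma_mV < 0) .stopf("sigma must be >= 0")
  vals <- if (instrument_sigma_mV == 0) rep(true_zeta_mV, n)
          else {
            if (is.null(seed)) .stopf("'seed' is required for noisy draws")
            withr::with_seed(as.integer(seed),
                             stats::rnorm(n, true_zeta_mV,
                                          instrument_sigma_mV))
          }
  gt <- .ground_truth("make_zeta_replicates",
                      list(true_zeta_mV = true_zeta_mV,
                           instrument_sigma_mV = instrument_sigma_mV, n = n),
                      seed, vals)
  list(values_mV = vals, ground_truth = gt)
}

#' Printed characterization replicate tables
#'
#' The replicate tables of the characterization campaign as in-package
#' fixtures: DLS diameters/PDIs and zeta replicates for the pellet,
#' supernatant and clodronate-formulation fractions.
#'
#' @return `characterization_tables()` returns a list with `dls` (data frame
#'   of per-synthesis diameter and PDI by fraction) and `zeta` (data frame of
#'   replicate zeta potentials in mV by fraction).
#' @export
characterization_tables <- function() {
  list(
    dls = data.frame(
      fraction = rep(c("pellet", "supernatant", "clodronate"), each = 3),
      synthesis = rep(1:3, times = 3),
      diameter_nm = c(169, 174, 173, 191, 194, 195, 340, 290, 450),
      pdi = c(1.17, 1.20, 1.17, 1.19, 1.24, 1.22, 1.54, 1.35, 1.60)
    ),
    zeta = data.frame(
      fraction = c(rep("pellet", 5), rep("supernatant", 5),
                   rep("clodronate", 3)),
      zeta_mV = c(-2, 3, 3, -3, -4,
                  40.7, 44.7, 42.4, 48.9, 44.3,
                  -45, -56, -26)
    )
  )
}

#' Reference synthesis recipe fixture
#'
#' Writes (or returns) the shell-lipid recipe of the reference synthesis
#' protocol as a YAML document: stock concentrations 10 mg/mL, the four
#' shell lipids with their masses (520/130/40/310 ug of POPC, cholesterol,
#' DSPE-PEG, DSPE-PEG-MAN), the payload/counterion amounts and dosing
#' volume. Round-trips through [read_recipe_yaml()].
#'
#' @param path Optional file path; when `NULL` the recipe list is returned
#'   without writing.
#' @return The recipe list (invisibly when written to `path`).
#' @export
make_recipe_fixture <- function(path = NULL) {
  rec <- list(
    reagents = list(
      list(name = "POPC", molar_mass = 760.1, stock_mg_ml = 10,
           role = "stabilizer"),
      list(name = "cholesterol", molar_mass = 386.7, stock_mg_ml = 10,
           role = "helper"),
      list(name = "DSPE-PEG", molar_mass = 2810, stock_mg_ml = 10,
           role = "adhesion"),
      list(name = "DSPE-PEG-MAN", molar_mass = 3000, stock_mg_ml = 10,
           role = "targeting"),
      list(name = "DChol", molar_mass = 537.3, stock_mg_ml = 18,
           role = "cationic_lipid")
    ),
    lines = list(
      list(reagent = "POPC", mass_ug = 520),
      list(reagent = "cholesterol", mass_ug = 130),
      list(reagent = "DSPE-PEG", mass_ug = 40),
      list(reagent = "DSPE-PEG-MAN", mass_ug = 310)
    ),
    payload = list(monomer_umol = 1.3, counterion_umol = 3.0, stoich = 2,
                   payload_nmol = 40, final_volume_uL = 250),
    target_mole_percent = list(POPC = 60, cholesterol = 30,
                               `DSPE-PEG` = 1, `DSPE-PEG-MAN` = 9)
  )
  if (!is.null(path)) {
    yaml::write_yaml(rec, path)
    return(invisible(rec))
  }
  rec
}

#' Read a recipe YAML file into recipe lines
#'
#' @param path YAML file as written by [make_recipe_fixture()].
#' @return List with `lines` (list of [recipe_line()]), `payload` and
#'   `target_mole_percent` as stored.
#' @export
read_recipe_yaml <- function(path) {
  rec <- yaml::read_yaml(path)
  reg <- list()
  for (rg in rec$reagents)
    reg[[rg$name]] <- reagent(rg$name, rg$molar_mass,
                              if (is.null(rg$stock_mg_ml)) NA_real_
                              else rg$stock_mg_ml,
                              role = rg$role)
  lines <- lapply(rec$lines, function(l) {
    rg <- reg[[l$reagent]]
    if (is.null(rg)) .stopf("recipe line references unknown reagent '%s'",
                            l$reagent)
    if (!is.null(l$mass_ug)) recipe_line(rg, mass_ug = l$mass_ug)
    else recipe_line(rg, volume_uL = l$volume_uL)
  })
  list(lines = lines, reagents = reg, payload = rec$payload,
       target_mole_percent = rec$target_mole_percent)
}
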
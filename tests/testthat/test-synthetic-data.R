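test_that("presets carry the reported archetype parameters", {
  a1 <- lamellar_preset("A1")
  expect_equal(a1$D, 5.4); expect_equal(a1$alpha, 8)
  expect_equal(a1$k, 0);   expect_equal(a1$delta, 0)
  a2 <- lamellar_preset("A2")
  expect_equal(a2$D, 7.3); expect_equal(a2$k, 0.05)
  expect_gt(a2$delta, 0)
  expect_true("delta" %in% attr(a2, "synthetic_choice"))
  b <- lamellar_preset("B")
  expect_equal(b$D, 5.2); expect_equal(b$alpha, 1)
  expect_equal(dls_preset("pellet"), list(diameter_nm = 172, pdi = 1.18))
})

test_that("image generator is seed-deterministic and hash-stable", {
  args <- list(size_px = 96, pixel_size_nm = 0.5,
               model = lamellar_preset("A1"),
               noise = list(poisson_scale = 1e-3, gaussian_sigma = 0.01))
  a <- do.call(make_lamellar_image, c(args, seed = 11))
  b <- do.call(make_lamellar_image, c(args, seed = 11))
  expect_identical(a$image, b$image)
  expect_identical(a$ground_truth$content_hash, b$ground_truth$content_hash)
  c2 <- do.call(make_lamellar_image, c(args, seed = 12))
  expect_false(identical(a$ground_truth$content_hash,
                         c2$ground_truth$content_hash))
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_error(make_lamellar_image(size_px = 64, pixel_size_nm = 0.5,
                                   outer_radius_nm = 100, seed = 1),
               "half-field")
  expect_error(make_lamellar_image(size_px = 64), "seed")
})

test_that("generators leave the global RNG state untouched", {
  set.seed(999)
  before <- .Random.seed
  invisible(make_lamellar_image(size_px = 48, pixel_size_nm = 0.5, seed = 3,
                                noise = list(poisson_scale = 1e-3,
                                             gaussian_sigma = 0.01)))
  invisible(make_dls_dataset(noise_sigma = 0.01, seed = 4))
  invisible(make_zeta_replicates(0, 3, 5, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("zero-noise generator outputs satisfy exact recovery", {
  m <- lamellar_preset("A2")
  prof <- make_noisy_profile(m)$profile
  fit <- fit_lamellar(prof)
  expect_lt(fit$residual_norm, 1e-6)
  expect_equal(fit$params$D, m$D, tolerance = 1e-4)
  mono <- make_dls_dataset(diameters_nm = 150, pdi = 1, noise_sigma = 0)
  fit_d <- cumulant_fit(mono$trace)
  expect_equal(fit_d$hydrodynamic_diameter, 150, tolerance = 1e-3)
})

test_that("DLS generator hits its diameter/PDI targets", {
  sim <- make_dls_dataset(preset = "pellet", noise_sigma = 0)
  dist <- lognormal_size_distribution(172, 1.18)
  mom <- oracle_cumulants(dist$weights, dist$diffusion, sim$trace$q)
  expect_equal(mom$pdi, 1.18, tolerance = 1e-6)
  expect_equal(hydrodynamic_size(mom$mu1 / sim$trace$q^2), 172,
               tolerance = 1e-9)
  # recovered diameter from the trace within 2% over seeds
  devs <- sapply(1:25, function(s) {
    tr <- make_dls_dataset(preset = "pellet", noise_sigma = 0.002,
                           seed = s)$trace
    abs(cumulant_fit(tr)$hydrodynamic_diameter - 172) / 172
  })
  expect_lt(median(devs), 0.02)
})

test_that("zeta replicate generator is calibrated and deterministic", {
  z0 <- make_zeta_replicates(12, 0, 5)
  expect_identical(z0$values_mV, rep(12, 5))
  a <- make_zeta_replicates(0, 3, 5, seed = 8)
  b <- make_zeta_replicates(0, 3, 5, seed = 8)
  expect_identical(a$values_mV, b$values_mV)
  expect_identical(a$ground_truth$content_hash, b$ground_truth$content_hash)
  # mean of many replicates concentrates on the true value
  big <- make_zeta_replicates(0, 3, 4000, seed = 9)
  expect_lt(abs(mean(big$values_mV)), 3 / sqrt(4000) * 4)
})

test_that("the printed characterization tables aggregate as published", {
  tabs <- characterization_tables()
  pellet_d <- tabs$dls$diameter_nm[tabs$dls$fraction == "pellet"]
  expect_equal(mean(pellet_d), 172)
  expect_equal(round(mean(
    tabs$dls$pdi[tabs$dls$fraction == "pellet"]), 2), 1.18)
  sup_d <- tabs$dls$diameter_nm[tabs$dls$fraction == "supernatant"]
  expect_equal(round(mean(sup_d)), 193)
})
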
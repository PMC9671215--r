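test_that("scattering vector follows the standard geometry", {
  expect_equal(scattering_vector(633, 1.33, 90), 1.867e7,
               tolerance = 1e-3)
  expect_equal(scattering_vector(633, 1.33, 90),
               2 * scattering_vector(2 * 633, 1.33, 90))
  expect_lt(scattering_vector(633, 1.33, 0.005),
            1e-4 * scattering_vector(633, 1.33, 90))
  expect_error(scattering_vector(633, 1.33, 180), "between")
})

test_that("Stokes-Einstein sizing round trips and matches closed form", {
  med <- water_medium()
  expect_equal(diffusion_from_diameter(172, med), 2.853e-12,
               tolerance = 1e-3)
  set.seed(2)
  for (d in runif(10, 20, 800)) {
    expect_equal(hydrodynamic_size(diffusion_from_diameter(d, med), med), d,
                 tolerance = 1e-12)
  }
  thin <- solvent_medium(80, 298.15, 0.89e-3 / 2)
  expect_equal(diffusion_from_diameter(172, thin),
               2 * diffusion_from_diameter(172, med))
  expect_error(hydrodynamic_size(1e-12, solvent_medium(80)), "viscosity")
})

test_that("simulated g2 matches the Siegert closed form", {
  q <- scattering_vector()
  lags <- exp(seq(log(1e-6), log(1e-2), length.out = 60))
  dist <- size_distribution(1, diameters_nm = 172)
  tr <- simulate_g2(dist, q, lags, beta = 0.8)
  D <- diffusion_from_diameter(172)
  expect_equal(tr$g2, 1 + 0.8 * exp(-2 * D * q^2 * lags), tolerance = 1e-12)
  # two components: initial slope of ln(g2-1) is -2 mu1 of the mixture
  dist2 <- size_distribution(c(0.3, 0.7), diameters_nm = c(100, 250))
  tr2 <- simulate_g2(dist2, q, lags)
  mom <- oracle_cumulants(dist2$weights, dist2$diffusion, q)
  slope <- (log(tr2$g2[2] - 1) - log(tr2$g2[1] - 1)) / (lags[2] - lags[1])
  expect_equal(slope, -2 * mom$mu1, tolerance = 1e-3)
  # seeded determinism
  a <- simulate_g2(dist, q, lags, noise_sigma = 0.01, seed = 5)
  b <- simulate_g2(dist, q, lags, noise_sigma = 0.01, seed = 5)
  expect_identical(a$g2, b$g2)
  c2 <- simulate_g2(dist, q, lags, noise_sigma = 0.01, seed = 6)
  expect_false(identical(a$g2, c2$g2))
})

test_that("cumulant fit recovers monodisperse traces essentially exactly", {
  sim <- make_dls_dataset(diameters_nm = 172, pdi = 1, noise_sigma = 0)
  fit <- cumulant_fit(sim$trace)
  D_true <- diffusion_from_diameter(172)
  expect_equal(fit$mean_diffusion, D_true, tolerance = 1e-3)
  expect_equal(fit$hydrodynamic_diameter, 172, tolerance = 1e-3)
  expect_equal(fit$pdi, 1, tolerance = 1e-6)
  # agreement with an independent brute-force nonlinear fit
  ora <- oracle_cumulant_nls(sim$trace$lags, sim$trace$g2, beta = 1,
                             mu1_init = D_true * sim$trace$q^2)
  expect_equal(fit$mu1, ora[1], tolerance = 1e-3)
  expect_error(cumulant_fit(list(lags = 1:20 * 1e-4, g2 = rep(0.9, 20),
                                 q = 1e7)), "no signal")
})

test_that("cumulant fit tracks closed-form moments of a narrow mixture", {
  q <- scattering_vector()
  dist <- size_distribution(c(0.5, 0.5), diameters_nm = c(150, 200))
  mom <- oracle_cumulants(dist$weights, dist$diffusion, q)
  rate <- 2 * sum(dist$weights * dist$diffusion) * q^2
  lags <- exp(seq(log(1e-3 / rate), log(8 / rate), length.out = 200))
  tr <- simulate_g2(dist, q, lags, noise_sigma = 0.01, seed = 31)  # SNR 100
  fit <- cumulant_fit(tr)
  expect_equal(fit$mu1, mom$mu1, tolerance = 0.02)
  expect_equal(fit$pdi, mom$pdi, tolerance = 0.02)
})

test_that("fitted PDI is >= 1, tracks width, and sizes stay within 5%", {
  cvs <- c(0.1, 0.2, 0.3)
  med_pdi <- numeric(length(cvs))
  for (j in seq_along(cvs)) {
    pdis <- sizes <- numeric(25)
    for (s in 1:25) {
      sim <- make_dls_dataset(diameters_nm = 172, pdi = 1 + cvs[j]^2,
                              noise_sigma = 0.005, seed = 1000 * j + s)
      fit <- cumulant_fit(sim$trace)
      pdis[s] <- fit$pdi
      sizes[s] <- fit$hydrodynamic_diameter
    }
    expect_true(all(pdis >= 1))
    expect_lt(median(abs(sizes - 172) / 172), 0.05)
    med_pdi[j] <- median(pdis)
  }
  expect_true(all(diff(med_pdi) > 0))
})
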
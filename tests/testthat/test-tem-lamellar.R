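test_that("structure factor agrees with an independent transcription", {
  set.seed(17)
  for (i in 1:20) {
    S0 <- runif(1, 0.2, 5); k <- runif(1, 0, 0.2); D <- runif(1, 3, 10)
    delta <- runif(1, 0, 0.02); alpha <- runif(1, 1, 10)
    B <- runif(1, 0, 0.5)
    r <- sort(runif(80, 0, 50))
    m <- lamellar_model(S0, k, D, delta, alpha, B)
    expect_equal(evaluate_model(m, r),
                 oracle_structure_factor(r, S0, k, D, delta, alpha, B),
                 tolerance = 1e-12)
  }
  # sine roots and peak for the undamped unit case
  m <- lamellar_model(1, 0, 5, 0, 1, 0)
  expect_equal(evaluate_model(m, c(0, 5, 10, 15)), rep(0, 4),
               tolerance = 1e-12)
  expect_equal(evaluate_model(m, 2.5), 1)
})

test_that("dense-layer thickness follows the FWHM closed form", {
  expect_equal(dense_layer_thickness(3, 1), 2)          # (2/3) D
  expect_equal(dense_layer_thickness(5.4, 8), 1.41, tolerance = 0.005)
  # against root-bracketing oracle at random parameters
  set.seed(23)
  for (i in 1:10) {
    D <- runif(1, 3, 9); a <- runif(1, 1, 12)
    expect_equal(dense_layer_thickness(D, a), oracle_fwhm(D, a),
                 tolerance = 1e-8)
  }
  alphas <- seq(1, 14, by = 0.5)
  d <- dense_layer_thickness(5, alphas)
  expect_true(all(diff(d) < 0))        # strictly decreasing in alpha
  expect_lt(dense_layer_thickness(5, 1e8), 1e-3)  # vanishes at high alpha
  expect_equal(dense_layer_thickness(10, 3), 2 * dense_layer_thickness(5, 3))
})

test_that("line profiles sample images faithfully", {
  img <- matrix(0.37, 64, 64)
  p <- extract_line_profile(img, c(5, 5), c(60, 40), width = 3,
                            pixel_size_nm = 0.7)
  expect_true(all(abs(p$intensities - 0.37) < 1e-12))
  expect_equal(max(p$distances), sqrt(55^2 + 35^2) * 0.7)
  # width 1 equals single-line sampling
  g <- outer(1:64, 1:64, function(i, j) sin(i / 5) + cos(j / 7) + 2) / 4
  p1 <- extract_line_profile(g, c(3, 10), c(60, 50), width = 1,
                             pixel_size_nm = 1)
  expect_equal(p1$provenance$averaging_width, 1)
  expect_error(extract_line_profile(img, c(-2, 5), c(10, 10), 1, 1),
               "inside")
  # axis-aligned extraction through a pixel-centre origin is the identity
  m <- lamellar_preset("A1")
  im <- make_lamellar_image(size_px = 257, pixel_size_nm = 0.5, model = m,
                            seed = 1)
  ctr <- c(129, 129)
  prof <- extract_line_profile(im$image, ctr, ctr + c(110, 0), width = 1,
                               pixel_size_nm = 0.5, sampling_px = 1)
  scale <- 0.6 / (m$S0 + m$baseline)
  pred <- scale * evaluate_model(m, prof$distances)
  expect_lt(max(abs(prof$intensities - pred)) / max(pred), 1e-3)
})

test_that("period estimation finds the dominant spacing", {
  r <- seq(0, 40, by = 0.2)
  prof <- radial_profile(r, 1 + sin(2 * pi * r / 5.4))
  expect_equal(as.numeric(estimate_period(prof)), 5.4, tolerance = 0.03)
  expect_error(estimate_period(radial_profile(r, rep(1, length(r)))),
               "peak|oscillat")
  # two-tone input returns the higher-power period, flagged
  two <- radial_profile(r, 2 + sin(2 * pi * r / 5.4) +
                          0.85 * sin(2 * pi * r / 8.7))
  est <- estimate_period(two)
  expect_equal(as.numeric(est), 5.4, tolerance = 0.1)
  expect_true(attr(est, "secondary"))
  # synthetic ring image sampled radially: period within one pixel
  m <- lamellar_preset("B")
  im <- make_lamellar_image(size_px = 257, pixel_size_nm = 0.5, model = m,
                            seed = 2)
  prof_img <- extract_line_profile(im$image, c(129, 129), c(245, 129),
                                   width = 1, pixel_size_nm = 0.5)
  expect_lt(abs(as.numeric(estimate_period(prof_img)) - m$D), 0.5)
})

test_that("noise-free fits recover the generating parameters", {
  set.seed(29)
  cases <- list(
    lamellar_preset("A1"), lamellar_preset("A2"), lamellar_preset("B"),
    lamellar_model(2.3, 0.03, 6.1, 0.004, 2.7, 0.4)
  )
  for (m in cases) {
    prof <- make_noisy_profile(m, r_max_nm = 6 * m$D, dr_nm = 0.25)$profile
    fit <- fit_lamellar(prof)
    expect_true(fit$converged)
    expect_lt(fit$residual_norm, 1e-6)
    expect_equal(fit$params$D, m$D, tolerance = 0.005)
    expect_equal(fit$params$S0, m$S0, tolerance = 0.005)
    expect_equal(fit$params$alpha, m$alpha, tolerance = 0.005)
    expect_equal(fit$params$baseline, m$baseline, tolerance = 0.005)
    expect_lt(abs(fit$params$k - m$k), 0.005 * max(m$k, 0.01))
    # refit started at the truth stays at the truth (fixed point)
    refit <- fit_lamellar(prof, init = unclass(m))
    expect_lt(refit$residual_norm, 1e-8)
    expect_equal(refit$params$D, m$D, tolerance = 1e-6)
  }
})

test_that("noisy presets classify correctly in the vast majority of seeds", {
  for (nm in c("A1", "A2", "B")) {
    m <- lamellar_preset(nm)
    ok <- 0L
    errs <- numeric(20)
    for (s in 1:20) {
      prof <- make_noisy_profile(m, snr = 10, seed = 7000 + s)$profile
      fit <- fit_lamellar(prof)
      errs[s] <- abs(fit$params$D - m$D) / m$D
      if (classify_particle(fit)$label == expected_label[[nm]]) ok <- ok + 1L
    }
    expect_gte(ok, 19L)
    expect_lt(median(errs), 0.05)
  }
})

test_that("classification rules and failure paths behave as specified", {
  fake_fit <- function(S0 = 1, k = 0, D = 5.4, delta = 0, alpha = 8, B = 0) {
    structure(list(params = lamellar_model(S0, k, D, delta, alpha, B),
                   converged = TRUE), class = "lamellar_fit")
  }
  expect_identical(classify_particle(fake_fit())$label, "A1_compact")
  expect_identical(
    classify_particle(fake_fit(k = 0.05, D = 7.3, delta = 0.014,
                               alpha = 4))$label, "A2_core_shell")
  expect_identical(classify_particle(fake_fit(D = 5.2, alpha = 1))$label,
                   "B_hollow")
  # appreciable decay but sinusoidal: no rule fires
  expect_identical(classify_particle(fake_fit(k = 0.1, alpha = 1))$label,
                   "unclassified")
  bad <- structure(list(params = NULL, converged = FALSE),
                   class = "lamellar_fit")
  out <- classify_particle(bad)
  expect_identical(out$label, "unclassified")
  expect_match(out$rule_trace, "not converged")
})
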
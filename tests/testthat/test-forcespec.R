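test_that("simulated post-contact force matches the closed-form cone law", {
  m <- indenter_model()
  # direct law (no compliance): F = (2/pi) tan(theta) E/(1-nu^2) delta^2
  for (d in c(0, 0.4, 1.3, 2.2)) {
    expect_equal(sneddon_force(d, 7.5, m), sneddon_oracle(d, 7.5),
                 tolerance = 1e-12)
  }
  expect_equal(sneddon_force(0, 123, m), 0)

  # simulated samples: recompute delta from the curve and check the law
  cv <- simulate_curve(7.5, m, z0 = 2, noise_sd = 0)
  post <- cv$piezo_z > 2
  delta <- (cv$piezo_z[post] - 2) - cv$force[post] / (cv$spring_constant * 1e3)
  expect_equal(cv$force[post], sneddon_oracle(delta, 7.5), tolerance = 1e-8)

  # linearity in E at fixed indentation (no compliance in the pure law)
  expect_equal(sneddon_force(1.1, 10, m), 2 * sneddon_force(1.1, 5, m))

  # termination at the threshold force
  expect_lte(max(cv$force), cv$threshold_force * 1.05)
})

test_that("curves are deterministic given a seed", {
  a <- simulate_curve(5, z0 = 2, noise_sd = 0.05, seed = 42)
  b <- simulate_curve(5, z0 = 2, noise_sd = 0.05, seed = 42)
  expect_identical(a$force, b$force)
  c2 <- simulate_curve(5, z0 = 2, noise_sd = 0.05, seed = 43)
  expect_false(identical(a$force, c2$force))
})

test_that("contact point is recovered on clean and noisy curves", {
  m <- indenter_model()
  cv <- simulate_curve(7.5, m, z0 = 2.13, noise_sd = 0)
  dz <- diff(cv$piezo_z)[1]
  expect_lt(abs(detect_contact_point(cv) - 2.13), dz)

  # noisy: within 2% of the indentation depth range (20 seeded curves)
  errs <- vapply(1:20, function(i) {
    z0 <- 1.5 + (i %% 5) * 0.2
    cvn <- simulate_curve(7.5, m, z0 = z0, noise_sd = 0.05, seed = i)
    depth <- max(cvn$piezo_z) - z0
    abs(detect_contact_point(cvn) - z0) / depth
  }, numeric(1))
  expect_lt(stats::median(errs), 0.02)

  # degenerate inputs
  flat <- simulate_curve(7.5, m, z0 = 50, noise_sd = 0.01, seed = 1,
                         z_max = 10)  # never contacts
  expect_error(detect_contact_point(flat),
               class = "nichefab_validation_error")
  short <- simulate_curve(7.5, m, z0 = 2, noise_sd = 0)
  short$piezo_z <- short$piezo_z[1:10]
  short$force <- short$force[1:10]
  expect_error(detect_contact_point(short), "20 samples",
               class = "nichefab_validation_error")
})

test_that("modulus fits recover truth and scale linearly with force", {
  m <- indenter_model()
  cv <- simulate_curve(7.5, m, z0 = 2, noise_sd = 0)
  fit <- fit_modulus(cv, m)
  expect_equal(fit$qc_status, "accepted")
  expect_lt(abs(fit$youngs_modulus - 7.5) / 7.5, 0.001)

  # scaling: multiplying the force data by c multiplies E by c (fixed z0)
  scaled <- cv
  scaled$force <- cv$force * 3
  f1 <- fit_modulus(cv, m, z0 = 2, tip_sample_correction = FALSE)
  f3 <- fit_modulus(scaled, m, z0 = 2, tip_sample_correction = FALSE)
  expect_equal(f3$youngs_modulus, 3 * f1$youngs_modulus, tolerance = 1e-9)
})

test_that("bottom-effect correction recovers thin-gel moduli", {
  m0 <- indenter_model()
  mb <- indenter_model(correction = "bottom_effect_cone")
  cv <- simulate_curve(2.5, mb, z0 = 2, h = 10, noise_sd = 0)
  naive <- fit_modulus(cv, m0)
  corrected <- fit_modulus(cv, mb)
  expect_gt(naive$youngs_modulus, 2.5)      # thin sample inflates E
  expect_lt(abs(corrected$youngs_modulus - 2.5) / 2.5, 0.01)

  # thickness -> infinity limit: corrected and uncorrected agree within 1%
  thick <- simulate_curve(7.5, m0, z0 = 2, noise_sd = 0)
  max_delta <- max(thick$piezo_z) - 2
  thick$sample_thickness <- 100 * max_delta
  ratio <- fit_modulus(thick, mb)$youngs_modulus /
           fit_modulus(thick, m0)$youngs_modulus
  expect_lt(abs(ratio - 1), 0.01)

  # configuration guard: correction without thickness
  bare <- simulate_curve(5, m0, z0 = 2, noise_sd = 0)
  expect_error(fit_modulus(bare, mb), class = "nichefab_config_error")
  expect_error(simulate_curve(5, mb, z0 = 2, h = Inf),
               class = "nichefab_config_error")
})

test_that("slip discontinuities are flagged and clean curves pass", {
  m <- indenter_model()
  clean <- simulate_curve(7.5, m, z0 = 2, noise_sd = 0.05, seed = 9)
  expect_identical(qc_discontinuity(clean), "accepted")
  slipped <- simulate_curve(7.5, m, z0 = 2, noise_sd = 0.05, seed = 9,
                            slip = c(3.5, -2))
  expect_identical(qc_discontinuity(slipped), "rejected_discontinuity")
  fit <- fit_modulus(slipped, m)
  expect_identical(fit$qc_status, "rejected_discontinuity")
  expect_true(is.na(fit$youngs_modulus))

  # threshold semantics: level shifts just above jump_sigma * scale are
  # rejected, comfortably smaller ones accepted
  z <- seq(0, 10, by = 0.01)
  set.seed(314)
  noise <- rnorm(length(z), 0, 0.05)
  base <- structure(list(piezo_z = z, force = noise, spring_constant = 0.05,
                         approach_velocity = 0.5, threshold_force = 10,
                         sample_thickness = NULL, truth = NULL),
                    class = "force_curve")
  expect_identical(qc_discontinuity(base), "accepted")
  # recompute the detector's scale as documented
  f <- base$force
  n <- length(f)
  med5 <- stats::runmed(f, 5L, endrule = "median")
  idx <- seq.int(12L, n - 13L)
  s <- (med5[idx + 3L] - med5[idx - 2L]) -
    (5 / 19) * (med5[idx + 10L] - med5[idx - 9L])
  scale <- max(stats::mad(s),
               0.15 * stats::quantile(abs(diff(f)), 0.99, names = FALSE),
               1e-12)
  i <- 600L
  at <- base
  # the statistic sees 14/19 of a step; compensate, plus a 20% margin
  at$force[(i + 1):n] <- at$force[(i + 1):n] + (19 / 14) * 1.2 * 6 * scale
  expect_identical(qc_discontinuity(at), "rejected_discontinuity")
  below <- base
  below$force[(i + 1):n] <- below$force[(i + 1):n] + 0.25 * 6 * scale
  expect_identical(qc_discontinuity(below), "accepted")
})

test_that("force curves round-trip through CSV plus sidecar", {
  cv <- simulate_curve(5, z0 = 2, h = 12, noise_sd = 0.05, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_force_curve(cv, path)
  back <- read_force_curve(path)
  expect_equal(back$piezo_z, cv$piezo_z)
  expect_equal(back$force, cv$force)
  expect_equal(back$spring_constant, cv$spring_constant)
  expect_equal(back$sample_thickness, 12)
})
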
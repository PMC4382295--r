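test_that("default configuration encodes the study design", {
  cfg <- default_generator_config(seed = 1)
  expect_identical(cfg$rates$rate_label, c("2", "20", "100"))
  expect_identical(cfg$rates$grip_rate, c(2, 20, 100))
  expect_identical(cfg$n_replicates, 6L)
  expect_identical(cfg$samples_per_test, 200L)
  expect_equal(cfg$geometry$diameter_mm, 9)
  expect_equal(cfg$geometry$height_mm, 5)
  expect_equal(cfg$rates$mu_pa, unname(reference_ogden_moduli()))
  anchors <- reference_end_stress()
  expect_equal(cfg$rates$replicate_scale_sd, anchors$sd_pa / anchors$mean_pa,
               tolerance = 1e-12)
})

test_that("calibrated Ogden exponents reproduce the target end stresses", {
  cfg <- default_generator_config(seed = 1)
  anchors <- reference_end_stress()
  for (i in 1:3) {
    p <- ogden_params(cfg$rates$mu_pa[i], cfg$rates$alpha[i])
    expect_equal(uniaxial_stress(p, END_STRETCH), anchors$mean_pa[i],
                 tolerance = 1e-6)
  }
  # slow rate needs a softening exponent (neo-Hookean already overshoots),
  # fast rate a stiffening one
  expect_lt(cfg$rates$alpha[1], 0)
  expect_equal(cfg$rates$alpha[1], -1.6, tolerance = 0.05)
  expect_equal(cfg$rates$alpha[3], 5.6, tolerance = 0.05)
})

test_that("Ogden end stress is strictly increasing in alpha on the solved branch", {
  # the alpha -> S11 map is U-shaped; calibration works on the branch right
  # of the minimum, where the root is unique
  mu <- 560.9
  s_of <- function(a) uniaxial_stress(ogden_params(mu, a), END_STRETCH)
  a_min <- optimize(s_of, c(-20, 20))$minimum
  grid <- seq(a_min + 1e-3, 20, length.out = 200)
  expect_true(all(diff(vapply(grid, s_of, numeric(1))) > 0))
})

test_that("records are a pure function of seed, rate and replicate", {
  cfg <- default_generator_config(seed = 99)
  a <- generate_record(cfg, "20", 3)
  b <- generate_record(cfg, "20", 3)
  expect_identical(a, b)
  c <- generate_record(cfg, "20", 4)
  expect_false(identical(a$force_n, c$force_n))
  d <- generate_record(default_generator_config(seed = 100), "20", 3)
  expect_false(identical(a$force_n, d$force_n))
})

test_that("every record ramps to exactly 30% grip strain", {
  cfg <- default_generator_config(seed = 3)
  for (lab in cfg$rates$rate_label) {
    rec <- generate_record(cfg, lab, 1)
    expect_equal(max(rec$displacement_mm), 1.5) # 30% of H = 5 mm
    cv <- record_to_curve(rec)
    expect_equal(max(cv$stretch), END_STRETCH)
    expect_equal(max(rec$time_s), 0.3 / cfg$rates$grip_rate[
      match(lab, cfg$rates$rate_label)])
  }
})

test_that("a noise-free record inverts back to its ground-truth law", {
  cfg <- default_generator_config(seed = 1, additive_noise_sd_pa = 0)
  cfg$rates$replicate_scale_sd <- 0
  for (lab in c("2", "100")) {
    rec <- generate_record(cfg, lab, 1)
    cv <- record_to_curve(rec)
    truth <- ground_truth_curve(cfg, lab)
    expect_equal(cv$stretch, truth$stretch, tolerance = 1e-12)
    expect_equal(cv$stress_pa, truth$stress_pa, tolerance = 1e-9)
  }
})

test_that("the default dataset has 18 records and a faithful manifest", {
  cfg <- default_generator_config(seed = 12)
  ds <- generate_dataset(cfg)
  expect_length(ds$records, 18)
  expect_identical(
    vapply(ds$manifest$ground_truth, `[[`, numeric(1), "mu_pa"),
    unname(reference_ogden_moduli())
  )
  expect_identical(ds$manifest$seed, 12L)
  expect_true(all(vapply(ds$records, inherits, TRUE, "tensile_record")))
})

test_that("generator-to-fitter closure recovers the configured Ogden law", {
  cfg <- default_generator_config(seed = 1)
  for (lab in c("2", "100")) {
    idx <- match(lab, cfg$rates$rate_label)
    truth_curve <- ground_truth_curve(cfg, lab, n = 120)
    fit <- fit_model(truth_curve, "ogden")
    expect_equal(fit$params$mu, cfg$rates$mu_pa[idx], tolerance = 1e-3)
    expect_equal(fit$params$alpha, cfg$rates$alpha[idx], tolerance = 1e-3)
  }
})

test_that("replicate scatter stays inside realistic CoV bounds", {
  for (seed in c(4, 5, 6)) {
    by_rate <- dataset_curves_by_rate(default_generator_config(seed = seed))
    for (curves in by_rate) {
      cv <- coefficient_of_variation(curves)
      expect_gte(attr(cv, "cov_min"), 0.01)
      expect_lte(attr(cv, "cov_max"), 0.5)
    }
  }
})

test_that("configuration validation rejects impossible designs", {
  expect_error(default_generator_config(n_replicates = 1),
               class = "elastifit_config_error")
  expect_error(default_generator_config(samples_per_test = 5),
               class = "elastifit_config_error")
  cfg <- default_generator_config(seed = 1)
  expect_error(generate_record(cfg, "7", 1), class = "elastifit_config_error")
})
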
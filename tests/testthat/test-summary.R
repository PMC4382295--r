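linear_curve <- function(slope = 1000, n = 40, rate_label = "") {
  e <- seq(0, 0.3, length.out = n)
  stress_stretch_curve(slope * e, grip_strain = e, rate_label = rate_label)
}

test_that("end-stress statistics use the sample SD at exactly 30% strain", {
  base <- linear_curve()
  same <- end_stress_stats(list(base, base, base))
  expect_equal(same$sd_pa, 0)
  expect_equal(same$mean_pa, 300)

  two <- end_stress_stats(list(linear_curve(1000), linear_curve(5000 / 3)))
  expect_equal(two$mean_pa, 400)
  expect_equal(two$sd_pa, sd(c(300, 500))) # 141.42 with n-1 denominator
  expect_equal(two$sd_pa, 141.42, tolerance = 1e-4)

  short <- stress_stretch_curve(seq(0, 100, length.out = 20),
                                grip_strain = seq(0, 0.2, length.out = 20))
  expect_error(end_stress_stats(list(base, short)),
               class = "elastifit_incomplete_test")
})

test_that("end-stress mean/sd equivariance under affine stress changes", {
  set.seed(5)
  e <- seq(0, 0.3, length.out = 30)
  curves <- lapply(1:4, function(i) {
    stress_stretch_curve(1000 * e * runif(1, 0.8, 1.2), grip_strain = e)
  })
  base <- end_stress_stats(curves)
  scaled <- end_stress_stats(lapply(curves, function(cv) {
    stress_stretch_curve(2.5 * cv$stress_pa + 7, grip_strain = cv$grip_strain)
  }))
  expect_equal(scaled$mean_pa, 2.5 * base$mean_pa + 7)
  expect_equal(scaled$sd_pa, 2.5 * base$sd_pa)
})

test_that("coefficient of variation matches the per-strain sd/mean definition", {
  base <- linear_curve()
  same <- coefficient_of_variation(list(base, base, base))
  expect_equal(same$cov, rep(0, nrow(same)))

  fam <- lapply(c(0.8, 1.0, 1.2), function(f) {
    stress_stretch_curve(f * base$stress_pa, grip_strain = base$grip_strain)
  })
  cv <- coefficient_of_variation(fam)
  expect_equal(cv$cov, rep(sd(c(0.8, 1, 1.2)), nrow(cv)), tolerance = 1e-12)
  expect_equal(attr(cv, "cov_max"), attr(cv, "cov_min"), tolerance = 1e-12)

  # invariant under a common positive rescaling of all curves
  cv2 <- coefficient_of_variation(lapply(fam, function(c0) {
    stress_stretch_curve(42 * c0$stress_pa, grip_strain = c0$grip_strain)
  }))
  expect_equal(cv2$cov, cv$cov, tolerance = 1e-12)
})

test_that("grid points with non-positive mean stress are dropped with a warning", {
  e <- seq(0, 0.3, length.out = 40)
  up <- stress_stretch_curve(1000 * e, grip_strain = e)
  down <- stress_stretch_curve(-1000 * e, grip_strain = e)
  expect_warning(
    out <- coefficient_of_variation(list(up, down)),
    class = "elastifit_undefined_cov"
  )
  expect_identical(nrow(out), 0L)
})

test_that("secant moduli are chord slopes over the strain decades", {
  lin <- secant_moduli(linear_curve(1000))
  expect_equal(lin$modulus_pa, c(1000, 1000, 1000))

  e <- seq(0, 0.3, length.out = 301)
  quad <- stress_stretch_curve(10000 * e^2, grip_strain = e)
  expect_equal(secant_moduli(quad)$modulus_pa, c(1000, 3000, 5000))

  expect_error(secant_moduli(linear_curve(), ranges = list(c(0.2, 0.5))),
               class = "elastifit_range_error")
  expect_error(secant_moduli(linear_curve(), ranges = list(c(0.2, 0.1))),
               class = "elastifit_range_error")
})

test_that("secant moduli agree with a brute-force interpolation oracle", {
  set.seed(9)
  e <- sort(c(0, runif(60, 0, 0.3), 0.3))
  s <- 5000 * e^1.7 + 200 * e
  curve <- stress_stretch_curve(s, grip_strain = e)
  ranges <- list(c(0, 0.1), c(0.1, 0.2), c(0.2, 0.3), c(0.05, 0.25))
  got <- secant_moduli(curve, ranges = ranges)$modulus_pa
  oracle <- vapply(ranges, function(r) {
    ya <- approx(e, s, xout = r[1])$y
    yb <- approx(e, s, xout = r[2])$y
    (yb - ya) / (r[2] - r[1])
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("convex increasing curves have non-decreasing secant moduli", {
  e <- seq(0, 0.3, length.out = 100)
  for (pw in c(1.3, 2, 3)) {
    mods <- secant_moduli(stress_stretch_curve(4000 * e^pw, grip_strain = e))
    expect_true(all(diff(mods$modulus_pa) >= 0))
  }
})

test_that("pairwise Welch comparison flags separated groups and not identical ones", {
  same <- compare_rates(list(a = c(5, 5, 5), b = c(5, 5, 5)))
  expect_false(same$significant)
  expect_equal(same$p_value, 1)

  far <- compare_rates(list(lo = c(1, 2, 3), hi = c(101, 102, 103)))
  expect_lt(far$p_value, 0.001)
  expect_true(far$significant)
  # matches the closed-form Welch statistic 100 / sqrt(2/3)
  expect_equal(abs(far$statistic), 100 / sqrt(2 / 3), tolerance = 1e-10)

  expect_error(compare_rates(list(a = 1, b = c(1, 2))),
               class = "elastifit_domain_error")
})

test_that("rate comparison is symmetric in group order", {
  g <- list(`2` = c(300, 400, 450), `100` = c(2300, 2600, 2700))
  ab <- compare_rates(g)
  ba <- compare_rates(rev(g))
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(abs(ab$statistic), abs(ba$statistic))
})

test_that("rate summary assembles one row per rate with moduli statistics", {
  e <- seq(0, 0.3, length.out = 50)
  mk <- function(f) stress_stretch_curve(f * 10000 * e^2, grip_strain = e)
  by_rate <- list(`2` = list(mk(0.9), mk(1.0), mk(1.1)),
                  `100` = list(mk(4.5), mk(5.0), mk(5.5)))
  out <- rate_summary(by_rate)
  expect_identical(nrow(out), 2L)
  expect_identical(out$n_replicates, c(3L, 3L))
  # chord slopes of e^2 sampled on 50 points: small linear-interpolation error
  expect_equal(out$E1_mean_pa[1], 1000, tolerance = 1e-2)
  expect_equal(out$E3_mean_pa[1], 5000, tolerance = 1e-2)
  expect_equal(out$end_stress_mean_pa[2], 5 * 900, tolerance = 1e-9)
  expect_true(all(out$cov_max >= out$cov_min))
})
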
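test_that("strain energy and stress vanish in the reference state", {
  fams <- list(fung_params(500, 3), gent_params(800, 2), ogden_params(1000, 9),
               ogden_params(700, -3))
  for (p in fams) {
    expect_equal(strain_energy(p, 1), 0)
    expect_equal(uniaxial_stress(p, 1), 0)
  }
  # the exponential family keeps its (generally nonzero) value at lambda = 1
  expo <- exponential_params(7957.9, 0.33936, 462.0)
  expect_equal(uniaxial_stress(expo, 1), -7957.9 * exp(-1 / 0.33936) + 462.0)
})

test_that("closed forms match hand-derived values", {
  # Ogden energy: (2*1000/4) * (1.44 + 2/1.2 - 3)
  expect_equal(strain_energy(ogden_params(1000, 2), 1.2),
               500 * (1.44 + 2 / 1.2 - 3))
  # Gent at huge Jm collapses to the neo-Hookean energy (mu/2)(I1 - 3)
  expect_equal(strain_energy(gent_params(1000, 1e6), 1.2),
               500 * (1.44 + 2 / 1.2 - 3), tolerance = 1e-4)
  # Ogden stress with alpha = 2 is mu * (l - l^-2)
  expect_equal(uniaxial_stress(ogden_params(1000, 2), 1.2),
               1000 * (1.2 - 1.2^-2))
  # published 2 1/s exponential law at the end stretch
  expect_equal(
    uniaxial_stress(exponential_params(7957.9, 0.33936, 462.0), 1.4749),
    -7957.9 * exp(-1.4749 / 0.33936) + 462.0
  )
  expect_equal(
    uniaxial_stress(exponential_params(7957.9, 0.33936, 462.0), 1.4749),
    358.9, tolerance = 2e-4
  )
})

test_that("closed-form stress equals the numeric strain-energy derivative", {
  # fixed spot checks
  expect_equal(stress_from_energy(ogden_params(1000, 9), 1.3),
               uniaxial_stress(ogden_params(1000, 9), 1.3), tolerance = 1e-6)
  expect_equal(stress_from_energy(fung_params(500, 3), 1.2),
               uniaxial_stress(fung_params(500, 3), 1.2), tolerance = 1e-6)
  expect_lt(abs(stress_from_energy(ogden_params(1000, 4), 1 + 1e-9)), 1e-3)

  # property: randomized parameter draws across the three energy families
  set.seed(101)
  lams <- seq(1.05, 1.45, length.out = 7)
  for (i in 1:20) {
    mu <- 10^runif(1, 1.5, 3.5)
    draws <- list(
      fung_params(mu, runif(1, 0.1, 5)),
      gent_params(mu, runif(1, 1, 100)),
      ogden_params(mu, runif(1, -10, 10) + 0.5) # keeps alpha away from 0
    )
    for (p in draws) {
      expect_equal(stress_from_energy(p, lams), uniaxial_stress(p, lams),
                   tolerance = 1e-6)
    }
  }
})

test_that("finite-difference step validation", {
  expect_error(stress_from_energy(ogden_params(1000, 2), 1.2, step = 1.3),
               class = "elastifit_domain_error")
  expect_error(stress_from_energy(exponential_params(1, 1, 0), 1.2),
               class = "elastifit_unsupported")
})

test_that("small-strain modulus is 3*mu for every energy family", {
  expect_equal(small_strain_modulus(ogden_params(1000, 7)), 3000)
  expect_equal(small_strain_modulus(fung_params(493.0, 1)), 1479.0)
  expect_equal(small_strain_modulus(gent_params(396.6, 5)), 1189.8)
  expect_error(small_strain_modulus(exponential_params(1, 1, 0)),
               class = "elastifit_unsupported")
  # numeric slope of S11 at lambda = 1 converges to 3*mu
  h <- 1e-6
  for (p in list(fung_params(500, 3), gent_params(800, 2),
                 ogden_params(1000, 9), ogden_params(700, -3))) {
    slope <- (uniaxial_stress(p, 1 + h) - uniaxial_stress(p, 1 - h)) / (2 * h)
    expect_equal(slope, 3 * p$mu, tolerance = 1e-6)
  }
})

test_that("Ogden(alpha=2), Fung(b->0) and Gent(Jm->inf) reduce to neo-Hookean", {
  mu <- 850
  lams <- seq(1, END_STRETCH, length.out = 10)
  nh <- mu * (lams - lams^-2)
  expect_equal(uniaxial_stress(ogden_params(mu, 2), lams), nh, tolerance = 1e-12)
  expect_equal(uniaxial_stress(fung_params(mu, 1e-8), lams), nh, tolerance = 1e-4)
  expect_equal(uniaxial_stress(gent_params(mu, 1e8), lams), nh, tolerance = 1e-4)
})

test_that("the three published exponential laws are ordered by rate", {
  laws <- reference_exponential_laws()
  lams <- seq(1.0500001, END_STRETCH, length.out = 200)
  s2 <- uniaxial_stress(laws[["2"]], lams)
  s20 <- uniaxial_stress(laws[["20"]], lams)
  s100 <- uniaxial_stress(laws[["100"]], lams)
  expect_true(all(s2 < s20))
  expect_true(all(s20 < s100))
})

test_that("Gent locks at I1 - 3 approaching Jm", {
  p <- gent_params(1000, 0.4) # I1 - 3 = 0.4818 at stretch 1.45 exceeds 0.999*Jm
  expect_error(uniaxial_stress(p, 1.45), class = "elastifit_gent_locking")
  expect_error(strain_energy(p, 1.45), class = "elastifit_gent_locking")
  expect_error(strain_energy(exponential_params(1, 1, 0), 1.2),
               class = "elastifit_unsupported")
})

test_that("strain energy is non-negative and increasing on the loading range", {
  set.seed(77)
  lams <- seq(1 + 1e-6, END_STRETCH, length.out = 50)
  for (i in 1:10) {
    mu <- 10^runif(1, 2, 3.5)
    for (p in list(fung_params(mu, runif(1, 0.1, 5)),
                   gent_params(mu, runif(1, 1, 50)),
                   ogden_params(mu, runif(1, 0.5, 12)))) {
      w <- strain_energy(p, lams)
      expect_true(all(w >= 0))
      expect_true(all(diff(w) > 0))
    }
    # negative alpha: stress stays tensile for lambda > 1
    pneg <- ogden_params(mu, runif(1, -12, -0.5))
    expect_true(all(uniaxial_stress(pneg, lams) > 0))
  }
})

test_that("parameter objects validate and serialize to flat configs", {
  expect_error(fung_params(-1, 2), class = "elastifit_bad_params")
  expect_error(gent_params(100, 0), class = "elastifit_bad_params")
  expect_error(ogden_params(100, 0), class = "elastifit_bad_params")
  expect_error(exponential_params(-5, 1, 0), class = "elastifit_bad_params")
  for (p in list(fung_params(500, 3), gent_params(800, 2),
                 ogden_params(1000, -1.6),
                 exponential_params(7957.9, 0.33936, 462.0))) {
    back <- params_from_config(params_to_config(p))
    expect_equal(back, p)
  }
})
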
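#' Hyperelastic model parameters
#'
#' Constructors for the four constitutive families used to describe
#' incompressible soft tissue in uniaxial tension:
#'
#' * **Fung** — exponential strain-energy `W = mu/(2b) * (exp(b(I1-3)) - 1)`;
#'   parameters `mu` (infinitesimal shear modulus, Pa) and `b` (> 0).
#' * **Gent** — limiting-chain-extensibility model
#'   `W = -(mu/2) * Jm * log(1 - (I1-3)/Jm)`; parameters `mu` (Pa) and the
#'   locking parameter `Jm` (> 0).
#' * **Ogden** (one term) — `W = 2 mu / alpha^2 * (l1^a + l2^a + l3^a - 3)`;
#'   parameters `mu` (Pa) and `alpha` (any nonzero real).
#' * **Exponential** — a stress-level law with no strain-energy function,
#'   `S11 = -A * exp(-lambda/B) + C`; parameters `amp` (A, Pa, >= 0),
#'   `scale` (B, > 0) and `offset` (C, Pa). Its stress at `lambda = 1` is
#'   generally nonzero, which is retained as defined.
#'
#' For Fung, Gent and Ogden, `mu` is the infinitesimal shear modulus: the
#' small-strain uniaxial slope `dS11/dlambda` at `lambda = 1` equals `3 mu`
#' for all three (incompressible Young's modulus).
#'
#' @param mu Infinitesimal shear modulus in Pa, positive.
#' @param b Fung exponent, positive, dimensionless.
#' @param jm Gent locking parameter, positive, dimensionless.
#' @param alpha Ogden exponent, nonzero, dimensionless.
#' @param amp,scale,offset Exponential-law coefficients A (Pa), B
#'   (dimensionless) and C (Pa).
#'
#' @return An object of class `hyperelastic_params` (and a family-specific
#'   subclass) holding the family tag and parameters.
#' @name hyperelastic_params
#' @examples
#' ogden_params(mu = 1000, alpha = 2)
#' exponential_params(amp = 7957.9, scale = 0.33936, offset = 462.0)
NULL

new_hyperelastic_params <- function(family, values) {
  structure(c(list(family = family), values),
            class = c(paste0(family, "_params"), "hyperelastic_params"))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE, nonzero = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "elastifit_bad_params")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name), class = "elastifit_bad_params")
  }
  if (nonneg && x < 0) {
    abort(sprintf("`%s` must be non-negative.", name), class = "elastifit_bad_params")
  }
  if (nonzero && x == 0) {
    abort(sprintf("`%s` must be nonzero.", name), class = "elastifit_bad_params")
  }
  as.numeric(x)
}

#' @rdname hyperelastic_params
#' @export
fung_params <- function(mu, b) {
  new_hyperelastic_params("fung", list(
    mu = check_scalar(mu, "mu", positive = TRUE),
    b = check_scalar(b, "b", positive = TRUE)
  ))
}

#' @rdname hyperelastic_params
#' @export
gent_params <- function(mu, jm) {
  new_hyperelastic_params("gent", list(
    mu = check_scalar(mu, "mu", positive = TRUE),
    jm = check_scalar(jm, "jm", positive = TRUE)
  ))
}

#' @rdname hyperelastic_params
#' @export
ogden_params <- function(mu, alpha) {
  new_hyperelastic_params("ogden", list(
    mu = check_scalar(mu, "mu", positive = TRUE),
    alpha = check_scalar(alpha, "alpha", nonzero = TRUE)
  ))
}

#' @rdname hyperelastic_params
#' @export
exponential_params <- function(amp, scale, offset) {
  new_hyperelastic_params("exponential", list(
    amp = check_scalar(amp, "amp", nonneg = TRUE),
    scale = check_scalar(scale, "scale", positive = TRUE),
    offset = check_scalar(offset, "offset")
  ))
}

#' @export
print.hyperelastic_params <- function(x, ...) {
  vals <- x[setdiff(names(x), "family")]
  cat(sprintf("<hyperelastic_params> %s: %s\n", x$family,
              paste(sprintf("%s = %g", names(vals), unlist(vals)), collapse = ", ")))
  invisible(x)
}

is_hyperelastic_params <- function(x) inherits(x, "hyperelastic_params")

check_stretch_positive <- function(stretch) {
  if (!is.numeric(stretch) || any(!is.finite(stretch)) || any(stretch <= 0)) {
    abort("`stretch` must be strictly positive.", class = "elastifit_domain_error")
  }
  as.numeric(stretch)
}

# Gent domain guard: the log argument must stay clearly away from the
# locking singularity I1 - 3 = Jm; overflow starts well before the pole.
check_gent_domain <- function(params, stretch) {
  i1m3 <- stretch^2 + 2 / stretch - 3
  if (any(i1m3 >= 0.999 * params$jm)) {
    abort(
      sprintf("Gent locking: I1 - 3 reaches %.4g, at or beyond 0.999 * Jm = %.4g.",
              max(i1m3), 0.999 * params$jm),
      class = "elastifit_gent_locking"
    )
  }
  i1m3
}

#' Strain-energy density
#'
#' Evaluates the strain-energy function `W(lambda)` of a Fung, Gent or
#' Ogden model at the given uniaxial stretch (incompressible kinematics,
#' `I1 = lambda^2 + 2/lambda`). `W(1) = 0` for every family. The
#' exponential family is a stress-level law without a strain-energy
#' function and is rejected.
#'
#' @param params A [hyperelastic_params] object (Fung, Gent or Ogden).
#' @param stretch Axial stretch(es), strictly positive.
#' @return Energy density in Pa (J/m^3), same length as `stretch`.
#' @export
strain_energy <- function(params, stretch) {
  UseMethod("strain_energy")
}

#' @export
strain_energy.default <- function(params, stretch) {
  abort("`params` must be a `hyperelastic_params` object.",
        class = "elastifit_bad_params")
}

#' @export
strain_energy.fung_params <- function(params, stretch) {
  stretch <- check_stretch_positive(stretch)
  i1m3 <- stretch^2 + 2 / stretch - 3
  params$mu / (2 * params$b) * (exp(params$b * i1m3) - 1)
}

#' @export
strain_energy.gent_params <- function(params, stretch) {
  stretch <- check_stretch_positive(stretch)
  i1m3 <- check_gent_domain(params, stretch)
  -(params$mu / 2) * params$jm * log(1 - i1m3 / params$jm)
}

#' @export
strain_energy.ogden_params <- function(params, stretch) {
  stretch <- check_stretch_positive(stretch)
  a <- params$alpha
  2 * params$mu / a^2 * (stretch^a + 2 * stretch^(-a / 2) - 3)
}

#' @export
strain_energy.exponential_params <- function(params, stretch) {
  abort("The exponential family is defined at stress level only; it has no strain-energy function.",
        class = "elastifit_unsupported")
}

#' Uniaxial nominal stress predicted by a model
#'
#' Closed-form Lagrange stress `S11(lambda) = dW/dlambda` for Fung, Gent
#' and Ogden (zero at `lambda = 1`), and the direct stress law
#' `S11 = -A exp(-lambda/B) + C` for the exponential family.
#'
#' @inheritParams strain_energy
#' @return Stress in Pa, same length as `stretch`.
#' @examples
#' uniaxial_stress(ogden_params(1000, 2), 1.2) # mu * (l - l^-2) = 505.56
#' @export
uniaxial_stress <- function(params, stretch) {
  UseMethod("uniaxial_stress")
}

#' @export
uniaxial_stress.default <- function(params, stretch) {
  abort("`params` must be a `hyperelastic_params` object.",
        class = "elastifit_bad_params")
}

#' @export
uniaxial_stress.fung_params <- function(params, stretch) {
  stretch <- check_stretch_positive(stretch)
  i1m3 <- stretch^2 + 2 / stretch - 3
  params$mu * exp(params$b * i1m3) * (stretch - stretch^-2)
}

#' @export
uniaxial_stress.gent_params <- function(params, stretch) {
  stretch <- check_stretch_positive(stretch)
  i1m3 <- check_gent_domain(params, stretch)
  params$mu * params$jm / (params$jm - i1m3) * (stretch - stretch^-2)
}

#' @export
uniaxial_stress.ogden_params <- function(params, stretch) {
  stretch <- check_stretch_positive(stretch)
  a <- params$alpha
  2 * params$mu / a * (stretch^(a - 1) - stretch^(-a / 2 - 1))
}

#' @export
uniaxial_stress.exponential_params <- function(params, stretch) {
  stretch <- check_stretch_positive(stretch)
  -params$amp * exp(-stretch / params$scale) + params$offset
}

#' Stress by numerical differentiation of the strain energy
#'
#' Central finite difference of [strain_energy()] with respect to stretch.
#' Serves as the internal correctness oracle for the closed-form
#' [uniaxial_stress()] expressions: away from `lambda = 1` the two agree
#' to better than 1e-6 relative for well-scaled parameters.
#'
#' @inheritParams strain_energy
#' @param step Finite-difference half-step (default 1e-6).
#' @return Stress in Pa.
#' @export
stress_from_energy <- function(params, stretch, step = 1e-6) {
  if (!is_hyperelastic_params(params)) {
    abort("`params` must be a `hyperelastic_params` object.",
          class = "elastifit_bad_params")
  }
  if (inherits(params, "exponential_params")) {
    abort("The exponential family has no strain-energy function.",
          class = "elastifit_unsupported")
  }
  stretch <- check_stretch_positive(stretch)
  if (!is.numeric(step) || length(step) != 1 || step <= 0) {
    abort("`step` must be a single positive number.", class = "elastifit_domain_error")
  }
  if (any(stretch - step <= 0)) {
    abort("`step` too large: stretch - step must stay positive.",
          class = "elastifit_domain_error")
  }
  (strain_energy(params, stretch + step) -
     strain_energy(params, stretch - step)) / (2 * step)
}

#' Small-strain uniaxial modulus
#'
#' The analytic slope `dS11/dlambda` at `lambda = 1` equals `3 mu` for
#' Fung, Gent and Ogden alike — the uniaxial Young's modulus of an
#' incompressible solid. The exponential family has no well-defined
#' small-strain modulus (its stress at `lambda = 1` is generally nonzero)
#' and is rejected.
#'
#' @param params A [hyperelastic_params] object (Fung, Gent or Ogden).
#' @return Modulus in Pa.
#' @examples
#' small_strain_modulus(ogden_params(1000, 7)) # 3000
#' @export
small_strain_modulus <- function(params) {
  if (!is_hyperelastic_params(params)) {
    abort("`params` must be a `hyperelastic_params` object.",
          class = "elastifit_bad_params")
  }
  if (inherits(params, "exponential_params")) {
    abort("The exponential family has no small-strain modulus.",
          class = "elastifit_unsupported")
  }
  3 * params$mu
}

#' Flat key-value serialization of model parameters
#'
#' `params_to_config()` flattens a parameter object to a named list with
#' keys `family`, `mu_pa`, `b`, `jm`, `alpha`, `amp_pa`, `scale`,
#' `offset_pa` (only the keys the family uses); `params_from_config()`
#' rebuilds the object.
#'
#' @param params A [hyperelastic_params] object.
#' @param config A named list as produced by `params_to_config()`.
#' @return A named list, or a `hyperelastic_params` object.
#' @export
params_to_config <- function(params) {
  if (!is_hyperelastic_params(params)) {
    abort("`params` must be a `hyperelastic_params` object.",
          class = "elastifit_bad_params")
  }
  switch(params$family,
    fung = list(family = "fung", mu_pa = params$mu, b = params$b),
    gent = list(family = "gent", mu_pa = params$mu, jm = params$jm),
    ogden = list(family = "ogden", mu_pa = params$mu, alpha = params$alpha),
    exponential = list(family = "exponential", amp_pa = params$amp,
                       scale = params$scale, offset_pa = params$offset)
  )
}

#' @rdname params_to_config
#' @export
params_from_config <- function(config) {
  family <- config$family %||% abort("`config` must contain `family`.",
                                     class = "elastifit_bad_params")
  switch(family,
    fung = fung_params(config$mu_pa, config$b),
    gent = gent_params(config$mu_pa, config$jm),
    ogden = ogden_params(config$mu_pa, config$alpha),
    exponential = exponential_params(config$amp_pa, config$scale, config$offset_pa),
    abort(sprintf("Unknown family '%s'.", family), class = "elastifit_bad_params")
  )
}

#' The three rate-specific exponential stress laws
#'
#' Returns the published exponential-law coefficients for the three
#' nominal strain rates (2, 20 and 100 1/s), as `exponential_params`
#' objects keyed by rate label. These describe infant cerebellum tissue in
#' tension up to 30% grip strain.
#'
#' @return A named list of three `exponential_params` objects
#'   (`"2"`, `"20"`, `"100"`).
#' @export
reference_exponential_laws <- function() {
  list(
    "2" = exponential_params(amp = 7957.9, scale = 0.33936, offset = 462.0),
    "20" = exponential_params(amp = 9882.8, scale = 0.44266, offset = 1169.6),
    "100" = exponential_params(amp = 51953.6, scale = 0.33834, offset = 3003.2)
  )
}

#' Reference Ogden shear moduli by strain rate
#'
#' Mean fitted infinitesimal shear moduli (Pa) of the one-term Ogden model
#' at the three nominal strain rates, used as the generator's calibration
#' anchors.
#'
#' @return A named numeric vector (`"2"`, `"20"`, `"100"`), in Pa.
#' @export
reference_ogden_moduli <- function() {
  c("2" = 560.9, "20" = 1110.8, "100" = 1239.6)
}

#' Reference end-stress summary by strain rate
#'
#' Mean and standard deviation of the Lagrange stress at 30% grip strain
#' across replicate specimens, per nominal strain rate (Pa).
#'
#' @return A tibble with columns `rate_label`, `mean_pa`, `sd_pa`.
#' @export
reference_end_stress <- function() {
  tibble(
    rate_label = c("2", "20", "100"),
    mean_pa = c(393.7, 928.3, 2582.4),
    sd_pa = c(84.4, 56.3, 282.2)
  )
}
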
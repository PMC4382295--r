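# Solve the one-term Ogden exponent so the model's end stress hits a
# target. At fixed mu and stretch, S11(alpha) is U-shaped in alpha (its
# minimum sits near alpha = -4 for end stretch 1.4749); the calibration
# uses the increasing branch to the right of the minimum, where the root
# is unique and matches the physically sensible small-|alpha| solution.
solve_ogden_alpha <- function(mu, target_stress_pa, stretch,
                              interval = c(-20, 20)) {
  f <- function(a) ogden_stress_num(mu, a, stretch) - target_stress_pa
  a_min <- optimize(function(a) ogden_stress_num(mu, a, stretch),
                    interval = interval)$minimum
  if (f(a_min) > 0) {
    abort(sprintf("No Ogden exponent in [%g, %g] reaches %.4g Pa at stretch %.4f.",
                  a_min, interval[2], target_stress_pa, stretch),
          class = "elastifit_config_error")
  }
  uniroot(f, lower = a_min, upper = interval[2], tol = 1e-12)$root
}

#' Default calibrated generator configuration
#'
#' Builds the generator configuration that emulates the study design:
#' three nominal strain rates (2, 20, 100 1/s — grip velocities 10, 100,
#' 500 mm/s on a 5 mm specimen), six replicates each, loaded to 30% grip
#' strain. Per rate, the ground truth is a one-term Ogden law whose shear
#' modulus is the corresponding published Ogden-column value and whose
#' exponent is solved so the end stress at stretch 1.4749 equals the
#' published mean end stress. Replicate scatter is one multiplicative
#' factor per specimen with SD equal to the published end-stress SD over
#' mean, plus small additive measurement jitter.
#'
#' @param seed Master seed (integer); every record is a pure function of
#'   it.
#' @param n_replicates Replicates per rate (default 6).
#' @param samples_per_test Samples along each ramp (default 200).
#' @param additive_noise_sd_pa Additive jitter SD in Pa (default 5).
#' @param geometry A [specimen_geometry()].
#'
#' @return An object of class `generator_config`: a list with elements
#'   `rates` (tibble: `rate_label`, `grip_rate`, `mu_pa`, `alpha`,
#'   `replicate_scale_sd`, `additive_noise_sd_pa`), `n_replicates`,
#'   `samples_per_test`, `geometry`, `seed`.
#' @examples
#' cfg <- default_generator_config(seed = 1)
#' cfg$rates
#' @export
default_generator_config <- function(seed = 1L, n_replicates = 6L,
                                     samples_per_test = 200L,
                                     additive_noise_sd_pa = 5,
                                     geometry = specimen_geometry()) {
  assert_geometry(geometry)
  if (n_replicates < 2) {
    abort("`n_replicates` must be at least 2.", class = "elastifit_config_error")
  }
  if (samples_per_test < 10) {
    abort("`samples_per_test` must be at least 10.", class = "elastifit_config_error")
  }
  end_stretch <- stretch_from_height_ratio(1 + MAX_GRIP_STRAIN)
  anchors <- reference_end_stress()
  mu <- reference_ogden_moduli()
  rates <- tibble(
    rate_label = anchors$rate_label,
    grip_rate = c(2, 20, 100),
    mu_pa = unname(mu[anchors$rate_label]),
    alpha = purrr::map2_dbl(unname(mu[anchors$rate_label]), anchors$mean_pa,
                            solve_ogden_alpha, stretch = end_stretch),
    replicate_scale_sd = anchors$sd_pa / anchors$mean_pa,
    additive_noise_sd_pa = additive_noise_sd_pa
  )
  structure(
    list(rates = rates,
         n_replicates = as.integer(n_replicates),
         samples_per_test = as.integer(samples_per_test),
         geometry = geometry,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> seed %d, %d replicates x %d rates, %d samples/test\n",
              x$seed, x$n_replicates, nrow(x$rates), x$samples_per_test))
  print(x$rates)
  invisible(x)
}

is_generator_config <- function(x) inherits(x, "generator_config")

# Deterministic per-record seed: master seed plus rate index x 1000 plus
# replicate index, kept inside 32-bit integer range.
record_seed <- function(config, rate_idx, replicate_index) {
  as.integer((as.double(config$seed) + rate_idx * 1000 + replicate_index) %%
               2147483647)
}

# One truncated-normal draw via inverse-CDF so a single uniform is
# consumed regardless of the truncation bounds (keeps streams aligned).
rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd == 0) return(mean)
  u <- stats::runif(1, stats::pnorm(lower, mean, sd), stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate one synthetic tensile record
#'
#' Simulates a constant-velocity ramp to 30% grip strain: grip strain
#' `e(t) = rate * t` on a uniform time grid, stretch through the
#' correction factor, true stress from the rate's ground-truth Ogden law,
#' and observed stress `c_i * S_true + eps(t)` with one replicate factor
#' `c_i ~ N(1, scale_sd)` truncated to (0.2, 1.8) and i.i.d. additive
#' jitter. Force and displacement are then the machine-side quantities
#' (stress times area; strain times height). Fully deterministic given
#' `(config$seed, rate_label, replicate_index)`.
#'
#' @param config A [default_generator_config()] (or compatible) object.
#' @param rate_label Which rate entry to use (e.g. `"100"`).
#' @param replicate_index Replicate number (1-based).
#' @return A [tensile_record()].
#' @export
generate_record <- function(config, rate_label, replicate_index) {
  if (!is_generator_config(config)) {
    abort("`config` must be a `generator_config`.", class = "elastifit_config_error")
  }
  rate_idx <- match(as.character(rate_label), config$rates$rate_label)
  if (is.na(rate_idx)) {
    abort(sprintf("Rate label '%s' not present in the configuration.", rate_label),
          class = "elastifit_config_error")
  }
  entry <- config$rates[rate_idx, ]
  n <- config$samples_per_test
  time_s <- seq(0, MAX_GRIP_STRAIN / entry$grip_rate, length.out = n)
  e <- entry$grip_rate * time_s
  e[1] <- 0
  lambda <- stretch_from_height_ratio(1 + e)
  s_true <- ogden_stress_num(entry$mu_pa, entry$alpha, lambda)

  seed_i <- record_seed(config, rate_idx, replicate_index)
  noise <- withr::with_seed(seed_i, {
    ci <- rtruncnorm1(1, entry$replicate_scale_sd, 0.2, 1.8)
    eps <- rnorm(n, 0, entry$additive_noise_sd_pa)
    list(ci = ci, eps = eps)
  })
  s_obs <- noise$ci * s_true + noise$eps

  tensile_record(
    time_s = time_s,
    displacement_mm = e * config$geometry$height_mm,
    force_n = s_obs * config$geometry$area_m2,
    geometry = config$geometry,
    nominal_rate = entry$grip_rate,
    specimen_id = sprintf("r%s_rep%02d", entry$rate_label, replicate_index)
  )
}

#' Generate the full synthetic dataset
#'
#' Produces `n_replicates` records for every rate in the configuration,
#' together with a manifest recording the seed, per-record seeds and the
#' ground-truth parameters. If `out_dir` is given, each record is written
#' as a record CSV and the manifest as `manifest.json`.
#'
#' @param config A generator configuration.
#' @param out_dir Optional output directory (created if missing).
#' @return A list with elements `records` (named list of
#'   [tensile_record()] objects), `manifest` (list), and `files`
#'   (character, empty when nothing was written).
#' @examples
#' ds <- generate_dataset(default_generator_config(seed = 7))
#' length(ds$records) # 18
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  if (!is_generator_config(config)) {
    abort("`config` must be a `generator_config`.", class = "elastifit_config_error")
  }
  grid <- tidyr::expand_grid(
    rate_label = config$rates$rate_label,
    replicate = seq_len(config$n_replicates)
  )
  records <- purrr::pmap(grid, function(rate_label, replicate) {
    generate_record(config, rate_label, replicate)
  })
  names(records) <- purrr::map_chr(records, attr, "specimen_id")

  manifest <- list(
    seed = config$seed,
    n_replicates = config$n_replicates,
    samples_per_test = config$samples_per_test,
    geometry = list(diameter_mm = config$geometry$diameter_mm,
                    height_mm = config$geometry$height_mm),
    ground_truth = purrr::pmap(config$rates, function(rate_label, grip_rate,
                                                      mu_pa, alpha,
                                                      replicate_scale_sd,
                                                      additive_noise_sd_pa) {
      list(rate_label = rate_label, grip_rate = grip_rate,
           family = "ogden", mu_pa = mu_pa, alpha = alpha,
           replicate_scale_sd = replicate_scale_sd,
           additive_noise_sd_pa = additive_noise_sd_pa)
    }),
    files = character(0)
  )

  files <- character(0)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    files <- purrr::imap_chr(records, function(rec, id) {
      path <- file.path(out_dir, paste0(id, ".csv"))
      write_record_csv(rec, path)
      path
    })
    manifest$files <- basename(unname(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(records = records, manifest = manifest, files = unname(files))
}

#' Noise-free ground-truth curve for a configured rate
#'
#' Evaluates the configuration's ground-truth Ogden law on the loading
#' ramp without any noise — the reference the generated records scatter
#' around.
#'
#' @param config A generator configuration.
#' @param rate_label Rate entry to evaluate.
#' @param n Number of points (default the config's samples per test).
#' @return A `stress_stretch_curve`.
#' @export
ground_truth_curve <- function(config, rate_label, n = NULL) {
  if (!is_generator_config(config)) {
    abort("`config` must be a `generator_config`.", class = "elastifit_config_error")
  }
  rate_idx <- match(as.character(rate_label), config$rates$rate_label)
  if (is.na(rate_idx)) {
    abort(sprintf("Rate label '%s' not present in the configuration.", rate_label),
          class = "elastifit_config_error")
  }
  entry <- config$rates[rate_idx, ]
  n <- n %||% config$samples_per_test
  e <- seq(0, MAX_GRIP_STRAIN, length.out = n)
  lambda <- stretch_from_height_ratio(1 + e)
  stress_stretch_curve(
    stress_pa = ogden_stress_num(entry$mu_pa, entry$alpha, lambda),
    grip_strain = e,
    rate_label = entry$rate_label
  )
}
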
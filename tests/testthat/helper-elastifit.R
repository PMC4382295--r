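# Shared fixture builders (all fixtures are generated in code).

END_STRETCH <- 1 + 1.583 * 0.3 # 1.4749

# Sample a constitutive law on a uniform stretch grid as a curve object.
sample_law_curve <- function(params, n = 100, lambda_max = END_STRETCH,
                             rate_label = "") {
  lambda <- seq(1, lambda_max, length.out = n)
  stress_stretch_curve(
    stress_pa = uniaxial_stress(params, lambda),
    stretch = lambda,
    rate_label = rate_label
  )
}

# A linear-ramp tensile record with prescribed force history.
ramp_record <- function(force_n, final_displacement_mm = 1.5,
                        duration_s = 0.15, nominal_rate = 2,
                        geometry = specimen_geometry()) {
  n <- length(force_n)
  tensile_record(
    time_s = seq(0, duration_s, length.out = n),
    displacement_mm = seq(0, final_displacement_mm, length.out = n),
    force_n = force_n,
    geometry = geometry,
    nominal_rate = nominal_rate
  )
}

# Flat list of curves from a generated dataset, split by rate label.
dataset_curves_by_rate <- function(config) {
  ds <- generate_dataset(config)
  curves <- lapply(ds$records, record_to_curve)
  split(curves, vapply(curves, attr, "", "rate_label"))
}
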
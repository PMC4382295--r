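#' Corrected stretch from the grip elongation ratio
#'
#' For a squat cylinder glued between platens the deformation is not
#' homogeneous: the mid-plane stretches more than the grip separation
#' suggests. The effective axial stretch is the linear correction
#' `lambda = 1 + K * (h/H - 1)` with `K = 1.583`, valid for grip
#' elongation ratios `h/H` between 1.0 and 1.3. Ratios above 1.3 are
#' still converted but flagged with a warning because the correction was
#' established only inside that window.
#'
#' @param h_over_H Grip elongation ratio(s) `h/H` (deformed over initial
#'   grip separation), dimensionless, each `>= 1` (tension only).
#'
#' @return Numeric vector of corrected stretches `lambda`.
#' @seealso [height_ratio_from_stretch()] for the inverse map.
#' @examples
#' stretch_from_height_ratio(1.3) # 1.4749
#' @export
stretch_from_height_ratio <- function(h_over_H) {
  if (!is.numeric(h_over_H) || any(!is.finite(h_over_H))) {
    abort("`h_over_H` must be finite numeric.", class = "elastifit_domain_error")
  }
  if (any(h_over_H < 1)) {
    abort("Grip elongation ratio below 1: compression is not supported.",
          class = "elastifit_domain_error")
  }
  if (any(h_over_H > 1.3 + 1e-12)) {
    warn(
      "Grip elongation ratio above 1.3: outside the validity window of the stretch correction.",
      class = "elastifit_outside_validity"
    )
  }
  1 + K_STRETCH_CORRECTION * (h_over_H - 1)
}

#' Grip elongation ratio from corrected stretch
#'
#' Exact inverse of [stretch_from_height_ratio()]; used by the synthetic
#' generator to construct displacement histories from a target stretch.
#'
#' @param stretch Corrected stretch(es) `lambda >= 1`.
#' @return Numeric vector of grip elongation ratios `h/H`.
#' @export
height_ratio_from_stretch <- function(stretch) {
  if (!is.numeric(stretch) || any(!is.finite(stretch))) {
    abort("`stretch` must be finite numeric.", class = "elastifit_domain_error")
  }
  if (any(stretch < 1)) {
    abort("Stretch below 1: compression is not supported.",
          class = "elastifit_domain_error")
  }
  1 + (stretch - 1) / K_STRETCH_CORRECTION
}

#' Strain invariants of incompressible uniaxial extension
#'
#' Under incompressibility and transverse symmetry the principal stretches
#' are `(lambda, lambda^-1/2, lambda^-1/2)`, so the first two invariants of
#' the left Cauchy-Green tensor reduce to functions of the axial stretch
#' alone: `I1 = lambda^2 + 2/lambda`, `I2 = lambda^-2 + 2*lambda`. The
#' third invariant is identically 1.
#'
#' @param stretch Axial stretch(es), strictly positive.
#' @return A tibble with columns `stretch`, `I1`, `I2`.
#' @examples
#' strain_invariants(1)   # both invariants equal 3
#' @export
strain_invariants <- function(stretch) {
  if (!is.numeric(stretch) || any(!is.finite(stretch)) || any(stretch <= 0)) {
    abort("`stretch` must be strictly positive.", class = "elastifit_domain_error")
  }
  tibble(
    stretch = as.numeric(stretch),
    I1 = stretch^2 + 2 / stretch,
    I2 = stretch^-2 + 2 * stretch
  )
}

#' Lagrange (nominal) stress from force
#'
#' Nominal-stress convention: the measured tensile force divided by the
#' *undeformed* cross-sectional area. Equals the axial first
#' Piola-Kirchhoff stress in uniaxial tension.
#'
#' @param force_n Measured force(s) in newtons.
#' @param geometry A [specimen_geometry()].
#' @return Stress in pascals, same length as `force_n`.
#' @examples
#' lagrange_stress(0.1, specimen_geometry()) # ~1572 Pa
#' @export
lagrange_stress <- function(force_n, geometry = specimen_geometry()) {
  assert_geometry(geometry)
  if (!is.numeric(force_n)) {
    abort("`force_n` must be numeric.", class = "elastifit_domain_error")
  }
  as.numeric(force_n) / geometry$area_m2
}

#' Raw tensile record
#'
#' Bundles the machine output for one specimen — time, grip displacement
#' and force — with its geometry and nominal strain rate. Displacement is
#' kept in millimetres as recorded; conversion to SI happens once, inside
#' [record_to_curve()].
#'
#' @param time_s Time in seconds; strictly increasing, starting at 0.
#' @param displacement_mm Grip elongation in mm; non-negative, starts at 0.
#' @param force_n Force in newtons, same length.
#' @param geometry A [specimen_geometry()].
#' @param nominal_rate Nominal grip strain rate in 1/s (grip velocity over
#'   initial height), positive.
#' @param specimen_id Label for the specimen.
#'
#' @return A tibble of class `tensile_record` with columns `time_s`,
#'   `displacement_mm`, `force_n`, and attributes `geometry`,
#'   `nominal_rate`, `specimen_id`.
#' @export
tensile_record <- function(time_s, displacement_mm, force_n,
                           geometry = specimen_geometry(),
                           nominal_rate, specimen_id = "specimen") {
  assert_geometry(geometry)
  n <- length(time_s)
  if (n < 2 || length(displacement_mm) != n || length(force_n) != n) {
    abort("time, displacement and force must have equal length >= 2.",
          class = "elastifit_bad_record")
  }
  if (any(!is.finite(time_s)) || time_s[1] != 0 || any(diff(time_s) <= 0)) {
    abort("`time_s` must start at 0 and be strictly increasing.",
          class = "elastifit_bad_record")
  }
  if (any(!is.finite(displacement_mm)) || displacement_mm[1] != 0 ||
      any(displacement_mm < 0)) {
    abort("`displacement_mm` must be non-negative and start at 0.",
          class = "elastifit_bad_record")
  }
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1 || nominal_rate <= 0) {
    abort("`nominal_rate` must be a single positive number.",
          class = "elastifit_bad_record")
  }
  out <- tibble(
    time_s = as.numeric(time_s),
    displacement_mm = as.numeric(displacement_mm),
    force_n = as.numeric(force_n)
  )
  structure(out,
            geometry = geometry,
            nominal_rate = as.numeric(nominal_rate),
            specimen_id = as.character(specimen_id),
            class = c("tensile_record", class(out)))
}

is_tensile_record <- function(x) inherits(x, "tensile_record")

#' Convert a raw record into a stress-stretch curve
#'
#' Applies the full kinematic pipeline: grip strain `e = displacement/H`,
#' corrected stretch `lambda = 1 + K*e`, and nominal stress `S11 = F/A`.
#' Points beyond the prescribed loading endpoint (grip strain 0.3) are
#' truncated. Records showing sustained negative stress — a run of at
#' least `negative_run` consecutive points below `-negative_stress_tol_pa`
#' — are rejected as adhesion failures (the glue bond between specimen and
#' platen let go, so the record does not measure tissue response).
#'
#' @param record A [tensile_record()].
#' @param max_grip_strain Truncation point in grip strain (default 0.3).
#' @param negative_stress_tol_pa Negative-stress tolerance in Pa
#'   (default 10).
#' @param negative_run Number of consecutive sub-tolerance points that
#'   counts as "sustained" (default 5).
#' @param rate_label Optional label for the curve; defaults to the
#'   record's nominal rate.
#'
#' @return A tibble of class `stress_stretch_curve` with columns
#'   `stretch`, `grip_strain`, `stress_pa` and attribute `rate_label`.
#' @examples
#' rec <- tensile_record(
#'   time_s = seq(0, 0.15, length.out = 16),
#'   displacement_mm = seq(0, 1.5, length.out = 16),
#'   force_n = seq(0, 0.1, length.out = 16),
#'   nominal_rate = 2
#' )
#' curve <- record_to_curve(rec)
#' tail(curve, 1) # final stretch 1.4749
#' @export
record_to_curve <- function(record,
                            max_grip_strain = MAX_GRIP_STRAIN,
                            negative_stress_tol_pa = 10,
                            negative_run = 5,
                            rate_label = NULL) {
  if (!is_tensile_record(record)) {
    abort("`record` must be a `tensile_record`.", class = "elastifit_bad_record")
  }
  geometry <- attr(record, "geometry")
  grip_strain <- record$displacement_mm / geometry$height_mm
  stress <- lagrange_stress(record$force_n, geometry)

  below <- stress < -abs(negative_stress_tol_pa)
  if (any(below)) {
    runs <- rle(below)
    if (any(runs$lengths[runs$values] >= negative_run)) {
      abort(
        paste0(
          "Sustained negative stress in record '", attr(record, "specimen_id"),
          "': likely adhesion failure at the glued platens; curve rejected."
        ),
        class = "elastifit_adhesion_failure"
      )
    }
  }

  keep <- grip_strain <= max_grip_strain + 1e-12
  grip_strain <- grip_strain[keep]
  stress <- stress[keep]
  stretch <- stretch_from_height_ratio(1 + grip_strain)

  out <- tibble(
    stretch = stretch,
    grip_strain = grip_strain,
    stress_pa = stress
  )
  new_stress_stretch_curve(
    out,
    rate_label = rate_label %||% format(attr(record, "nominal_rate"))
  )
}

new_stress_stretch_curve <- function(data, rate_label = "") {
  if (nrow(data) < 2 || data$stretch[1] != 1 || any(diff(data$stretch) <= 0)) {
    abort("A stress-stretch curve must start at stretch 1 and be strictly increasing.",
          class = "elastifit_bad_curve")
  }
  structure(data,
            rate_label = as.character(rate_label),
            class = c("stress_stretch_curve", class(tibble())))
}

#' Construct a stress-stretch curve directly
#'
#' Builds a `stress_stretch_curve` from already-processed values, e.g. to
#' sample a constitutive law. Exactly one of `stretch` or `grip_strain`
#' may be given; the other is filled in through the stretch correction.
#'
#' @param stress_pa Nominal stress in Pa.
#' @param stretch Corrected stretch, starting at 1, strictly increasing.
#' @param grip_strain Grip strain, starting at 0, strictly increasing.
#' @param rate_label Label carried through summaries.
#' @return A `stress_stretch_curve` tibble.
#' @export
stress_stretch_curve <- function(stress_pa, stretch = NULL, grip_strain = NULL,
                                 rate_label = "") {
  if (is.null(stretch) && is.null(grip_strain)) {
    abort("Provide `stretch` or `grip_strain`.", class = "elastifit_bad_curve")
  }
  if (is.null(grip_strain)) {
    grip_strain <- height_ratio_from_stretch(stretch) - 1
  }
  if (is.null(stretch)) {
    stretch <- stretch_from_height_ratio(1 + grip_strain)
  }
  n <- length(stress_pa)
  if (length(stretch) != n || length(grip_strain) != n) {
    abort("Curve columns must have equal length.", class = "elastifit_bad_curve")
  }
  new_stress_stretch_curve(
    tibble(stretch = as.numeric(stretch),
           grip_strain = as.numeric(grip_strain),
           stress_pa = as.numeric(stress_pa)),
    rate_label = rate_label
  )
}

is_stress_stretch_curve <- function(x) inherits(x, "stress_stretch_curve")

#' @export
print.tensile_record <- function(x, ...) {
  cat(sprintf("<tensile_record> '%s', %d samples, nominal rate %g 1/s\n",
              attr(x, "specimen_id"), nrow(x), attr(x, "nominal_rate")))
  NextMethod()
}

#' @export
print.stress_stretch_curve <- function(x, ...) {
  cat(sprintf("<stress_stretch_curve> rate '%s', %d points, final stretch %.4f\n",
              attr(x, "rate_label"), nrow(x), max(x$stretch)))
  NextMethod()
}
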
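#' Cylindrical specimen geometry
#'
#' Describes the undeformed test cylinder. The cross-sectional area is
#' derived from the diameter and stored in SI units (m^2); it is the `A`
#' in the nominal-stress definition `S11 = F / A`.
#'
#' @param diameter_mm Cylinder diameter in millimetres (default 9, the
#'   trephine bore used for cerebellum cores).
#' @param height_mm Cylinder height `H` in millimetres (default 5).
#'
#' @return An object of class `specimen_geometry`: a list with elements
#'   `diameter_mm`, `height_mm` and `area_m2`.
#'
#' @examples
#' geom <- specimen_geometry()
#' geom$area_m2 # pi * (0.0045)^2
#' @export
specimen_geometry <- function(diameter_mm = 9, height_mm = 5) {
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1 || !is.finite(diameter_mm) ||
      diameter_mm <= 0) {
    abort("`diameter_mm` must be a single positive number.",
          class = "elastifit_bad_geometry")
  }
  if (!is.numeric(height_mm) || length(height_mm) != 1 || !is.finite(height_mm) ||
      height_mm <= 0) {
    abort("`height_mm` must be a single positive number.",
          class = "elastifit_bad_geometry")
  }
  structure(
    list(
      diameter_mm = as.numeric(diameter_mm),
      height_mm = as.numeric(height_mm),
      area_m2 = pi * (diameter_mm / 2000)^2
    ),
    class = "specimen_geometry"
  )
}

#' @export
print.specimen_geometry <- function(x, ...) {
  cat(sprintf(
    "<specimen_geometry> cylinder %g mm diameter x %g mm height (A = %.4e m^2)\n",
    x$diameter_mm, x$height_mm, x$area_m2
  ))
  invisible(x)
}

is_specimen_geometry <- function(x) inherits(x, "specimen_geometry")

assert_geometry <- function(geometry) {
  if (!is_specimen_geometry(geometry)) {
    abort("`geometry` must be created by `specimen_geometry()`.",
          class = "elastifit_bad_geometry")
  }
  expected <- pi * (geometry$diameter_mm / 2000)^2
  if (abs(geometry$area_m2 - expected) > 1e-12 * expected) {
    abort("Geometry cross-section is inconsistent with its diameter.",
          class = "elastifit_bad_geometry")
  }
  invisible(geometry)
}
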
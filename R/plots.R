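#' Plot a stress-stretch curve
#'
#' @param object A `stress_stretch_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stress_stretch_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$stretch, y = .data$stress_pa)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Stretch λ (corrected)",
      y = "Lagrange stress S11 (Pa)",
      title = sprintf("Rate %s 1/s", attr(object, "rate_label"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fit overlaid on its data
#'
#' @param object A `hyperelastic_fit`.
#' @param n Number of points for the model line (default 200).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hyperelastic_fit <- function(object, n = 200, ...) {
  grid <- seq(min(object$data$stretch), max(object$data$stretch),
              length.out = n)
  line <- tibble(stretch = grid,
                 stress_pa = uniaxial_stress(object$params, grid))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$stretch, y = .data$stress_pa)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = line, colour = "firebrick") +
    ggplot2::labs(
      x = "Stretch λ (corrected)",
      y = "Lagrange stress S11 (Pa)",
      title = sprintf("%s fit, R² = %.3f", object$family, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Overlay replicate curves by rate
#'
#' @param curves_by_rate Named list of curve lists (as in
#'   [run_pipeline()]'s `curves_by_rate`), or a flat list of curves.
#' @return A ggplot object with one colour per rate.
#' @export
plot_rate_curves <- function(curves_by_rate) {
  if (length(curves_by_rate) > 0 && is.data.frame(curves_by_rate[[1]])) {
    rate_of <- purrr::map_chr(curves_by_rate, attr, "rate_label")
    curves_by_rate <- split(curves_by_rate, rate_of)
  }
  dat <- purrr::imap_dfr(curves_by_rate, function(cvs, label) {
    purrr::imap_dfr(cvs, function(cv, id) {
      dplyr::mutate(as_tibble(cv), rate_label = label, specimen_id = id)
    })
  })
  dat$rate_label <- factor(dat$rate_label,
                           levels = unique(dat$rate_label[order(suppressWarnings(
                             as.numeric(dat$rate_label)))]))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stretch, y = .data$stress_pa,
                                    colour = .data$rate_label,
                                    group = .data$specimen_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Stretch λ (corrected)",
                  y = "Lagrange stress S11 (Pa)",
                  colour = "Rate (1/s)") +
    ggplot2::theme_minimal()
}
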
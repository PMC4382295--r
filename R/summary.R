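#' Interpolate a curve's stress at given grip strains
#'
#' Linear interpolation of `stress_pa` against `grip_strain`. Used by all
#' summary statistics so they share one interpolation convention.
#'
#' @param curve A `stress_stretch_curve` (or data frame with
#'   `grip_strain` and `stress_pa`).
#' @param grip_strain Strain(s) at which to evaluate; must lie within the
#'   curve's span.
#' @return Stress in Pa.
#' @export
curve_stress_at <- function(curve, grip_strain) {
  if (!is.data.frame(curve) || !all(c("grip_strain", "stress_pa") %in% names(curve))) {
    abort("`curve` must have columns `grip_strain` and `stress_pa`.",
          class = "elastifit_bad_curve")
  }
  rng <- range(curve$grip_strain)
  if (any(grip_strain < rng[1] - 1e-12) || any(grip_strain > rng[2] + 1e-12)) {
    abort(sprintf("Requested strain outside curve span [%.4g, %.4g].",
                  rng[1], rng[2]),
          class = "elastifit_range_error")
  }
  approx(curve$grip_strain, curve$stress_pa, xout = grip_strain, rule = 2)$y
}

check_curve_list <- function(curves, min_n = 2) {
  if (is.data.frame(curves)) curves <- list(curves)
  if (!is.list(curves) || length(curves) < min_n) {
    abort(sprintf("Need a list of at least %d curves.", min_n),
          class = "elastifit_domain_error")
  }
  curves
}

#' End-stress summary across replicate curves
#'
#' Interpolates each replicate's Lagrange stress at exactly 30% grip
#' strain and returns the sample mean and standard deviation (n - 1
#' denominator). Curves that stop short of 30% (beyond `tol`) indicate an
#' incomplete test and are an error.
#'
#' @param curves List of `stress_stretch_curve` objects (replicates of
#'   one loading rate), at least 2.
#' @param at Grip strain at which the end stress is read (default 0.3).
#' @param tol Shortfall tolerance in grip strain (default 1e-3).
#' @return A one-row tibble: `n`, `mean_pa`, `sd_pa`.
#' @examples
#' base <- stress_stretch_curve(seq(0, 400, length.out = 30),
#'                              grip_strain = seq(0, 0.3, length.out = 30))
#' end_stress_stats(list(base, base))
#' @export
end_stress_stats <- function(curves, at = MAX_GRIP_STRAIN, tol = 1e-3) {
  curves <- check_curve_list(curves)
  vals <- purrr::map_dbl(curves, function(cv) {
    if (max(cv$grip_strain) < at - tol) {
      abort(sprintf("Curve reaches only grip strain %.4f < %.4f: incomplete test.",
                    max(cv$grip_strain), at),
            class = "elastifit_incomplete_test")
    }
    curve_stress_at(cv, min(at, max(cv$grip_strain)))
  })
  tibble(n = length(vals), mean_pa = mean(vals), sd_pa = sd(vals))
}

#' Coefficient of variation across replicates
#'
#' At each strain of an evaluation grid, interpolates every replicate's
#' stress and reports the across-replicate sample SD divided by the mean.
#' Grid points where the mean stress is not positive (CoV undefined) are
#' dropped with a warning. The default grid spans 0.05-0.30; below 0.05
#' the mean stress is near zero and the ratio diverges.
#'
#' @param curves List of at least 2 replicate curves.
#' @param grid Grip-strain evaluation grid (default 26 points on
#'   \[0.05, 0.30\]).
#' @return A tibble with columns `grip_strain`, `mean_pa`, `sd_pa`,
#'   `cov`, plus attributes `cov_min` and `cov_max`.
#' @export
coefficient_of_variation <- function(curves,
                                     grid = seq(0.05, 0.30, length.out = 26)) {
  curves <- check_curve_list(curves)
  mat <- vapply(curves, curve_stress_at, numeric(length(grid)),
                grip_strain = grid)
  mat <- matrix(mat, nrow = length(grid))
  m <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  bad <- m <= 0
  if (any(bad)) {
    warn(sprintf("Dropped %d grid point(s) with non-positive mean stress (CoV undefined).",
                 sum(bad)),
         class = "elastifit_undefined_cov")
  }
  out <- tibble(grip_strain = grid, mean_pa = m, sd_pa = s,
                cov = s / m)[!bad, ]
  attr(out, "cov_min") <- if (nrow(out)) min(out$cov) else NA_real_
  attr(out, "cov_max") <- if (nrow(out)) max(out$cov) else NA_real_
  out
}

#' Secant (chord) moduli over strain ranges
#'
#' For each strain interval `[a, b]` returns the chord slope
#' `(S(b) - S(a)) / (b - a)` with stresses interpolated at the interval
#' endpoints — the slope of the stress-strain response over that range.
#' Defaults to the three decades of the loading ramp: 0-10%, 10-20%,
#' 20-30% grip strain.
#'
#' @param curve A `stress_stretch_curve`.
#' @param ranges List of 2-vectors `c(a, b)` in grip strain.
#' @return A tibble with columns `strain_lo`, `strain_hi`, `modulus_pa`.
#' @examples
#' cv <- stress_stretch_curve(1000 * seq(0, 0.3, length.out = 40),
#'                            grip_strain = seq(0, 0.3, length.out = 40))
#' secant_moduli(cv) # 1000 Pa in every range
#' @export
secant_moduli <- function(curve,
                          ranges = list(c(0, 0.1), c(0.1, 0.2), c(0.2, 0.3))) {
  purrr::map_dfr(ranges, function(r) {
    if (length(r) != 2 || r[2] <= r[1]) {
      abort("Each range must be an increasing 2-vector.",
            class = "elastifit_range_error")
    }
    ends <- curve_stress_at(curve, r) # errors if outside span
    tibble(strain_lo = r[1], strain_hi = r[2],
           modulus_pa = (ends[2] - ends[1]) / (r[2] - r[1]))
  })
}

#' Pairwise rate comparison of end stresses
#'
#' Welch's two-sample, two-sided t-test for every pair of rate groups,
#' flagged significant at p < 0.05. Groups that are both constant get
#' p = 1 when their means agree (no evidence of difference) and p = 0
#' when they differ (deterministically distinct).
#'
#' @param groups Named list of numeric vectors (end stresses per rate),
#'   each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with one row per unordered pair: `group1`, `group2`,
#'   `statistic`, `p_value`, `significant`.
#' @examples
#' compare_rates(list(`2` = c(1, 2, 3), `100` = c(101, 102, 103)))
#' @export
compare_rates <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2 || is.null(names(groups))) {
    abort("`groups` must be a named list of at least 2 numeric vectors.",
          class = "elastifit_domain_error")
  }
  if (any(lengths(groups) < 2)) {
    abort("Every group needs at least 2 values.", class = "elastifit_domain_error")
  }
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- groups[[pr[1]]]
    y <- groups[[pr[2]]]
    if (var(x) == 0 && var(y) == 0) {
      p <- if (mean(x) == mean(y)) 1 else 0
      stat <- if (mean(x) == mean(y)) 0 else Inf
    } else {
      tt <- t.test(x, y, var.equal = FALSE)
      p <- tt$p.value
      stat <- unname(tt$statistic)
    }
    tibble(group1 = pr[1], group2 = pr[2], statistic = stat,
           p_value = p, significant = p < alpha)
  })
}

#' Per-rate descriptive summary
#'
#' Combines the end-stress statistics, coefficient-of-variation range and
#' across-replicate secant-modulus statistics for each rate group into
#' one row per rate — the study's rate-wise characterization table.
#'
#' @param curves_by_rate Named list: one entry per rate label, each a
#'   list of at least 2 replicate `stress_stretch_curve` objects.
#' @param cov_grid Grip-strain grid for the CoV scan.
#' @param moduli_ranges Strain intervals for the secant moduli.
#' @return A tibble with one row per rate: `rate_label`, `n_replicates`,
#'   `end_stress_mean_pa`, `end_stress_sd_pa`, `cov_min`, `cov_max`, and
#'   `E<k>_mean_pa` / `E<k>_sd_pa` per modulus range.
#' @export
rate_summary <- function(curves_by_rate,
                         cov_grid = seq(0.05, 0.30, length.out = 26),
                         moduli_ranges = list(c(0, 0.1), c(0.1, 0.2), c(0.2, 0.3))) {
  if (!is.list(curves_by_rate) || is.null(names(curves_by_rate))) {
    abort("`curves_by_rate` must be a named list of curve lists.",
          class = "elastifit_domain_error")
  }
  purrr::imap_dfr(curves_by_rate, function(curves, label) {
    curves <- check_curve_list(curves)
    ends <- end_stress_stats(curves)
    cv <- coefficient_of_variation(curves, grid = cov_grid)
    mod <- purrr::map(curves, secant_moduli, ranges = moduli_ranges)
    mod_mat <- vapply(mod, function(m) m$modulus_pa, numeric(length(moduli_ranges)))
    mod_mat <- matrix(mod_mat, nrow = length(moduli_ranges))
    mod_cols <- purrr::imap(seq_len(nrow(mod_mat)), function(i, idx) {
      stats::setNames(
        list(mean(mod_mat[i, ]), sd(mod_mat[i, ])),
        c(sprintf("E%d_mean_pa", i), sprintf("E%d_sd_pa", i))
      )
    })
    dplyr::bind_cols(
      tibble(rate_label = label, n_replicates = length(curves),
             end_stress_mean_pa = ends$mean_pa, end_stress_sd_pa = ends$sd_pa,
             cov_min = attr(cv, "cov_min"), cov_max = attr(cv, "cov_max")),
      tibble::as_tibble(purrr::flatten(mod_cols))
    )
  })
}
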
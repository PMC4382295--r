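#' Coefficient of determination
#'
#' `R^2 = 1 - SSres/SStot`, with the total sum of squares taken about the
#' mean of the observations. Can be negative when the model fits worse
#' than the mean; it is never above 1.
#'
#' @param observed Observed stresses (Pa).
#' @param predicted Model-predicted stresses (Pa), same length.
#' @return A single number `<= 1`.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' @export
r_squared <- function(observed, predicted) {
  if (!is.numeric(observed) || !is.numeric(predicted) ||
      length(observed) != length(predicted) || length(observed) < 2) {
    abort("`observed` and `predicted` must be equal-length numeric, length >= 2.",
          class = "elastifit_domain_error")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    abort("R^2 is undefined for a constant observed sequence.",
          class = "elastifit_degenerate")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

# ---- family descriptors ----------------------------------------------------

# Ogden uniaxial stress on raw numbers, stable through alpha -> 0
# (limit 3*mu*log(l)/l), so the optimizer may cross small alpha.
ogden_stress_num <- function(mu, alpha, stretch) {
  ifelse(rep(abs(alpha) < 1e-8, length(stretch)),
         3 * mu * log(stretch) / stretch,
         2 * mu / alpha * (stretch^(alpha - 1) - stretch^(-alpha / 2 - 1)))
}

fit_family_spec <- function(family, curve) {
  lambda <- curve$stretch
  i1max_m3 <- max(lambda^2 + 2 / lambda - 3)
  s <- curve$stress_pa
  mu_grid <- c(1e2, 1e3, 1e4)

  switch(family,
    fung = list(
      par_names = c("mu", "b"),
      lower = c(1e-6, 1e-6), upper = c(1e6, 50),
      predict = function(p, l) p[1] * exp(p[2] * (l^2 + 2 / l - 3)) * (l - l^-2),
      starts = as.matrix(expand.grid(mu = mu_grid, b = c(0.1, 1, 5))),
      to_params = function(p) fung_params(p[1], p[2])
    ),
    gent = {
      # Jm must exceed the largest I1 - 3 seen by the data or the model
      # hits its locking singularity inside the fit range.
      jm_lb <- i1max_m3 / 0.999 * (1 + 1e-8)
      starts <- as.matrix(expand.grid(mu = mu_grid, jm = c(0.2, 1, 10)))
      starts[, "jm"] <- pmax(starts[, "jm"], jm_lb * 1.01)
      list(
        par_names = c("mu", "jm"),
        lower = c(1e-6, jm_lb), upper = c(1e6, 1e4),
        predict = function(p, l) p[1] * p[2] / (p[2] - (l^2 + 2 / l - 3)) * (l - l^-2),
        starts = starts,
        to_params = function(p) gent_params(p[1], p[2])
      )
    },
    ogden = list(
      par_names = c("mu", "alpha"),
      lower = c(1e-6, -20), upper = c(1e6, 20),
      predict = function(p, l) ogden_stress_num(p[1], p[2], l),
      starts = as.matrix(expand.grid(mu = mu_grid, alpha = c(-4, -1, 2, 6, 12))),
      to_params = function(p) {
        a <- if (abs(p[2]) < 1e-8) 1e-8 else p[2]
        ogden_params(p[1], a)
      }
    ),
    exponential = list(
      par_names = c("amp", "scale", "offset"),
      lower = c(0, 1e-6, -Inf), upper = c(1e7, 10, Inf),
      predict = function(p, l) -p[1] * exp(-l / p[2]) + p[3],
      starts = exponential_starts(lambda, s),
      to_params = function(p) exponential_params(p[1], p[2], p[3])
    ),
    abort(sprintf("Unknown family '%s'.", family), class = "elastifit_bad_params")
  )
}

# Log-linear initialization for S = -A exp(-l/B) + C: for a trial offset
# C0 above the data, log(C0 - S) is linear in lambda with slope -1/B and
# intercept log A.
exponential_starts <- function(lambda, s) {
  smax <- max(s)
  spread <- max(max(s) - min(s), 1)
  starts <- list()
  for (f in c(0.02, 0.1, 0.5, 2, 10)) {
    c0 <- smax + f * spread
    y <- c0 - s
    if (any(y <= 0)) next
    co <- coef(lm(log(y) ~ lambda))
    slope <- co[[2]]
    if (!is.finite(slope) || slope >= -1e-12) next
    b0 <- min(max(-1 / slope, 1e-4), 10)
    a0 <- min(max(exp(co[[1]]), 0), 1e7)
    starts[[length(starts) + 1]] <- c(a0, b0, c0)
  }
  if (length(starts) == 0) {
    # flat or decreasing data: fall back to crude scale-based guesses
    starts <- list(c(spread, 0.3, smax + spread), c(10 * spread, 1, smax + spread))
  }
  do.call(rbind, starts)
}

# ---- fitting ---------------------------------------------------------------

#' Fit one hyperelastic family to a stress-stretch curve
#'
#' Minimizes the unweighted sum of squared stress residuals over the
#' family's free parameters with bounded Levenberg-Marquardt
#' (minpack.lm), started from a deterministic multi-start grid (or from
#' `init` alone when supplied). The best of all starts is returned.
#'
#' @param curve A `stress_stretch_curve` (or any data frame with columns
#'   `stretch` and `stress_pa`) with at least 4 points.
#' @param family One of `"fung"`, `"gent"`, `"ogden"`, `"exponential"`.
#' @param init Optional [hyperelastic_params] of the same family used as
#'   the sole starting point (replaces the grid).
#' @param bounds Optional list with numeric vectors `lower` and `upper`
#'   in the family's parameter order (Fung: mu, b; Gent: mu, Jm; Ogden:
#'   mu, alpha; Exponential: A, B, C), replacing the defaults.
#' @param ftol Relative objective-reduction convergence tolerance passed
#'   to the optimizer (default 1e-10).
#'
#' @return An object of class `hyperelastic_fit`: a list with elements
#'   `family`, `params`, `r_squared`, `residual_ss`, `n_points`,
#'   `converged`, `n_restarts_used`, `fitted`, `residuals` and `data`.
#'   Supports [tidy()], [glance()], `predict()` and [autoplot()].
#' @examples
#' curve <- stress_stretch_curve(
#'   stress_pa = uniaxial_stress(ogden_params(1000, 9), seq(1, 1.4749, length.out = 50)),
#'   stretch = seq(1, 1.4749, length.out = 50)
#' )
#' fit <- fit_model(curve, "ogden")
#' tidy(fit)
#' @export
fit_model <- function(curve, family, init = NULL, bounds = NULL, ftol = 1e-10) {
  family <- match.arg(family, c("fung", "gent", "ogden", "exponential"))
  if (!is.data.frame(curve) || !all(c("stretch", "stress_pa") %in% names(curve))) {
    abort("`curve` must have columns `stretch` and `stress_pa`.",
          class = "elastifit_bad_curve")
  }
  lambda <- curve$stretch
  s <- curve$stress_pa
  n <- length(s)
  if (n < 4) {
    abort("Need at least 4 points to fit.", class = "elastifit_degenerate")
  }
  if (all(s <= 0) || var(s) == 0) {
    abort("Degenerate curve: stresses are non-positive or constant; cannot fit.",
          class = "elastifit_degenerate")
  }

  spec <- fit_family_spec(family, curve)
  lower <- bounds$lower %||% spec$lower
  upper <- bounds$upper %||% spec$upper

  if (!is.null(init)) {
    if (!is_hyperelastic_params(init) || init$family != family) {
      abort("`init` must be `hyperelastic_params` of the fitted family.",
            class = "elastifit_bad_params")
    }
    starts <- matrix(unlist(init[setdiff(names(init), "family")]), nrow = 1)
  } else {
    starts <- spec$starts
  }
  # Gent: drop starts outside the feasible box
  keep <- apply(starts, 1, function(p) all(p >= lower & p <= upper))
  if (!any(keep)) {
    abort("No feasible starting point within bounds (Gent locking constraint?).",
          class = "elastifit_domain_infeasible")
  }
  starts <- starts[keep, , drop = FALSE]

  resid_fn <- function(p) s - spec$predict(p, lambda)
  control <- minpack.lm::nls.lm.control(ftol = ftol, ptol = 1e-10, maxiter = 500)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn, control = control),
      error = function(e) NULL
    )
    if (is.null(res) || !all(is.finite(res$par))) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    abort(sprintf("All %d starts failed for family '%s'.", nrow(starts), family),
          class = "elastifit_fit_failure")
  }

  par <- as.numeric(best$par)
  fitted_vals <- spec$predict(par, lambda)
  residuals <- s - fitted_vals
  rss <- sum(residuals^2)
  # info 1-3 are minpack's ftol/xtol convergence codes and 4 is the
  # gradient-orthogonality criterion (met exactly on zero-residual data);
  # anything else (iteration cap, improper input) is not converged.
  converged <- best$info %in% 1:4 && all(is.finite(fitted_vals))

  structure(
    list(
      family = family,
      params = spec$to_params(par),
      r_squared = r_squared(s, fitted_vals),
      residual_ss = rss,
      n_points = n,
      converged = isTRUE(converged),
      n_restarts_used = nrow(starts),
      fitted = fitted_vals,
      residuals = residuals,
      data = tibble(stretch = lambda, stress_pa = s)
    ),
    class = "hyperelastic_fit"
  )
}

#' Fit all four families and rank them
#'
#' Fits Fung, Gent, Ogden and exponential models to the same curve and
#' returns one row per family sorted by descending R-squared; ties are
#' broken by fewer parameters, then family name. A family that errors
#' (degenerate data, infeasible domain) is kept as a failed row rather
#' than aborting the others.
#'
#' @inheritParams fit_model
#' @return A tibble with columns `family`, `n_params`, `r_squared`,
#'   `converged`, `failed`, `error` and a list-column `fit` holding the
#'   `hyperelastic_fit` objects (NULL where failed).
#' @export
fit_all_models <- function(curve, ftol = 1e-10) {
  families <- c("fung", "gent", "ogden", "exponential")
  n_par <- c(fung = 2, gent = 2, ogden = 2, exponential = 3)
  rows <- purrr::map(families, function(fam) {
    fit <- tryCatch(fit_model(curve, fam, ftol = ftol), error = function(e) e)
    if (inherits(fit, "error")) {
      tibble(family = fam, n_params = n_par[[fam]], r_squared = NA_real_,
             converged = FALSE, failed = TRUE,
             error = conditionMessage(fit), fit = list(NULL))
    } else {
      tibble(family = fam, n_params = n_par[[fam]], r_squared = fit$r_squared,
             converged = fit$converged, failed = FALSE,
             error = NA_character_, fit = list(fit))
    }
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$failed, dplyr::desc(.data$r_squared),
                   .data$n_params, .data$family)
}

# ---- methods ---------------------------------------------------------------

#' @export
print.hyperelastic_fit <- function(x, ...) {
  cat(sprintf("<hyperelastic_fit> %s on %d points: R^2 = %.4f%s\n",
              x$family, x$n_points, x$r_squared,
              if (x$converged) "" else " (NOT converged)"))
  print(x$params)
  invisible(x)
}

#' Tidy a hyperelastic fit
#'
#' @param x A `hyperelastic_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.hyperelastic_fit <- function(x, ...) {
  vals <- x$params[setdiff(names(x$params), "family")]
  tibble(term = names(vals), estimate = as.numeric(unlist(vals)))
}

#' One-row summary of a hyperelastic fit
#'
#' @param x A `hyperelastic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `family`, `r.squared`, `residual_ss`,
#'   `nobs`, `converged`, `n_restarts_used`.
#' @export
glance.hyperelastic_fit <- function(x, ...) {
  tibble(
    family = x$family,
    r.squared = x$r_squared,
    residual_ss = x$residual_ss,
    nobs = x$n_points,
    converged = x$converged,
    n_restarts_used = x$n_restarts_used
  )
}

#' Predict stresses from a fit
#'
#' @param object A `hyperelastic_fit`.
#' @param stretch Stretches at which to predict; defaults to the fitted
#'   data's stretches.
#' @param ... Unused.
#' @return Stress in Pa.
#' @export
predict.hyperelastic_fit <- function(object, stretch = NULL, ...) {
  uniaxial_stress(object$params, stretch %||% object$data$stretch)
}
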
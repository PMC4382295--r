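# Record CSV dialect: comma-separated, "." decimal, UTF-8, with metadata
# in "# key=value" header lines followed by the column header
# time_s,displacement_mm,force_N.  Defined here bit-exactly; no standard
# bioscience container fits a tensile-machine record.

#' Write a tensile record to CSV
#'
#' @param record A [tensile_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_record_csv()]
#' @export
write_record_csv <- function(record, path) {
  if (!is_tensile_record(record)) {
    abort("`record` must be a `tensile_record`.", class = "elastifit_bad_record")
  }
  geometry <- attr(record, "geometry")
  header <- c(
    sprintf("# specimen_id=%s", attr(record, "specimen_id")),
    sprintf("# diameter_mm=%.17g", geometry$diameter_mm),
    sprintf("# height_mm=%.17g", geometry$height_mm),
    sprintf("# nominal_rate_per_s=%.17g", attr(record, "nominal_rate"))
  )
  body <- sprintf("%.17g,%.17g,%.17g",
                  record$time_s, record$displacement_mm, record$force_n)
  writeLines(c(header, "time_s,displacement_mm,force_N", body), path)
  invisible(path)
}

parse_header_meta <- function(lines, path) {
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (i in meta_lines) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines[i]))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  needed <- c("specimen_id", "diameter_mm", "height_mm", "nominal_rate_per_s")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing header metadata: %s.", path,
                  paste(missing, collapse = ", ")),
          class = "elastifit_parse_error")
  }
  meta
}

#' Read a tensile record from CSV
#'
#' Parses the record CSV dialect (metadata in `# key=value` lines, then
#' columns `time_s,displacement_mm,force_N`) and validates the record
#' invariants. If the displacement history implies a grip strain rate
#' differing from the header's nominal rate by more than 5%, a warning is
#' issued (mislabeled file or machine lag).
#'
#' @param path Input file path.
#' @return A [tensile_record()].
#' @export
read_record_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "elastifit_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  meta <- parse_header_meta(lines, path)
  header_line <- grep("^time_s,", lines)[1]
  if (is.na(header_line)) {
    abort(sprintf("%s: no `time_s,...` column header found.", path),
          class = "elastifit_parse_error")
  }
  cols <- strsplit(lines[header_line], ",")[[1]]
  needed_cols <- c("time_s", "displacement_mm", "force_N")
  if (!all(needed_cols %in% cols)) {
    abort(sprintf("%s line %d: missing column(s) %s.", path, header_line,
                  paste(setdiff(needed_cols, cols), collapse = ", ")),
          class = "elastifit_parse_error")
  }
  dat <- readr::read_csv(I(lines[-seq_len(header_line - 1)]),
                         col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  if (anyNA(dat)) {
    bad <- which(!stats::complete.cases(dat))[1]
    abort(sprintf("%s line %d: non-numeric or missing value.",
                  path, header_line + bad),
          class = "elastifit_parse_error")
  }
  geometry <- specimen_geometry(as.numeric(meta$diameter_mm),
                                as.numeric(meta$height_mm))
  nominal_rate <- as.numeric(meta$nominal_rate_per_s)
  rec <- tensile_record(
    time_s = dat$time_s,
    displacement_mm = dat$displacement_mm,
    force_n = dat$force_N,
    geometry = geometry,
    nominal_rate = nominal_rate,
    specimen_id = meta$specimen_id
  )
  t_end <- max(rec$time_s)
  if (t_end > 0) {
    implied <- (max(rec$displacement_mm) / geometry$height_mm) / t_end
    if (abs(implied - nominal_rate) > 0.05 * nominal_rate) {
      warn(sprintf("%s: displacement history implies rate %.3g 1/s vs header %.3g 1/s (>5%% off).",
                   path, implied, nominal_rate),
           class = "elastifit_rate_mismatch")
    }
  }
  rec
}

#' Write / read a stress-stretch curve CSV
#'
#' Plain CSV with columns `stretch,grip_strain,stress_pa` and an optional
#' `# rate_label=` header line.
#'
#' @param curve A `stress_stretch_curve`.
#' @param path File path.
#' @return `write_curve_csv()` returns `path` invisibly;
#'   `read_curve_csv()` returns a `stress_stretch_curve`.
#' @export
write_curve_csv <- function(curve, path) {
  if (!is_stress_stretch_curve(curve)) {
    abort("`curve` must be a `stress_stretch_curve`.", class = "elastifit_bad_curve")
  }
  body <- sprintf("%.17g,%.17g,%.17g", curve$stretch, curve$grip_strain,
                  curve$stress_pa)
  writeLines(c(sprintf("# rate_label=%s", attr(curve, "rate_label")),
               "stretch,grip_strain,stress_pa", body), path)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "elastifit_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  rate_label <- ""
  m <- regmatches(lines, regexec("^#\\s*rate_label\\s*=\\s*(.*)$", lines))
  hit <- which(lengths(m) == 2)
  if (length(hit) > 0) rate_label <- trimws(m[[hit[1]]][2])
  header_line <- grep("^stretch,", lines)[1]
  if (is.na(header_line)) {
    abort(sprintf("%s: no `stretch,...` column header found.", path),
          class = "elastifit_parse_error")
  }
  dat <- readr::read_csv(I(lines[-seq_len(header_line - 1)]),
                         col_types = readr::cols(.default = readr::col_double()),
                         progress = FALSE)
  new_stress_stretch_curve(
    tibble(stretch = dat$stretch, grip_strain = dat$grip_strain,
           stress_pa = dat$stress_pa),
    rate_label = rate_label
  )
}

fit_to_report <- function(fit_row) {
  if (fit_row$failed) {
    list(family = fit_row$family, failed = TRUE, error = fit_row$error)
  } else {
    fit <- fit_row$fit[[1]]
    c(params_to_config(fit$params),
      list(r_squared = fit$r_squared, converged = fit$converged,
           failed = FALSE))
  }
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: obtain records (from a directory of record
#' CSVs or by running the synthetic generator), convert them to
#' stress-stretch curves, fit all four model families per replicate and
#' to the across-replicate average curve, build the per-rate summary and
#' the pairwise rate comparison, and (optionally) write every artifact to
#' `out_dir` as CSV/JSON. A record that fails a stage (e.g. adhesion
#' failure) is reported in `$errors` without aborting the rest.
#'
#' @param input Either a directory containing record CSVs or a
#'   `generator_config`.
#' @param out_dir Optional output directory for the report artifacts.
#' @param cov_grid Grip-strain grid for the CoV scan.
#' @param moduli_ranges Strain intervals for the secant moduli.
#' @param fit_families Families fitted per curve (default all four).
#' @return A list: `curves_by_rate`, `replicate_fits` (tibble),
#'   `average_fits` (tibble), `summary` (tibble from [rate_summary()]),
#'   `comparisons` (tibble from [compare_rates()]), `errors` (tibble),
#'   `seed` (when generated).
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         cov_grid = seq(0.05, 0.30, length.out = 26),
                         moduli_ranges = list(c(0, 0.1), c(0.1, 0.2), c(0.2, 0.3)),
                         fit_families = c("fung", "gent", "ogden", "exponential")) {
  seed <- NULL
  if (is_generator_config(input)) {
    records <- generate_dataset(input)$records
    seed <- input$seed
  } else if (is.character(input) && length(input) == 1 && dir.exists(input)) {
    paths <- sort(list.files(input, pattern = "\\.csv$", full.names = TRUE))
    if (length(paths) == 0) {
      abort(sprintf("No record CSVs found in '%s'.", input),
            class = "elastifit_no_input")
    }
    records <- purrr::map(paths, read_record_csv)
    names(records) <- purrr::map_chr(records, attr, "specimen_id")
  } else {
    abort("`input` must be a generator_config or an existing directory.",
          class = "elastifit_no_input")
  }

  errors <- list()
  curves <- list()
  for (id in names(records)) {
    cv <- tryCatch(record_to_curve(records[[id]]), error = function(e) e)
    if (inherits(cv, "error")) {
      errors[[id]] <- tibble(specimen_id = id, stage = "kinematics",
                             error = conditionMessage(cv))
    } else {
      curves[[id]] <- cv
    }
  }
  if (length(curves) == 0) {
    abort("Every record failed the kinematics stage.", class = "elastifit_no_input")
  }

  rate_of <- purrr::map_chr(curves, attr, "rate_label")
  curves_by_rate <- split(curves, rate_of)

  replicate_fits <- purrr::imap_dfr(curves, function(cv, id) {
    dplyr::mutate(fit_all_models(cv), specimen_id = id,
                  rate_label = attr(cv, "rate_label"), .before = 1)
  })
  replicate_fits <- dplyr::filter(replicate_fits, .data$family %in% fit_families)

  average_fits <- purrr::imap_dfr(curves_by_rate, function(cvs, label) {
    grid <- seq(0, MAX_GRIP_STRAIN, length.out = 101)
    avg <- rowMeans(vapply(cvs, curve_stress_at, numeric(length(grid)),
                           grip_strain = grid))
    avg_curve <- stress_stretch_curve(avg, grip_strain = grid, rate_label = label)
    dplyr::mutate(fit_all_models(avg_curve), rate_label = label, .before = 1)
  })
  average_fits <- dplyr::filter(average_fits, .data$family %in% fit_families)

  summary_tbl <- rate_summary(curves_by_rate, cov_grid = cov_grid,
                              moduli_ranges = moduli_ranges)
  ends_by_rate <- purrr::map(curves_by_rate, function(cvs) {
    purrr::map_dbl(cvs, curve_stress_at, grip_strain = MAX_GRIP_STRAIN)
  })
  comparisons <- compare_rates(ends_by_rate)

  bundle <- list(
    curves_by_rate = curves_by_rate,
    replicate_fits = replicate_fits,
    average_fits = average_fits,
    summary = summary_tbl,
    comparisons = comparisons,
    errors = if (length(errors)) dplyr::bind_rows(errors) else
      tibble(specimen_id = character(), stage = character(), error = character()),
    seed = seed
  )

  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

write_report_bundle <- function(bundle, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (label in names(bundle$curves_by_rate)) {
    for (id in names(bundle$curves_by_rate[[label]])) {
      write_curve_csv(bundle$curves_by_rate[[label]][[id]],
                      file.path(out_dir, paste0("curve_", id, ".csv")))
    }
  }
  readr::write_csv(bundle$summary, file.path(out_dir, "summary.csv"))
  readr::write_csv(bundle$comparisons, file.path(out_dir, "comparisons.csv"))

  report <- list(
    software = paste0("elastifit ", as.character(utils::packageVersion("elastifit"))),
    seed = bundle$seed,
    summary = bundle$summary,
    comparisons = bundle$comparisons,
    average_fits = purrr::map(
      split(bundle$average_fits, bundle$average_fits$rate_label),
      function(rows) purrr::map(seq_len(nrow(rows)),
                                function(i) fit_to_report(rows[i, ]))
    ),
    errors = bundle$errors
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}
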
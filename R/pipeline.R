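#' Assemble a pipeline run configuration
#'
#' A run configuration drives [run_pipeline()]. Three modes cover the
#' workflow: `"tables"` starts from per-year area tables (the reproduction
#' path for published results — no rasters needed), `"rasters"` starts from
#' land-cover rasters on disk, and `"synthetic"` generates the landscape
#' from a [landscape_spec()].
#'
#' @param mode `"tables"`, `"rasters"` or `"synthetic"`.
#' @param areas Tables mode: path to a wide CSV (`year`, one column per
#'   class, km²) or a data frame of that shape. `NULL` uses the bundled
#'   NTMEZ table.
#' @param rasters Rasters mode: character vector of ASCII-grid paths, one
#'   per calibration date.
#' @param dates Calibration dates (years), strictly increasing; two are
#'   required for simulation.
#' @param horizons Dates to simulate beyond the last calibration date.
#' @param coefficients Path to a coefficient CSV, an `esv_coefficients`
#'   object, or `NULL` for the bundled NTMEZ table.
#' @param synthetic Synthetic mode: a [landscape_spec()] or a list of
#'   arguments for one.
#' @param ca A [ca_params()] or list of arguments for one.
#' @param n_zones Zones for zonal accounting (rasters/synthetic modes).
#' @param unit_convention,report_scale See [compute_esv()].
#' @param sensitivity_delta Relative coefficient adjustment for the
#'   sensitivity stage.
#' @param seed Master seed for every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("tables", "rasters", "synthetic"),
                       areas = NULL, rasters = NULL, dates = NULL,
                       horizons = NULL, coefficients = NULL,
                       synthetic = NULL, ca = list(), n_zones = 1,
                       unit_convention = "tabulated", report_scale = 1e8,
                       sensitivity_delta = 0.5, seed = 1) {
  mode <- match.arg(mode)
  if (!is.null(dates) && any(diff(dates) <= 0)) {
    stop("dates must be strictly increasing")
  }
  if (!is.null(horizons) && !is.null(dates) &&
    any(horizons <= max(dates))) {
    stop("horizons must lie after the last input date")
  }
  if (mode == "rasters" && (is.null(rasters) || length(rasters) < 2)) {
    stop("rasters mode needs at least two raster paths")
  }
  if (!inherits(ca, "ca_params")) ca <- do.call(ca_params, ca)
  if (!is.null(synthetic) && !inherits(synthetic, "landscape_spec")) {
    synthetic <- do.call(landscape_spec, synthetic)
  }
  structure(
    list(
      mode = mode, areas = areas, rasters = rasters, dates = dates,
      horizons = horizons, coefficients = coefficients,
      synthetic = synthetic, ca = ca, n_zones = as.integer(n_zones),
      unit_convention = unit_convention, report_scale = report_scale,
      sensitivity_delta = sensitivity_delta, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `ca` and
#' `synthetic` are nested maps.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full LUCC / ESV pipeline
#'
#' Executes the configured stages — load or generate land-cover data,
#' cross-tabulate and estimate the transition matrix, validate a hold-out
#' simulation with Kappa (synthetic mode), simulate the horizon dates, build
#' area tables, value them per class / function / zone, and produce
#' change-rate, contribution-share and coefficient-sensitivity reports.
#' Every output is written as CSV (rasters as ASCII grids) under `out_dir`,
#' together with a `run_log.txt` recording the seed and settings; re-running
#' the same configuration reproduces the outputs byte for byte. Any stage
#' failure aborts with the stage name.
#'
#' @param config A `run_config` (or YAML path).
#' @param out_dir Output directory, created if needed. `NULL` skips writing
#'   and just returns the results.
#' @return Invisibly, a named list of result tibbles and objects.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  coeffs <- stage("coefficients", load_coefficients(config$coefficients))
  res <- if (config$mode == "tables") {
    pipeline_tables(config, coeffs)
  } else {
    pipeline_spatial(config, coeffs)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stage("write_outputs", write_outputs(res, config, out_dir))
  }
  invisible(res)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
      call. = FALSE
    )
  })
}

load_coefficients <- function(x) {
  if (is.null(x)) {
    ntmez_coefficients()
  } else if (inherits(x, "esv_coefficients")) {
    x
  } else {
    read_esv_coefficients(x)
  }
}

load_year_areas <- function(x) {
  wide <- if (is.null(x)) {
    readr::read_csv(
      system.file("extdata", "lulc_areas_ntmez.csv",
        package = "esvca", mustWork = TRUE
      ),
      show_col_types = FALSE
    )
  } else if (is.data.frame(x)) {
    tibble::as_tibble(x)
  } else {
    readr::read_csv(x, show_col_types = FALSE)
  }
  long <- tidyr::pivot_longer(wide, -"year",
    names_to = "class_name", values_to = "area_km2"
  )
  years <- sort(unique(long$year))
  tabs <- lapply(years, function(y) {
    area_table(long[long$year == y, c("class_name", "area_km2")])
  })
  names(tabs) <- years
  tabs
}

# valuation + reporting stages shared by every mode:
# per-year class/function values, change rates, shares, sensitivity
value_years <- function(area_tabs, coeffs, config) {
  years <- names(area_tabs)
  by_class <- lapply(area_tabs, compute_esv,
    coeffs = coeffs,
    unit_convention = config$unit_convention,
    report_scale = config$report_scale
  )
  by_fun <- lapply(area_tabs, esv_by_function,
    coeffs = coeffs,
    unit_convention = config$unit_convention,
    report_scale = config$report_scale
  )
  first <- years[1]
  last <- years[length(years)]
  list(
    years = years,
    esv_by_class = wide_values(by_class, "class_name"),
    esv_by_function = wide_values(by_fun, "service"),
    area_change = change_rate(area_tabs[[first]], area_tabs[[last]]),
    esv_change = change_rate(by_class[[first]], by_class[[last]]),
    shares_class = lapply(by_class, contribution_shares),
    shares_function = lapply(by_fun, contribution_shares),
    sensitivity = lapply(area_tabs, coefficient_sensitivity,
      coeffs = coeffs, delta = config$sensitivity_delta,
      unit_convention = config$unit_convention
    ),
    by_class = by_class, by_function = by_fun
  )
}

# one column of reported values per year, plus the total row
wide_values <- function(results, key) {
  cats <- c(results[[1]][[key]], "total")
  cols <- lapply(results, function(r) c(r$value, esv_total(r)))
  out <- tibble::tibble(category = cats)
  for (y in names(results)) out[[y]] <- cols[[y]]
  out
}

pipeline_tables <- function(config, coeffs) {
  area_tabs <- stage("load_areas", load_year_areas(config$areas))
  c(
    list(mode = "tables", area_tables = area_tabs),
    stage("valuation", value_years(area_tabs, coeffs, config))
  )
}

pipeline_spatial <- function(config, coeffs) {
  if (config$mode == "synthetic") {
    spec <- config$synthetic %||% landscape_spec(seed = config$seed)
    g0 <- stage("generate_initial", generate_initial(spec))
    g1 <- stage(
      "evolve",
      evolve(g0, spec$transition_matrix, seed = spec$seed + 1)
    )
    dates <- config$dates %||% c(0, 1)
    zones <- generate_zones(spec, max(config$n_zones, spec$n_zones))
  } else {
    scheme <- lulc_scheme()
    grids <- stage(
      "read_rasters",
      lapply(config$rasters, read_grid, scheme = scheme)
    )
    if (length(grids) < 2) stop("need two calibration rasters")
    g0 <- grids[[1]]
    g1 <- grids[[2]]
    dates <- config$dates
    if (is.null(dates)) stop("rasters mode requires `dates`")
    zones <- if (config$n_zones > 1) {
      generate_zones(g0, config$n_zones)
    }
  }
  period <- diff(dates[1:2])
  ct <- stage("cross_tabulate", cross_tabulate(g0, g1))
  a <- stage(
    "estimate_probabilities",
    estimate_probabilities(ct, period_years = period)
  )
  horizons <- config$horizons %||% (dates[2] + period * (1:2))
  sims <- stage(
    "simulate",
    run_prediction(g0, g1, dates[1:2], horizons, params = config$ca)
  )
  validation <- if (config$mode == "synthetic") {
    truth <- stage(
      "holdout_truth",
      evolve(g1, config$synthetic$transition_matrix,
        seed = config$synthetic$seed + 2
      )
    )
    stage("kappa", kappa_agreement(truth, sims[[1]]))
  }
  grids_all <- c(
    stats::setNames(list(g0, g1), dates[1:2]),
    sims
  )
  area_tabs <- stage("areas", lapply(grids_all, tabulate_areas))
  res <- c(
    list(
      mode = config$mode, grids = grids_all, crosstab = ct,
      transition_matrix = a, validation = validation,
      area_tables = area_tabs
    ),
    stage("valuation", value_years(area_tabs, coeffs, config))
  )
  if (!is.null(zones)) {
    res$zones <- zones
    res$esv_by_zone <- stage(
      "zonal",
      esv_by_zone(g1, zones, coeffs,
        unit_convention = config$unit_convention,
        report_scale = config$report_scale
      )
    )
  }
  res
}

write_outputs <- function(res, config, out_dir) {
  p <- function(f) file.path(out_dir, f)
  readr::write_csv(report_table(res$esv_by_class), p("esv_by_class.csv"))
  readr::write_csv(report_table(res$esv_by_function), p("esv_by_function.csv"))
  readr::write_csv(report_table(res$area_change), p("area_change.csv"))
  readr::write_csv(report_table(res$esv_change), p("esv_change.csv"))
  shares <- dplyr::bind_rows(
    lapply(names(res$shares_class), function(y) {
      tibble::add_column(res$shares_class[[y]], year = y, .before = 1)
    })
  )
  readr::write_csv(report_table(shares), p("contribution_shares.csv"))
  sens <- dplyr::bind_rows(
    lapply(names(res$sensitivity), function(y) {
      tibble::add_column(res$sensitivity[[y]], year = y, .before = 1)
    })
  )
  readr::write_csv(report_table(sens, digits = 4), p("sensitivity.csv"))
  if (!is.null(res$transition_matrix)) {
    write_transition_matrix(res$transition_matrix, p("transition_matrix.csv"))
  }
  if (!is.null(res$grids)) {
    for (d in names(res$grids)) {
      write_grid(res$grids[[d]], p(paste0("landcover_", d, ".asc")))
    }
  }
  if (!is.null(res$validation)) {
    readr::write_csv(glance(res$validation), p("kappa.csv"))
  }
  if (!is.null(res$esv_by_zone)) {
    readr::write_csv(
      report_table(tibble::as_tibble(res$esv_by_zone), digits = 6),
      p("esv_by_zone.csv")
    )
  }
  writeLines(c(
    paste("package esvca", as.character(utils::packageVersion("esvca"))),
    paste("mode", config$mode),
    paste("seed", config$seed),
    paste("unit_convention", config$unit_convention),
    paste("report_scale", format(config$report_scale, scientific = TRUE)),
    paste("sensitivity_delta", config$sensitivity_delta),
    paste(
      "ca kernel_radius", config$ca$kernel_radius, "iterations",
      config$ca$iterations, "quota_tolerance", config$ca$quota_tolerance
    )
  ), p("run_log.txt"))
  invisible(out_dir)
}

#' Reproduce the NTMEZ case-study report tables
#'
#' Tables-only pipeline run on the bundled coefficient and area tables:
#' per-class and per-function ESV for 1980-2030 on the 10^8-yuan scale,
#' area and ESV change rates, contribution shares and the coefficient
#' sensitivity report.
#'
#' @param out_dir Optional output directory for the CSV bundle.
#' @return Invisibly, the [run_pipeline()] result list.
#' @examples
#' res <- reproduce_ntmez()
#' report_table(res$esv_by_class)
#' @export
reproduce_ntmez <- function(out_dir = NULL) {
  run_pipeline(run_config(mode = "tables"), out_dir = out_dir)
}
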
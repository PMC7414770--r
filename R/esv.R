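#' Build an ecosystem-service value coefficient table
#'
#' The coefficient table holds VC_if, the per-area annual value of service
#' function f delivered by land-cover class i, in yuan per hectare per year.
#' Layout follows the conventional equivalent-factor table: one row per
#' service function, one column per class. An optional `Total` row is
#' cross-checked against the column sums (it may disagree in the last printed
#' digit) and then dropped: all computations use the exact column sums, so
#' per-class, per-function and per-zone accounts add up to machine precision.
#'
#' @param df Data frame whose first column (`service`) names the function and
#'   whose remaining columns are classes.
#' @param scheme A [category_scheme()] naming the expected classes.
#' @param total_tolerance Allowed absolute discrepancy between a supplied
#'   `Total` row and the column sums (default 0.05, one unit in the last
#'   printed digit of typical tables plus rounding slack).
#' @return An `esv_coefficients` object: list with `vc` (functions x classes
#'   matrix), `totals` (exact column sums), `printed_totals` (if supplied),
#'   `functions`, `classes`.
#' @export
esv_coefficient_table <- function(df, scheme = lulc_scheme(),
                                  total_tolerance = 0.05) {
  df <- as.data.frame(df)
  service <- df[[1]]
  vc <- as.matrix(df[-1])
  miss <- setdiff(scheme$names, colnames(vc))
  if (length(miss)) {
    stop("coefficient table lacks classes: ", paste(miss, collapse = ", "))
  }
  vc <- vc[, scheme$names, drop = FALSE]
  is_total <- tolower(trimws(service)) == "total"
  printed <- NULL
  if (any(is_total)) {
    printed <- vc[which(is_total)[1], ]
    vc <- vc[!is_total, , drop = FALSE]
    service <- service[!is_total]
    dev <- abs(printed - colSums(vc))
    if (any(dev > total_tolerance)) {
      stop(
        "Total row disagrees with column sums by up to ",
        format(max(dev)), " (tolerance ", total_tolerance, ")"
      )
    }
  }
  rownames(vc) <- service
  structure(
    list(
      vc = vc, totals = colSums(vc), printed_totals = printed,
      functions = as.character(service), classes = colnames(vc),
      scheme = scheme
    ),
    class = "esv_coefficients"
  )
}

#' Read a coefficient table from CSV
#'
#' @param path CSV with a `service` column followed by one column per class.
#' @inheritParams esv_coefficient_table
#' @return An `esv_coefficients` object.
#' @export
read_esv_coefficients <- function(path, scheme = lulc_scheme()) {
  esv_coefficient_table(
    readr::read_csv(path, show_col_types = FALSE),
    scheme = scheme
  )
}

#' @export
print.esv_coefficients <- function(x, ...) {
  cat(
    "<esv_coefficients> ", length(x$functions), " functions x ",
    length(x$classes), " classes (yuan/hm2/yr)\n",
    sep = ""
  )
  print(round(x$vc, 2))
  invisible(x)
}

#' Regional equivalent factor from grain-economy data
#'
#' The equivalent factor E_a — the monetary value of one standard
#' equivalent-value unit — is one seventh of the economic value of the
#' average annual grain yield of one hectare of cropland:
#' E_a = (1/7) * sum_i(M_i * p_i * q_i) / M over the staple crops i
#' (typically rice, wheat, corn), with M_i the sown area (hm²), p_i the
#' price (yuan/t), q_i the yield (t/hm²) and M the total sown area.
#'
#' @param grain Data frame with columns `crop`, `area_hm2`, `price_yuan_t`,
#'   `yield_t_hm2`.
#' @return E_a in yuan per hectare.
#' @examples
#' equivalent_factor(tibble::tibble(
#'   crop = c("wheat", "corn"), area_hm2 = c(60, 40),
#'   price_yuan_t = c(2000, 1000), yield_t_hm2 = c(3, 2)
#' ))
#' @export
equivalent_factor <- function(grain) {
  need <- c("area_hm2", "price_yuan_t", "yield_t_hm2")
  if (!all(need %in% names(grain))) {
    stop("grain table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(grain$area_hm2 < 0) || any(grain$price_yuan_t < 0) ||
    any(grain$yield_t_hm2 < 0)) {
    stop("grain-economy quantities must be non-negative")
  }
  m_total <- sum(grain$area_hm2)
  if (m_total == 0) stop("total grain area is zero")
  sum(grain$area_hm2 * grain$price_yuan_t * grain$yield_t_hm2) / m_total / 7
}

resolve_convention <- function(unit_convention) {
  unit_convention <- match.arg(unit_convention, c("tabulated", "si"))
  # "tabulated": km2 areas multiply per-hm2 coefficients directly — the
  # convention under which the bundled NTMEZ report tables were produced
  # (their 10^8-yuan scale omits the km2 -> hm2 factor of 100).
  # "si": dimensionally consistent, converts km2 to hm2 first (x100).
  list(name = unit_convention, factor = if (unit_convention == "si") 100 else 1)
}

#' Total and per-class ecosystem-service value
#'
#' Computes the bilinear valuation ESV = sum_i A_i x VC_i, with VC_i the
#' column sum of the coefficient table. Values are reported both raw (yuan
#' under the declared unit convention) and on the reporting scale (default
#' 10^8 yuan).
#'
#' @param areas An `area_table` (see [tabulate_areas()], [area_table()]).
#' @param coeffs An `esv_coefficients` table.
#' @param unit_convention `"tabulated"` (default) multiplies km² areas by the
#'   per-hm² coefficients directly, matching the reporting convention of the
#'   bundled case-study tables; `"si"` converts km² to hm² first, giving
#'   values 100 times larger.
#' @param report_scale Divisor for the reported value column (default 1e8).
#' @return An `esv_result` tibble with `class_name`, `area_km2`,
#'   `coefficient`, `value_raw`, `value`; attributes `total_raw`, `total`,
#'   `report_scale`, `unit_convention`, `by = "class"`.
#' @examples
#' areas <- ntmez_area_table(1980)
#' compute_esv(areas, ntmez_coefficients())
#' @export
compute_esv <- function(areas, coeffs, unit_convention = "tabulated",
                        report_scale = 1e8) {
  conv <- resolve_convention(unit_convention)
  a <- match_classes(areas, coeffs)
  raw <- a$area_km2 * conv$factor * coeffs$totals
  out <- tibble::tibble(
    class_name = coeffs$classes,
    area_km2 = a$area_km2,
    coefficient = unname(coeffs$totals),
    value_raw = unname(raw),
    value = unname(raw) / report_scale
  )
  new_esv_result(out,
    by = "class", report_scale = report_scale,
    unit_convention = conv$name
  )
}

#' Ecosystem-service value by service function
#'
#' Computes ESV_f = sum_i A_i x VC_if for each of the service functions in
#' the coefficient table. By bilinearity the function values sum to the
#' [compute_esv()] total exactly.
#'
#' @inheritParams compute_esv
#' @return An `esv_result` tibble with `service`, `value_raw`, `value`;
#'   attribute `by = "function"`.
#' @export
esv_by_function <- function(areas, coeffs, unit_convention = "tabulated",
                            report_scale = 1e8) {
  conv <- resolve_convention(unit_convention)
  a <- match_classes(areas, coeffs)
  raw <- as.vector(coeffs$vc %*% (a$area_km2 * conv$factor))
  out <- tibble::tibble(
    service = coeffs$functions,
    value_raw = raw,
    value = raw / report_scale
  )
  new_esv_result(out,
    by = "function", report_scale = report_scale,
    unit_convention = conv$name
  )
}

#' Zonal ecosystem-service value
#'
#' Tabulates per-class areas within each zone of a label grid and values each
#' zone with [compute_esv()]. When the zones partition the valid pixels the
#' zone totals sum to the whole-landscape total exactly.
#'
#' @param grid A [land_grid()].
#' @param zones Integer matrix (or [land_grid()]) of zone labels, same shape
#'   as `grid`.
#' @inheritParams compute_esv
#' @return An `esv_result` tibble with one row per zone x class:
#'   `zone`, `class_name`, `area_km2`, `value_raw`, `value`;
#'   attribute `by = "zone"`. Summarise per zone with
#'   `dplyr::summarise(value = sum(value), .by = zone)`.
#' @export
esv_by_zone <- function(grid, zones, coeffs, unit_convention = "tabulated",
                        report_scale = 1e8) {
  if (inherits(zones, "land_grid")) zones <- zones$values
  if (!identical(dim(zones), dim(grid$values))) {
    stop("zone grid shape differs from the land-cover grid")
  }
  labels <- sort(unique(as.vector(zones)))
  parts <- lapply(labels, function(z) {
    at <- tabulate_areas(grid, mask = zones == z)
    res <- compute_esv(at, coeffs,
      unit_convention = unit_convention,
      report_scale = report_scale
    )
    tibble::add_column(tibble::as_tibble(res)[
      c("class_name", "area_km2", "value_raw", "value")
    ], zone = z, .before = 1)
  })
  out <- dplyr::bind_rows(parts)
  new_esv_result(out,
    by = "zone",
    report_scale = report_scale,
    unit_convention = resolve_convention(unit_convention)$name
  )
}

new_esv_result <- function(out, by, report_scale, unit_convention) {
  structure(
    tibble::new_tibble(out, class = "esv_result"),
    total_raw = sum(out$value_raw),
    total = sum(out$value_raw) / report_scale,
    report_scale = report_scale,
    unit_convention = unit_convention,
    by = by
  )
}

#' Total value of an ESV result
#'
#' @param result An `esv_result`.
#' @param raw Return yuan (`TRUE`) rather than the reporting scale.
#' @return A single number.
#' @export
esv_total <- function(result, raw = FALSE) {
  if (raw) attr(result, "total_raw") else attr(result, "total")
}

#' One-row summary of an ESV result
#'
#' @param x An `esv_result`.
#' @param ... Unused.
#' @return Tibble with `by`, `n`, `total_raw`, `total`, `report_scale`,
#'   `unit_convention`.
#' @method glance esv_result
#' @export
glance.esv_result <- function(x, ...) {
  tibble::tibble(
    by = attr(x, "by"), n = nrow(x),
    total_raw = attr(x, "total_raw"), total = attr(x, "total"),
    report_scale = attr(x, "report_scale"),
    unit_convention = attr(x, "unit_convention")
  )
}

match_classes <- function(areas, coeffs) {
  if (!all(c("class_name", "area_km2") %in% names(areas))) {
    stop("`areas` must be an area table with class_name and area_km2")
  }
  unmatched <- setdiff(areas$class_name, coeffs$classes)
  if (length(unmatched)) {
    stop(
      "classes missing from the coefficient table: ",
      paste(unmatched, collapse = ", ")
    )
  }
  idx <- match(coeffs$classes, areas$class_name)
  if (anyNA(idx)) {
    stop(
      "classes missing from the area table: ",
      paste(coeffs$classes[is.na(idx)], collapse = ", ")
    )
  }
  list(area_km2 = areas$area_km2[idx])
}

#' Percentage change between two accounts
#'
#' Computes 100 x (end - start) / start per category and for the total.
#' Categories with a zero start value get `NA` and `defined = FALSE` rather
#' than a silent zero.
#'
#' @param start,end Two `esv_result`s or `area_table`s of the same kind.
#' @return A tibble with `category`, `start`, `end`, `change_pct`, `defined`;
#'   the final row is the total.
#' @examples
#' change_rate(ntmez_area_table(1980), ntmez_area_table(2010))
#' @export
change_rate <- function(start, end) {
  s <- account_values(start)
  e <- account_values(end)
  if (!identical(s$category, e$category)) {
    stop("start and end accounts have different categories")
  }
  cat <- c(s$category, "total")
  v0 <- c(s$value, sum(s$value))
  v1 <- c(e$value, sum(e$value))
  defined <- v0 != 0
  tibble::tibble(
    category = cat, start = v0, end = v1,
    change_pct = ifelse(defined, 100 * (v1 - v0) / v0, NA_real_),
    defined = defined
  )
}

#' Percentage contribution of each category to the total
#'
#' @param result An `esv_result` (per class or per function) or `area_table`.
#' @return A tibble with `category`, `value`, `share_pct`. Shares sum to 100
#'   (negative-valued categories are included in the total).
#' @export
contribution_shares <- function(result) {
  v <- account_values(result)
  total <- sum(v$value)
  if (total == 0) stop("total is zero; shares undefined")
  tibble::tibble(
    category = v$category, value = v$value,
    share_pct = 100 * v$value / total
  )
}

# common accessor: categories + values of an account-like object
account_values <- function(x) {
  if (inherits(x, "esv_result")) {
    by <- attr(x, "by")
    if (by == "zone") {
      agg <- dplyr::summarise(tibble::as_tibble(x),
        value = sum(.data$value), .by = "zone"
      )
      list(category = as.character(agg$zone), value = agg$value)
    } else {
      key <- if (by == "function") "service" else "class_name"
      list(category = x[[key]], value = x$value)
    }
  } else if (inherits(x, "area_table") ||
    all(c("class_name", "area_km2") %in% names(x))) {
    list(category = x$class_name, value = x$area_km2)
  } else {
    stop("unsupported account type: ", paste(class(x), collapse = "/"))
  }
}

#' Round an account into a report table
#'
#' Formats an `esv_result`, `area_table` or change-rate tibble the way
#' valuation reports are printed: values rounded half-up to `digits`
#' decimals. Setting `intermediate_digits` first rounds to that many decimals
#' and then to `digits` — the two-stage chain some published tables were
#' typeset with (see the methods vignette); the default is a single rounding.
#'
#' @param x A tibble of results.
#' @param digits Decimal places of the report (default 2).
#' @param intermediate_digits Optional pre-rounding stage (e.g. 3).
#' @return The tibble with numeric columns rounded.
#' @export
report_table <- function(x, digits = 2, intermediate_digits = NULL) {
  num <- vapply(x, is.numeric, logical(1))
  out <- tibble::as_tibble(x)
  for (col in names(out)[num]) {
    v <- out[[col]]
    if (!is.null(intermediate_digits)) {
      v <- round_half_up(v, intermediate_digits)
    }
    out[[col]] <- round_half_up(v, digits)
  }
  out
}

#' Plot an ESV result as a bar chart
#'
#' @param object An `esv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot esv_result
#' @export
autoplot.esv_result <- function(object, ...) {
  v <- account_values(object)
  df <- tibble::tibble(
    category = factor(v$category, levels = v$category),
    value = v$value
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL,
      y = sprintf(
        "ESV (x%g yuan)",
        attr(object, "report_scale")
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
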
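#' Bundled NTMEZ case-study tables
#'
#' The package ships the published input tables of the Northern Tianshan
#' Mountain Economic Zone (NTMEZ, Xinjiang, China) ESV case study as plain
#' CSVs: the 9-function x 6-class value-coefficient table (yuan/hm²/yr,
#' derived from a regional equivalent factor of 1,304.86 yuan/hm²) and the
#' per-class areas (km²) for 1980-2030, the last two years being CA-Markov
#' projections. They drive the tables-only reproduction pipeline and the
#' examples.
#'
#' @return `ntmez_coefficients()`: an `esv_coefficients` object.
#' @export
ntmez_coefficients <- function() {
  read_esv_coefficients(
    system.file("extdata", "esv_coefficients_ntmez.csv",
      package = "esvca", mustWork = TRUE
    )
  )
}

#' @rdname ntmez_coefficients
#' @return `ntmez_areas()`: a long tibble with `year`, `class_name`,
#'   `area_km2` for six snapshot years.
#' @export
ntmez_areas <- function() {
  wide <- readr::read_csv(
    system.file("extdata", "lulc_areas_ntmez.csv",
      package = "esvca", mustWork = TRUE
    ),
    show_col_types = FALSE
  )
  tidyr::pivot_longer(wide, -"year",
    names_to = "class_name", values_to = "area_km2"
  )
}

#' @rdname ntmez_coefficients
#' @param year One of the tabulated years (1980, 1990, 2000, 2010, 2020,
#'   2030).
#' @return `ntmez_area_table(year)`: an `area_table` for that year.
#' @export
ntmez_area_table <- function(year) {
  long <- ntmez_areas()
  sub <- long[long$year == year, ]
  if (nrow(sub) == 0) {
    stop(
      "no areas for year ", year, "; available: ",
      paste(unique(long$year), collapse = ", ")
    )
  }
  area_table(sub[c("class_name", "area_km2")])
}
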
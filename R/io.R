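#' Read a categorical raster from an ESRI ASCII grid file
#'
#' Parses the standard six-line ASCII grid header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `NODATA_value`) followed by whitespace-separated cell values, top row
#' first. Values are validated against `scheme`; the file's nodata value is
#' mapped to `scheme$nodata_code`.
#'
#' @param path Path to an `.asc` file.
#' @param scheme A [category_scheme()] the values must belong to.
#' @return A [land_grid()].
#' @seealso [write_grid()]
#' @export
read_grid <- function(path, scheme = lulc_scheme()) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(tok[1])
    if (length(tok) == 2 && key %in% c(
      "ncols", "nrows", "xllcorner", "yllcorner",
      "xllcenter", "yllcenter", "cellsize", "nodata_value"
    )) {
      hdr[[key]] <- as.numeric(tok[2])
      n_hdr <- n_hdr + 1
    } else {
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path)
  }
  body <- paste(lines[(n_hdr + 1):length(lines)], collapse = " ")
  vals <- scan(text = body, what = numeric(), quiet = TRUE)
  nr <- as.integer(hdr$nrows)
  nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(
      "ASCII grid body has ", length(vals), " values; header promises ",
      nr * nc
    )
  }
  m <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) {
    m[m == hdr$nodata_value] <- NA_integer_
  }
  xll <- hdr$xllcorner %||% hdr$xllcenter %||% 0
  yll <- hdr$yllcorner %||% hdr$yllcenter %||% 0
  land_grid(m,
    cell_size = hdr$cellsize, scheme = scheme,
    xllcorner = xll, yllcorner = yll
  )
}

#' Write a land-cover grid as an ESRI ASCII grid file
#'
#' @param grid A [land_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_grid()]
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "land_grid"))
  v <- grid$values
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(grid$xllcorner, scientific = FALSE)),
    paste("yllcorner", format(grid$yllcorner, scientific = FALSE)),
    paste("cellsize", format(grid$cell_size, scientific = FALSE)),
    paste("NODATA_value", grid$scheme$nodata_code)
  ), con)
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a per-class area table from CSV
#'
#' Expects columns `class_code`, `class_name`, `area_km2`.
#'
#' @param path CSV path.
#' @param scheme Scheme the classes are checked against.
#' @return An `area_table` tibble (see [tabulate_areas()]).
#' @export
read_area_table <- function(path, scheme = lulc_scheme()) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("class_code", "class_name", "area_km2")
  if (!all(need %in% names(df))) {
    stop("area table needs columns: ", paste(need, collapse = ", "))
  }
  area_table(df, scheme = scheme)
}

#' Write an area table to CSV
#'
#' @param areas An `area_table` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(areas, path) {
  readr::write_csv(areas[c("class_code", "class_name", "area_km2")], path)
  invisible(path)
}
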
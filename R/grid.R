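#' Construct a categorical land-cover grid
#'
#' Wraps an integer matrix of class codes together with its cell size and
#' classification scheme. Values are validated against the scheme; anything
#' equal to the scheme's nodata code (or `NA`) is treated as missing.
#' Orientation is row-major with the first matrix row at the top of the map.
#'
#' @param values Integer matrix of class codes (rows x cols).
#' @param cell_size Pixel edge length in metres (> 0).
#' @param scheme A [category_scheme()]; defaults to [lulc_scheme()].
#' @param xllcorner,yllcorner Georeference of the lower-left corner, carried
#'   through I/O untouched.
#' @return An object of class `land_grid`.
#' @examples
#' g <- land_grid(matrix(1L, 3, 3), cell_size = 1000)
#' tabulate_areas(g)
#' @export
land_grid <- function(values, cell_size, scheme = lulc_scheme(),
                      xllcorner = 0, yllcorner = 0) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("`cell_size` must be a single positive number")
  }
  storage.mode(values) <- "integer"
  values[is.na(values)] <- scheme$nodata_code
  class_index(values, scheme) # validates; errors on unknown codes
  structure(
    list(
      values = values, cell_size = as.numeric(cell_size), scheme = scheme,
      xllcorner = as.numeric(xllcorner), yllcorner = as.numeric(yllcorner)
    ),
    class = "land_grid"
  )
}

#' @export
print.land_grid <- function(x, ...) {
  v <- x$values
  nod <- sum(v == x$scheme$nodata_code)
  cat("<land_grid> ", nrow(v), "x", ncol(v), " pixels @ ", x$cell_size,
    " m (", nod, " nodata)\n",
    sep = ""
  )
  counts <- table(factor(v[v != x$scheme$nodata_code],
    levels = x$scheme$codes, labels = x$scheme$names
  ))
  print(counts)
  invisible(x)
}

#' @export
dim.land_grid <- function(x) dim(x$values)

# logical mask of valid (non-nodata) pixels
valid_mask <- function(grid) grid$values != grid$scheme$nodata_code

# per-class pixel counts over an optional logical mask
class_counts <- function(grid, mask = valid_mask(grid)) {
  v <- grid$values[mask]
  tabulate(match(v, grid$scheme$codes), nbins = n_classes(grid$scheme))
}

#' Plot a land-cover grid
#'
#' @param object A [land_grid()].
#' @param ... Unused.
#' @return A ggplot object mapping class labels to fill.
#' @method autoplot land_grid
#' @export
autoplot.land_grid <- function(object, ...) {
  sch <- object$scheme
  df <- tidy.land_grid(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$col, y = .data$row, fill = .data$class_name
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "class", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy a land-cover grid into a long tibble
#'
#' @param x A [land_grid()].
#' @param ... Unused.
#' @return A tibble with one row per valid pixel: `row`, `col`, `class_code`,
#'   `class_name`.
#' @method tidy land_grid
#' @export
tidy.land_grid <- function(x, ...) {
  v <- x$values
  idx <- class_index(v, x$scheme)
  keep <- !is.na(idx)
  tibble::tibble(
    row = as.integer(row(v)[keep]),
    col = as.integer(col(v)[keep]),
    class_code = as.integer(v[keep]),
    class_name = x$scheme$names[idx[keep]]
  )
}
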
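#' Build an area table from a data frame
#'
#' An area table records the area of each land-cover class in km². It is the
#' tabular interface between the raster stages and the valuation stages: both
#' [tabulate_areas()] (from a raster) and hand-entered tables (for
#' tables-only reproduction runs) produce the same structure.
#'
#' @param df Data frame with `class_name` and `area_km2` (and optionally
#'   `class_code`, `pixels`).
#' @param scheme Scheme used to fill in codes and fix the class order.
#' @return A tibble of class `area_table` ordered by scheme, with attribute
#'   `total_km2`.
#' @export
area_table <- function(df, scheme = lulc_scheme()) {
  df <- tibble::as_tibble(df)
  if (!all(c("class_name", "area_km2") %in% names(df))) {
    stop("`df` needs columns class_name and area_km2")
  }
  idx <- match(df$class_name, scheme$names)
  if (anyNA(idx)) {
    stop(
      "unknown classes: ",
      paste(unique(df$class_name[is.na(idx)]), collapse = ", ")
    )
  }
  if (any(df$area_km2 < 0)) stop("areas must be non-negative")
  out <- tibble::tibble(
    class_code = scheme$codes[idx],
    class_name = df$class_name,
    area_km2 = as.numeric(df$area_km2)
  )
  if ("pixels" %in% names(df)) out$pixels <- as.integer(df$pixels)
  out <- out[order(match(out$class_name, scheme$names)), ]
  structure(out,
    class = c("area_table", class(out)),
    total_km2 = sum(out$area_km2), scheme = scheme
  )
}

#' Tabulate per-class areas of a land-cover grid
#'
#' Counts pixels per class (nodata excluded) and converts to km² using the
#' grid's cell size. This is the A_i that enters the valuation ESV = sum of
#' A_i x VC_i.
#'
#' @param grid A [land_grid()].
#' @param mask Optional logical matrix restricting the tabulation (used for
#'   zonal accounting); combined with the grid's own validity mask.
#' @return An `area_table` tibble with columns `class_code`, `class_name`,
#'   `pixels`, `area_km2`; attribute `total_km2` holds the summed area.
#' @examples
#' g <- land_grid(matrix(c(1, 1, 2, 2), 2, 2), cell_size = 1000)
#' tabulate_areas(g)
#' @export
tabulate_areas <- function(grid, mask = NULL) {
  stopifnot(inherits(grid, "land_grid"))
  m <- valid_mask(grid)
  if (!is.null(mask)) m <- m & mask
  if (!any(m)) stop("empty landscape: no valid pixels to tabulate")
  counts <- class_counts(grid, m)
  km2_per_px <- (grid$cell_size / 1000)^2
  sch <- grid$scheme
  out <- tibble::tibble(
    class_code = sch$codes,
    class_name = sch$names,
    pixels = as.integer(counts),
    area_km2 = counts * km2_per_px
  )
  structure(out,
    class = c("area_table", class(out)),
    total_km2 = sum(out$area_km2), scheme = sch
  )
}

#' Cross-tabulate land-cover change between two dates
#'
#' Entry (i, j) is the area (km²) that moved from class i at the first date
#' to class j at the second. Pixels that are nodata at either date are
#' excluded pairwise, so the row sums equal the first date's area table and
#' the column sums the second's, over the shared valid mask.
#'
#' @param grid_t,grid_t1 Two [land_grid()]s of identical shape, scheme and
#'   cell size.
#' @return A `cross_tab`: an n x n numeric matrix of km² areas with class
#'   names as dimnames and attributes `cell_size`, `scheme`, `n_pixels`.
#' @export
cross_tabulate <- function(grid_t, grid_t1) {
  stopifnot(inherits(grid_t, "land_grid"), inherits(grid_t1, "land_grid"))
  if (!identical(dim(grid_t$values), dim(grid_t1$values))) {
    stop("grids differ in shape")
  }
  if (!same_scheme(grid_t$scheme, grid_t1$scheme)) {
    stop("grids differ in classification scheme")
  }
  if (grid_t$cell_size != grid_t1$cell_size) {
    stop("grids differ in cell size")
  }
  sch <- grid_t$scheme
  n <- n_classes(sch)
  keep <- valid_mask(grid_t) & valid_mask(grid_t1)
  i <- match(grid_t$values[keep], sch$codes)
  j <- match(grid_t1$values[keep], sch$codes)
  counts <- matrix(tabulate((j - 1) * n + i, nbins = n * n), n, n)
  km2_per_px <- (grid_t$cell_size / 1000)^2
  structure(counts * km2_per_px,
    dimnames = list(from = sch$names, to = sch$names),
    class = c("cross_tab", "matrix", "array"),
    cell_size = grid_t$cell_size, scheme = sch, n_pixels = sum(keep)
  )
}

#' Tidy a cross-tabulation into long form
#'
#' @param x A `cross_tab` from [cross_tabulate()].
#' @param ... Unused.
#' @return A tibble with `from`, `to`, `area_km2`.
#' @method tidy cross_tab
#' @export
tidy.cross_tab <- function(x, ...) {
  sch <- attr(x, "scheme")
  tibble::tibble(
    from = rep(sch$names, times = ncol(x)),
    to = rep(sch$names, each = nrow(x)),
    area_km2 = as.vector(unclass(x))
  )
}
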
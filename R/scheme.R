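#' Define a categorical land-cover classification scheme
#'
#' A scheme pairs integer class codes with class labels and designates a
#' nodata code. Every grid, cross-tabulation, transition matrix and area
#' table in the package carries (or is checked against) a scheme.
#'
#' @param codes Integer vector of unique class codes.
#' @param names Character vector of class labels, one per code.
#' @param nodata_code Integer code marking missing pixels; must not collide
#'   with `codes`.
#' @return An object of class `category_scheme`.
#' @seealso [lulc_scheme()] for the standard six-class scheme.
#' @export
category_scheme <- function(codes, names, nodata_code = -9999L) {
  codes <- as.integer(codes)
  nodata_code <- as.integer(nodata_code)
  if (anyDuplicated(codes)) stop("class codes must be unique")
  if (length(names) != length(codes)) {
    stop("need exactly one class name per code")
  }
  if (nodata_code %in% codes) stop("nodata_code must not be a class code")
  structure(
    list(codes = codes, names = as.character(names), nodata_code = nodata_code),
    class = "category_scheme"
  )
}

#' The standard six-class land-use/land-cover scheme
#'
#' Forestland, grassland, cropland, water body, built-up land and unutilized
#' land, coded 1 to 6 — the classification used by the bundled NTMEZ
#' (Northern Tianshan Mountain Economic Zone) case-study tables. The class
#' order matches the columns of the bundled coefficient table.
#'
#' @return A [category_scheme()] with codes 1:6.
#' @export
lulc_scheme <- function() {
  category_scheme(
    codes = 1:6,
    names = c(
      "forestland", "grassland", "cropland",
      "water body", "built-up land", "unutilized land"
    )
  )
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("<category_scheme> ", length(x$codes), " classes, nodata=",
    x$nodata_code, "\n",
    sep = ""
  )
  cat(paste0("  ", format(x$codes), " ", x$names, collapse = "\n"), "\n")
  invisible(x)
}

n_classes <- function(scheme) length(scheme$codes)

same_scheme <- function(a, b) {
  identical(a$codes, b$codes) && identical(a$names, b$names)
}

# map raw values onto 1..n class indices; NA for nodata; error on strangers
class_index <- function(values, scheme) {
  idx <- match(values, scheme$codes)
  bad <- !is.na(values) & values != scheme$nodata_code & is.na(idx)
  if (any(bad)) {
    offenders <- sort(unique(values[bad]))
    stop(
      "values not in scheme: {", paste(offenders, collapse = ", "), "} (",
      sum(bad), " pixel(s))"
    )
  }
  idx
}
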
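#' Estimate a transition-probability matrix from a cross-tabulation
#'
#' Row-normalises the change matrix: A_ij = area(i to j) / area(i at date t).
#' A class absent at the first date yields an identity row (it trivially
#' persists), keeping the matrix row-stochastic.
#'
#' @param crosstab A `cross_tab` from [cross_tabulate()], or a plain
#'   non-negative square matrix of transition areas/counts.
#' @param period_years Number of years the matrix spans (metadata used by
#'   [rescale_period()] and horizon checks). Optional.
#' @return A `transition_matrix`: row-stochastic n x n matrix with attributes
#'   `period_years` and `scheme` (when available).
#' @examples
#' estimate_probabilities(matrix(c(3, 0, 1, 4), 2, 2))
#' @export
estimate_probabilities <- function(crosstab, period_years = NULL) {
  m <- unclass(crosstab)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("`crosstab` must be a square matrix")
  }
  if (any(m < 0)) stop("transition areas must be non-negative")
  if (all(m == 0)) stop("cross-tabulation is entirely zero")
  rs <- rowSums(m)
  a <- m / ifelse(rs > 0, rs, 1)
  zero <- which(rs == 0)
  a[zero, ] <- 0
  a[cbind(zero, zero)] <- 1
  new_transition_matrix(a,
    period_years = period_years,
    scheme = attr(crosstab, "scheme")
  )
}

new_transition_matrix <- function(a, period_years = NULL, scheme = NULL,
                                  period_approx = FALSE) {
  stopifnot(all(a >= -1e-12), all(abs(rowSums(a) - 1) < 1e-9))
  structure(a,
    class = c("transition_matrix", "matrix", "array"),
    period_years = period_years, scheme = scheme,
    period_approx = period_approx
  )
}

#' Coerce a plain row-stochastic matrix to a transition matrix
#'
#' @param a Square matrix with non-negative entries and unit row sums.
#' @inheritParams estimate_probabilities
#' @return A `transition_matrix`.
#' @export
transition_matrix <- function(a, period_years = NULL) {
  new_transition_matrix(as.matrix(a), period_years = period_years)
}

#' Project class areas forward with a Markov chain
#'
#' Computes S x A^steps. Because A is row-stochastic the total area is
#' conserved exactly; areas and proportions are never silently renormalised.
#'
#' @param areas An `area_table` tibble or a numeric vector of class areas or
#'   proportions (in scheme order).
#' @param a A `transition_matrix`.
#' @param steps Number of applications of the matrix (positive integer).
#' @return Same shape as `areas`: an `area_table` (pixels column dropped) or
#'   a numeric vector.
#' @examples
#' a <- transition_matrix(matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2))
#' project_areas(c(100, 0), a, steps = 1)
#' @export
project_areas <- function(areas, a, steps = 1) {
  if (!is.numeric(steps) || length(steps) != 1 || steps < 1 ||
    steps != round(steps)) {
    stop("`steps` must be a positive integer")
  }
  s <- if (inherits(areas, "area_table")) areas$area_km2 else as.numeric(areas)
  if (length(s) != nrow(a)) {
    stop("length(areas) must equal the matrix dimension")
  }
  for (k in seq_len(steps)) s <- as.vector(s %*% unclass(a))
  if (inherits(areas, "area_table")) {
    out <- areas
    out$area_km2 <- s
    out$pixels <- NULL
    attr(out, "total_km2") <- sum(s)
    out
  } else {
    s
  }
}

#' Rescale a transition matrix to a different period length
#'
#' Returns A^(target_years / period_years). When the target is not an integer
#' multiple of the calibration period the nearest integer power is used and
#' the approximation is flagged in the result's `period_approx` attribute.
#' By default the projection machinery applies a calibrated matrix once per
#' calibration period without rescaling; this function makes any rescaling an
#' explicit, visible step.
#'
#' @param a A `transition_matrix` whose `period_years` attribute is set.
#' @param target_years Positive period the returned matrix should represent.
#' @return A `transition_matrix` with `period_years = target_years`.
#' @export
rescale_period <- function(a, target_years) {
  if (!is.numeric(target_years) || target_years <= 0) {
    stop("`target_years` must be positive")
  }
  period <- attr(a, "period_years")
  if (is.null(period)) stop("matrix has no period_years attribute")
  ratio <- target_years / period
  k <- max(1L, as.integer(round(ratio)))
  approx <- abs(ratio - k) > 1e-9
  out <- diag(nrow(a))
  m <- unclass(a)
  for (i in seq_len(k)) out <- out %*% m
  # renormalise away accumulated floating-point drift in the row sums
  out <- out / rowSums(out)
  new_transition_matrix(out,
    period_years = target_years, scheme = attr(a, "scheme"),
    period_approx = approx
  )
}

#' Read / write transition matrices as CSV
#'
#' CSV layout: first column `from` holding class names, remaining columns one
#' per destination class.
#'
#' @param a A `transition_matrix`.
#' @param path CSV path.
#' @return `path` (write) or a `transition_matrix` (read).
#' @export
write_transition_matrix <- function(a, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(a)))
  names(df) <- colnames(a) %||% paste0("class_", seq_len(ncol(a)))
  df <- tibble::add_column(df,
    from = rownames(a) %||% names(df),
    .before = 1
  )
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @param period_years Optional period metadata to attach on read.
#' @export
read_transition_matrix <- function(path, period_years = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  transition_matrix(m, period_years = period_years)
}

#' Tidy a transition matrix into long form
#'
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @return A tibble with `from`, `to`, `probability`.
#' @method tidy transition_matrix
#' @export
tidy.transition_matrix <- function(x, ...) {
  nm <- rownames(x) %||% as.character(seq_len(nrow(x)))
  tibble::tibble(
    from = rep(nm, times = ncol(x)),
    to = rep(colnames(x) %||% nm, each = nrow(x)),
    probability = as.vector(unclass(x))
  )
}
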
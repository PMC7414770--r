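#' Specify a synthetic landscape
#'
#' Describes a multi-date categorical landscape with known ground truth:
#' target class proportions for the initial date, a row-stochastic matrix
#' governing per-pixel transitions between dates, an optional majority-filter
#' radius that turns i.i.d. noise into contiguous patches, and a zone count
#' for zonal accounting. Fixed seeds make every derived raster bit-identical
#' across runs.
#'
#' @param shape Length-2 integer vector, rows x cols.
#' @param cell_size Pixel edge in metres (default 30, the usual Landsat
#'   product resolution).
#' @param class_proportions Length-n simplex vector of target proportions.
#' @param transition_matrix Row-stochastic n x n matrix (defaults to
#'   identity).
#' @param autocorrelation Majority-smoothing radius in pixels; 0 = i.i.d.
#' @param n_zones Number of rectangular zones for [generate_zones()].
#' @param seed RNG seed.
#' @param scheme A [category_scheme()].
#' @return A list of class `landscape_spec`.
#' @export
landscape_spec <- function(shape = c(200, 200), cell_size = 30,
                           class_proportions =
                             c(0.04, 0.43, 0.11, 0.03, 0.01, 0.38),
                           transition_matrix = NULL,
                           autocorrelation = 0, n_zones = 1, seed = 1,
                           scheme = lulc_scheme()) {
  n <- n_classes(scheme)
  if (length(class_proportions) != n) {
    stop("need one proportion per scheme class")
  }
  if (any(class_proportions < 0)) stop("proportions must be non-negative")
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1")
  }
  if (is.null(transition_matrix)) transition_matrix <- diag(n)
  transition_matrix <- unclass(as.matrix(transition_matrix))
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1")
  }
  if (n_zones < 1 || n_zones > prod(shape)) {
    stop("n_zones must be between 1 and the pixel count")
  }
  structure(
    list(
      shape = as.integer(shape), cell_size = cell_size,
      class_proportions = class_proportions,
      transition_matrix = transition_matrix,
      autocorrelation = as.integer(autocorrelation),
      n_zones = as.integer(n_zones), seed = as.integer(seed),
      scheme = scheme
    ),
    class = "landscape_spec"
  )
}

#' Generate the initial synthetic land-cover grid
#'
#' Draws pixels i.i.d. from the spec's class proportions, then (if
#' `autocorrelation > 0`) applies a majority filter of that radius to create
#' contiguous patches. Smoothing biases realised proportions toward dominant
#' classes; at radius 0 the empirical proportions are unbiased.
#'
#' @param spec A [landscape_spec()].
#' @return A [land_grid()].
#' @export
generate_initial <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  sch <- spec$scheme
  npx <- prod(spec$shape)
  draws <- with_seed(
    spec$seed,
    sample.int(n_classes(sch), npx, replace = TRUE, prob = spec$class_proportions)
  )
  m <- matrix(sch$codes[draws], spec$shape[1], spec$shape[2])
  if (spec$autocorrelation > 0) {
    m <- majority_filter(m, sch, spec$autocorrelation)
  }
  land_grid(m, cell_size = spec$cell_size, scheme = sch)
}

# modal class in each (2r+1)^2 window; ties -> lowest class index
majority_filter <- function(m, scheme, r) {
  counts <- lapply(scheme$codes, function(code) box_sum((m == code) * 1, r))
  best <- counts[[1]]
  pick <- matrix(1L, nrow(m), ncol(m))
  for (k in seq_along(counts)[-1]) {
    better <- counts[[k]] > best
    best[better] <- counts[[k]][better]
    pick[better] <- k
  }
  matrix(scheme$codes[pick], nrow(m), ncol(m))
}

#' Evolve a grid by per-pixel Markov sampling
#'
#' Resamples every valid pixel's class from its row of the transition matrix,
#' independently, `steps` times. Expected class areas therefore follow the
#' Markov projection exactly; this is the sampling model under which
#' transition-matrix recovery from a cross-tabulation is consistent.
#'
#' @param grid A [land_grid()].
#' @param transition_matrix Row-stochastic matrix (or `transition_matrix`
#'   object).
#' @param steps Number of sampling sweeps.
#' @param seed RNG seed.
#' @return A [land_grid()].
#' @export
evolve <- function(grid, transition_matrix, steps = 1, seed = 1) {
  stopifnot(inherits(grid, "land_grid"))
  a <- unclass(as.matrix(transition_matrix))
  sch <- grid$scheme
  n <- n_classes(sch)
  stopifnot(nrow(a) == n, all(abs(rowSums(a) - 1) < 1e-9))
  v <- grid$values
  ok <- valid_mask(grid)
  with_seed(seed, {
    for (s in seq_len(steps)) {
      idx <- match(v[ok], sch$codes)
      u <- runif(length(idx))
      cum <- t(apply(a, 1, cumsum))
      # class drawn per pixel: first column whose cumulative prob exceeds u
      newidx <- max.col(cum[idx, , drop = FALSE] >= u, ties.method = "first")
      v[ok] <- sch$codes[newidx]
    }
  })
  land_grid(v,
    cell_size = grid$cell_size, scheme = sch,
    xllcorner = grid$xllcorner, yllcorner = grid$yllcorner
  )
}

#' Tile a landscape into contiguous rectangular zones
#'
#' Splits the lattice into an a x b grid of near-equal rectangular tiles
#' (a*b = n_zones, a and b as close as possible), labelled 1..n_zones in
#' row-major order — a stand-in for administrative regions in zonal
#' accounting.
#'
#' @param spec A [landscape_spec()], or a [land_grid()] whose shape to tile.
#' @param n_zones Zone count; defaults to the spec's `n_zones`.
#' @return An integer matrix of zone labels.
#' @export
generate_zones <- function(spec, n_zones = NULL) {
  shape <- if (inherits(spec, "landscape_spec")) spec$shape else dim(spec)
  if (is.null(n_zones)) {
    n_zones <- if (inherits(spec, "landscape_spec")) spec$n_zones else 1L
  }
  if (n_zones < 1 || n_zones > prod(shape)) {
    stop("n_zones must be between 1 and the pixel count")
  }
  # factor n_zones = a * b with a <= b as close to square as possible
  a <- max(which(n_zones %% seq_len(floor(sqrt(n_zones))) == 0))
  b <- n_zones %/% a
  if (shape[1] < a || shape[2] < b) stop("grid too small for that tiling")
  band <- function(len, k) {
    if (k == 1) rep(1L, len) else as.integer(cut(seq_len(len), k, labels = FALSE))
  }
  row_band <- band(shape[1], a)
  col_band <- band(shape[2], b)
  matrix((row_band[row(matrix(0, shape[1], shape[2]))] - 1L) * b +
    col_band[col(matrix(0, shape[1], shape[2]))], shape[1], shape[2])
}
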
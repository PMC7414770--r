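#' Cellular-automaton allocation parameters
#'
#' @param kernel_radius Neighbourhood half-width in pixels; the suitability
#'   window is (2r+1) x (2r+1). Default 2 (a 5x5 contiguity filter).
#' @param iterations Allocation passes per projection step. Default 1.
#' @param seed RNG seed for the tie-breaking jitter — the only stochastic
#'   element of the allocation.
#' @param quota_tolerance Maximum allowed relative deviation of realised
#'   from target class areas. The greedy allocator satisfies quotas exactly,
#'   so the default 0 is attainable; the parameter exists as a guard that is
#'   checked after allocation.
#' @return A list of class `ca_params`.
#' @export
ca_params <- function(kernel_radius = 2L, iterations = 1L, seed = 1L,
                      quota_tolerance = 0) {
  stopifnot(
    kernel_radius >= 1, iterations >= 1, quota_tolerance >= 0,
    is.numeric(seed), length(seed) == 1
  )
  structure(
    list(
      kernel_radius = as.integer(kernel_radius),
      iterations = as.integer(iterations),
      seed = as.integer(seed),
      quota_tolerance = quota_tolerance
    ),
    class = "ca_params"
  )
}

#' Neighbourhood suitability of each class at each pixel
#'
#' Suitability of class c at a pixel is the fraction of class-c pixels in
#' the surrounding (2r+1) x (2r+1) window, truncated at the map edge, with
#' nodata pixels excluded from numerator and denominator. When the classes
#' partition every window the per-pixel suitabilities sum to one — a
#' contiguity measure in [0, 1] that rewards converting a pixel to a class
#' already dense around it.
#'
#' @param grid A [land_grid()].
#' @param params A [ca_params()] (only `kernel_radius` is used).
#' @return A named list of numeric matrices, one per class.
#' @export
neighborhood_suitability <- function(grid, params = ca_params()) {
  stopifnot(inherits(grid, "land_grid"))
  r <- params$kernel_radius
  sch <- grid$scheme
  ok <- valid_mask(grid)
  denom <- box_sum(ok * 1, r)
  denom[denom == 0] <- 1
  out <- lapply(sch$codes, function(code) {
    box_sum((grid$values == code & ok) * 1, r) / denom
  })
  names(out) <- sch$names
  out
}

#' Spatially allocate Markov-projected areas with a cellular automaton
#'
#' Each projection step (1) projects the current class areas one step with
#' the transition matrix, (2) converts the targets to exact pixel quotas by
#' largest-remainder rounding, and (3) assigns pixels to classes greedily in
#' descending score, where the score of converting a pixel of class i to
#' class j is `A[i, j] * suitability_j` plus an infinitesimal seeded jitter
#' that breaks ties reproducibly. Quotas are met exactly; nodata pixels are
#' untouched.
#'
#' @param grid_t Starting [land_grid()].
#' @param a A `transition_matrix` over the same scheme.
#' @param steps Number of projection steps to chain.
#' @param params A [ca_params()].
#' @return A [land_grid()] with the allocated classes.
#' @export
allocate <- function(grid_t, a, steps = 1, params = ca_params()) {
  stopifnot(inherits(grid_t, "land_grid"))
  if (nrow(a) != n_classes(grid_t$scheme)) {
    stop("transition matrix and grid scheme disagree on class count")
  }
  out <- grid_t
  for (s in seq_len(steps)) {
    out <- allocate_one_step(out, a, params, step_id = s)
  }
  out
}

allocate_one_step <- function(grid, a, params, step_id = 1) {
  sch <- grid$scheme
  n <- n_classes(sch)
  ok <- valid_mask(grid)
  counts <- class_counts(grid, ok)
  n_valid <- sum(counts)
  targets <- as.vector(counts %*% unclass(a))
  if (round(sum(targets)) > n_valid + 1e-6) {
    stop("infeasible quotas: targets exceed landscape size")
  }
  quotas <- largest_remainder(targets, n_valid)
  current <- grid
  for (pass in seq_len(params$iterations)) {
    current <- greedy_assign(
      current, a, quotas,
      seed = params$seed + 1000L * (step_id - 1L) + pass - 1L,
      params = params
    )
  }
  realised <- class_counts(current, valid_mask(current))
  rel <- abs(realised - quotas) / pmax(quotas, 1)
  if (any(rel > params$quota_tolerance + 1e-12)) {
    stop("allocation missed its quotas beyond quota_tolerance")
  }
  current
}

greedy_assign <- function(grid, a, quotas, seed, params) {
  sch <- grid$scheme
  n <- n_classes(sch)
  ok <- valid_mask(grid)
  suit <- neighborhood_suitability(grid, params)
  idx <- which(ok)
  npx <- length(idx)
  cls <- match(grid$values[idx], sch$codes)
  # score[p, j] = A[class(p), j] * suitability_j(p) + jitter
  score <- matrix(0, npx, n)
  am <- unclass(a)
  for (j in seq_len(n)) {
    score[, j] <- am[cls, j] * suit[[j]][idx]
  }
  jitter <- with_seed(seed, stats::runif(npx * n))
  score <- score + 1e-9 * jitter
  ord <- order(score, decreasing = TRUE)
  assigned <- greedy_fill(ord, npx, quotas)
  v <- grid$values
  v[idx] <- sch$codes[assigned]
  land_grid(v,
    cell_size = grid$cell_size, scheme = sch,
    xllcorner = grid$xllcorner, yllcorner = grid$yllcorner
  )
}

# Walk (pixel, class) pairs in score order, assigning each still-free pixel
# to the first class whose quota is open. Quotas sum to the pixel count, so
# every pixel ends up assigned.
greedy_fill <- function(ord, npx, quotas) {
  assigned <- integer(npx)
  left <- as.integer(quotas)
  remaining <- npx
  for (k in ord) {
    p <- ((k - 1L) %% npx) + 1L
    j <- ((k - 1L) %/% npx) + 1L
    if (assigned[p] == 0L && left[j] > 0L) {
      assigned[p] <- j
      left[j] <- left[j] - 1L
      remaining <- remaining - 1L
      if (remaining == 0L) break
    }
  }
  assigned
}

#' Calibrate on two dates and simulate forward
#'
#' Estimates the transition matrix from the two calibration grids, then
#' chains [allocate()] one calibration period per horizon step. Horizon dates
#' must be the second calibration date plus whole multiples of the
#' calibration period; set `rescale = TRUE` to rescale the matrix (matrix
#' power, see [rescale_period()]) for other spacings.
#'
#' @param grid_t0,grid_t1 Calibration [land_grid()]s.
#' @param dates Numeric length-2 vector of the calibration dates (years),
#'   strictly increasing.
#' @param horizon_dates Dates to simulate, all after `dates[2]`.
#' @param params A [ca_params()].
#' @param rescale Rescale the matrix for horizons not aligned to the
#'   calibration period (default FALSE: misalignment is an error).
#' @return Named list of simulated [land_grid()]s, one per horizon date.
#' @export
run_prediction <- function(grid_t0, grid_t1, dates, horizon_dates,
                           params = ca_params(), rescale = FALSE) {
  stopifnot(length(dates) == 2)
  if (diff(dates) <= 0) stop("calibration dates must be strictly increasing")
  if (any(horizon_dates <= dates[2])) {
    stop("horizon dates must lie after the second calibration date")
  }
  period <- diff(dates)
  a <- estimate_probabilities(
    cross_tabulate(grid_t0, grid_t1),
    period_years = period
  )
  gaps <- diff(c(dates[2], sort(horizon_dates)))
  if (!rescale && any(abs(gaps / period - round(gaps / period)) > 1e-9)) {
    bad <- sort(horizon_dates)[abs(gaps / period - round(gaps / period)) > 1e-9]
    stop(
      "horizon(s) ", paste(bad, collapse = ", "), " not aligned to the ",
      period, "-year calibration period; use rescale = TRUE"
    )
  }
  out <- list()
  current <- grid_t1
  for (h in seq_along(gaps)) {
    if (rescale && abs(gaps[h] - period) > 1e-9) {
      ah <- rescale_period(a, gaps[h])
      current <- allocate(current, ah, steps = 1, params = params)
    } else {
      current <- allocate(current, a,
        steps = as.integer(round(gaps[h] / period)), params = params
      )
    }
    out[[as.character(sort(horizon_dates)[h])]] <- current
  }
  out
}
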
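#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (`0.125 -> 0.13` at two
#' digits), the convention used in the package's report tables. Base R's
#' [round()] rounds ties to even, which does not match how valuation tables
#' are conventionally typeset.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(0.125, -0.125, 2.675), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small epsilon absorbs binary representation error of decimal inputs
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

#' Largest-remainder apportionment of counts
#'
#' Rounds a vector of non-negative real targets to integers that sum exactly
#' to `total`, assigning each entry its floor and distributing the remaining
#' units in order of decreasing fractional remainder (ties broken by position).
#'
#' @param targets Non-negative numeric vector of real-valued quotas.
#' @param total Integer the result must sum to. Defaults to `round(sum(targets))`.
#' @return Integer vector, same length as `targets`, summing to `total`.
#' @export
largest_remainder <- function(targets, total = round(sum(targets))) {
  stopifnot(all(targets >= 0), total >= 0)
  if (sum(targets) == 0) {
    if (total != 0) stop("cannot apportion a positive total over all-zero targets")
    return(integer(length(targets)))
  }
  scaled <- targets / sum(targets) * total
  base <- floor(scaled)
  left <- total - sum(base)
  if (left > 0) {
    frac <- scaled - base
    take <- order(frac, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Sum of each (2r+1)x(2r+1) edge-truncated window of m, via an integral image.
box_sum <- function(m, r) {
  nr <- nrow(m)
  nc <- ncol(m)
  p <- rbind(0, apply(m, 2, cumsum))
  p <- cbind(0, t(apply(p, 1, cumsum)))
  i1 <- pmax(seq_len(nr) - r, 1)
  i2 <- pmin(seq_len(nr) + r, nr)
  j1 <- pmax(seq_len(nc) - r, 1)
  j2 <- pmin(seq_len(nc) + r, nc)
  p[i2 + 1, j2 + 1, drop = FALSE] - p[i1, j2 + 1, drop = FALSE] -
    p[i2 + 1, j1, drop = FALSE] + p[i1, j1, drop = FALSE]
}

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package randomness never perturbs the session stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
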
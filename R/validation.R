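#' Kappa agreement between two categorical maps
#'
#' Builds the pixel confusion matrix (reference in rows, simulated in
#' columns; nodata excluded pairwise) and computes observed agreement
#' P0 = trace/total, chance agreement Pc = sum_i row_i * col_i / total², and
#' Kappa = (P0 - Pc) / (1 - Pc). When both maps are the same single class,
#' Pc = 1 and Kappa is reported as 1 with `degenerate = TRUE`.
#'
#' @param reference,simulated [land_grid()]s of identical shape and scheme.
#' @return An `agreement_report`: list with `confusion`, `p0`, `pc`, `kappa`,
#'   `degenerate`, `n_pixels`.
#' @examples
#' g <- land_grid(matrix(c(1, 1, 2, 2), 2, 2), 1000)
#' kappa_agreement(g, g)$kappa
#' @export
kappa_agreement <- function(reference, simulated) {
  ct <- cross_tabulate(reference, simulated)
  km2_per_px <- (attr(ct, "cell_size") / 1000)^2
  confusion <- unclass(ct) / km2_per_px
  names(dimnames(confusion)) <- c("reference", "simulated")
  rep <- kappa_from_confusion(confusion)
  rep$threshold_pass <- NULL # filled by agreement_pass() on demand
  rep
}

#' Kappa statistic from a confusion matrix
#'
#' @param confusion Square matrix of pixel counts, reference classes in rows
#'   and simulated classes in columns.
#' @return An `agreement_report` (see [kappa_agreement()]).
#' @examples
#' kappa_from_confusion(matrix(c(40, 20, 10, 30), 2, 2))$kappa # 0.40
#' @export
kappa_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion must be square")
  if (any(confusion < 0)) stop("confusion counts must be non-negative")
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  p0 <- sum(diag(confusion)) / total
  pc <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  degenerate <- pc >= 1 - 1e-12
  kappa <- if (degenerate) {
    if (p0 >= 1 - 1e-12) 1 else NA_real_
  } else {
    (p0 - pc) / (1 - pc)
  }
  structure(
    list(
      confusion = confusion, p0 = p0, pc = pc, kappa = kappa,
      degenerate = degenerate, n_pixels = total
    ),
    class = "agreement_report"
  )
}

#' Does an agreement report clear a Kappa threshold?
#'
#' The conventional acceptance standard for land-change simulations is
#' Kappa at least 0.70; the threshold is configurable.
#'
#' @param report An `agreement_report`.
#' @param threshold Minimum acceptable Kappa (default 0.70).
#' @return Logical.
#' @export
agreement_pass <- function(report, threshold = 0.70) {
  isTRUE(report$kappa >= threshold)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> n=%g  P0=%.4f  Pc=%.4f  kappa=%.4f%s\n",
    x$n_pixels, x$p0, x$pc, x$kappa,
    if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

#' Tidy the confusion matrix of an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return A tibble with `reference`, `simulated`, `pixels`.
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) {
  cm <- x$confusion
  nm_r <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  nm_c <- colnames(cm) %||% nm_r
  tibble::tibble(
    reference = rep(nm_r, times = ncol(cm)),
    simulated = rep(nm_c, each = nrow(cm)),
    pixels = as.vector(cm)
  )
}

#' One-row summary of an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return A one-row tibble with `n_pixels`, `p0`, `pc`, `kappa`,
#'   `degenerate`.
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(
    n_pixels = x$n_pixels, p0 = x$p0, pc = x$pc,
    kappa = x$kappa, degenerate = x$degenerate
  )
}
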
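#' Coefficient sensitivity (elasticity) of total ESV
#'
#' For each land-cover class k the class's entire coefficient column (all
#' service functions together) is scaled by (1 + delta), the total ESV is
#' recomputed, and the coefficient of sensitivity is the standard elasticity
#'
#'   CS_k = (relative change of total ESV) / (relative change of VC_k).
#'
#' Because the valuation is linear in the coefficients, CS_k equals class
#' k's signed share of total ESV and does not depend on delta; CS below 1
#' for every class means the total is robust (inelastic) to uncertainty in
#' any single class's coefficient.
#'
#' @param areas An `area_table`.
#' @param coeffs An `esv_coefficients` table.
#' @param delta Relative coefficient adjustment in (0, 1]; default 0.5
#'   (the conventional +/-50 percent test).
#' @inheritParams compute_esv
#' @return A `sensitivity_report` tibble with `class_name`,
#'   `esv_change_pct` (absolute percent change of the total under the
#'   adjustment), and `cs`; attribute `delta`.
#' @examples
#' coefficient_sensitivity(ntmez_area_table(1980), ntmez_coefficients())
#' @export
coefficient_sensitivity <- function(areas, coeffs, delta = 0.5,
                                    unit_convention = "tabulated") {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta > 1) {
    stop("`delta` must be in (0, 1]")
  }
  base <- compute_esv(areas, coeffs, unit_convention = unit_convention)
  total0 <- esv_total(base, raw = TRUE)
  if (total0 == 0) stop("total ESV is zero; sensitivity undefined")
  cs <- vapply(seq_along(coeffs$classes), function(k) {
    perturbed <- coeffs
    perturbed$vc[, k] <- perturbed$vc[, k] * (1 + delta)
    perturbed$totals <- colSums(perturbed$vc)
    total1 <- esv_total(
      compute_esv(areas, perturbed, unit_convention = unit_convention),
      raw = TRUE
    )
    ((total1 - total0) / total0) / delta
  }, numeric(1))
  structure(
    tibble::new_tibble(
      tibble::tibble(
        class_name = coeffs$classes,
        esv_change_pct = abs(cs) * delta * 100,
        cs = cs
      ),
      class = "sensitivity_report"
    ),
    delta = delta
  )
}
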
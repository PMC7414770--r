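test_that("equivalent factor is 1/7 of per-hectare grain value", {
  one <- tibble::tibble(
    crop = "rice", area_hm2 = 123,
    price_yuan_t = 7, yield_t_hm2 = 1
  )
  expect_equal(equivalent_factor(one), 1)

  two <- tibble::tibble(
    crop = c("wheat", "corn"), area_hm2 = c(60, 40),
    price_yuan_t = c(2000, 1000), yield_t_hm2 = c(3, 2)
  )
  expect_equal(equivalent_factor(two), (60 * 2000 * 3 + 40 * 1000 * 2) / 100 / 7)

  zero <- tibble::tibble(
    crop = "rice", area_hm2 = 0, price_yuan_t = 1, yield_t_hm2 = 1
  )
  expect_error(equivalent_factor(zero), "zero")
})

test_that("the bundled coefficient table is internally consistent", {
  co <- ntmez_coefficients()
  expect_equal(dim(co$vc), c(9, 6))
  # printed totals agree with exact column sums to the last printed digit(s)
  expect_true(all(abs(co$printed_totals - co$totals) <= 0.02))
  # built-up land carries only the two negative cost terms
  expect_true(all(co$vc[, "built-up land"] <= 0))
  expect_equal(sum(co$vc[, "built-up land"] < 0), 2)

  bad <- tibble::tibble(
    service = c("f1", "Total"),
    forestland = c(1, 5), grassland = c(1, 1), cropland = c(1, 1),
    `water body` = c(1, 1), `built-up land` = c(1, 1),
    `unutilized land` = c(1, 1)
  )
  expect_error(esv_coefficient_table(bad), "Total row")
})

test_that("per-class ESV reproduces the case-study accounting", {
  co <- ntmez_coefficients()
  r80 <- compute_esv(ntmez_area_table(1980), co)
  v <- round_half_up(r80$value)
  names(v) <- r80$class_name
  expect_equal(v[["grassland"]], 3.87)
  expect_equal(v[["built-up land"]], -0.08) # negative value is legal
  expect_equal(round_half_up(esv_total(r80)), 7.83)

  empty <- area_table(tibble::tibble(
    class_name = lulc_scheme()$names, area_km2 = 0
  ))
  expect_equal(esv_total(compute_esv(empty, co), raw = TRUE), 0)

  two_sch <- two_class_scheme()
  bad_areas <- area_table(
    tibble::tibble(class_name = c("a", "b"), area_km2 = 1),
    scheme = two_sch
  )
  expect_error(compute_esv(bad_areas, co), "missing")
})

test_that("per-function ESV is bilinear and sums to the class total", {
  co <- ntmez_coefficients()
  at <- ntmez_area_table(1980)
  f <- esv_by_function(at, co)
  expect_equal(
    round_half_up(f$value[f$service == "food production"]), 0.31
  )
  expect_equal(
    esv_total(f, raw = TRUE), esv_total(compute_esv(at, co), raw = TRUE),
    tolerance = 1e-12
  )

  # a one-class landscape with a zero coefficient contributes nothing
  solo <- area_table(tibble::tibble(
    class_name = lulc_scheme()$names,
    area_km2 = c(0, 0, 0, 0, 0, 100)
  ))
  fs <- esv_by_function(solo, co)
  expect_equal(fs$value_raw[fs$service == "gas regulation"], 0)

  # linear in areas: doubling areas doubles every value
  doubled <- area_table(tibble::tibble(
    class_name = at$class_name, area_km2 = at$area_km2 * 2
  ))
  expect_equal(
    esv_by_function(doubled, co)$value_raw, 2 * f$value_raw,
    tolerance = 1e-12
  )
})

test_that("the SI convention scales values by the km2->hm2 factor", {
  co <- ntmez_coefficients()
  at <- ntmez_area_table(1980)
  expect_equal(
    esv_total(compute_esv(at, co, unit_convention = "si"), raw = TRUE),
    100 * esv_total(compute_esv(at, co), raw = TRUE)
  )
})

test_that("zonal ESV matches hand-enumerated zones and adds up", {
  co <- ntmez_coefficients()
  # 2x4 lattice at 1 km cells; left zone {1,1,2,2}, right zone {3,3,3,4}
  g <- grid_from(c(1, 1, 3, 3, 2, 2, 3, 4), nrow = 2, cell_size = 1000)
  zones <- matrix(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), nrow = 2)
  z <- esv_by_zone(g, zones, co)
  per_zone <- dplyr::summarise(tibble::as_tibble(z),
    value_raw = sum(value_raw), .by = "zone"
  )
  expect_equal(
    per_zone$value_raw[per_zone$zone == 1],
    2 * co$totals[["forestland"]] + 2 * co$totals[["grassland"]]
  )
  expect_equal(
    per_zone$value_raw[per_zone$zone == 2],
    3 * co$totals[["cropland"]] + co$totals[["water body"]]
  )

  # single all-covering zone equals the global account
  whole <- esv_by_zone(g, matrix(1L, 2, 4), co)
  expect_equal(
    esv_total(whole, raw = TRUE),
    esv_total(compute_esv(tabulate_areas(g), co), raw = TRUE)
  )

  # additivity over a random 16-zone partition
  gl <- random_grid(64, 64, seed = 13)
  zl <- generate_zones(gl, 16)
  expect_equal(
    esv_total(esv_by_zone(gl, zl, co), raw = TRUE),
    esv_total(compute_esv(tabulate_areas(gl), co), raw = TRUE),
    tolerance = 1e-9
  )
  expect_error(esv_by_zone(gl, matrix(1L, 2, 2), co), "shape")
})

test_that("change rates reproduce the case-study area dynamics", {
  cr <- change_rate(ntmez_area_table(1980), ntmez_area_table(2030))
  pct <- round_half_up(cr$change_pct)
  names(pct) <- cr$category
  expect_equal(pct[["cropland"]], 34.38)
  expect_equal(pct[["built-up land"]], 196.66)

  same <- change_rate(ntmez_area_table(2010), ntmez_area_table(2010))
  expect_true(all(same$change_pct == 0))
})

test_that("zero starting values are flagged, not silently zeroed", {
  sch <- lulc_scheme()
  s <- area_table(tibble::tibble(class_name = sch$names, area_km2 = c(0, 1, 1, 1, 1, 1)))
  e <- area_table(tibble::tibble(class_name = sch$names, area_km2 = 1))
  cr <- change_rate(s, e)
  expect_true(is.na(cr$change_pct[cr$category == "forestland"]))
  expect_false(cr$defined[cr$category == "forestland"])
})

test_that("contribution shares sum to 100 and handle single categories", {
  co <- ntmez_coefficients()
  sh <- contribution_shares(compute_esv(ntmez_area_table(1980), co))
  expect_equal(sum(sh$share_pct), 100)
  expect_equal(
    round_half_up(sh$share_pct[sh$category == "grassland"]), 49.43
  )

  solo <- area_table(tibble::tibble(
    class_name = lulc_scheme()$names, area_km2 = c(0, 100, 0, 0, 0, 0)
  ))
  sh1 <- contribution_shares(compute_esv(solo, co))
  expect_equal(sh1$share_pct[sh1$category == "grassland"], 100)

  empty <- area_table(tibble::tibble(
    class_name = lulc_scheme()$names, area_km2 = 0
  ))
  expect_error(contribution_shares(compute_esv(empty, co)), "zero")
})

test_that("report rounding is half-up at the requested precision", {
  expect_equal(round_half_up(c(0.125, 0.135, -0.125), 2), c(0.13, 0.14, -0.13))
  expect_equal(round_half_up(2.675, 2), 2.68) # binary-representation trap
  df <- tibble::tibble(a = c(1.005, 2.0049), b = c("x", "y"))
  expect_equal(report_table(df)$a, c(1.01, 2.00))
  expect_equal(report_table(df, intermediate_digits = 3)$a, c(1.01, 2.01))
})
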
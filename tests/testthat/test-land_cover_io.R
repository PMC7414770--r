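test_that("ASCII grid round-trip preserves values and georeference", {
  g <- random_grid(50, 50, seed = 11, cell_size = 30)
  g$values[3, 7] <- g$scheme$nodata_code
  g$xllcorner <- 500000
  g$yllcorner <- 4.4e6
  path <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, path)
  g2 <- read_grid(path)
  expect_identical(g2$values, g$values)
  expect_equal(g2$cell_size, g$cell_size)
  expect_equal(g2$xllcorner, g$xllcorner)
  expect_equal(g2$yllcorner, g$yllcorner)
})

test_that("reading validates class codes against the scheme", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
    "cellsize 30", "NODATA_value -9999",
    "1 1 1", "1 1 1", "1 1 1"
  ), path)
  g <- read_grid(path)
  expect_equal(sum(g$values == 1), 9)

  writeLines(c(
    "ncols 2", "nrows 2", "cellsize 30",
    "1 99", "99 2"
  ), path)
  expect_error(read_grid(path), "99")
})

test_that("tabulate_areas converts pixel counts at the cell size", {
  v <- c(rep(1, 40), rep(2, 60))
  g <- grid_from(v, nrow = 10, cell_size = 1000)
  at <- tabulate_areas(g)
  expect_equal(at$area_km2[at$class_name == "forestland"], 40)
  expect_equal(attr(at, "total_km2"), 100)

  g2 <- grid_from(v, nrow = 10, cell_size = 100)
  at2 <- tabulate_areas(g2)
  expect_equal(at2$area_km2[1:2], c(0.4, 0.6))

  g_empty <- land_grid(matrix(-9999L, 4, 4), 30)
  expect_error(tabulate_areas(g_empty), "empty landscape")
})

test_that("tabulated proportions track sampling proportions at large n", {
  p <- c(0.4, 0.3, 0.2, 0.05, 0.02, 0.03)
  n <- 1e5
  g <- random_grid(250, 400, seed = 42, prob = p)
  at <- tabulate_areas(g)
  phat <- at$pixels / n # rows are in scheme (code) order
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(phat - p) <= 3 * se))
})

test_that("cross_tabulate counts transitions and honours conservation", {
  # hand-enumerated 2x2 example: [[1,1],[2,2]] -> [[1,2],[1,2]] at 1 km cells
  g1 <- grid_from(c(1, 1, 2, 2), nrow = 2, cell_size = 1000)
  g2 <- grid_from(c(1, 2, 1, 2), nrow = 2, cell_size = 1000)
  ct <- cross_tabulate(g1, g2)
  expect_equal(ct["forestland", "forestland"], 1)
  expect_equal(ct["forestland", "grassland"], 1)
  expect_equal(ct["grassland", "forestland"], 1)
  expect_equal(ct["grassland", "grassland"], 1)

  # no change => purely diagonal
  ct_same <- cross_tabulate(g1, g1)
  expect_equal(sum(ct_same) - sum(diag(ct_same)), 0)

  # marginals match the per-date area tables over the shared mask
  ga <- random_grid(100, 100, seed = 1)
  gb <- random_grid(100, 100, seed = 2)
  gb$values[1:5, 1:5] <- gb$scheme$nodata_code
  ctab <- cross_tabulate(ga, gb)
  mask <- ga$values != -9999 & gb$values != -9999
  expect_equal(unname(rowSums(ctab)), tabulate_areas(ga, mask)$area_km2)
  expect_equal(unname(colSums(ctab)), tabulate_areas(gb, mask)$area_km2)
})

test_that("cross_tabulate rejects mismatched grids", {
  g1 <- random_grid(10, 10, seed = 1)
  g2 <- random_grid(10, 11, seed = 1)
  expect_error(cross_tabulate(g1, g2), "shape")
  g3 <- random_grid(10, 10, seed = 1)
  g3$cell_size <- 60
  expect_error(cross_tabulate(g1, g3), "cell size")
})

test_that("area tables round-trip through CSV", {
  at <- tabulate_areas(random_grid(20, 20, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_area_table(at, path)
  at2 <- read_area_table(path)
  expect_equal(at2$area_km2, at$area_km2)
  expect_equal(at2$class_name, at$class_name)
})
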
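test_that("degenerate proportions give a constant grid", {
  spec <- landscape_spec(
    shape = c(10, 10),
    class_proportions = c(1, 0, 0, 0, 0, 0), seed = 1
  )
  g <- generate_initial(spec)
  expect_true(all(g$values == 1))
  expect_error(
    landscape_spec(class_proportions = c(1.2, -0.2, 0, 0, 0, 0)),
    "non-negative"
  )
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- landscape_spec(shape = c(50, 50), seed = 33, autocorrelation = 1)
  expect_identical(
    generate_initial(spec)$values,
    generate_initial(spec)$values
  )
  g <- generate_initial(spec)
  a <- persistence_matrix(d = 0.85)
  expect_identical(
    evolve(g, a, seed = 9)$values,
    evolve(g, a, seed = 9)$values
  )
})

test_that("i.i.d. draws hit the target mix within binomial error", {
  p <- c(0.11, 0.04, 0.43, 0.03, 0.01, 0.38) # approximate 1980 NTMEZ mix
  spec <- landscape_spec(
    shape = c(250, 400), class_proportions = p, seed = 2
  )
  at <- tabulate_areas(generate_initial(spec))
  phat <- at$pixels / 1e5
  expect_true(all(abs(phat - p) <= 3 * sqrt(p * (1 - p) / 1e5)))
})

test_that("autocorrelation produces contiguous patches", {
  p <- rep(1 / 6, 6)
  smooth <- generate_initial(landscape_spec(
    shape = c(80, 80), class_proportions = p, seed = 3, autocorrelation = 2
  ))
  rough <- generate_initial(landscape_spec(
    shape = c(80, 80), class_proportions = p, seed = 3
  ))
  agree <- function(g) {
    v <- g$values
    mean(v[, -1] == v[, -ncol(v)]) # horizontal neighbour agreement
  }
  expect_gt(agree(smooth), agree(rough) + 0.2)
})

test_that("evolve follows the prescribed transition rows", {
  a <- persistence_matrix(d = 0.95)
  spec <- landscape_spec(
    shape = c(250, 400), seed = 5,
    class_proportions = rep(1 / 6, 6)
  )
  g0 <- generate_initial(spec)
  expect_identical(evolve(g0, diag(6), seed = 1)$values, g0$values)

  g1 <- evolve(g0, a, seed = 6)
  ct <- cross_tabulate(g0, g1)
  freq <- unclass(ct) / rowSums(unclass(ct))
  n_i <- rowSums(unclass(ct)) / (spec$cell_size / 1000)^2
  se <- sqrt(a * (1 - a) / n_i) # binomial SE per row
  expect_true(all(abs(freq - a) <= 3 * se + 1e-12))
})

test_that("estimated probabilities recover the generating matrix", {
  a <- persistence_matrix(d = 0.9)
  spec <- landscape_spec(
    shape = c(250, 400), seed = 7,
    class_proportions = c(0.25, 0.2, 0.2, 0.15, 0.1, 0.1)
  )
  g0 <- generate_initial(spec)
  g1 <- evolve(g0, a, seed = 8)
  a_hat <- estimate_probabilities(cross_tabulate(g0, g1))
  expect_lt(max(abs(unclass(a_hat) - a)), 0.02)
})

test_that("zones tile the lattice evenly and exhaustively", {
  z1 <- generate_zones(landscape_spec(shape = c(7, 9), n_zones = 1))
  expect_true(all(z1 == 1))

  spec <- landscape_spec(shape = c(400, 400), n_zones = 16)
  z <- generate_zones(spec)
  expect_equal(sort(unique(as.vector(z))), 1:16)
  expect_true(all(table(z) == 100 * 100))
  expect_equal(length(z), 400 * 400)
  expect_error(generate_zones(spec, n_zones = 1e7), "pixel count")
})
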
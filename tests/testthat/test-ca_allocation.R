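test_that("neighbourhood suitability is the windowed class fraction", {
  # uniform map: own class 1 everywhere, others 0
  g <- grid_from(rep(2, 16), nrow = 4)
  s <- neighborhood_suitability(g, ca_params(kernel_radius = 1))
  expect_true(all(s[["grassland"]] == 1))
  expect_true(all(s[["forestland"]] == 0))

  # 3x3 with 4 of 9 pixels class 2: centre fraction 4/9
  g2 <- grid_from(c(2, 2, 1, 2, 2, 1, 1, 1, 1), nrow = 3)
  s2 <- neighborhood_suitability(g2, ca_params(kernel_radius = 1))
  expect_equal(s2[["grassland"]][2, 2], 4 / 9)
  expect_equal(s2[["forestland"]][2, 2], 5 / 9)

  # class fractions partition every window
  g3 <- random_grid(20, 20, seed = 9)
  s3 <- neighborhood_suitability(g3, ca_params(kernel_radius = 2))
  expect_equal(Reduce(`+`, s3), matrix(1, 20, 20))
})

test_that("suitability is monotone in neighbourhood density", {
  g <- random_grid(9, 9, seed = 21)
  p <- ca_params(kernel_radius = 2)
  before <- neighborhood_suitability(g, p)[["cropland"]][5, 5]
  g$values[5, 6] <- 3L # add one cropland neighbour
  after <- neighborhood_suitability(g, p)[["cropland"]][5, 5]
  expect_gte(after, before)
})

test_that("identity dynamics leave the map unchanged", {
  g <- random_grid(40, 40, seed = 4)
  a <- transition_matrix(diag(6))
  out <- allocate(g, a, steps = 3, params = ca_params(seed = 17))
  expect_identical(out$values, g$values)
})

test_that("realised class counts equal the largest-remainder quotas", {
  g <- random_grid(100, 100, seed = 8)
  set.seed(31)
  a <- transition_matrix(t(apply(
    matrix(rexp(36), 6, 6) + 5 * diag(6), 1,
    function(r) r / sum(r)
  )))
  counts <- table(factor(g$values, levels = 1:6))
  quotas <- largest_remainder(as.vector(counts %*% unclass(a)), 10000)
  out <- allocate(g, a, steps = 1, params = ca_params(seed = 2))
  realised <- as.vector(table(factor(out$values, levels = 1:6)))
  expect_identical(realised, as.integer(quotas))
})

test_that("allocation is deterministic under a fixed seed", {
  g <- random_grid(50, 50, seed = 12)
  a <- transition_matrix(persistence_matrix(d = 0.8))
  o1 <- allocate(g, a, params = ca_params(seed = 5))
  o2 <- allocate(g, a, params = ca_params(seed = 5))
  o3 <- allocate(g, a, params = ca_params(seed = 6))
  expect_identical(o1$values, o2$values)
  # different seed: identical class areas, map may differ
  expect_equal(
    tabulate_areas(o3)$area_km2,
    tabulate_areas(o1)$area_km2
  )
})

test_that("largest_remainder apportions exactly", {
  q <- largest_remainder(c(1.4, 1.4, 1.2), 4)
  expect_equal(sum(q), 4)
  expect_equal(q, c(2L, 1L, 1L))
  expect_equal(largest_remainder(c(0, 0), 0), c(0L, 0L))
  expect_error(largest_remainder(c(0, 0), 3), "all-zero")
})

test_that("run_prediction chains calibration into aligned horizons", {
  g <- random_grid(40, 40, seed = 14)
  sims <- run_prediction(g, g, c(2005, 2010), c(2015, 2020))
  expect_named(sims, c("2015", "2020"))
  expect_identical(sims[["2020"]]$values, g$values)

  expect_error(
    run_prediction(g, g, c(2005, 2010), 2017),
    "not aligned"
  )
  expect_error(run_prediction(g, g, c(2010, 2005), 2020), "increasing")
  expect_error(run_prediction(g, g, c(2005, 2010), 2008), "after")
})

test_that("simulated maps beat a random-marginal baseline on persistent dynamics", {
  a_true <- persistence_matrix(d = 0.92)
  spec <- landscape_spec(
    shape = c(80, 80), seed = 3, autocorrelation = 1,
    class_proportions = c(0.2, 0.3, 0.2, 0.1, 0.1, 0.1)
  )
  g0 <- generate_initial(spec)
  g1 <- evolve(g0, a_true, seed = 4)
  truth <- evolve(g1, a_true, seed = 5)
  sim <- run_prediction(g0, g1, c(0, 5), 10, params = ca_params(seed = 6))[[1]]
  k_sim <- kappa_agreement(truth, sim)$kappa

  # permutation baseline: same marginals, randomised locations
  set.seed(7)
  k_null <- replicate(10, {
    shuf <- sim
    shuf$values[] <- sample(sim$values)
    kappa_agreement(truth, shuf)$kappa
  })
  expect_gt(k_sim, max(k_null))
})
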
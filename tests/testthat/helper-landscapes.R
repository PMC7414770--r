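# shared fixtures: tiny grids and matrices built in code

grid_from <- function(v, nrow, cell_size = 1000, scheme = lulc_scheme()) {
  land_grid(matrix(as.integer(v), nrow = nrow, byrow = TRUE),
    cell_size = cell_size, scheme = scheme
  )
}

random_grid <- function(nr, nc, seed, cell_size = 100,
                        scheme = lulc_scheme(),
                        prob = rep(1 / 6, 6)) {
  set.seed(seed)
  v <- sample(scheme$codes, nr * nc, replace = TRUE, prob = prob)
  land_grid(matrix(v, nr, nc), cell_size = cell_size, scheme = scheme)
}

# strong-persistence row-stochastic matrix: diagonal d, rest uniform
persistence_matrix <- function(n = 6, d = 0.9) {
  m <- matrix((1 - d) / (n - 1), n, n)
  diag(m) <- d
  m
}

two_class_scheme <- function() {
  category_scheme(1:2, c("a", "b"))
}
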
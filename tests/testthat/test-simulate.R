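test_that("grid coordinates enumerate the lattice in row-major order", {
  expect_equal(nrow(make_grid_coords(36)), 1296)
  expect_equal(unname(make_grid_coords(2)),
               matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L), 4, 2, byrow = TRUE))
  g5 <- make_grid_coords(5)
  expect_equal(nrow(g5), 25)
  expect_equal(nrow(unique(g5)), 25)
  expect_equal(max(g5), 4)
  expect_error(make_grid_coords(1), "grid_side")
})

test_that("pattern libraries have the stated disjointness/overlap structure", {
  gg <- pattern_library("ggblocks")
  cp <- crossprod(gg$factors)
  expect_equal(ncol(gg$factors), 4)
  expect_true(all(cp[upper.tri(cp)] == 0))      # pairwise disjoint
  expect_true(all(colSums(gg$factors) > 0))

  q <- pattern_library("quilt")
  cpq <- crossprod(q$factors)
  expect_equal(ncol(q$factors), 4)
  expect_true(any(cpq[upper.tri(cpq)] > 0))     # overlapping patches
  # every quilt pattern overlaps at least one other
  diag(cpq) <- 0
  expect_true(all(rowSums(cpq) > 0))

  both <- pattern_library("both")
  expect_equal(ncol(both$factors), 8)
  expect_equal(both$factors, cbind(gg$factors, q$factors))
  expect_error(pattern_library("nope"), "arg")
})

test_that("scenario I produces the stated mean structure and conservation", {
  sim <- simulate_scenario1("quilt", n_features = 200, seed = 7)
  expect_equal(dim(sim$data$Y), c(1296, 200))
  vals <- sort(unique(as.numeric(sim$truth$mean_matrix)))
  expect_equal(vals, c(0.2, 20.2))
  # each loading row is one-hot with weight 20
  expect_true(all(rowSums(sim$truth$W > 0) == 1))
  expect_true(all(sim$truth$W[sim$truth$W > 0] == 20))
  # conservation: column sums of the mean matrix
  active <- colSums(sim$truth$F)
  assigned <- apply(sim$truth$W, 1, which.max)
  expect_equal(colSums(sim$truth$mean_matrix),
               unname(0.2 * 1296 + 20 * active[assigned]))
})

test_that("simulations are reproducible and seeded", {
  a <- simulate_scenario1("ggblocks", n_features = 5, seed = 11)
  b <- simulate_scenario1("ggblocks", n_features = 5, seed = 11)
  expect_identical(a$data$Y, b$data$Y)
  expect_identical(a$truth$W, b$truth$W)
  c <- simulate_scenario1("ggblocks", n_features = 5, seed = 12)
  expect_false(identical(a$data$Y, c$data$Y))
})

test_that("scenario II split and mixed loading structures match their design", {
  sp <- simulate_scenario2("quilt", "split", n_features = 500, seed = 3)
  expect_equal(ncol(sp$truth$H), 3)
  expect_true(all(sp$truth$H %in% c(0, 1)))
  # exactly half the features have all-zero nonspatial loadings
  expect_equal(sum(rowSums(sp$truth$V) == 0), 250)
  expect_equal(sum(rowSums(sp$truth$W) == 0), 250)
  # true scores sit at the poles
  sc <- sp$truth$true_gene_scores
  expect_true(all(sc > 0.9 | sc < 0.1))
  expect_equal(sc[1:250], rep(1, 250))
  expect_equal(sc[251:500], rep(0, 250))

  mx <- simulate_scenario2("quilt", "mixed", n_features = 500, seed = 3)
  expect_true(all(rowSums(mx$truth$W > 0) == 1))
  expect_true(all(mx$truth$W[mx$truth$W > 0] == 12))
  expect_true(all(rowSums(mx$truth$V > 0) == 1))
  expect_true(all(mx$truth$V[mx$truth$V > 0] == 8))
  expect_equal(mx$truth$mean_matrix,
               0.2 + mx$truth$F %*% t(mx$truth$W) + mx$truth$H %*% t(mx$truth$V))
  both <- simulate_scenario2("both", "mixed", n_features = 20, seed = 1)
  expect_equal(ncol(both$truth$H), 6)
  expect_error(simulate_scenario2("quilt", "split", n_features = 9),
               "even")
})

test_that("negative binomial sampler matches its moments", {
  mu <- matrix(20.2, 200, 500)
  y <- draw_negative_binomial(mu, shape = 10, seed = 1)
  expect_equal(mean(y), 20.2, tolerance = 0.01)
  # Var = mu + mu^2 / shape = 61.004, within 5% over 1e5 draws
  expect_equal(stats::var(as.numeric(y)), 61.004, tolerance = 0.05)
  # Poisson limit: huge shape, background mean
  y0 <- draw_negative_binomial(matrix(0.2, 36, 36), shape = 1e8, seed = 4)
  expect_equal(mean(y0), 0.2, tolerance = 0.1)
  expect_equal(stats::var(as.numeric(y0)), 0.2, tolerance = 0.1)
  # determinism and input validation
  expect_identical(draw_negative_binomial(mu[1:5, 1:5], 10, seed = 2),
                   draw_negative_binomial(mu[1:5, 1:5], 10, seed = 2))
  expect_error(draw_negative_binomial(matrix(-1, 2, 2), 10), "positive")
  expect_error(draw_negative_binomial(mu[1:2, 1:2], 0), "shape")
})
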
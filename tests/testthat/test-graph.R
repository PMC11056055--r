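# Adjacency structures, Leroux precision, CAR densities, Moran's I.

test_that("leroux_precision reproduces hand-computed matrices and edge cases", {
  g2 <- spatial_graph(rbind(c(0, 1), c(1, 0)))
  expect_equal(unname(leroux_precision(g2, 0)), diag(2))
  expect_equal(unname(leroux_precision(g2, 0.5)),
               rbind(c(1, -0.5), c(-0.5, 1)))
  path3 <- spatial_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  Q1 <- leroux_precision(path3, 1)
  expect_equal(unname(Q1), rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  expect_equal(unname(rowSums(Q1)), rep(0, 3))  # intrinsic limit is singular
  expect_error(leroux_precision(g2, 1.2), "rho")
  expect_error(spatial_graph(rbind(c(0, 1), c(0, 0))), "symmetric")
  expect_error(spatial_graph(rbind(c(1, 1), c(1, 0))), "diagonal")
  expect_error(spatial_graph(rbind(c(0, 2), c(2, 0))), "0 or 1")
})

test_that("leroux_precision is positive definite with eigenvalues >= 1 - rho", {
  set.seed(11)
  for (i in 1:20) {
    g <- random_graph(sample(2:20, 1))
    rho <- runif(1, 0, 0.999)
    ev <- eigen(leroux_precision(g, rho), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), 1 - rho - 1e-10)
  }
})

test_that("CAR full conditional matches the printed formula and edge cases", {
  g <- spatial_graph(rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0)))
  phi <- c(0, 1, 3)
  fc0 <- car_full_conditional(1, phi, car_params(0, 2), g)
  expect_equal(fc0$mean, 0)
  expect_equal(fc0$variance, 2)
  fc1 <- car_full_conditional(1, phi, car_params(1, 1), g)
  expect_equal(fc1$mean, 2)           # neighbours (1, 3)
  expect_equal(fc1$variance, 1 / 2)
  # isolated node: denominator collapses to 1 - rho
  giso <- spatial_graph(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  fci <- car_full_conditional(3, phi, car_params(0.5, 1), giso)
  expect_equal(fci$mean, 0)
  expect_equal(fci$variance, 2)
  expect_error(car_full_conditional(4, phi, car_params(0.5, 1), g), "out of range")
})

test_that("CAR conditionals agree with the Schur-complement oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    g <- random_graph(n)
    rho <- runif(1, 0.05, 0.95)
    k2 <- runif(1, 0.2, 3)
    phi <- rnorm(n)
    P <- leroux_precision(g, rho) / k2
    for (i in seq_len(n)) {
      fc <- car_full_conditional(i, phi, car_params(rho, k2), g)
      expect_equal(fc$variance, 1 / P[i, i], tolerance = 1e-8)
      expect_equal(fc$mean, -sum(P[i, -i] * phi[-i]) / P[i, i], tolerance = 1e-8)
    }
  }
})

test_that("CAR joint log density matches a dense multivariate-normal oracle", {
  g2 <- spatial_graph(rbind(c(0, 1), c(1, 0)))
  expect_equal(car_log_density(c(0, 0), car_params(0, 1), g2), -log(2 * pi))
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(2:8, 1)
    g <- random_graph(n)
    rho <- runif(1, 0, 0.95)
    k2 <- runif(1, 0.2, 4)
    phi <- rnorm(n)
    Sigma <- k2 * solve(leroux_precision(g, rho))
    expect_equal(car_log_density(phi, car_params(rho, k2), g),
                 drop(dense_mvn_logpdf(phi, Sigma)), tolerance = 1e-8)
  }
  # determinant scaling identity at the origin
  g <- random_graph(5)
  d1 <- car_log_density(rep(0, 5), car_params(0.4, 1), g)
  d4 <- car_log_density(rep(0, 5), car_params(0.4, 4), g)
  expect_equal(d1 - d4, (5 / 2) * log(4), tolerance = 1e-10)
  expect_error(car_log_density(rep(0, 5), car_params(1, 1), g), "improper")
})

test_that("Moran's I matches direct evaluation and is affine invariant", {
  g2 <- spatial_graph(rbind(c(0, 1), c(1, 0)))
  expect_equal(morans_i(c(1, -1), g2), -1)
  cyc4 <- spatial_graph(rbind(c(0, 1, 0, 1), c(1, 0, 1, 0),
                              c(0, 1, 0, 1), c(1, 0, 1, 0)))
  expect_equal(morans_i(c(1, -1, 1, -1), cyc4), -1)
  expect_error(morans_i(rep(2, 2), g2), "zero variance")
  edgeless <- spatial_graph(matrix(0, 3, 3))
  expect_error(morans_i(c(1, 2, 3), edgeless), "no edges")
  set.seed(41)
  g <- random_graph(9)
  x <- rnorm(9)
  i0 <- morans_i(x, g)
  expect_equal(morans_i(2.5 * x - 7, g), i0, tolerance = 1e-12)
  expect_equal(morans_i(-0.3 * x + 2, g), i0, tolerance = 1e-12)
})

test_that("temporal adjacency is the tridiagonal lag-one structure", {
  expect_equal(temporal_adjacency(3)$A,
               rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(temporal_adjacency(1)$A, matrix(0, 1, 1))
  expect_equal(temporal_adjacency(5)$degrees, c(1, 2, 2, 2, 1))
  expect_error(temporal_adjacency(0), "positive")
})

test_that("adjacency CSV and edge-list round trips preserve the graph", {
  set.seed(51)
  g <- random_graph(7)
  f <- tempfile(fileext = ".csv")
  write_adjacency(g, f)
  g2 <- read_adjacency(f)
  expect_equal(g2$A, g$A)
  edges <- which(upper.tri(g$A) & g$A == 1, arr.ind = TRUE)
  df <- data.frame(from = g$ids[edges[, 1]], to = g$ids[edges[, 2]])
  g3 <- adjacency_from_edges(df, ids = g$ids)
  expect_equal(g3$A, g$A)
  unlink(f)
})
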
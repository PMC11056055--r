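# Synthetic-data generator: equicorrelated noise, covariates, truncated
# counts, adjacency from coordinates, splits, IO.

test_that("equicorrelation matrices have the compound-symmetry structure", {
  expect_equal(equicorrelation_matrix(3, 0.05),
               rbind(c(1, .05, .05), c(.05, 1, .05), c(.05, .05, 1)))
  expect_equal(equicorrelation_matrix(6, 0), diag(6))
  ev <- eigen(equicorrelation_matrix(54, 0.95), only.values = TRUE)$values
  expect_equal(min(ev), 0.05, tolerance = 1e-10)
  expect_error(equicorrelation_matrix(3, 1), "\\[0, 1\\)")
  expect_error(equicorrelation_matrix(3, -0.1), "\\[0, 1\\)")
})

test_that("generated noise is reproducible and matches the target correlation", {
  scen <- scenario(0.95, 0.05, n_units = 8, n_times = 6, seed = 5)
  set.seed(5); n1 <- generate_noise(scen)
  set.seed(5); n2 <- generate_noise(scen)
  expect_identical(n1, n2)
  # sampling check against the target equicorrelation covariance
  set.seed(99)
  reps <- 20000
  SP <- matrix(NA_real_, reps, 8)
  TM <- matrix(NA_real_, reps, 6)
  for (r in seq_len(reps)) {
    z <- generate_noise(scen)
    SP[r, ] <- z$spatial
    TM[r, ] <- z$temporal
  }
  expect_lt(max(abs(cov(SP) - equicorrelation_matrix(8, 0.95))), 0.05)
  expect_lt(max(abs(cov(TM) - equicorrelation_matrix(6, 0.05))), 0.05)
  off_sp <- cor(SP)[upper.tri(diag(8))]
  off_tm <- cor(TM)[upper.tri(diag(6))]
  expect_equal(mean(off_sp), 0.95, tolerance = 0.02)
  expect_equal(mean(off_tm), 0.05, tolerance = 0.02)
})

test_that("covariates are exactly orthogonal and standardized with unit VIF", {
  set.seed(3)
  X <- generate_covariates(54, 20, 10)
  expect_equal(dim(X), c(1080, 10))
  expect_lt(max(abs(colMeans(X))), 1e-10)
  expect_lt(max(abs(apply(X, 2, sd) - 1)), 1e-10)
  expect_equal(unname(compute_vif(X)), rep(1, 10), tolerance = 1e-6)
  X1 <- generate_covariates(10, 4, 1)
  expect_equal(unname(compute_vif(X1)), 1)
  expect_error(generate_covariates(3, 3, 9), "smaller")
})

test_that("VIF matches the closed form for correlated pairs and flags collinearity", {
  set.seed(13)
  U <- generate_covariates(30, 4, 2)  # exactly orthonormal standardized pair
  x1 <- U[, 1]
  x2 <- 0.8 * U[, 1] + 0.6 * U[, 2]  # sample correlation with x1 exactly 0.8
  v <- compute_vif(cbind(x1, x2))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-8)
  expect_warning(vdup <- compute_vif(cbind(x1, x1)), "collinearity")
  expect_true(all(is.infinite(vdup)))
})

test_that("k-nearest-neighbour adjacency is symmetric with correct edges", {
  coords <- cbind(c(0, 1, 2), c(0, 0, 0))
  g <- build_knn_adjacency(coords, k = 1)
  expect_equal(unname(g$A), rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  set.seed(23)
  co <- matrix(rnorm(24), 12, 2)
  g2 <- build_knn_adjacency(co, k = 4)
  expect_true(isSymmetric(unname(g2$A)))
  expect_true(all(diag(g2$A) == 0))
  gc <- build_knn_adjacency(co, k = 11)
  expect_equal(unname(gc$A), 1 - diag(12))
  expect_error(build_knn_adjacency(co, k = 0), "k must")
  expect_error(build_knn_adjacency(co, k = 12), "k must")
})

test_that("zero-truncated Poisson draws are positive with the truncated mean", {
  set.seed(33)
  y <- rztpois(rep(1, 200000))
  expect_gte(min(y), 1)
  expect_equal(mean(y), 1 / (1 - exp(-1)), tolerance = 0.01)  # 1.582
  ysmall <- rztpois(rep(0.01, 5000))
  expect_gte(min(ysmall), 1)
  expect_error(rztpois(c(1, -1)), "positive")
})

test_that("generate_panel honors dimensions, positivity and the latent decomposition", {
  scen <- scenario(0.45, 0.85, seed = 9)  # study dimensions 54 x 20
  panel <- generate_panel(scen)
  expect_equal(length(panel$y), 1080)
  expect_gte(min(panel$y), 1)
  expect_true(all(is.finite(panel$lambda)) && all(panel$lambda > 0))
  # spatial term constant over time, temporal term constant over units
  recomposed <- exp(outer(panel$spatial_term, rep(1, 20)) +
                    outer(rep(1, 54), panel$temporal_term))
  expect_equal(panel$lambda, recomposed, tolerance = 1e-12)
  # bit-for-bit reproducibility under the scenario seed
  panel2 <- generate_panel(scen)
  expect_identical(panel$y, panel2$y)
  expect_identical(panel$X, panel2$X)
  expect_identical(panel$graph$A, panel2$graph$A)
  # covariate columns standardized over all records
  expect_lt(max(abs(colMeans(panel$X))), 1e-10)
  expect_lt(max(abs(apply(panel$X, 2, sd) - 1)), 1e-10)
})

test_that("train/test splits have the stated sizes and partition the records", {
  panel <- generate_panel(scenario(0.5, 0.5, 54, 20, seed = 2))
  set.seed(7); sp <- train_test_split(panel, 0.7)
  expect_length(sp$train_index, 756)
  expect_length(sp$test_index, 324)
  expect_setequal(c(sp$train_index, sp$test_index), seq_len(1080))
  set.seed(7); sp2 <- train_test_split(panel, 0.7)
  expect_identical(sp, sp2)
  small <- list(y = matrix(1, 2, 5))
  set.seed(1)
  s55 <- train_test_split(small, 0.5)
  expect_length(s55$train_index, 5)
  expect_length(s55$test_index, 5)
})

test_that("panel CSV round trip preserves counts, offsets and covariates", {
  panel <- generate_panel(scenario(0.25, 0.65, 8, 5, seed = 4), p = 3)
  f <- tempfile(fileext = ".csv")
  write_panel(panel, f)
  back <- read_panel(f)
  expect_equal(back$y, panel$y)
  expect_equal(back$offset, panel$offset)
  expect_equal(unname(back$X), unname(panel$X))
  expect_equal(back$scenario$sp, 0.25)
  expect_equal(back$scenario$seed, 4L)
  unlink(c(f, paste0(f, ".json")))
})
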
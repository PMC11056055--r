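# Linear predictors, likelihood, priors, posterior, and agreement between
# the R reference implementation and the C++ gradient backend.

zero_state <- function(model, data) {
  fl <- ns$state_fields(model, data$N, data$T, data$p)
  st <- lapply(names(fl), function(nm) {
    if (startsWith(nm, "rho")) rep(0.5, fl[[nm]])
    else if (startsWith(nm, "k2")) rep(1, fl[[nm]])
    else rep(0, fl[[nm]])
  })
  setNames(st, names(fl))
}

test_that("linear predictors reduce correctly in degenerate configurations", {
  fx <- tiny_panel(N = 5, Tt = 5)
  d <- fx$data
  for (model in st_models()) {
    st <- zero_state(model, d)
    expect_equal(linear_predictor(model, st, d), d$offset, info = model)
  }
  # SPLTM slope terms vanish at t = tbar = (T+1)/2 (T = 5 -> t = 3)
  st <- zero_state("SPLTM", d)
  st$omega1 <- 0.7; st$omega2 <- 5; st$b <- rnorm(5); st$a <- rnorm(5)
  lmu <- linear_predictor("SPLTM", st, d)
  expect_equal(lmu[, 3], d$offset[, 3] + 0.7 + st$a)
  # SPAM additive arithmetic
  st2 <- zero_state("SPAM", d)
  st2$a <- rep(1, 5); st2$b <- rep(2, 5); st2$c <- rep(3, 25)
  expect_equal(linear_predictor("SPAM", st2, d),
               d$offset + 6)
  expect_error(linear_predictor("SPAM", zero_state("TMS", d), d), "mismatch")
})

test_that("Poisson pointwise log likelihood matches direct evaluation", {
  g1 <- spatial_graph(matrix(0, 1, 1))
  d <- panel_data(matrix(1L, 1, 1), matrix(0, 1, 1), g1)
  st <- zero_state("TMS", d)       # mu = 1, y = 1
  ll <- log_likelihood(st, d, "TMS")
  expect_equal(ll$total, -1)
  d2 <- panel_data(matrix(2L, 1, 1), matrix(0, 1, 1), g1)
  st$a <- log(2)                   # mu = 2, y = 2
  expect_equal(log_likelihood(st, d2, "TMS")$total, log(2) - 2, tolerance = 1e-12)
  st$a <- -Inf                     # mu -> 0 with positive count
  expect_equal(log_likelihood(st, d2, "TMS")$total, -Inf)
})

test_that("priors cover supports, factorizations and the iid interaction term", {
  fx <- tiny_panel(N = 4, Tt = 3)
  d <- fx$data
  pr <- prior_config()
  # SPAM with zero interaction and unit variance: the interaction block
  # contributes exactly -(N*T/2) log(2*pi)
  st <- zero_state("SPAM", d)
  st$a <- rnorm(4); st$b <- rnorm(3); st$k2_I <- 1
  base <- car_log_density(st$a, car_params(0.5, 1), d$graph) +
    car_log_density(st$b, car_params(0.5, 1), d$tgraph) +
    sum(vapply(c(st$k2_s, st$k2_T, st$k2_I), ns$dinvgamma_log, numeric(1),
               shape = pr$ig_shape, scale = pr$ig_scale))
  expect_equal(log_prior(st, pr, "SPAM", d) - base, -(4 * 3 / 2) * log(2 * pi),
               tolerance = 1e-10)
  # TMS with rho_T ~ 0 factorizes into independent CAR terms per time slice
  stt <- zero_state("TMS", d)
  stt$a <- rnorm(12); stt$rho_T <- 1e-9
  A <- matrix(stt$a, 4, 3)
  indep <- sum(vapply(1:3, function(t)
    car_log_density(A[, t], car_params(0.5, 1), d$graph), numeric(1))) +
    ns$dinvgamma_log(1, pr$ig_shape, pr$ig_scale)
  expect_equal(log_prior(stt, pr, "TMS", d), indep, tolerance = 1e-6)
  # outside the support
  stv <- zero_state("STSM", d); stv$k2 <- -1
  expect_equal(log_prior(stv, pr, "STSM", d), -Inf)
  str <- zero_state("SPLTM", d); str$rho_int <- 1.2
  expect_equal(log_prior(str, pr, "SPLTM", d), -Inf)
})

test_that("log posterior is likelihood plus prior and permutation invariant", {
  fx <- tiny_panel(N = 4, Tt = 4, p = 2, seed = 17)
  d <- fx$data
  pr <- prior_config()
  set.seed(61)
  for (model in st_models()) {
    st <- zero_state(model, d)
    for (nm in names(st))
      if (!startsWith(nm, "rho") && !startsWith(nm, "k2"))
        st[[nm]] <- rnorm(length(st[[nm]]), 0, 0.3)
    expect_equal(log_posterior(st, d, pr, model),
                 log_likelihood(st, d, model)$total + log_prior(st, pr, model, d),
                 tolerance = 1e-12, info = model)
  }
  # permuting units consistently leaves the posterior unchanged
  perm <- c(3, 1, 4, 2)
  gperm <- spatial_graph(d$graph$A[perm, perm])
  Xm <- array(d$X, c(4, 4, 2))
  Xp <- array(Xm[perm, , ], c(4, 4, 2)); dim(Xp) <- c(16, 2)
  dp <- panel_data(d$y[perm, ], Xp, gperm, offset = d$offset[perm, ])
  st <- zero_state("SPAM", d)
  set.seed(62)
  st$a <- rnorm(4); st$b <- rnorm(4); st$c <- rnorm(16); st$beta <- rnorm(2)
  stp <- st
  stp$a <- st$a[perm]
  stp$c <- as.vector(matrix(st$c, 4, 4)[perm, ])
  expect_equal(log_posterior(stp, dp, pr, "SPAM"),
               log_posterior(st, d, pr, "SPAM"), tolerance = 1e-10)
  # improving mu toward y increases the posterior on a one-cell panel
  g1 <- spatial_graph(matrix(0, 1, 1))
  d1 <- panel_data(matrix(5L, 1, 1), matrix(0, 1, 1), g1)
  s1 <- zero_state("TMS", d1)
  s1$a <- log(2); lp_far <- log_posterior(s1, d1, pr, "TMS")
  s1$a <- log(5); lp_near <- log_posterior(s1, d1, pr, "TMS")
  expect_gt(lp_near, lp_far)
})

test_that("C++ backend agrees with the R reference and with finite differences", {
  fx <- tiny_panel(N = 5, Tt = 4, p = 2, seed = 29)
  d <- fx$data
  pr <- prior_config()
  set.seed(71)
  for (model in st_models()) {
    st <- initialize_state(model, d, pr)
    th0 <- ns$to_unconstrained(st, model, d)
    th <- th0 + rnorm(length(th0), 0, 0.25)
    cd <- ns$build_cdata(model, d, pr)
    res <- ns$cpp_lp_grad(cd, th)
    s <- ns$from_unconstrained(th, model, d)
    rhos <- unlist(s[ns$rho_names(model)])
    vars <- unlist(s[ns$var_names(model)])
    jac <- sum(log(rhos) + log(1 - rhos)) + sum(log(vars))
    expect_equal(res$value, log_posterior(s, d, pr, model) + jac,
                 tolerance = 1e-8, info = model)
    ng <- num_grad(function(t) ns$cpp_lp_grad(cd, t)$value, th)
    expect_equal(drop(res$grad), ng, tolerance = 1e-4, info = model)
  }
})

test_that("recentering folds effect means into levels without changing fit", {
  fx <- tiny_panel(N = 5, Tt = 4, p = 2, seed = 37)
  d <- fx$data
  set.seed(81)
  for (model in c("SPLTM", "SPAM")) {
    st <- zero_state(model, d)
    for (nm in names(st))
      if (!startsWith(nm, "rho") && !startsWith(nm, "k2"))
        st[[nm]] <- rnorm(length(st[[nm]]), 1, 0.5)
    rc <- ns$recenter_draw(st, model)
    expect_equal(linear_predictor(model, rc, d),
                 linear_predictor(model, st, d), tolerance = 1e-12, info = model)
    expect_equal(mean(rc$a), 0, tolerance = 1e-12)
    if (model == "SPLTM") expect_equal(mean(rc$b), 0, tolerance = 1e-12)
    if (model == "SPAM") expect_equal(mean(rc$c), 0, tolerance = 1e-12)
  }
})

test_that("TMS prior simulation stays stationary for moderate rho_T", {
  set.seed(91)
  g <- random_graph(8)
  cw <- car_params(0.5, 0.3)
  vars_t <- matrix(NA_real_, 200, 3)
  for (r in 1:200) {
    A <- matrix(0, 8, 12)
    A[, 1] <- drop(rcar(1, cw, g))
    for (t in 2:12) A[, t] <- 0.5 * A[, t - 1] + drop(rcar(1, cw, g))
    vars_t[r, ] <- c(var(A[, 4]), var(A[, 8]), var(A[, 12]))
  }
  m <- colMeans(vars_t)
  expect_lt(m[3] / m[1], 2)  # no variance blow-up along the chain
})
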
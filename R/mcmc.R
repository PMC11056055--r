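# Chain configuration, initialization, the run_chain front end to the C++
# samplers, post-processing (recentering, pointwise log-likelihoods) and
# convergence diagnostics.

#' Chain configuration
#'
#' The \code{"full"} profile is the full-scale configuration (120,000
#' iterations, 20,000 burn-in, thinning 10, hence 10,000 retained draws);
#' the \code{"desk"} profile (6,000 / 1,000 / 5) is a scaled-down setting
#' for interactive runs and tests. Explicit arguments override the profile.
#'
#' @param profile \code{"desk"} or \code{"full"}.
#' @param n_total,burn_in,thin chain length, burn-in, thinning interval.
#' @param sampler \code{"nuts"} (default; No-U-Turn HMC with dual-averaging
#'   step-size adaptation and diagonal mass adaptation) or \code{"rwm"}
#'   (adaptive random-walk Metropolis; bit-reproducible under a seed).
#' @param seed optional integer seed set before sampling.
#' @param target_accept NUTS dual-averaging target acceptance (default 0.8).
#' @param max_treedepth NUTS maximum doublings per iteration (default 10).
#' @param adapt_mass estimate a diagonal mass matrix during burn-in.
#' @param rwm_scale initial random-walk proposal scale (default
#'   \code{2.38/sqrt(dim)}).
#' @return list of class \code{chain_config}.
#' @export
chain_config <- function(profile = c("desk", "full"), n_total = NULL,
                         burn_in = NULL, thin = NULL,
                         sampler = c("nuts", "rwm"), seed = NULL,
                         target_accept = 0.8, max_treedepth = 10,
                         adapt_mass = TRUE, rwm_scale = NULL) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    desk  = list(n_total = 6000L, burn_in = 1000L, thin = 5L),
    full = list(n_total = 120000L, burn_in = 20000L, thin = 10L))
  n_total <- as.integer(n_total %||% defaults$n_total)
  burn_in <- as.integer(burn_in %||% defaults$burn_in)
  thin <- as.integer(thin %||% defaults$thin)
  if (burn_in >= n_total) stop("burn_in must be smaller than n_total")
  if (thin < 1L) stop("thin must be >= 1")
  if ((n_total - burn_in) %% thin != 0L)
    message("(n_total - burn_in) not divisible by thin; retained count floors")
  structure(list(profile = profile, n_total = n_total, burn_in = burn_in,
                 thin = thin, sampler = match.arg(sampler),
                 seed = if (!is.null(seed)) as.integer(seed),
                 target_accept = target_accept,
                 max_treedepth = as.integer(max_treedepth),
                 adapt_mass = adapt_mass, rwm_scale = rwm_scale),
            class = "chain_config")
}

#' Number of retained draws implied by a chain configuration
#'
#' \code{floor((n_total - burn_in) / thin)}; the full-scale profile yields
#' exactly 10,000.
#'
#' @param config a \code{\link{chain_config}}.
#' @return integer.
#' @export
retained_draws <- function(config) {
  (config$n_total - config$burn_in) %/% config$thin
}

#' Initial parameter state
#'
#' Fixed effects start at a moment estimate (least squares of
#' \code{log(y) - offset} on X) plus small noise; random effects at zero
#' plus jitter; every correlation parameter at 0.5 and every variance at
#' 0.1. Jitter is redrawn (up to \code{max_tries}) until the log posterior
#' is finite.
#'
#' @param model one of \code{st_models()}.
#' @param data a \code{\link{panel_data}}.
#' @param priors a \code{\link{prior_config}}.
#' @param jitter_sd standard deviation of the initialization noise.
#' @param max_tries attempts before giving up.
#' @return named list (natural-scale parameter state).
#' @export
initialize_state <- function(model, data, priors = prior_config(),
                             jitter_sd = 0.01, max_tries = 100) {
  model <- check_model(model)
  fl <- state_fields(model, data$N, data$T, data$p)
  ylog <- log(pmax(as.vector(data$y), 0.5)) - as.vector(data$offset)
  beta_hat <- tryCatch(qr.solve(data$X, ylog), error = function(e) rep(0, data$p))
  for (try in seq_len(max_tries)) {
    state <- lapply(names(fl), function(nm) {
      len <- fl[[nm]]
      if (nm == "beta") return(beta_hat + rnorm(len, 0, jitter_sd))
      if (startsWith(nm, "rho")) return(rep(0.5, len))
      if (startsWith(nm, "k2")) return(rep(0.1, len))
      rnorm(len, 0, jitter_sd)
    })
    names(state) <- names(fl)
    if (is.finite(log_posterior(state, data, priors, model))) return(state)
  }
  stop("could not find a finite log posterior after ", max_tries, " attempts")
}

# data list handed to the C++ backend
build_cdata <- function(model, data, priors, likelihood = TRUE) {
  model_id <- match(model, st_models())
  LW <- graph_laplacian(data$graph)
  LZ <- graph_laplacian(data$tgraph)
  mask <- data$mask
  if (!likelihood) mask[] <- FALSE
  maskn <- matrix(as.numeric(mask), data$N, data$T)
  dim <- sum(unlist(state_fields(model, data$N, data$T, data$p)))
  list(model = model_id, N = data$N, T = data$T, p = data$p, dim = dim,
       y = data$y, off = data$offset, mask = maskn, X = data$X,
       LW = LW, lW = eigen(LW, symmetric = TRUE, only.values = TRUE)$values,
       LZ = LZ, lZ = eigen(LZ, symmetric = TRUE, only.values = TRUE)$values,
       tc = time_covariate(data$T),
       ig_a = priors$ig_shape, ig_b = priors$ig_scale,
       llconst = -sum(lgamma(data$y[mask] + 1)))
}

# recenter SPLTM/SPAM random-effect draws; the removed means are folded into
# the level terms so fitted log-means are unchanged draw by draw.
recenter_draw <- function(state, model) {
  if (model == "SPLTM") {
    ma <- mean(state$a); mb <- mean(state$b)
    state$omega1 <- state$omega1 + ma; state$a <- state$a - ma
    state$omega2 <- state$omega2 + mb; state$b <- state$b - mb
  } else if (model == "SPAM") {
    ma <- mean(state$a); mc <- mean(state$c)
    state$a <- state$a - ma
    state$c <- state$c - mc
    state$b <- state$b + ma + mc  # temporal main effect carries the level
  }
  state
}

#' Run one MCMC chain for a spatio-temporal Poisson model
#'
#' Samples the model posterior with NUTS (or random-walk Metropolis).
#' Correlation parameters are sampled on the logit scale and variances on
#' the log scale with Jacobian corrections. Retained draws are thinned
#' after burn-in; for SPLTM and SPAM the structured random-effect draws are
#' recentered with the removed mean folded into the level terms (fitted
#' log-means unchanged). Per-draw, per-cell Poisson log-likelihoods over
#' the likelihood mask are attached for WAIC.
#'
#' @param model one of \code{st_models()}.
#' @param data a \code{\link{panel_data}}.
#' @param priors a \code{\link{prior_config}}.
#' @param config a \code{\link{chain_config}}.
#' @param init optional initial state (default \code{\link{initialize_state}}).
#' @param likelihood set FALSE to sample from the prior only (the
#'   likelihood term is switched off).
#' @param recenter apply the sum-to-zero post-processing (default TRUE).
#' @return object of class \code{posterior_draws}: matrix \code{draws}
#'   (retained draws x named natural-scale parameters),
#'   \code{pointwise_loglik} (draws x masked cells), acceptance statistics,
#'   the configuration and model/dimension bookkeeping.
#' @export
run_chain <- function(model, data, priors = prior_config(),
                      config = chain_config(), init = NULL,
                      likelihood = TRUE, recenter = TRUE) {
  model <- check_model(model)
  stopifnot(inherits(data, "panel_data"))
  if (!is.null(config$seed)) set.seed(config$seed)
  init <- init %||% initialize_state(model, data, priors)
  check_state(init, model, data)
  theta0 <- to_unconstrained(init, model, data)
  cdata <- build_cdata(model, data, priors, likelihood = likelihood)
  res <- cpp_sample(cdata, NULL, theta0,
                    config$n_total, config$burn_in, config$thin,
                    config$sampler, config$target_accept,
                    config$max_treedepth, isTRUE(config$adapt_mass),
                    config$rwm_scale %||% -1)
  theta_draws <- res$draws
  n_keep <- nrow(theta_draws)
  nms <- param_names(model, data)
  draws <- matrix(NA_real_, n_keep, length(nms), dimnames = list(NULL, nms))
  mask <- if (likelihood) data$mask else matrix(FALSE, data$N, data$T)
  cells <- which(mask)
  pll <- matrix(NA_real_, n_keep, length(cells))
  if (length(cells))
    colnames(pll) <- sprintf("ll[%d,%d]", row(mask)[cells], col(mask)[cells])
  for (s in seq_len(n_keep)) {
    st <- from_unconstrained(theta_draws[s, ], model, data)
    if (recenter) st <- recenter_draw(st, model)
    draws[s, ] <- flatten_state(st, model, data)
    if (length(cells)) {
      lmu <- linear_predictor(model, st, data)
      pll[s, ] <- (data$y * lmu - exp(lmu) - lgamma(data$y + 1))[cells]
    }
  }
  structure(list(draws = draws, pointwise_loglik = pll,
                 model = model, N = data$N, T = data$T, p = data$p,
                 cells = cells, config = config, seed = config$seed,
                 accept_rate = res$accept_rate, step_size = res$step_size,
                 divergences = res$divergences,
                 n_retained = n_keep),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %s: %d draws x %d parameters (%s; accept %.2f, %d divergences)\n",
              x$model, nrow(x$draws), ncol(x$draws), x$config$sampler,
              x$accept_rate, x$divergences))
  invisible(x)
}

#' Sample an arbitrary log density (test harness)
#'
#' Runs the same NUTS / random-walk machinery on a user-supplied log
#' density with gradient. Intended for sampler verification against known
#' distributions.
#'
#' @param fn function of the parameter vector returning
#'   \code{list(value = , grad = )}.
#' @param init numeric initial vector.
#' @param config a \code{\link{chain_config}}.
#' @return list with \code{draws} matrix and acceptance statistics.
#' @export
sample_logdensity <- function(fn, init, config = chain_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- cpp_sample(list(), fn, as.numeric(init),
                    config$n_total, config$burn_in, config$thin,
                    config$sampler, config$target_accept,
                    config$max_treedepth, isTRUE(config$adapt_mass),
                    config$rwm_scale %||% -1)
  res
}

# ---- diagnostics ------------------------------------------------------------

# effective sample size by Geyer's initial positive sequence
ess_one <- function(x) {
  n <- length(x)
  if (n < 4 || sd(x) == 0) return(NA_real_)
  rho <- drop(acf(x, lag.max = min(n - 1L, 500L), plot = FALSE)$acf)[-1]
  tau <- 1
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  n / tau
}

split_rhat <- function(chains) {
  # chains: list of numeric vectors, split each in half
  halves <- unlist(lapply(chains, function(x) {
    m <- length(x) %/% 2L
    list(x[seq_len(m)], x[m + seq_len(m)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Chain summary diagnostics
#'
#' Per-parameter posterior mean, sd, effective sample size and (given two
#' or more chains) the split-chain potential scale reduction factor.
#' Constant (degenerate) chains are flagged with a warning and \code{NA}
#' effective sample size.
#'
#' @param x a \code{posterior_draws} object, or a list of them (multiple
#'   chains of the same model).
#' @param params optional subset of parameter names.
#' @return data frame with columns \code{param, mean, sd, ess, rhat}.
#' @export
chain_diagnostics <- function(x, params = NULL) {
  chains <- if (inherits(x, "posterior_draws")) list(x) else x
  stopifnot(length(chains) >= 1, nrow(chains[[1]]$draws) >= 2)
  nms <- params %||% colnames(chains[[1]]$draws)
  all_draws <- do.call(rbind, lapply(chains, function(ch) ch$draws[, nms, drop = FALSE]))
  out <- data.frame(param = nms,
                    mean = colMeans(all_draws),
                    sd = apply(all_draws, 2, sd),
                    ess = NA_real_, rhat = NA_real_,
                    row.names = NULL)
  degenerate <- FALSE
  for (i in seq_along(nms)) {
    per_chain <- lapply(chains, function(ch) ch$draws[, nms[i]])
    e <- sum(vapply(per_chain, function(v) {
      z <- ess_one(v); if (is.na(z)) 0 else z
    }, numeric(1)))
    if (e == 0) { degenerate <- TRUE; e <- NA_real_ }
    out$ess[i] <- e
    if (length(chains) >= 2) out$rhat[i] <- split_rhat(per_chain)
  }
  if (degenerate) warning("degenerate (constant) chain for some parameters")
  out
}

# ---- draws IO ---------------------------------------------------------------

#' Persist retained draws as CSV plus JSON metadata
#'
#' One row per retained draw, flattened parameter names as columns; a JSON
#' sidecar (\code{<path>.json}) records the model, configuration, seed and
#' acceptance statistics.
#'
#' @param draws a \code{posterior_draws} object.
#' @param path CSV file path.
#' @return \code{path}, invisibly.
#' @export
write_draws <- function(draws, path) {
  write.csv(as.data.frame(draws$draws), path, row.names = FALSE)
  meta <- list(model = draws$model,
               config = draws$config[c("profile", "n_total", "burn_in", "thin", "sampler")],
               seed = draws$seed, accept_rate = draws$accept_rate,
               divergences = draws$divergences, n_retained = draws$n_retained)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
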
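# The four spatio-temporal Poisson models: linear predictors, likelihood,
# priors, posterior. This file is the reference (pure R) implementation;
# the sampler uses an equivalent C++ version with analytic gradients.

#' @export
st_models <- function() c("SPLTM", "SPAM", "STSM", "TMS")

check_model <- function(model) {
  match.arg(toupper(model), st_models())
}

#' Panel data container for model fitting
#'
#' Bundles the count matrix, covariates, offset and the spatial/temporal
#' adjacency structures consumed by the four models. An optional logical
#' \code{mask} marks which cells contribute to the likelihood (used for
#' train/test validation; masked-out cells are still predicted).
#'
#' @param y \code{N x T} matrix of nonnegative integer counts.
#' @param X \code{(N*T) x p} covariate matrix, records ordered unit-fastest.
#' @param graph a \code{\link{spatial_graph}} on the N units.
#' @param offset \code{N x T} matrix of log-exposures (default 0).
#' @param tgraph temporal graph (default \code{temporal_adjacency(T)}).
#' @param mask logical \code{N x T} matrix; TRUE cells enter the likelihood
#'   (default all TRUE).
#' @return object of class \code{panel_data}.
#' @export
panel_data <- function(y, X, graph, offset = NULL, tgraph = NULL, mask = NULL) {
  y <- as.matrix(y)
  N <- nrow(y); Tt <- ncol(y)
  if (anyNA(y) || any(y < 0) || any(y != round(y)))
    stop("y must be nonnegative integers")
  X <- as.matrix(X)
  if (nrow(X) != N * Tt) stop("X must have N*T rows (unit-fastest order)")
  check_graph(graph)
  if (graph$n != N) stop("graph size does not match nrow(y)")
  offset <- if (is.null(offset)) matrix(0, N, Tt) else matrix(as.numeric(offset), N, Tt)
  if (any(!is.finite(offset))) stop("offset must be finite")
  tgraph <- tgraph %||% temporal_adjacency(Tt)
  if (tgraph$n != Tt) stop("temporal graph size does not match ncol(y)")
  mask <- if (is.null(mask)) matrix(TRUE, N, Tt) else matrix(as.logical(mask), N, Tt)
  structure(list(y = y, X = X, offset = offset, graph = graph,
                 tgraph = tgraph, mask = mask,
                 N = N, T = Tt, p = ncol(X)),
            class = "panel_data")
}

#' Build panel_data from a simulated panel
#'
#' @param panel a \code{\link{generate_panel}} result.
#' @param split optional \code{\link{train_test_split}} result; when given,
#'   only the training records enter the likelihood.
#' @return a \code{\link{panel_data}} object.
#' @export
as_panel_data <- function(panel, split = NULL) {
  mask <- NULL
  if (!is.null(split)) {
    mask <- matrix(FALSE, nrow(panel$y), ncol(panel$y))
    mask[split$train_index] <- TRUE
  }
  panel_data(panel$y, panel$X, panel$graph, offset = panel$offset, mask = mask)
}

#' Prior configuration
#'
#' Every CAR/interaction variance k2 gets an inverse-gamma prior
#' IG(\code{ig_shape}, \code{ig_scale}); every correlation parameter rho a
#' uniform(0, 1) prior; fixed effects (beta, omega) improper flat priors.
#'
#' @param ig_shape,ig_scale inverse-gamma hyperparameters (defaults 1, 0.01,
#'   a weakly informative standard for CAR variance components).
#' @return list of class \code{prior_config}.
#' @export
prior_config <- function(ig_shape = 1, ig_scale = 0.01) {
  if (ig_shape <= 0 || ig_scale <= 0) stop("inverse-gamma hyperparameters must be positive")
  structure(list(ig_shape = ig_shape, ig_scale = ig_scale), class = "prior_config")
}

# centered time covariate (t - tbar)/T with tbar = (T+1)/2
time_covariate <- function(Tt) (seq_len(Tt) - (Tt + 1) / 2) / Tt

# ---- parameter state --------------------------------------------------------

state_fields <- function(model, N, Tt, p) {
  switch(model,
    SPLTM = list(beta = p, omega1 = 1, omega2 = 1, a = N, b = N,
                 rho_int = 1, rho_slo = 1, k2_int = 1, k2_slo = 1),
    SPAM  = list(beta = p, a = N, b = Tt, c = N * Tt,
                 rho_s = 1, rho_T = 1, k2_s = 1, k2_T = 1, k2_I = 1),
    STSM  = list(beta = p, a = N * Tt, b = Tt,
                 rho_s = 1, rho_T = 1, k2_t = Tt, k2 = 1),
    TMS   = list(beta = p, a = N * Tt, rho_s = 1, rho_T = 1, k2 = 1))
}

rho_names <- function(model) switch(model,
  SPLTM = c("rho_int", "rho_slo"), SPAM = c("rho_s", "rho_T"),
  STSM = c("rho_s", "rho_T"), TMS = c("rho_s", "rho_T"))

var_names <- function(model) switch(model,
  SPLTM = c("k2_int", "k2_slo"), SPAM = c("k2_s", "k2_T", "k2_I"),
  STSM = c("k2_t", "k2"), TMS = "k2")

check_state <- function(state, model, data) {
  fl <- state_fields(model, data$N, data$T, data$p)
  if (!setequal(names(fl), names(state)))
    stop(sprintf("state/model mismatch for %s: need fields {%s}", model,
                 paste(names(fl), collapse = ", ")))
  for (nm in names(fl))
    if (length(state[[nm]]) != fl[[nm]])
      stop(sprintf("state field '%s' has length %d, expected %d",
                   nm, length(state[[nm]]), fl[[nm]]))
  invisible(state)
}

#' Flat parameter names for a model
#'
#' Names of the flattened parameter vector, in the order used by the
#' sampler's draw matrices (e.g. \code{beta[1]}, \code{a[3]},
#' \code{c[2,5]}, \code{rho_s}, \code{k2_T}).
#'
#' @param model one of \code{st_models()}.
#' @param data a \code{\link{panel_data}} object.
#' @return character vector.
#' @export
param_names <- function(model, data) {
  model <- check_model(model)
  N <- data$N; Tt <- data$T
  fl <- state_fields(model, N, Tt, data$p)
  unlist(lapply(names(fl), function(nm) {
    len <- fl[[nm]]
    if (len == 1L) return(nm)
    if (nm %in% c("c", "a") && len == N * Tt)
      return(paste0(nm, "[", rep(seq_len(N), Tt), ",", rep(seq_len(Tt), each = N), "]"))
    paste0(nm, "[", seq_len(len), "]")
  }), use.names = FALSE)
}

flatten_state <- function(state, model, data) {
  fl <- state_fields(model, data$N, data$T, data$p)
  unlist(lapply(names(fl), function(nm) as.numeric(state[[nm]])), use.names = FALSE)
}

unflatten_state <- function(vec, model, data) {
  fl <- state_fields(model, data$N, data$T, data$p)
  out <- list(); pos <- 0L
  for (nm in names(fl)) {
    out[[nm]] <- vec[pos + seq_len(fl[[nm]])]
    pos <- pos + fl[[nm]]
  }
  out
}

# natural -> unconstrained (logit for rho, log for variances)
to_unconstrained <- function(state, model, data) {
  s <- state
  for (nm in rho_names(model)) s[[nm]] <- log(s[[nm]] / (1 - s[[nm]]))
  for (nm in var_names(model)) s[[nm]] <- log(s[[nm]])
  flatten_state(s, model, data)
}

from_unconstrained <- function(theta, model, data) {
  s <- unflatten_state(theta, model, data)
  for (nm in rho_names(model)) s[[nm]] <- 1 / (1 + exp(-s[[nm]]))
  for (nm in var_names(model)) s[[nm]] <- exp(s[[nm]])
  s
}

# ---- linear predictor, likelihood, priors -----------------------------------

#' Model linear predictor (log mean)
#'
#' Computes \code{log mu_it = X beta + offset + v_it} where the
#' spatio-temporal term \code{v_it} is model specific: SPLTM adds
#' \code{omega1 + a_i + (omega2 + b_i) (t - tbar)/T} with
#' \code{tbar = (T+1)/2}; SPAM adds \code{a_i + b_t + c_it}; STSM adds
#' \code{a_it + b_t}; TMS adds \code{a_it}.
#'
#' @param model one of \code{st_models()}.
#' @param state named list of parameters for the model (natural scale).
#' @param data a \code{\link{panel_data}} object.
#' @return \code{N x T} matrix of log means.
#' @export
linear_predictor <- function(model, state, data) {
  model <- check_model(model)
  check_state(state, model, data)
  N <- data$N; Tt <- data$T
  eta <- matrix(data$X %*% state$beta, N, Tt) + data$offset
  switch(model,
    SPLTM = {
      tc <- time_covariate(Tt)
      eta + state$omega1 + state$a +
        outer(state$omega2 + state$b, tc)
    },
    SPAM = eta + state$a + rep(state$b, each = N) + matrix(state$c, N, Tt),
    STSM = eta + matrix(state$a, N, Tt) + rep(state$b, each = N),
    TMS  = eta + matrix(state$a, N, Tt))
}

#' Poisson log-likelihood
#'
#' Pointwise Poisson log-pmf \code{y log mu - mu - log(y!)} at each cell,
#' and the total over the likelihood mask.
#'
#' @inheritParams linear_predictor
#' @return list with \code{total} (scalar; \code{-Inf} if any masked mean is
#'   nonpositive/nonfinite with positive count) and \code{pointwise}
#'   (\code{N x T} matrix).
#' @export
log_likelihood <- function(state, data, model) {
  lmu <- linear_predictor(model, state, data)
  mu <- exp(lmu)
  pw <- data$y * lmu - mu - lgamma(data$y + 1)
  pw[!is.finite(pw)] <- -Inf
  list(total = sum(pw[data$mask]), pointwise = pw)
}

dinvgamma_log <- function(x, shape, scale) {
  if (x <= 0) return(-Inf)
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Model log prior
#'
#' Sum of the CAR log densities of the structured effects, iid normal terms,
#' inverse-gamma terms for the variances, and the (zero) contribution of the
#' uniform/flat priors inside their supports. Densities are on the natural
#' parameter scale (no transformation Jacobians). Returns \code{-Inf}
#' outside the support.
#'
#' @inheritParams linear_predictor
#' @param priors a \code{\link{prior_config}}.
#' @return scalar log prior density.
#' @export
log_prior <- function(state, priors, model, data) {
  model <- check_model(model)
  check_state(state, model, data)
  g <- data$graph; tg <- data$tgraph
  N <- data$N; Tt <- data$T
  rhos <- unlist(state[rho_names(model)])
  vars <- unlist(state[var_names(model)])
  if (any(rhos <= 0) || any(rhos >= 1) || any(vars <= 0)) return(-Inf)
  a <- priors$ig_shape; b <- priors$ig_scale
  lp <- sum(vapply(vars, dinvgamma_log, numeric(1), shape = a, scale = b))
  lp + switch(model,
    SPLTM = car_log_density(state$a, car_params(state$rho_int, state$k2_int), g) +
            car_log_density(state$b, car_params(state$rho_slo, state$k2_slo), g),
    SPAM = car_log_density(state$a, car_params(state$rho_s, state$k2_s), g) +
           car_log_density(state$b, car_params(state$rho_T, state$k2_T), tg) +
           sum(-0.5 * log(2 * pi * state$k2_I) - 0.5 * state$c^2 / state$k2_I),
    STSM = {
      A <- matrix(state$a, N, Tt)
      sum(vapply(seq_len(Tt), function(t)
        car_log_density(A[, t], car_params(state$rho_s, state$k2_t[t]), g),
        numeric(1))) +
        car_log_density(state$b, car_params(state$rho_T, state$k2), tg)
    },
    TMS = {
      A <- matrix(state$a, N, Tt)
      L <- graph_laplacian(g)
      ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
      ldQ <- sum(log(state$rho_s * ev + 1 - state$rho_s))
      tot <- 0
      for (t in seq_len(Tt)) {
        e <- if (t == 1L) A[, 1] else A[, t] - state$rho_T * A[, t - 1]
        q <- state$rho_s * drop(crossprod(e, L %*% e)) + (1 - state$rho_s) * sum(e^2)
        tot <- tot - 0.5 * N * log(2 * pi * state$k2) + 0.5 * ldQ - 0.5 * q / state$k2
      }
      tot
    })
}

#' Model log posterior
#'
#' \code{log_likelihood + log_prior} (unnormalized), on the natural
#' parameter scale.
#'
#' @inheritParams log_prior
#' @return scalar.
#' @export
log_posterior <- function(state, data, priors, model) {
  lp <- log_prior(state, priors, model, data)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(state, data, model)$total
}

# ---- generative simulation (for recovery checks) ----------------------------

#' Simulate a panel from a model's own generative process
#'
#' Draws all random effects from their priors at the given hyperparameters,
#' forms \code{log mu = X beta + offset + v_it}, and draws plain Poisson
#' counts. Used to test that each model recovers parameters from data it
#' itself generated.
#'
#' @param model one of \code{st_models()}.
#' @param graph spatial graph on N units.
#' @param n_times number of time points.
#' @param beta fixed-effect vector; covariates are generated orthogonal
#'   standardized with \code{p = length(beta)}.
#' @param rho,k2 CAR hyperparameters used for every structured effect.
#' @param k2_I interaction variance (SPAM only).
#' @param intercept added to the linear predictor (absorbed by the model's
#'   level terms).
#' @return list with \code{data} (a \code{\link{panel_data}}), the true
#'   \code{state}, and \code{mu}.
#' @export
simulate_from_model <- function(model, graph, n_times, beta, rho = 0.5, k2 = 0.2,
                                k2_I = 0.1, intercept = 1) {
  model <- check_model(model)
  N <- graph$n; Tt <- as.integer(n_times); p <- length(beta)
  X <- generate_covariates(N, Tt, p)
  tg <- temporal_adjacency(Tt)
  cw <- car_params(rho, k2)
  state <- switch(model,
    SPLTM = list(beta = beta, omega1 = intercept, omega2 = 0.5,
                 a = drop(rcar(1, cw, graph)), b = drop(rcar(1, cw, graph)),
                 rho_int = rho, rho_slo = rho, k2_int = k2, k2_slo = k2),
    SPAM = list(beta = beta, a = intercept + drop(rcar(1, cw, graph)),
                b = drop(rcar(1, cw, tg)),
                c = rnorm(N * Tt, 0, sqrt(k2_I)),
                rho_s = rho, rho_T = rho, k2_s = k2, k2_T = k2, k2_I = k2_I),
    STSM = list(beta = beta,
                a = as.vector(intercept + t(rcar(Tt, cw, graph))),
                b = drop(rcar(1, cw, tg)),
                rho_s = rho, rho_T = rho, k2_t = rep(k2, Tt), k2 = k2),
    TMS = {
      A <- matrix(0, N, Tt)
      A[, 1] <- drop(rcar(1, cw, graph))
      for (t in seq_len(Tt)[-1]) A[, t] <- rho * A[, t - 1] + drop(rcar(1, cw, graph))
      list(beta = beta, a = as.vector(intercept + A),
           rho_s = rho, rho_T = rho, k2 = k2)
    })
  dummy <- panel_data(matrix(1L, N, Tt), X, graph, tgraph = tg)
  mu <- exp(linear_predictor(model, state, dummy))
  y <- matrix(rpois(N * Tt, as.vector(mu)), N, Tt)
  list(data = panel_data(y, X, graph, tgraph = tg), state = state, mu = mu)
}
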
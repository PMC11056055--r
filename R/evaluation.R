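# Model evaluation: WAIC, point predictions, RMSE/MAE, predictive coverage.

#' Watanabe-Akaike information criterion
#'
#' \code{WAIC = -2 (lpd - pWAIC)} where \code{lpd} is the log pointwise
#' predictive density, \code{sum_i log mean_s p(y_i | theta_s)} (computed
#' with log-sum-exp), and \code{pWAIC} is the effective number of
#' parameters, \code{sum_i Var_s[log p(y_i | theta_s)]} (sample variance
#' over draws).
#'
#' @param x a \code{posterior_draws} object or a draws x records matrix of
#'   pointwise log-likelihoods.
#' @return list of class \code{waic_result} with \code{waic}, \code{lpd},
#'   \code{p_waic}.
#' @export
waic <- function(x) {
  ll <- if (inherits(x, "posterior_draws")) x$pointwise_loglik else as.matrix(x)
  if (is.null(ll) || ncol(ll) == 0) stop("no pointwise log-likelihoods available")
  if (any(!is.finite(ll))) stop("non-finite pointwise log-likelihoods")
  S <- nrow(ll)
  if (S < 2) {
    warning("single draw: p_waic set to 0")
    lpd <- sum(ll)
    p <- 0
  } else {
    M <- apply(ll, 2, max)
    lpd <- sum(M + log(colMeans(exp(sweep(ll, 2, M)))))
    p <- sum(apply(ll, 2, var))
  }
  structure(list(waic = -2 * (lpd - p), lpd = lpd, p_waic = p),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.2f (lpd %.2f, p_waic %.2f)\n", x$waic, x$lpd, x$p_waic))
  invisible(x)
}

# iterate over retained draws as natural-scale states
draw_state <- function(draws, s, data) {
  from_flat <- unflatten_state(draws$draws[s, ], draws$model, data)
  from_flat
}

#' Posterior-mean fitted values
#'
#' \code{yhat_it}: posterior mean of \code{mu_it = exp(log mu_it)} over the
#' retained draws.
#'
#' @param draws a \code{posterior_draws} object.
#' @param data the \code{\link{panel_data}} the chain was run on.
#' @return \code{N x T} matrix of fitted means.
#' @export
point_predictions <- function(draws, data) {
  acc <- matrix(0, data$N, data$T)
  S <- nrow(draws$draws)
  for (s in seq_len(S)) {
    st <- draw_state(draws, s, data)
    acc <- acc + exp(linear_predictor(draws$model, st, data))
  }
  acc / S
}

#' Root mean squared error
#'
#' \code{sqrt(mean((y - yhat)^2))}.
#'
#' @param y,yhat numeric vectors (or matrices) of equal length.
#' @return nonnegative scalar.
#' @export
rmse <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  sqrt(mean((y - yhat)^2))
}

#' Mean absolute error
#'
#' \code{mean(|y - yhat|)}.
#'
#' @inheritParams rmse
#' @return nonnegative scalar.
#' @export
mae <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  mean(abs(y - yhat))
}

#' Predictive-interval coverage on held-out records
#'
#' For each test record, equal-tailed 100*level% intervals are formed from
#' posterior-predictive draws (one zero-truncated Poisson draw of y per
#' retained posterior state, matching the support of the data-generating
#' process) and the coverage percentage
#' \code{CP = 100 * mean(L_i <= y_i <= U_i)} is reported. Random effects of
#' held-out cells have no likelihood contribution, so their draws are
#' prior draws given the sampled hyperparameters. Setting
#' \code{type = "mean"} uses credible intervals for mu instead of
#' predictive intervals for y.
#'
#' @param draws a \code{posterior_draws} fitted with the test records
#'   masked out of the likelihood.
#' @param data the \code{\link{panel_data}} used for fitting.
#' @param test_index linear indices (unit-fastest) of the held-out records.
#' @param level interval level (default 0.95).
#' @param type \code{"predictive"} (default) or \code{"mean"}.
#' @return list of class \code{coverage_result} with the coverage
#'   percentage \code{cp}, the per-record \code{intervals} data frame and
#'   \code{level}.
#' @export
coverage <- function(draws, data, test_index, level = 0.95,
                     type = c("predictive", "mean")) {
  type <- match.arg(type)
  test_index <- as.integer(test_index)
  if (!length(test_index)) stop("empty test set")
  S <- nrow(draws$draws)
  k <- length(test_index)
  sims <- matrix(NA_real_, S, k)
  for (s in seq_len(S)) {
    st <- draw_state(draws, s, data)
    mu <- exp(linear_predictor(draws$model, st, data))[test_index]
    sims[s, ] <- if (type == "predictive") rztpois(mu) else mu
  }
  alpha <- (1 - level) / 2
  L <- apply(sims, 2, quantile, probs = alpha)
  U <- apply(sims, 2, quantile, probs = 1 - alpha)
  y <- data$y[test_index]
  cp <- 100 * mean(y >= L & y <= U)
  structure(list(cp = cp,
                 intervals = data.frame(record = test_index, y = y, L = L, U = U),
                 level = level, type = type),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("coverage %.1f%% at level %.0f%% (%d test records)\n",
              x$cp, 100 * x$level, nrow(x$intervals)))
  invisible(x)
}
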
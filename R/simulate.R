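# Synthetic panel generation: equicorrelated noise, zero-truncated counts,
# orthogonal covariates, k-nearest-neighbour adjacency, train/test splits.

#' Simulation scenario
#'
#' One (spatial, temporal) correlation pair together with the panel
#' dimensions and a seed. The study dimensions are 54 units x 20 time
#' points; the correlation grid of interest is 0.05, 0.15, ..., 0.95 in
#' each direction, though any value in (0, 1) is accepted.
#'
#' @param sp spatial correlation, in (0, 1).
#' @param tm temporal correlation, in (0, 1).
#' @param n_units number of spatial units (default 54).
#' @param n_times number of time points (default 20).
#' @param seed integer seed controlling the replication.
#' @return list of class \code{scenario}.
#' @export
scenario <- function(sp, tm, n_units = 54, n_times = 20, seed = 1L) {
  for (v in list(sp = sp, tm = tm))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      stop("sp and tm must be scalars strictly inside (0, 1)")
  n_units <- as.integer(n_units); n_times <- as.integer(n_times)
  if (n_units < 1L || n_times < 1L) stop("n_units and n_times must be positive")
  structure(list(sp = sp, tm = tm, n_units = n_units, n_times = n_times,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' Equicorrelation (compound symmetry) matrix
#'
#' Matrix with unit diagonal and common off-diagonal value \code{r};
#' eigenvalues are \code{1 + (dim - 1) r} (once) and \code{1 - r}
#' (\code{dim - 1} times), so it is positive definite for \code{0 <= r < 1}.
#'
#' @param dim dimension (>= 1).
#' @param r common correlation, in [0, 1).
#' @return \code{dim x dim} matrix.
#' @export
equicorrelation_matrix <- function(dim, r) {
  dim <- as.integer(dim)
  if (length(dim) != 1L || is.na(dim) || dim < 1L) stop("dim must be a positive integer")
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r >= 1)
    stop("r must be in [0, 1)")
  S <- matrix(r, dim, dim)
  diag(S) <- 1
  S
}

# draws from MVN(0, S) via the Cholesky factor; one draw per row
rmvn_chol <- function(n, S) {
  R <- chol(S)
  matrix(rnorm(n * ncol(S)), n, ncol(S)) %*% R
}

#' Correlated spatial and temporal noise
#'
#' Draws the two noise vectors of the data-generating process: spatial noise
#' from MVN(0, equicorrelation(n_units, sp)) and temporal noise from
#' MVN(0, equicorrelation(n_times, tm)). Uses the current RNG stream; wrap
#' in \code{set.seed} (or call via \code{\link{generate_panel}}, which seeds
#' from the scenario) for reproducibility.
#'
#' @param scen a \code{\link{scenario}}.
#' @return list with \code{spatial} (length \code{n_units}) and
#'   \code{temporal} (length \code{n_times}).
#' @export
generate_noise <- function(scen) {
  stopifnot(inherits(scen, "scenario"))
  list(spatial  = drop(rmvn_chol(1, equicorrelation_matrix(scen$n_units, scen$sp))),
       temporal = drop(rmvn_chol(1, equicorrelation_matrix(scen$n_times, scen$tm))))
}

#' Orthogonal standardized covariates
#'
#' Generates \code{p} covariate columns over the \code{n_units * n_times}
#' records that are exactly mutually orthogonal (Gram-Schmidt via QR on iid
#' normal draws, after centering) and standardized to mean 0, sd 1. All
#' variance inflation factors are therefore 1, emulating principal-component
#' covariates. Records are ordered unit-fastest (unit 1..N at time 1, then
#' time 2, ...).
#'
#' @param n_units,n_times panel dimensions.
#' @param p number of covariates (default 10); must satisfy
#'   \code{p < n_units * n_times}.
#' @return \code{(n_units * n_times) x p} matrix with columns x1..xp.
#' @export
generate_covariates <- function(n_units, n_times, p = 10) {
  n <- as.integer(n_units) * as.integer(n_times)
  p <- as.integer(p)
  if (p < 1L) stop("p must be >= 1")
  if (p >= n) stop("p must be smaller than n_units * n_times")
  Z <- matrix(rnorm(n * p), n, p)
  Zc <- sweep(Z, 2, colMeans(Z))
  Q <- qr.Q(qr(Zc))[, seq_len(p), drop = FALSE]
  X <- sweep(Q, 2, apply(Q, 2, sd), "/")
  colnames(X) <- paste0("x", seq_len(p))
  X
}

#' Variance inflation factors
#'
#' \code{VIF_j = 1 / (1 - R^2_j)} from regressing column \code{j} on the
#' remaining columns. Exactly collinear columns are reported as \code{Inf}
#' with a warning.
#'
#' @param X numeric matrix with at least two non-constant columns.
#' @return numeric vector of length \code{ncol(X)}.
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) {
    if (ncol(X) == 1L) return(setNames(1, colnames(X)))
    stop("X needs at least one column")
  }
  if (any(apply(X, 2, sd) == 0)) stop("constant covariate column")
  R <- stats::cor(X)
  vif <- tryCatch(diag(solve(R)), error = function(e) NULL)
  if (is.null(vif) || any(!is.finite(vif)) || any(vif < 0)) {
    warning("exact collinearity among covariates; infinite VIF reported")
    vif <- vapply(seq_len(ncol(X)), function(j) {
      fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
      r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
      if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  setNames(as.numeric(vif), colnames(X))
}

#' Symmetrized k-nearest-neighbour adjacency
#'
#' Connects each unit to its \code{k} nearest neighbours in the coordinate
#' plane; the result is symmetrized (an edge exists if either unit is among
#' the other's k nearest). Ties are broken by unit index.
#'
#' @param coords numeric matrix of per-unit 2-D coordinates.
#' @param k number of neighbours, \code{0 < k < n_units}.
#' @return a \code{\link{spatial_graph}}.
#' @export
build_knn_adjacency <- function(coords, k = 4) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k <- as.integer(k)
  if (k <= 0L || k >= n) stop("k must satisfy 0 < k < n_units")
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, order(D[i, ])[seq_len(k)]] <- 1
  W <- pmax(W, t(W))
  spatial_graph(W)
}

#' Zero-truncated Poisson sampler
#'
#' Draws from the Poisson distribution conditioned on being at least 1.
#' Rates below 0.1 use inverse-CDF sampling (rejection would be slow);
#' larger rates use rejection of zeros.
#'
#' @param lambda vector of positive Poisson rates.
#' @return integer vector of draws, all >= 1.
#' @export
rztpois <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop("lambda must be positive and finite")
  n <- length(lambda)
  y <- integer(n)
  small <- lambda < 0.1
  if (any(small)) {
    l <- lambda[small]
    p0 <- exp(-l)
    u <- runif(sum(small))
    y[small] <- qpois(p0 + u * (1 - p0), l)
  }
  todo <- which(!small)
  while (length(todo)) {
    y[todo] <- rpois(length(todo), lambda[todo])
    todo <- todo[y[todo] == 0L]
  }
  y[y < 1L] <- 1L  # numerical guard for inverse-CDF at tiny rates
  y
}

#' Generate one synthetic panel replication
#'
#' Implements the data-generating process: per-unit 2-D coordinates are
#' drawn iid standard normal; spatial noise with the scenario's
#' equicorrelation is added to the x-coordinates, giving a per-unit spatial
#' term constant over time; equicorrelated temporal noise is replicated
#' across units; the latent log-intensity is the centered sum of the two
#' terms scaled by \code{latent_scale}; counts are zero-truncated Poisson
#' draws around \code{lambda = exp(latent)}. Covariates are orthogonal
#' standardized columns (they do not enter \code{lambda}: the true
#' fixed-effect vector is zero by construction). The spatial adjacency is
#' the symmetrized k-nearest-neighbour graph of the coordinates.
#'
#' If the latent term exceeds \code{latent_bound} in absolute value the
#' replication is rescaled to the bound and a warning is issued.
#'
#' @param scen a \code{\link{scenario}}; its seed fixes the replication.
#' @param p number of covariates (default 10).
#' @param k_neighbors neighbours for the adjacency graph (default 4).
#' @param latent_scale multiplier applied to the centered latent sum before
#'   exponentiation (default 0.5, keeping counts moderate).
#' @param latent_bound overflow guard on the latent scale (default 10).
#' @param offset optional \code{n_units x n_times} matrix of log-exposures
#'   (default all zero); added to the latent log-intensity.
#' @param resample_spatial_each_time if TRUE, fresh spatial noise is drawn
#'   for every time point instead of once per replication (not the default
#'   reading of the generating algorithm; exposed for sensitivity checks).
#' @return object of class \code{simulated_panel}: counts \code{y},
#'   intensities \code{lambda} (both \code{n_units x n_times}), covariates
#'   \code{X} (records x p, unit-fastest order), \code{offset},
#'   \code{coords}, \code{graph}, the latent decomposition
#'   (\code{spatial_term}, \code{temporal_term}) and the \code{scenario}.
#' @export
generate_panel <- function(scen, p = 10, k_neighbors = 4, latent_scale = 0.5,
                           latent_bound = 10, offset = NULL,
                           resample_spatial_each_time = FALSE) {
  stopifnot(inherits(scen, "scenario"))
  set.seed(scen$seed)
  N <- scen$n_units; Tt <- scen$n_times
  coords <- matrix(rnorm(2 * N), N, 2, dimnames = list(NULL, c("x", "y")))
  tm_noise <- drop(rmvn_chol(1, equicorrelation_matrix(Tt, scen$tm)))
  if (resample_spatial_each_time) {
    sp_noise <- rmvn_chol(Tt, equicorrelation_matrix(N, scen$sp)) # Tt x N
    S <- coords[, 1] + t(sp_noise)                                # N x Tt
    Zl <- latent_scale * (S - mean(S)) +
      latent_scale * rep(tm_noise - mean(tm_noise), each = N)
    dim(Zl) <- c(N, Tt)
    s_eff <- NULL
  } else {
    sp_noise <- drop(rmvn_chol(1, equicorrelation_matrix(N, scen$sp)))
    s_raw <- coords[, 1] + sp_noise
    s_eff <- latent_scale * (s_raw - mean(s_raw))
    Zl <- outer(s_eff, rep(1, Tt))
  }
  t_eff <- latent_scale * (tm_noise - mean(tm_noise))
  if (!resample_spatial_each_time)
    Zl <- Zl + outer(rep(1, N), t_eff)
  m <- max(abs(Zl))
  if (m > latent_bound) {
    warning(sprintf("latent term exceeded bound (%.2f > %g); replication rescaled",
                    m, latent_bound))
    fac <- latent_bound / m
    Zl <- Zl * fac
    if (!is.null(s_eff)) s_eff <- s_eff * fac
    t_eff <- t_eff * fac
  }
  if (is.null(offset)) offset <- matrix(0, N, Tt)
  offset <- matrix(as.numeric(offset), N, Tt)
  lambda <- exp(Zl + offset)
  y <- matrix(rztpois(as.vector(lambda)), N, Tt)
  X <- generate_covariates(N, Tt, p)
  graph <- build_knn_adjacency(coords, k = min(k_neighbors, N - 1L))
  structure(list(y = y, lambda = lambda, X = X, offset = offset,
                 coords = coords, graph = graph, scenario = scen,
                 spatial_term = s_eff, temporal_term = t_eff,
                 latent = Zl, latent_scale = latent_scale),
            class = "simulated_panel")
}

#' @export
print.simulated_panel <- function(x, ...) {
  cat(sprintf("<simulated_panel> %d units x %d times (sp=%.2f, tm=%.2f, seed=%d)\n",
              x$scenario$n_units, x$scenario$n_times,
              x$scenario$sp, x$scenario$tm, x$scenario$seed))
  invisible(x)
}

#' Train/test split of panel records
#'
#' Uniform random partition of the \code{n_units * n_times} records into a
#' training set of size \code{round(fraction * total)} and its complement.
#' Record indices are linear indices into the \code{n_units x n_times}
#' matrices (unit-fastest).
#'
#' @param panel a \code{simulated_panel} (or any object with a matrix
#'   \code{y}).
#' @param fraction training fraction, in (0, 1); default 0.7.
#' @return list of class \code{split_panel} with sorted integer vectors
#'   \code{train_index} and \code{test_index}, and \code{fraction}.
#' @export
train_test_split <- function(panel, fraction = 0.7) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  n <- length(panel$y)
  n_train <- round(fraction * n)
  train <- sort(sample.int(n, n_train))
  structure(list(train_index = train,
                 test_index = setdiff(seq_len(n), train),
                 fraction = fraction),
            class = "split_panel")
}

# ---- panel IO ---------------------------------------------------------------

#' Read / write panels as long-format CSV
#'
#' Columns \code{unit_id, time, y, offset, x1..xp}; unit-fastest record
#' order. A JSON sidecar (\code{<path>.json}) records the scenario and seed
#' for provenance.
#'
#' @param panel a \code{simulated_panel}.
#' @param path CSV file path.
#' @return \code{write_panel} returns \code{path} invisibly;
#'   \code{read_panel} returns a list with \code{y}, \code{offset},
#'   \code{X} matrices and, when the sidecar exists, the \code{scenario}.
#' @export
write_panel <- function(panel, path) {
  N <- nrow(panel$y); Tt <- ncol(panel$y)
  df <- data.frame(unit_id = rep(panel$graph$ids %||% paste0("u", seq_len(N)), Tt),
                   time = rep(seq_len(Tt), each = N),
                   y = as.vector(panel$y),
                   offset = as.vector(panel$offset))
  df <- cbind(df, as.data.frame(panel$X))
  write.csv(df, path, row.names = FALSE)
  sidecar <- list(scenario = unclass(panel$scenario),
                  latent_scale = panel$latent_scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- read.csv(path)
  units <- unique(df$unit_id)
  times <- sort(unique(df$time))
  N <- length(units); Tt <- length(times)
  df <- df[order(df$time, match(df$unit_id, units)), ]
  y <- matrix(df$y, N, Tt)
  offset <- matrix(df$offset, N, Tt)
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  X <- as.matrix(df[, xcols, drop = FALSE])
  out <- list(y = y, offset = offset, X = X, unit_ids = units)
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    out$scenario <- do.call(scenario, meta$scenario[c("sp", "tm", "n_units", "n_times", "seed")])
  }
  out
}
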
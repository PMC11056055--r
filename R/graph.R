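# Adjacency structures, Leroux CAR machinery, Moran's I.

#' Spatial adjacency graph
#'
#' Validates and wraps a binary symmetric adjacency matrix \code{W} with zero
#' diagonal. The degree diagonal \code{W_d} (row sums of \code{W}) together
#' with \code{W} defines the Leroux precision structure used by all CAR
#' priors in the package.
#'
#' @param W square 0/1 matrix, symmetric, zero diagonal.
#' @param ids optional character vector of unit identifiers; defaults to the
#'   row names of \code{W} or \code{u1, u2, ...}.
#' @return An object of class \code{spatial_graph}: list with the adjacency
#'   \code{A}, the degree vector \code{degrees}, the number of units \code{n}
#'   and \code{ids}.
#' @examples
#' g <- spatial_graph(rbind(c(0, 1), c(1, 0)))
#' leroux_precision(g, 0.5)
#' @export
spatial_graph <- function(W, ids = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("adjacency matrix must be square")
  if (anyNA(W) || !all(W %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (any(diag(W) != 0)) stop("adjacency diagonal must be zero")
  if (!isSymmetric(unname(W))) stop("adjacency matrix must be symmetric")
  storage.mode(W) <- "double"
  ids <- ids %||% rownames(W) %||% paste0("u", seq_len(nrow(W)))
  if (length(ids) != nrow(W)) stop("ids length must match adjacency dimension")
  dimnames(W) <- list(ids, ids)
  structure(list(A = W, degrees = rowSums(W), n = nrow(W), ids = ids),
            class = c("spatial_graph", "st_graph"))
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("<spatial_graph>", x$n, "units,", sum(x$A) / 2, "edges\n")
  invisible(x)
}

#' Temporal adjacency graph
#'
#' Builds the tridiagonal temporal neighbourhood matrix \code{Z} with
#' \code{Z[i, j] = 1} iff \code{|i - j| = 1}, linking consecutive time
#' points.
#'
#' @param n_times number of time points (>= 1).
#' @return An object of class \code{temporal_graph} (also an
#'   \code{st_graph}) with adjacency \code{A}, \code{degrees} and \code{n}.
#' @examples
#' temporal_adjacency(3)$A
#' @export
temporal_adjacency <- function(n_times) {
  n_times <- as.integer(n_times)
  if (length(n_times) != 1L || is.na(n_times) || n_times < 1L)
    stop("n_times must be a positive integer")
  Z <- matrix(0, n_times, n_times)
  if (n_times > 1L) {
    idx <- seq_len(n_times - 1L)
    Z[cbind(idx, idx + 1L)] <- 1
    Z[cbind(idx + 1L, idx)] <- 1
  }
  structure(list(A = Z, degrees = rowSums(Z), n = n_times),
            class = c("temporal_graph", "st_graph"))
}

#' @export
print.temporal_graph <- function(x, ...) {
  cat("<temporal_graph>", x$n, "time points\n")
  invisible(x)
}

is_st_graph <- function(x) inherits(x, "st_graph")

check_graph <- function(graph) {
  if (!is_st_graph(graph)) stop("expected a spatial_graph or temporal_graph")
  graph
}

#' CAR parameters
#'
#' Bundle of the correlation-strength parameter \code{rho} (in [0, 1]) and
#' the variance \code{k2} (> 0) of a Leroux CAR distribution.
#'
#' @param rho correlation strength, in [0, 1].
#' @param k2 variance, positive.
#' @return list of class \code{car_params}.
#' @export
car_params <- function(rho, k2) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1)
    stop("rho must be a scalar in [0, 1]")
  if (!is.numeric(k2) || length(k2) != 1L || is.na(k2) || k2 <= 0)
    stop("k2 must be a positive scalar")
  structure(list(rho = rho, k2 = k2), class = "car_params")
}

#' Graph Laplacian
#'
#' Degree diagonal minus adjacency, \code{W_d - W}.
#'
#' @param graph a \code{spatial_graph} or \code{temporal_graph}.
#' @return square matrix.
#' @export
graph_laplacian <- function(graph) {
  check_graph(graph)
  diag(graph$degrees, graph$n) - graph$A
}

#' Leroux precision matrix
#'
#' Computes \code{Q(W, rho) = rho * (W_d - W) + (1 - rho) * I}, where
#' \code{W_d} is the degree diagonal of the adjacency \code{W}. \code{Q} is
#' symmetric and positive definite for \code{rho < 1}; at \code{rho = 1} it
#' degenerates to the (singular) intrinsic-CAR graph Laplacian.
#'
#' @param graph a \code{spatial_graph} or \code{temporal_graph}.
#' @param rho correlation strength in [0, 1].
#' @return square matrix Q.
#' @export
leroux_precision <- function(graph, rho) {
  check_graph(graph)
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho < 0 || rho > 1)
    stop("rho must be a scalar in [0, 1]")
  rho * graph_laplacian(graph) + (1 - rho) * diag(graph$n)
}

#' CAR full conditional for one unit
#'
#' Conditional distribution of the CAR effect at unit \code{i} given the
#' effects of all other units: mean
#' \code{rho * sum_j w_ij phi_j / (rho * sum_j w_ij + 1 - rho)} and variance
#' \code{k2 / (rho * sum_j w_ij + 1 - rho)}. Isolated units (degree zero)
#' reduce to \code{N(0, k2 / (1 - rho))}.
#'
#' @param i unit index.
#' @param phi vector of current effects (length \code{graph$n}).
#' @param params a \code{\link{car_params}} object.
#' @param graph a \code{spatial_graph} or \code{temporal_graph}.
#' @return list with elements \code{mean} and \code{variance}.
#' @export
car_full_conditional <- function(i, phi, params, graph) {
  check_graph(graph)
  if (!inherits(params, "car_params")) params <- do.call(car_params, params)
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > graph$n)
    stop("unit index out of range")
  if (length(phi) != graph$n) stop("phi must have length graph$n")
  wi <- graph$A[i, ]
  denom <- params$rho * sum(wi) + 1 - params$rho
  if (denom <= 0) stop("degenerate conditional: rho = 1 at an isolated unit")
  list(mean = params$rho * sum(wi * phi) / denom,
       variance = params$k2 / denom)
}

#' Joint CAR log density
#'
#' Log density of the zero-mean multivariate normal with precision
#' \code{Q(W, rho) / k2} implied by the Leroux CAR conditionals. Proper only
#' for \code{rho < 1}; the intrinsic limit \code{rho = 1} has no normalizable
#' joint density and raises an error.
#'
#' @param phi real vector of effects.
#' @param params a \code{\link{car_params}} object.
#' @param graph a \code{spatial_graph} or \code{temporal_graph}.
#' @return scalar log density.
#' @export
car_log_density <- function(phi, params, graph) {
  check_graph(graph)
  if (!inherits(params, "car_params")) params <- do.call(car_params, params)
  if (params$rho >= 1)
    stop("rho = 1 gives an improper joint density; use the conditionals or a constrained subspace")
  n <- graph$n
  if (length(phi) != n) stop("phi must have length graph$n")
  L <- graph_laplacian(graph)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  rho <- params$rho
  k2 <- params$k2
  q1 <- drop(crossprod(phi, L %*% phi))
  q0 <- sum(phi^2)
  -0.5 * n * log(2 * pi * k2) + 0.5 * sum(log(rho * ev + 1 - rho)) -
    0.5 * (rho * q1 + (1 - rho) * q0) / k2
}

#' Sample from a Leroux CAR distribution
#'
#' Draws from the zero-mean multivariate normal with precision
#' \code{Q(W, rho) / k2}. Uses the Cholesky factor of Q.
#'
#' @inheritParams car_log_density
#' @param n number of draws.
#' @return matrix with \code{n} rows (one draw per row).
#' @export
rcar <- function(n = 1, params, graph) {
  check_graph(graph)
  if (!inherits(params, "car_params")) params <- do.call(car_params, params)
  if (params$rho >= 1) stop("rho = 1 gives an improper distribution")
  Q <- leroux_precision(graph, params$rho)
  R <- chol(Q)
  z <- matrix(rnorm(n * graph$n), nrow = graph$n)
  t(backsolve(R, z)) * sqrt(params$k2)
}

#' Moran's I
#'
#' Global spatial autocorrelation statistic
#' \code{I = (n / S0) * sum_ij w_ij (x_i - mu)(x_j - mu) / sum_i (x_i - mu)^2}
#' with \code{S0 = sum_ij w_ij}. The value is reported unclamped; it can
#' fall slightly outside [-1, 1] for some weight configurations.
#'
#' @param x numeric vector with nonzero variance, one value per unit.
#' @param graph a \code{spatial_graph} with at least one edge.
#' @return scalar Moran's I.
#' @export
morans_i <- function(x, graph) {
  check_graph(graph)
  if (length(x) != graph$n) stop("x must have length graph$n")
  s0 <- sum(graph$A)
  if (s0 == 0) stop("graph has no edges: S0 = 0")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop("x has zero variance")
  (graph$n / s0) * drop(crossprod(xc, graph$A %*% xc)) / denom
}

# ---- adjacency IO -----------------------------------------------------------

#' Read / write adjacency matrices as CSV
#'
#' The matrix format is a square 0/1 CSV whose header row carries the unit
#' identifiers. \code{adjacency_from_edges} builds a graph from a two-column
#' edge list of unit identifiers instead.
#'
#' @param path file path.
#' @param graph a \code{spatial_graph}.
#' @return \code{read_adjacency} and \code{adjacency_from_edges} return a
#'   \code{spatial_graph}; \code{write_adjacency} returns \code{path}
#'   invisibly.
#' @export
read_adjacency <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  M <- as.matrix(df)
  spatial_graph(M, ids = colnames(df))
}

#' @rdname read_adjacency
#' @export
write_adjacency <- function(graph, path) {
  check_graph(graph)
  write.csv(as.data.frame(graph$A), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_adjacency
#' @param edges data frame (or path to a two-column CSV) whose first two
#'   columns are unit identifiers of connected pairs.
#' @param ids full set of unit identifiers (so isolated units are kept);
#'   defaults to the identifiers present in \code{edges}.
#' @export
adjacency_from_edges <- function(edges, ids = NULL) {
  if (is.character(edges) && length(edges) == 1L) edges <- read.csv(edges)
  if (ncol(edges) < 2L) stop("edge list needs two identifier columns")
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  ids <- ids %||% sort(unique(c(a, b)))
  if (!all(c(a, b) %in% ids)) stop("edge identifiers not all present in ids")
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  W[cbind(match(a, ids), match(b, ids))] <- 1
  W[cbind(match(b, ids), match(a, ids))] <- 1
  diag(W) <- 0
  spatial_graph(W, ids = ids)
}
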
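#' Factorization configuration for latent state profiles
#'
#' @param rank Latent dimension of the factorization, >= 1.
#' @param temporal_smoothness_weight Weight of the squared-forward-difference
#'   penalty on the temporal factor (shift-model backend).
#' @param row_graph_weight,time_graph_weight Weights of the Laplacian
#'   penalties in the graph-regularized backend.
#' @param shift_value Baseline added to the low-rank reconstruction; 1 (the
#'   normal state) by default so the factors only model departures from
#'   normal.
#' @param max_iters Maximum alternating least squares iterations.
#' @param tol Relative objective-change convergence tolerance.
#' @param ridge Small ridge damping on both factors (also the quadratic
#'   solves' regularizer).
#' @param seed Seed for the deterministic factor initialization.
#' @return Object of class `factorization_config`.
#' @export
factorization_config <- function(rank = 4L,
                                 temporal_smoothness_weight = 2,
                                 row_graph_weight = 1,
                                 time_graph_weight = 2,
                                 shift_value = 1,
                                 max_iters = 100L,
                                 tol = 5e-3,
                                 ridge = 1e-4,
                                 seed = 1L) {
  stopifnot(rank >= 1, tol > 0, max_iters >= 1, ridge >= 0,
            temporal_smoothness_weight >= 0, row_graph_weight >= 0,
            time_graph_weight >= 0)
  structure(list(rank = as.integer(rank),
                 temporal_smoothness_weight = temporal_smoothness_weight,
                 row_graph_weight = row_graph_weight,
                 time_graph_weight = time_graph_weight,
                 shift_value = shift_value, max_iters = as.integer(max_iters),
                 tol = tol, ridge = ridge, seed = as.integer(seed)),
            class = "factorization_config")
}

# Alternating least squares for masked low-rank completion with optional
# quadratic penalties. With penalize = "factor" the penalties are
# tr(U' Kr U) + tr(V' Kt V) on the factors themselves (the temporal
# smoothness formulation); with penalize = "product" they act on the
# reconstruction M0 = U V' as tr(M0' Kr M0) + tr(M0 Kt M0'), the graph
# Laplacian formulation (the shift is invisible to a Laplacian, whose null
# space contains constants). Both half-steps are exact block minimizers of
# the full objective, so it is non-increasing.
als_masked_factorization <- function(Z, rank, shift, Kr = NULL, Kt = NULL,
                                     penalize = c("factor", "product"),
                                     ridge = 1e-4, max_iters = 60L,
                                     tol = 1e-6, seed = 1L) {
  penalize <- match.arg(penalize)
  W <- !is.na(Z)
  empty_rows <- which(rowSums(W) == 0)
  if (length(empty_rows))
    stop("rows with no observed entries: ",
         paste(utils::head(empty_rows, 5L), collapse = ", "))
  N <- nrow(Z); Tn <- ncol(Z)
  rank <- min(rank, N, Tn)
  R <- Z - shift
  R[!W] <- 0

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  V <- matrix(stats::rnorm(Tn * rank, sd = 0.5), Tn, rank)
  U <- matrix(0, N, rank)

  product <- penalize == "product"
  objective <- function(U, V) {
    E <- (R - U %*% t(V)) * W
    obj <- sum(E^2) + ridge * (sum(U^2) + sum(V^2))
    if (product) {
      M0 <- U %*% t(V)
      if (!is.null(Kr)) obj <- obj + sum(M0 * as.matrix(Kr %*% M0))
      if (!is.null(Kt)) obj <- obj + sum(M0 * t(as.matrix(Kt %*% t(M0))))
    } else {
      if (!is.null(Kr)) obj <- obj + sum(U * as.matrix(Kr %*% U))
      if (!is.null(Kt)) obj <- obj + sum(V * as.matrix(Kt %*% V))
    }
    obj
  }

  # Solve for one factor (rows of the output) given the other factor B.
  # `extra` is an r x r matrix added to every per-row block (the blockwise
  # part a product penalty on the *other* dimension contributes);
  # `K`/`gram` give the coupling K %x% gram across rows (gram = I_r for a
  # factor penalty, B'B for a product penalty).
  solve_factor <- function(A, B, mask, K = NULL, gram = NULL, extra = NULL) {
    n <- nrow(A); r <- ncol(B)
    base <- diag(ridge, r)
    if (!is.null(extra)) base <- base + extra
    blocks <- lapply(seq_len(n), function(i) {
      idx <- which(mask[i, ])
      Bi <- B[idx, , drop = FALSE]
      crossprod(Bi) + base
    })
    rhs_list <- vapply(seq_len(n), function(i) {
      idx <- which(mask[i, ])
      Bi <- B[idx, , drop = FALSE]
      as.vector(crossprod(Bi, A[i, idx]))
    }, numeric(r))
    dim(rhs_list) <- c(r, n)
    if (is.null(K)) {
      out <- matrix(0, n, r)
      for (i in seq_len(n)) out[i, ] <- solve(blocks[[i]], rhs_list[, i])
      return(out)
    }
    lhs <- Matrix::bdiag(blocks) +
      Matrix::kronecker(K, if (is.null(gram)) Matrix::Diagonal(r) else gram)
    # vec ordering: factor rows stacked (u_1; ...; u_n), matching K %x% gram;
    # the system is symmetric positive definite, so use a sparse Cholesky
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(lhs))
    matrix(as.numeric(Matrix::solve(ch, as.vector(rhs_list))), n, r,
           byrow = TRUE)
  }

  obj_trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iters)) {
    if (product) {
      SV <- if (is.null(Kt)) NULL else crossprod(V, as.matrix(Kt %*% V))
      U <- solve_factor(R, V, W, K = Kr,
                        gram = if (is.null(Kr)) NULL else crossprod(V),
                        extra = SV)
      SU <- if (is.null(Kr)) NULL else crossprod(U, as.matrix(Kr %*% U))
      V <- solve_factor(t(R), U, t(W), K = Kt,
                        gram = if (is.null(Kt)) NULL else crossprod(U),
                        extra = SU)
    } else {
      U <- solve_factor(R, V, W, K = Kr)
      V <- solve_factor(t(R), U, t(W), K = Kt)
    }
    cur <- objective(U, V)
    obj_trace <- c(obj_trace, cur)
    if (is.finite(prev) && abs(prev - cur) <= tol * max(1, abs(prev))) break
    prev <- cur
  }
  converged <- it < max_iters ||
    (length(obj_trace) > 1 &&
       abs(diff(utils::tail(obj_trace, 2))) <= tol * max(1, abs(prev)))
  if (!converged)
    warning("factorization did not converge in ", max_iters,
            " iterations; returning current iterate")
  list(M = shift + U %*% t(V), U = U, V = V, objective = obj_trace,
       converged = converged)
}

forward_difference_penalty <- function(Tn, weight) {
  if (weight == 0 || Tn < 2) return(NULL)
  D <- Matrix::bandSparse(Tn - 1, Tn, k = 0:1,
                          diagonals = list(rep(-1, Tn - 1), rep(1, Tn - 1)))
  weight * Matrix::crossprod(D)
}

graph_laplacian <- function(A) {
  A <- methods::as(A, "CsparseMatrix")
  Matrix::Diagonal(x = Matrix::rowSums(A)) - A
}

new_latent_profiles <- function(M, grid, sigma, config, extra = list()) {
  stopifnot(all(is.finite(M)), sigma > 0)
  structure(c(list(values = M, grid = grid, sigma = sigma, config = config),
              extra),
            class = "latent_profiles")
}

#' @export
print.latent_profiles <- function(x, ...) {
  cat(sprintf("<latent_profiles> %d profiles x %d age bins, sigma = %.4f\n",
              nrow(x$values), ncol(x$values), x$sigma))
  invisible(x)
}

#' Fit latent state profiles by shifted masked matrix factorization
#'
#' Estimates a complete N x T matrix of continuous latent state trajectories
#' from the partially observed state matrix. The reconstruction is
#' `shift + U V'` fitted to the observed states by masked least squares with
#' a squared-forward-difference penalty on the temporal factor, so the
#' latent profiles change slowly on the age grid. The emission noise scale
#' `sigma` is then estimated by maximum likelihood under the discrete
#' emission model (see [emission_prob()]).
#'
#' @param Z A `state_matrix` from [to_state_matrix()].
#' @param config A [factorization_config()].
#' @return A `latent_profiles` object: `values` (N x T), `grid`, `sigma`,
#'   plus the factors and the objective trace.
#' @export
fit_swcmf <- function(Z, config = factorization_config()) {
  stopifnot(inherits(Z, "state_matrix"), inherits(config, "factorization_config"))
  Kt <- forward_difference_penalty(ncol(Z$values),
                                   config$temporal_smoothness_weight)
  fit <- als_masked_factorization(
    Z$values, rank = config$rank, shift = config$shift_value,
    Kr = NULL, Kt = Kt, ridge = config$ridge,
    max_iters = config$max_iters, tol = config$tol, seed = config$seed)
  sigma <- estimate_sigma(fit$M, Z)
  new_latent_profiles(fit$M, Z$grid, sigma, config,
                      extra = list(factors = fit[c("U", "V")],
                                   objective = fit$objective,
                                   subjects = Z$subjects,
                                   backend = "swcmf"))
}

#' Learn a similarity graph over screening histories
#'
#' Builds a symmetric nonnegative adjacency over the rows of a partially
#' observed state matrix. Pairwise distances are mean squared differences
#' over co-observed columns; weights use a Gaussian kernel with a per-node
#' adaptive bandwidth (the mean distance to the `k_bandwidth` nearest
#' comparable rows), then weights below `sparsity_threshold` times each
#' node's largest weight are dropped. Node degrees are therefore variable;
#' row pairs with no co-observed column get weight zero.
#'
#' @param Z A `state_matrix` with at least two rows.
#' @param k_bandwidth Neighbourhood size for the adaptive kernel bandwidth.
#' @param sparsity_threshold Relative weight cut-off in (0, 1).
#' @param max_degree Upper bound on retained neighbours per node before
#'   symmetrization (degrees stay variable below it via the threshold).
#' @return Sparse symmetric adjacency matrix (zero diagonal).
#' @export
learn_row_graph <- function(Z, k_bandwidth = 7L, sparsity_threshold = 0.15,
                            max_degree = 15L) {
  stopifnot(inherits(Z, "state_matrix"))
  X <- Z$values
  N <- nrow(X)
  if (N < 2) stop("need at least 2 rows to learn a graph")
  W <- !is.na(X)
  X0 <- X; X0[!W] <- 0
  # co-observation counts and masked squared distances via cross-products
  C <- tcrossprod(W * 1)                       # co-observed column counts
  S2 <- tcrossprod(X0^2 * W, W)                # sum x_i^2 over co-observed
  G <- tcrossprod(X0)                          # sum x_i x_j
  D2 <- S2 + t(S2) - 2 * G
  D <- matrix(Inf, N, N)
  has <- C > 0
  D[has] <- pmax(D2[has], 0) / C[has]
  diag(D) <- Inf
  # adaptive bandwidth: mean distance to k nearest comparable neighbours
  bw <- apply(D, 1, function(d) {
    d <- sort(d[is.finite(d)])
    if (!length(d)) return(NA_real_)
    max(mean(utils::head(d, k_bandwidth)), 1e-8)
  })
  A <- matrix(0, N, N)
  fin <- which(is.finite(D), arr.ind = TRUE)
  if (nrow(fin)) {
    s <- sqrt(bw[fin[, 1]] * bw[fin[, 2]])     # symmetric local scale
    A[fin] <- exp(-D[fin] / s)
  }
  A <- (A + t(A)) / 2
  keep <- A >= sparsity_threshold * pmax(apply(A, 1, max), 1e-300)
  if (is.finite(max_degree) && N > max_degree) {
    ranks <- t(apply(-A, 1, rank, ties.method = "first"))
    keep <- keep & ranks <= max_degree
  }
  keep <- keep | t(keep)
  A[!keep] <- 0
  diag(A) <- 0
  Matrix::Matrix(A, sparse = TRUE)
}

#' Path graph over the age grid
#'
#' Chain adjacency linking consecutive age bins, encoding the assumption
#' that the latent risk does not change rapidly within a year.
#'
#' @param n_cols Number of grid columns.
#' @return Sparse symmetric adjacency.
#' @export
time_path_graph <- function(n_cols) {
  Matrix::bandSparse(n_cols, n_cols, k = c(-1, 1),
                     diagonals = list(rep(1, n_cols - 1), rep(1, n_cols - 1)),
                     symmetric = FALSE)
}

validate_adjacency <- function(A, n, what) {
  if (nrow(A) != n || ncol(A) != n)
    stop(what, " dimension mismatch: expected ", n, " nodes")
  if (max(abs(A - Matrix::t(A))) > 1e-9) stop(what, " must be symmetric")
  if (min(A) < -1e-12) stop(what, " must be nonnegative")
  if (any(abs(Matrix::diag(A)) > 1e-12)) stop(what, " must have zero diagonal")
  invisible(A)
}

#' Fit latent state profiles with graph-regularized factorization
#'
#' Variant of [fit_swcmf()] in which the structure of the latent profiles is
#' driven by two similarity graphs: a learned graph over screening histories
#' (rows) and a path graph over the age grid (columns). The masked
#' reconstruction is penalized by the Laplacian quadratic forms of both
#' graphs, pulling similar histories toward similar profiles and making the
#' profiles vary slowly in age. With both graph weights zero the fit reduces
#' exactly to the unregularized masked factorization.
#'
#' @param Z A `state_matrix`.
#' @param row_graph Symmetric nonnegative adjacency over rows; learned with
#'   [learn_row_graph()] when `NULL`.
#' @param time_graph Adjacency over columns; defaults to the path graph.
#' @param config A [factorization_config()]; `row_graph_weight` and
#'   `time_graph_weight` scale the two Laplacian penalties.
#' @return A `latent_profiles` object.
#' @export
fit_gdl <- function(Z, row_graph = NULL, time_graph = NULL,
                    config = factorization_config()) {
  stopifnot(inherits(Z, "state_matrix"), inherits(config, "factorization_config"))
  N <- nrow(Z$values); Tn <- ncol(Z$values)
  if (is.null(row_graph) && config$row_graph_weight > 0)
    row_graph <- learn_row_graph(Z)
  if (is.null(time_graph)) time_graph <- time_path_graph(Tn)
  Kr <- NULL
  if (config$row_graph_weight > 0) {
    validate_adjacency(row_graph, N, "row graph")
    Kr <- config$row_graph_weight * graph_laplacian(row_graph)
  }
  Kt <- NULL
  if (config$time_graph_weight > 0) {
    validate_adjacency(time_graph, Tn, "time graph")
    Kt <- config$time_graph_weight * graph_laplacian(time_graph)
  }
  fit <- als_masked_factorization(
    Z$values, rank = config$rank, shift = config$shift_value,
    Kr = Kr, Kt = Kt, penalize = "product", ridge = config$ridge,
    max_iters = config$max_iters, tol = config$tol, seed = config$seed)
  sigma <- estimate_sigma(fit$M, Z)
  new_latent_profiles(fit$M, Z$grid, sigma, config,
                      extra = list(factors = fit[c("U", "V")],
                                   objective = fit$objective,
                                   subjects = Z$subjects,
                                   backend = "gdl"))
}

#' Maximum likelihood emission noise scale
#'
#' Estimates the emission scale `sigma` by maximizing, over the observed
#' cells, the product of normalized emission probabilities of the recorded
#' discrete states given the reconstructed latent values (a bounded 1-D
#' search on the log scale).
#'
#' @param M Numeric matrix of reconstructed latent values (same shape as the
#'   observed matrix).
#' @param Z A `state_matrix` (its `NA` pattern defines the observed cells).
#' @param sigma_min,sigma_max Search bounds.
#' @return The estimated sigma. When every residual is zero the likelihood
#'   is maximized at the boundary and `sigma_min` is returned with a
#'   warning.
#' @export
estimate_sigma <- function(M, Z, sigma_min = 0.01, sigma_max = 10) {
  vals <- if (inherits(Z, "state_matrix")) Z$values else Z
  obs <- which(!is.na(vals))
  if (!length(obs)) stop("no observed entries to estimate sigma from")
  m <- as.numeric(M[obs])
  x <- as.integer(vals[obs])
  nll <- function(log_sigma) {
    -sum(log(emission_prob(m, x, exp(log_sigma))))
  }
  if (all(abs(m - x) < 1e-12)) {
    warning("all residuals zero: sigma likelihood maximized at the boundary; ",
            "returning sigma_min")
    return(sigma_min)
  }
  opt <- stats::optimize(nll, c(log(sigma_min), log(sigma_max)), tol = 1e-8)
  sigma <- exp(opt$minimum)
  # boundary diagnostics
  if (nll(log(sigma_min)) < opt$objective) sigma <- sigma_min
  if (nll(log(sigma_max)) < opt$objective) sigma <- sigma_max
  sigma
}
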
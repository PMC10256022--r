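#' Simulation configuration
#'
#' Bundles the parameters of the synthetic multi-dataset generator: `N`
#' latent sources observed in `K` datasets over `T` samples, of which the
#' first `n_shared` source component vectors (SCVs) are "shared" (rank-one
#' covariance structure, correlation level on an equally spaced grid from
#' `mu_hi` down to `mu_lo`) and the rest are "non-shared" (random full-rank
#' correlation matrices). SCVs are drawn from a multivariate generalized
#' Gaussian distribution (MGGD) with shape `beta`; `beta = 0.5` gives the
#' heavy, Laplacian-like tails typical of fMRI sources.
#'
#' @param n_sources Number of latent sources `N` per dataset.
#' @param n_datasets Number of datasets `K` (e.g. subjects).
#' @param n_shared Number of shared SCVs, between 0 and `n_sources`.
#' @param n_samples Number of samples `T`; defaults to `20 * N * K`.
#' @param mu_lo,mu_hi Lowest and highest shared-SCV correlation levels,
#'   both in `[0, 1]` with `mu_lo <= mu_hi`.
#' @param beta MGGD shape parameter; 1 is Gaussian, 0.5 Laplacian-like.
#' @param seed Integer seed for reproducible generation, or `NULL` to use
#'   the current RNG state.
#' @return An object of class `sim_config`.
#' @seealso [generate_ground_truth()]
#' @export
sim_config <- function(n_sources, n_datasets, n_shared,
                       n_samples = 20L * n_sources * n_datasets,
                       mu_lo = 0.5, mu_hi = 0.8, beta = 0.5, seed = NULL) {
  n_sources <- as.integer(n_sources)
  n_datasets <- as.integer(n_datasets)
  n_shared <- as.integer(n_shared)
  n_samples <- as.integer(n_samples)
  if (n_sources < 1L) stop("`n_sources` must be at least 1")
  if (n_datasets < 1L) stop("`n_datasets` must be at least 1")
  if (n_shared < 0L || n_shared > n_sources)
    stop("`n_shared` must lie in [0, n_sources]")
  if (mu_lo < 0 || mu_hi > 1 || mu_lo > mu_hi)
    stop("need 0 <= mu_lo <= mu_hi <= 1")
  if (beta <= 0) stop("`beta` must be positive")
  if (n_samples < n_sources * n_datasets)
    stop("`n_samples` must be at least n_sources * n_datasets")
  structure(
    list(n_sources = n_sources, n_datasets = n_datasets,
         n_shared = n_shared, n_samples = n_samples,
         mu_lo = mu_lo, mu_hi = mu_hi, beta = beta, seed = seed),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: N = %d sources, K = %d datasets, T = %d samples\n",
    x$n_sources, x$n_datasets, x$n_samples))
  cat(sprintf("  shared SCVs: %d (mu in [%.2f, %.2f]), non-shared: %d\n",
              x$n_shared, x$mu_lo, x$mu_hi, x$n_sources - x$n_shared))
  cat(sprintf("  MGGD shape beta = %g, seed = %s\n", x$beta,
              if (is.null(x$seed)) "<none>" else format(x$seed)))
  invisible(x)
}

#' Rank-one-plus-identity shared-SCV covariance
#'
#' Builds the `K x K` covariance `mu * 11' + (1 - mu) * I` of a shared SCV:
#' every off-diagonal entry equals `mu` and the diagonal is 1, so the matrix
#' is also a correlation matrix. Its eigenvalues are `K*mu + 1 - mu` (once)
#' and `1 - mu` (`K - 1` times): one dominant "signal" eigenvalue plus a flat
#' noise floor, i.e. effective rank one.
#'
#' @param mu Common correlation level in `[0, 1]`.
#' @param K Number of datasets (matrix dimension).
#' @return A `K x K` numeric matrix.
#' @export
make_shared_covariance <- function(mu, K) {
  if (length(mu) != 1L || !is.finite(mu) || mu < 0 || mu > 1)
    stop("`mu` must be a single value in [0, 1]")
  K <- as.integer(K)
  if (K < 1L) stop("`K` must be at least 1")
  S <- matrix(mu, K, K)
  diag(S) <- 1
  S
}

#' Random full-rank non-shared-SCV correlation matrix
#'
#' Draws `Q` with i.i.d. standard Gaussian rows, normalizes each row to unit
#' length, and returns `Q Q'`: a random correlation matrix (unit diagonal,
#' off-diagonals in `(-1, 1)`) with effective full rank. Draws are repeated
#' until the smallest eigenvalue exceeds `1e-6` so the matrix is comfortably
#' positive definite.
#'
#' @param K Matrix dimension (number of datasets), at least 2.
#' @param max_tries Resampling budget before giving up.
#' @return A `K x K` correlation matrix.
#' @export
make_nonshared_covariance <- function(K, max_tries = 100L) {
  K <- as.integer(K)
  if (K < 2L) stop("`K` must be at least 2")
  for (i in seq_len(max_tries)) {
    Q <- matrix(stats::rnorm(K * K), K, K)
    Q <- Q / sqrt(rowSums(Q^2))
    S <- tcrossprod(Q)
    S <- (S + t(S)) / 2
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > 1e-6)
      return(S)
  }
  stop("failed to draw a full-rank correlation matrix in ", max_tries,
       " tries")
}

#' Sample from a multivariate generalized Gaussian distribution
#'
#' Draws `n` i.i.d. columns from MGGD(0, `sigma`, `beta`) via the stochastic
#' representation `x = c * R * sigma^(1/2) * u`, with `u` uniform on the unit
#' sphere and `R^(2*beta) ~ Gamma(shape = K/(2*beta), scale = 2)`. The
#' constant `c` rescales the radius so that `Cov(x) = sigma` exactly for
#' every shape: `beta = 1` recovers the multivariate Gaussian and
#' `K = 1, beta = 0.5` the Laplace distribution (excess kurtosis 3).
#'
#' @param sigma `K x K` symmetric positive semi-definite scatter matrix.
#' @param beta Shape parameter, positive.
#' @param n Number of samples (columns).
#' @return A `K x n` numeric matrix.
#' @export
sample_mggd <- function(sigma, beta, n) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma))
    stop("`sigma` must be a square matrix")
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("`sigma` must be symmetric")
  if (beta <= 0) stop("`beta` must be positive")
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be at least 1")
  K <- nrow(sigma)
  e <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("`sigma` is not positive semi-definite: matrix square root failed")
  root <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  # direction: normalized Gaussian; radius: R^(2 beta) ~ Gamma(K/(2 beta), 2)
  z <- matrix(stats::rnorm(K * n), K, n)
  u <- z / rep(sqrt(colSums(z^2)), each = K)
  r <- stats::rgamma(n, shape = K / (2 * beta), scale = 2)^(1 / (2 * beta))
  # second moment of R: E[G^(1/beta)], G ~ Gamma(K/(2 beta), scale 2)
  a <- K / (2 * beta)
  log_er2 <- (1 / beta) * log(2) + lgamma(a + 1 / beta) - lgamma(a)
  scale_c <- sqrt(K) * exp(-log_er2 / 2)
  root %*% (u * rep(scale_c * r, each = K))
}

# standardize matrix rows to zero mean, unit variance (divisor n - 1)
.standardize_rows <- function(X) {
  m <- rowMeans(X)
  Xc <- X - m
  s <- sqrt(rowSums(Xc^2) / (ncol(X) - 1))
  if (any(s == 0)) {
    bad <- which(s == 0)[1L]
    stop("row ", bad, " is constant: cannot standardize")
  }
  Xc / s
}

# equally spaced descending grid of shared correlation levels
.mu_grid <- function(n_shared, mu_lo, mu_hi) {
  if (n_shared == 0L) return(numeric(0))
  if (n_shared == 1L) return(mu_hi)
  seq(mu_hi, mu_lo, length.out = n_shared)
}

#' Generate ground-truth mixtures for a simulation scenario
#'
#' Draws `N` latent SCVs — the first `n_shared` with rank-one covariances
#' at correlation levels equally spaced from `mu_hi` down to `mu_lo`, the
#' rest with random full-rank correlation matrices — samples each from the
#' MGGD, standardizes every source to zero mean and unit variance,
#' distributes the sources to their datasets, and mixes with square Gaussian
#' mixing matrices `A[[k]]` (resampled until the condition number is below
#' 1000) to produce observations `X[[k]] = A[[k]] %*% S[[k]]`.
#'
#' @param config A [sim_config()] object.
#' @return A list with components
#'   \describe{
#'     \item{data}{`dataset_stack`: the `K` observed matrices `X` plus
#'       `N`, `K`, `T`.}
#'     \item{truth}{`ground_truth`: mixing matrices `A`, per-dataset sources
#'       `S`, SCV matrices `scvs` (each `K x T`), logical `shared_flags`,
#'       population `scv_covariances`, and the shared-level grid `mu`.}
#'   }
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$seed)) .generate_ground_truth_impl(config)
  else withr::with_seed(config$seed, .generate_ground_truth_impl(config))
}

.generate_ground_truth_impl <- function(config) {
  N <- config$n_sources; K <- config$n_datasets; Tn <- config$n_samples
  Ns <- config$n_shared
  mus <- .mu_grid(Ns, config$mu_lo, config$mu_hi)
  covs <- vector("list", N)
  flags <- logical(N)
  for (n in seq_len(N)) {
    if (n <= Ns) {
      covs[[n]] <- make_shared_covariance(mus[n], K)
      flags[n] <- TRUE
    } else {
      covs[[n]] <- if (K >= 2L) make_nonshared_covariance(K) else
        matrix(1, 1, 1)
    }
  }
  scvs <- lapply(seq_len(N), function(n)
    .standardize_rows(sample_mggd(covs[[n]], config$beta, Tn)))
  S <- lapply(seq_len(K), function(k) {
    Sk <- matrix(0, N, Tn)
    for (n in seq_len(N)) Sk[n, ] <- scvs[[n]][k, ]
    Sk
  })
  A <- lapply(seq_len(K), function(k) .draw_mixing(N))
  X <- lapply(seq_len(K), function(k) A[[k]] %*% S[[k]])
  data <- structure(list(X = X, N = N, K = K, T = Tn),
                    class = "dataset_stack")
  truth <- structure(
    list(A = A, S = S, scvs = scvs, shared_flags = flags,
         scv_covariances = covs, mu = mus, beta = config$beta),
    class = "ground_truth")
  list(data = data, truth = truth)
}

# square Gaussian mixing matrix with condition number below 1e3
.draw_mixing <- function(N, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    A <- matrix(stats::rnorm(N * N), N, N)
    if (N == 1L) {
      if (abs(A[1, 1]) > 1e-3) return(A)
      next
    }
    d <- svd(A, nu = 0, nv = 0)$d
    if (d[N] > 0 && d[1] / d[N] < 1e3) return(A)
  }
  stop("failed to draw a well-conditioned mixing matrix in ", max_tries,
       " tries")
}

#' @export
print.dataset_stack <- function(x, ...) {
  cat(sprintf("Dataset stack: K = %d datasets of %d x %d (observations x samples)\n",
              x$K, x$N, x$T))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d SCVs over %d datasets (%d shared, %d non-shared)\n",
              length(x$scvs), nrow(x$scvs[[1]]), sum(x$shared_flags),
              sum(!x$shared_flags)))
  if (length(x$mu))
    cat("  shared correlation levels:", paste(sprintf("%.3f", x$mu),
                                              collapse = ", "), "\n")
  invisible(x)
}
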
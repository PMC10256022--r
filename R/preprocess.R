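#' Standardize the rows of a data matrix
#'
#' Centers each row (observation) to zero mean and scales it to unit
#' variance, using the unbiased variance (divisor `T - 1`). Standardizing is
#' the usual first step before joint blind source separation so that sample
#' covariances and correlations coincide.
#'
#' @param X Numeric matrix, observations in rows and samples in columns
#'   (`T >= 2`).
#' @return Matrix of the same shape with standardized rows.
#' @export
standardize <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 samples (columns) to standardize")
  .standardize_rows(X)
}

#' Whiten a data matrix by principal component analysis
#'
#' Centers the rows, eigendecomposes the sample covariance (divisor
#' `T - 1`), and projects onto the top-`order` eigenpairs scaled so the
#' output sample covariance is the identity. Eigenvalues are taken in
#' descending order; each eigenvector's sign is fixed so its
#' largest-magnitude entry is positive, making the whitener deterministic.
#' Directions whose eigenvalue falls below `1e-10` times the largest are
#' treated as numerically null and refused: keeping them would let
#' near-zero eigenvalues dominate downstream log-determinant costs.
#'
#' @param X Numeric matrix (`N_obs x T`).
#' @param order Number of components to keep, between 1 and the numerical
#'   rank of the centered data.
#' @return List with `data` (`order x T` whitened matrix), `whitener`
#'   (`order x N_obs`), and `mean` (row means removed).
#' @export
whiten <- function(X, order = nrow(X)) {
  if (!is.matrix(X)) X <- as.matrix(X)
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be at least 1")
  if (order > nrow(X)) stop("`order` exceeds the number of observations (",
                            nrow(X), ")")
  m <- rowMeans(X)
  Xc <- X - m
  Cs <- tcrossprod(Xc) / (ncol(X) - 1)
  e <- eigen((Cs + t(Cs)) / 2, symmetric = TRUE)
  rank <- sum(e$values > 1e-10 * max(e$values, 0))
  if (order > rank)
    stop("`order` (", order, ") exceeds the numerical rank (", rank,
         ") of the centered data")
  U <- e$vectors[, seq_len(order), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(order)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  W <- (1 / sqrt(e$values[seq_len(order)])) * t(U)
  list(data = W %*% Xc, whitener = W, mean = m)
}

#' Whiten every dataset in a stack
#'
#' Applies [whiten()] independently to each of the `K` datasets (the mixing
#' model has a distinct mixing matrix per dataset, so whitening is
#' per-dataset rather than group-level), reducing each to `order` rows.
#'
#' @param stack A `dataset_stack` (see [generate_ground_truth()]) or a list
#'   of `N_obs x T` matrices.
#' @param order Model order `N` retained per dataset; defaults to the full
#'   observation count.
#' @return An object of class `whitened_stack` with `data` (list of
#'   `order x T` matrices), `whiteners`, `means`, `order`, `K`, `T`.
#' @export
whiten_stack <- function(stack, order = NULL) {
  X <- if (inherits(stack, "dataset_stack")) stack$X else stack
  if (!is.list(X) || !length(X)) stop("`stack` must contain datasets")
  Ts <- vapply(X, ncol, integer(1))
  if (length(unique(Ts)) != 1L)
    stop("all datasets must share the same number of samples T")
  if (is.null(order)) order <- nrow(X[[1]])
  wh <- lapply(X, whiten, order = order)
  structure(
    list(data = lapply(wh, `[[`, "data"),
         whiteners = lapply(wh, `[[`, "whitener"),
         means = lapply(wh, `[[`, "mean"),
         order = as.integer(order), K = length(X), T = Ts[1]),
    class = "whitened_stack")
}

#' @export
print.whitened_stack <- function(x, ...) {
  cat(sprintf("Whitened stack: K = %d datasets, order N = %d, T = %d\n",
              x$K, x$order, x$T))
  invisible(x)
}
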
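#' Sample covariance of the vertically stacked datasets
#'
#' Concatenates the `K` datasets into one tall `NK x T` matrix and returns
#' its unbiased sample covariance (divisor `T - 1`), laid out as a `K x K`
#' grid of `N x N` blocks; block `(k, l)` is the cross-covariance of
#' datasets `k` and `l`. For whitened input the diagonal blocks are the
#' identity. This single matrix carries all the second-order statistics the
#' SUMCORR solution and the Gaussian-prior IVA cost need, so both run off
#' it without ever revisiting the samples.
#'
#' @param data A `whitened_stack`, a `dataset_stack`, or a list of `N x T`
#'   matrices sharing `T`.
#' @return An object of class `stacked_cov` with `matrix` (`NK x NK`), `N`,
#'   and `K`.
#' @export
stacked_covariance <- function(data) {
  X <- if (inherits(data, "whitened_stack")) data$data
       else if (inherits(data, "dataset_stack")) data$X
       else data
  if (!is.list(X) || !length(X)) stop("`data` must contain datasets")
  Ns <- vapply(X, nrow, integer(1))
  Ts <- vapply(X, ncol, integer(1))
  if (length(unique(Ns)) != 1L)
    stop("all datasets must share the same number of rows N")
  if (length(unique(Ts)) != 1L)
    stop("all datasets must share the same number of samples T")
  tall <- do.call(rbind, X)
  tall <- tall - rowMeans(tall)
  C <- tcrossprod(tall) / (Ts[1] - 1)
  C <- (C + t(C)) / 2
  structure(list(matrix = C, N = Ns[1], K = length(X)),
            class = "stacked_cov")
}

#' @export
print.stacked_cov <- function(x, ...) {
  cat(sprintf("Stacked covariance: %d x %d (K = %d blocks of N = %d)\n",
              nrow(x$matrix), ncol(x$matrix), x$K, x$N))
  invisible(x)
}

# row index range of dataset k inside the stacked layout
.block_idx <- function(k, N) ((k - 1L) * N + 1L):(k * N)

#' Analytic MCCA SUMCORR demixing
#'
#' The multiset-CCA variant that maximizes the sum of correlations within
#' each SCV has an analytic solution: the top-`N` principal eigenvectors of
#' the stacked covariance. The `n`-th principal eigenvector, split into `K`
#' length-`N` blocks, yields (up to scale) the demixing vectors of the
#' `n`-th SCV across the `K` datasets. Each block becomes row `n` of
#' `W[[k]]`, renormalized to unit norm, with a deterministic sign (the
#' block's largest-magnitude entry is made positive). Because the solution
#' inherently assumes a rank-one SCV model, it excels on shared SCVs and is
#' the natural initializer for IVA on data with a shared subspace. With
#' `K = 1` it reduces to PCA of the single dataset.
#'
#' @param C A `stacked_cov` from [stacked_covariance()].
#' @param N Model order (number of SCVs to extract); defaults to the block
#'   size.
#' @return A `demixing_set`: list with `W` (list of `K` `N x N` matrices),
#'   `N`, `K`.
#' @export
sumcorr_demixing <- function(C, N = C$N) {
  stopifnot(inherits(C, "stacked_cov"))
  N <- as.integer(N)
  if (N < 1L || N > C$N)
    stop("`N` must lie in [1, ", C$N, "] (the block size)")
  K <- C$K; Nb <- C$N
  e <- eigen(C$matrix, symmetric = TRUE)
  W <- lapply(seq_len(K), function(k) matrix(0, N, Nb))
  for (n in seq_len(N)) {
    v <- e$vectors[, n]
    for (k in seq_len(K)) {
      b <- v[.block_idx(k, Nb)]
      nb <- sqrt(sum(b^2))
      if (nb < 1e-12) {
        # fully degenerate spectrum (e.g. identity covariance): the
        # eigenvector does not load on this dataset at all; fall back to
        # the axis-aligned row, tie-broken by index
        warning("SCV ", n, " does not load on dataset ", k,
                "; using the axis-aligned demixing vector")
        b <- numeric(Nb); b[n] <- 1
      } else {
        b <- b / nb
        i <- which.max(abs(b))
        if (b[i] < 0) b <- -b
      }
      W[[k]][n, ] <- b
    }
  }
  new_demixing_set(W)
}

#' Construct a demixing set
#'
#' Wraps `K` demixing matrices (rows are per-SCV demixing vectors, unit
#' norm by convention) in the class the optimizers exchange.
#'
#' @param W List of `K` numeric matrices with identical dimensions.
#' @return An object of class `demixing_set`.
#' @export
new_demixing_set <- function(W) {
  stopifnot(is.list(W), length(W) >= 1L)
  d <- vapply(W, dim, integer(2))
  if (length(unique(d[1, ])) != 1L || length(unique(d[2, ])) != 1L)
    stop("all demixing matrices must share dimensions")
  structure(list(W = W, N = d[1, 1], K = length(W)), class = "demixing_set")
}

#' @export
print.demixing_set <- function(x, ...) {
  cat(sprintf("Demixing set: K = %d matrices of %d x %d\n",
              x$K, x$N, ncol(x$W[[1]])))
  invisible(x)
}

#' Apply a demixing set to a stack of datasets
#'
#' @param W A `demixing_set`.
#' @param data A `whitened_stack`, `dataset_stack`, or list of matrices.
#' @return List of `K` estimated source matrices `Y[[k]] = W[[k]] X[[k]]`.
#' @export
apply_demixing <- function(W, data) {
  stopifnot(inherits(W, "demixing_set"))
  X <- if (inherits(data, "whitened_stack")) data$data
       else if (inherits(data, "dataset_stack")) data$X
       else data
  if (length(X) != W$K) stop("dataset count does not match demixing set")
  lapply(seq_len(W$K), function(k) W$W[[k]] %*% X[[k]])
}
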
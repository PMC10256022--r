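#' Optimizer settings for IVA-G
#'
#' @param max_iter Maximum number of full sweeps over all demixing vectors.
#' @param tol Convergence threshold on the maximum absolute entrywise change
#'   of any demixing matrix between sweeps (scale-free under the unit-norm
#'   row convention).
#' @param step0 Initial step size of the per-vector gradient steps.
#' @param jitter Ridge added to each SCV covariance before taking its
#'   log-determinant; guards the near-singular covariances of shared SCVs.
#' @param seed Seed for the random initialization used when no initial
#'   demixing set is supplied; `NULL` uses the current RNG state.
#' @return An object of class `ivag_settings`.
#' @export
ivag_settings <- function(max_iter = 1024L, tol = 1e-6, step0 = 0.1,
                          jitter = 1e-12, seed = NULL) {
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("`max_iter` must be at least 1")
  if (tol <= 0) stop("`tol` must be positive")
  if (step0 <= 0) stop("`step0` must be positive")
  if (jitter < 0) stop("`jitter` must be non-negative")
  structure(list(max_iter = max_iter, tol = tol, step0 = step0,
                 jitter = jitter, seed = seed), class = "ivag_settings")
}

# resolve input to a stacked_cov (and remember the source stack if present)
.as_stacked_cov <- function(data) {
  if (inherits(data, "stacked_cov")) data else stacked_covariance(data)
}

#' Covariance of one estimated SCV
#'
#' The covariance of the `n`-th estimated SCV, `[Sigma]_{kl} =
#' w_n[k]' C_{kl} w_n[l]`, computed algebraically from the stacked
#' covariance rather than from the samples; for whitened data and unit-norm
#' demixing rows its diagonal is 1, making it a correlation matrix.
#'
#' @param W A `demixing_set`.
#' @param C A `stacked_cov` (or data accepted by [stacked_covariance()]).
#' @param n SCV index in `1..N`.
#' @return Symmetric `K x K` matrix.
#' @export
scv_covariance <- function(W, C, n) {
  stopifnot(inherits(W, "demixing_set"))
  C <- .as_stacked_cov(C)
  n <- as.integer(n)
  if (n < 1L || n > W$N) stop("`n` must lie in [1, ", W$N, "]")
  K <- W$K; Nb <- C$N
  B <- matrix(0, Nb * K, K)
  for (k in seq_len(K)) B[.block_idx(k, Nb), k] <- W$W[[k]][n, ]
  S <- crossprod(B, C$matrix %*% B)
  (S + t(S)) / 2
}

# log|det| of a symmetric PD matrix via Cholesky; -Inf if not PD
.logdet_psd <- function(S, jitter = 0) {
  if (jitter > 0) S <- S + diag(jitter, nrow(S))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  2 * sum(log(diag(ch)))
}

#' Gaussian-prior IVA cost
#'
#' The mutual-information cost under a multivariate Gaussian SCV prior:
#' `N*K*log(2*pi*e)/2 + (1/2) * sum_n log det(Sigma_n) -
#' sum_k log |det W[[k]]|`, where `Sigma_n` is the covariance of the `n`-th
#' estimated SCV. Equivalently the second term is half the log of the
#' product of all SCV covariance eigenvalues. Minimizing it simultaneously
#' decorrelates different SCVs and maximizes correlation within each SCV.
#' A singular demixing matrix yields `Inf` (not an error) so line searches
#' can reject the step.
#'
#' @param W A `demixing_set` with nonsingular matrices.
#' @param C A `stacked_cov` (or data accepted by [stacked_covariance()]).
#' @param jitter Ridge added to each SCV covariance before the
#'   log-determinant.
#' @return Scalar cost (possibly `Inf`).
#' @export
iva_g_cost <- function(W, C, jitter = 1e-12) {
  stopifnot(inherits(W, "demixing_set"))
  C <- .as_stacked_cov(C)
  N <- W$N; K <- W$K
  ld_w <- vapply(W$W, function(Wk) {
    d <- determinant(Wk, logarithm = TRUE)
    as.numeric(d$modulus)
  }, numeric(1))
  if (any(!is.finite(ld_w))) return(Inf)
  ld_s <- vapply(seq_len(N), function(n)
    .logdet_psd(scv_covariance(W, C, n), jitter), numeric(1))
  if (any(!is.finite(ld_s))) return(Inf)
  N * K * log(2 * pi * exp(1)) / 2 + sum(ld_s) / 2 - sum(ld_w)
}

# random unit-norm-row demixing set
.random_demixing <- function(N, K, seed = NULL) {
  draw <- function() {
    W <- lapply(seq_len(K), function(k) {
      M <- matrix(stats::rnorm(N * N), N, N)
      M / sqrt(rowSums(M^2))
    })
    new_demixing_set(W)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Optimize the IVA-G cost
#'
#' Minimizes the Gaussian-prior IVA cost by cyclic decoupled updates: for
#' each SCV index `n` and dataset `k`, a steepest-descent step on the
#' demixing vector `w_n[k]` with a backtracking line search (step halving,
#' at most 20 halvings), followed by renormalization of the row to unit
#' norm (the cost is invariant to per-row scaling, so renormalizing is
#' free). All gradient and cost algebra runs off the one-time stacked
#' covariance, never the samples, so the per-iteration cost is independent
#' of `T`. The cost trace is non-increasing by construction; the run stops
#' when the largest absolute change in any demixing entry over a sweep
#' falls below `tol`, or at `max_iter` sweeps.
#'
#' @param data A `whitened_stack`, a list of equally sized data matrices,
#'   or a precomputed `stacked_cov`.
#' @param W_init Initial `demixing_set`; `NULL` draws a random unit-norm
#'   initialization (seeded via `settings$seed`). Pass the result of
#'   [sumcorr_demixing()] for the shared-subspace-friendly initialization.
#' @param settings An [ivag_settings()] object.
#' @return An `ivag_result`: `demixing` (a `demixing_set`), `cost_trace`
#'   (cost after each sweep, preceded by the initial cost), `n_iter`,
#'   `converged`.
#' @export
iva_g_optimize <- function(data, W_init = NULL, settings = ivag_settings()) {
  stopifnot(inherits(settings, "ivag_settings"))
  C <- .as_stacked_cov(data)
  N <- C$N; K <- C$K
  Cm <- C$matrix
  if (is.null(W_init)) W_init <- .random_demixing(N, K, settings$seed)
  stopifnot(inherits(W_init, "demixing_set"))
  if (W_init$N != N || W_init$K != K)
    stop("`W_init` dimensions do not match the data")
  jitter <- settings$jitter

  # state: unit-norm rows, cached inverses, log-dets, SCV covariances
  W <- lapply(W_init$W, function(Wk) Wk / sqrt(rowSums(Wk^2)))
  Winv <- lapply(W, solve)
  ld_w <- vapply(W, function(Wk)
    as.numeric(determinant(Wk, logarithm = TRUE)$modulus), numeric(1))
  # C_{kl} blocks
  Cb <- vector("list", K)
  for (k in seq_len(K)) {
    Cb[[k]] <- vector("list", K)
    for (l in seq_len(K))
      Cb[[k]][[l]] <- Cm[.block_idx(k, N), .block_idx(l, N), drop = FALSE]
  }
  # Wn[[n]]: K x N matrix of the n-th demixing vectors across datasets
  Wn <- lapply(seq_len(N), function(n)
    t(vapply(W, function(Wk) Wk[n, ], numeric(N))))
  if (N == 1L) Wn <- lapply(seq_len(N), function(n)
    matrix(vapply(W, function(Wk) Wk[n, ], numeric(N)), K, N))
  sigma_of <- function(n) {
    S <- matrix(0, K, K)
    for (k in seq_len(K)) {
      wk <- Wn[[n]][k, ]
      for (l in k:K) {
        v <- sum(wk * (Cb[[k]][[l]] %*% Wn[[n]][l, ]))
        S[k, l] <- v; S[l, k] <- v
      }
    }
    S
  }
  Sig <- lapply(seq_len(N), function(n) sigma_of(n))
  ld_s <- vapply(Sig, .logdet_psd, numeric(1), jitter = jitter)
  const <- N * K * log(2 * pi * exp(1)) / 2
  cost0 <- const + sum(ld_s) / 2 - sum(ld_w)
  if (!is.finite(cost0))
    stop("initial demixing set gives an infinite cost (singular matrix?)")
  cost_trace <- cost0

  stepmat <- matrix(settings$step0, N, K)
  converged <- FALSE
  n_iter <- 0L
  for (iter in seq_len(settings$max_iter)) {
    max_delta <- 0
    for (n in seq_len(N)) {
      # Q[, l] = C_{kl} w_n[l], refreshed per k below
      for (k in seq_len(K)) {
        w_old <- Wn[[n]][k, ]
        Q <- vapply(seq_len(K), function(l)
          as.numeric(Cb[[k]][[l]] %*% Wn[[n]][l, ]), numeric(N))
        if (N == 1L) Q <- matrix(Q, 1L, K)
        Sj <- Sig[[n]] + diag(jitter, K)
        sinv_row <- tryCatch(solve(Sj)[k, ], error = function(e) NULL)
        if (is.null(sinv_row)) next
        grad <- as.numeric(Q %*% sinv_row) - Winv[[k]][, n]
        gn <- sqrt(sum(grad^2))
        if (!is.finite(gn) || gn < 1e-14) next
        s <- stepmat[n, k]
        accepted <- FALSE
        for (h in 0:20) {
          w <- w_old - (s / 2^h) * grad
          nw <- sqrt(sum(w^2))
          if (nw < 1e-12) next
          w <- w / nw
          dratio <- sum(w * Winv[[k]][, n])   # det(W_new)/det(W_old)
          if (!is.finite(dratio) || abs(dratio) < 1e-12) next
          srow <- as.numeric(w %*% Q)
          srow[k] <- sum(w * (Cb[[k]][[k]] %*% w))
          S_new <- Sig[[n]]
          S_new[k, ] <- srow; S_new[, k] <- srow
          ld_new <- .logdet_psd(S_new, jitter)
          if (!is.finite(ld_new)) next
          dcost <- (ld_new - ld_s[n]) / 2 - log(abs(dratio))
          if (dcost < -1e-13) {
            # commit: Sherman-Morrison update of the inverse
            u <- w - w_old
            col_n <- Winv[[k]][, n]
            Winv[[k]] <- Winv[[k]] -
              tcrossprod(col_n, as.numeric(u %*% Winv[[k]])) / dratio
            ld_w[k] <- ld_w[k] + log(abs(dratio))
            W[[k]][n, ] <- w
            Wn[[n]][k, ] <- w
            Sig[[n]] <- S_new
            ld_s[n] <- ld_new
            stepmat[n, k] <- min(2 * (s / 2^h), 10)
            max_delta <- max(max_delta, max(abs(u)))
            accepted <- TRUE
            break
          }
        }
        if (!accepted) stepmat[n, k] <- max(s / 4, 1e-10)
      }
    }
    # refresh caches exactly once per sweep to cap accumulated error
    Winv <- lapply(W, solve)
    ld_w <- vapply(W, function(Wk)
      as.numeric(determinant(Wk, logarithm = TRUE)$modulus), numeric(1))
    Sig <- lapply(seq_len(N), function(n) sigma_of(n))
    ld_s <- vapply(Sig, .logdet_psd, numeric(1), jitter = jitter)
    cost <- const + sum(ld_s) / 2 - sum(ld_w)
    if (cost > cost_trace[length(cost_trace)] + 1e-8)
      stop("optimizer stall: cost increased from ",
           format(cost_trace[length(cost_trace)]), " to ", format(cost),
           " at sweep ", iter)
    cost_trace <- c(cost_trace, cost)
    n_iter <- iter
    if (max_delta < settings$tol) { converged <- TRUE; break }
  }
  structure(
    list(demixing = new_demixing_set(W), cost_trace = cost_trace,
         n_iter = n_iter, converged = converged, settings = settings),
    class = "ivag_result")
}

#' @export
print.ivag_result <- function(x, ...) {
  cat(sprintf(
    "IVA-G result: N = %d, K = %d; %d sweep(s), %sconverged\n",
    x$demixing$N, x$demixing$K, x$n_iter, if (x$converged) "" else "NOT "))
  cat(sprintf("  cost %.6f -> %.6f\n", x$cost_trace[1],
              x$cost_trace[length(x$cost_trace)]))
  invisible(x)
}
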
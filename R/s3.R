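#' Spectral gap ratio of an SCV covariance
#'
#' `sigma = (lambda_1 - lambda_2) / lambda_1` for the two largest
#' eigenvalues of a `K x K` SCV covariance. A shared SCV — one source
#' repeated across the `K` datasets — has a single dominant eigenvalue, so
#' its ratio is near 1; a full-rank SCV has comparable top eigenvalues and
#' a ratio near 0. For the rank-one-plus-identity covariance with level
#' `mu` the ratio is exactly `K*mu / (K*mu + 1 - mu)`.
#'
#' @param cov Symmetric positive semi-definite matrix with `K >= 2` and a
#'   strictly positive top eigenvalue.
#' @return Scalar in `[0, 1]`.
#' @export
spectral_gap_ratio <- function(cov) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov))
    stop("`cov` must be a square matrix")
  if (nrow(cov) < 2L)
    stop("spectral gap ratio is undefined for K = 1")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("`cov` must be symmetric")
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) stop("top eigenvalue must be positive")
  (ev[1] - ev[2]) / ev[1]
}

#' Partition SCVs into shared and non-shared subspaces
#'
#' Classifies each SCV by its spectral gap ratio: strictly greater than the
#' threshold routes to the shared subspace, ties and smaller values to the
#' non-shared one. Original index order is preserved within each subset.
#'
#' @param covs List of `K x K` SCV covariance matrices (one per SCV), or a
#'   numeric vector of precomputed spectral gap ratios.
#' @param threshold Classification threshold Delta in `(0, 1)`; 0.86 has
#'   proven a useful default on fMRI-like data.
#' @return An object of class `subspace_partition` with `sigma`,
#'   `threshold`, `shared_idx`, `nonshared_idx`, `Ns`, `Nns`.
#' @export
partition_scvs <- function(covs, threshold = 0.86) {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)")
  sigma <- if (is.numeric(covs)) as.numeric(covs)
           else vapply(covs, spectral_gap_ratio, numeric(1))
  if (!length(sigma)) stop("need at least one SCV")
  shared <- which(sigma > threshold)
  nonshared <- setdiff(seq_along(sigma), shared)
  structure(
    list(sigma = sigma, threshold = threshold,
         shared_idx = shared, nonshared_idx = nonshared,
         Ns = length(shared), Nns = length(nonshared)),
    class = "subspace_partition")
}

#' @export
print.subspace_partition <- function(x, ...) {
  cat(sprintf(
    "Subspace partition (Delta = %.2f): %d shared, %d non-shared of %d SCVs\n",
    x$threshold, x$Ns, x$Nns, length(x$sigma)))
  invisible(x)
}

#' Compose stage-wise demixing into one total demixing
#'
#' The final-stage demixing matrices act on the reordered stage-1 sources;
#' composing them with the stage-1 demixing gives the single linear map
#' from whitened data to final sources:
#' `W_total[[k]] = blockdiag(Ws[[k]], Wns[[k]]) %*% P %*% W_stage1[[k]]`,
#' with `P` the permutation sorting stage-1 rows into shared-first order.
#' Either subspace may be empty, in which case its block is dropped.
#'
#' @param W_stage1 Stage-1 `demixing_set`.
#' @param partition A `subspace_partition`.
#' @param Ws,Wns Final-stage `demixing_set`s for the shared and non-shared
#'   subspaces (or `NULL` when that subspace is empty).
#' @return A `demixing_set` of full `N x N` matrices.
#' @export
compose_demixing <- function(W_stage1, partition, Ws = NULL, Wns = NULL) {
  stopifnot(inherits(W_stage1, "demixing_set"),
            inherits(partition, "subspace_partition"))
  N <- W_stage1$N; K <- W_stage1$K
  if (partition$Ns + partition$Nns != N)
    stop("partition size does not match the stage-1 demixing order")
  if (partition$Ns > 0L) {
    stopifnot(inherits(Ws, "demixing_set"))
    if (Ws$N != partition$Ns || Ws$K != K)
      stop("`Ws` dimensions do not match the shared subspace")
  }
  if (partition$Nns > 0L) {
    stopifnot(inherits(Wns, "demixing_set"))
    if (Wns$N != partition$Nns || Wns$K != K)
      stop("`Wns` dimensions do not match the non-shared subspace")
  }
  perm <- c(partition$shared_idx, partition$nonshared_idx)
  W <- lapply(seq_len(K), function(k) {
    B <- matrix(0, N, N)
    if (partition$Ns > 0L)
      B[seq_len(partition$Ns), seq_len(partition$Ns)] <- Ws$W[[k]]
    if (partition$Nns > 0L)
      B[partition$Ns + seq_len(partition$Nns),
        partition$Ns + seq_len(partition$Nns)] <- Wns$W[[k]]
    B %*% W_stage1$W[[k]][perm, , drop = FALSE]
  })
  new_demixing_set(W)
}

#' Run the three-stage shared-subspace IVA
#'
#' The full pipeline: (1) IVA-G on the whitened data initialized with the
#' analytic SUMCORR solution; (2) classification of each estimated SCV as
#' shared or non-shared by the spectral gap ratio of its covariance
#' (computed from the stage-1 demixing and the stacked covariance) against
#' the threshold; (3) a separate IVA pass on each subspace's source stack,
#' both initialized with identity matrices (i.e. warm-started at the
#' stage-1 sources). The stage demixings are composed into one total
#' demixing mapping whitened data to final sources, returned in
#' shared-first row order.
#'
#' @param data A `whitened_stack` (see [whiten_stack()]).
#' @param threshold Spectral-gap-ratio threshold Delta in `(0, 1)`.
#' @param settings [ivag_settings()] shared by all stages.
#' @param stage3_optimizer Optimizer applied per subspace in stage 3; any
#'   function with the signature of [iva_g_optimize()] (the default). This
#'   is the hook for plugging in IVA variants that exploit further source
#'   statistics.
#' @return An `iva_s3_result` with `stage1`, `partition`,
#'   `stage3_shared`, `stage3_nonshared` (each `NULL` when its subspace is
#'   empty), `total_demixing`, `final_sources` (list of `K` `N x T`
#'   matrices, shared rows first), `row_map` (original stage-1 SCV index of
#'   each final row), and `sigma`.
#' @export
run_iva_s3 <- function(data, threshold = 0.86, settings = ivag_settings(),
                       stage3_optimizer = iva_g_optimize) {
  stopifnot(inherits(data, "whitened_stack"))
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)")
  C <- stacked_covariance(data)
  N <- C$N; K <- C$K
  W0 <- sumcorr_demixing(C, N)
  stage1 <- tryCatch(iva_g_optimize(C, W0, settings), error = function(e)
    stop("stage 1 (SUMCORR-initialized IVA-G) failed: ",
         conditionMessage(e)))
  covs <- lapply(seq_len(N), function(n)
    scv_covariance(stage1$demixing, C, n))
  partition <- partition_scvs(covs, threshold)

  Y1 <- apply_demixing(stage1$demixing, data)
  run_stage3 <- function(idx, label) {
    if (!length(idx)) return(NULL)
    Ysub <- lapply(Y1, function(Yk) Yk[idx, , drop = FALSE])
    Wid <- new_demixing_set(
      lapply(seq_len(K), function(k) diag(length(idx))))
    tryCatch(stage3_optimizer(Ysub, Wid, settings), error = function(e)
      stop("stage 3 (", label, " subspace) failed: ", conditionMessage(e)))
  }
  s3s <- run_stage3(partition$shared_idx, "shared")
  s3ns <- run_stage3(partition$nonshared_idx, "non-shared")
  total <- compose_demixing(stage1$demixing, partition,
                            if (is.null(s3s)) NULL else s3s$demixing,
                            if (is.null(s3ns)) NULL else s3ns$demixing)
  final <- apply_demixing(total, data)
  structure(
    list(stage1 = stage1, partition = partition,
         stage3_shared = s3s, stage3_nonshared = s3ns,
         total_demixing = total, final_sources = final,
         row_map = c(partition$shared_idx, partition$nonshared_idx),
         sigma = partition$sigma, threshold = threshold),
    class = "iva_s3_result")
}

#' @export
print.iva_s3_result <- function(x, ...) {
  p <- x$partition
  cat(sprintf("IVA-S3 result: N = %d SCVs, K = %d datasets\n",
              length(p$sigma), x$total_demixing$K))
  cat(sprintf("  partition at Delta = %.2f: %d shared / %d non-shared\n",
              p$threshold, p$Ns, p$Nns))
  cat(sprintf("  stage-1 sweeps: %d; stage-3 sweeps: %s (shared), %s (non-shared)\n",
              x$stage1$n_iter,
              if (is.null(x$stage3_shared)) "-" else
                format(x$stage3_shared$n_iter),
              if (is.null(x$stage3_nonshared)) "-" else
                format(x$stage3_nonshared$n_iter)))
  invisible(x)
}
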
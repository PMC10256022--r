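#' Intersymbol interference of a global mix-demix product
#'
#' The normalized ISI of `G = W %*% A`: 0 when `G` is a scaled permutation
#' (perfect separation up to the inherent scale and permutation
#' ambiguities), 1 in the worst case. Each row's entries are compared with
#' the row's largest magnitude, likewise per column, and the excesses are
#' averaged and scaled by `2*N*(N-1)`.
#'
#' @param G Square numeric matrix, `N >= 2`, with no all-zero row or
#'   column.
#' @return Scalar in `[0, 1]`.
#' @export
isi_single <- function(G) {
  if (!is.matrix(G) || nrow(G) != ncol(G))
    stop("`G` must be a square matrix")
  N <- nrow(G)
  if (N < 2L) stop("ISI needs N >= 2")
  A <- abs(G)
  rmax <- apply(A, 1, max)
  cmax <- apply(A, 2, max)
  if (any(rmax == 0) || any(cmax == 0))
    stop("`G` has an all-zero row or column")
  rows <- sum(rowSums(A / rmax) - 1)
  cols <- sum(colSums(t(t(A) / cmax)) - 1)
  (rows + cols) / (2 * N * (N - 1))
}

#' Joint ISI over K mix-demix products
#'
#' The ISI of the entrywise-absolute average `(1/K) * sum_k |G[[k]]|`.
#' It is 0 only when every `G[[k]]` is a scaled version of one *common*
#' permutation, so it additionally penalizes datasets whose sources are
#' aligned to different SCV orders — the failure mode a per-dataset ISI
#' cannot see.
#'
#' @param G_list List of equally sized square matrices (or a single
#'   matrix).
#' @return Scalar in `[0, 1]`.
#' @export
joint_isi <- function(G_list) {
  if (is.matrix(G_list)) G_list <- list(G_list)
  stopifnot(is.list(G_list), length(G_list) >= 1L)
  d <- vapply(G_list, dim, integer(2))
  if (length(unique(c(d))) != 1L)
    stop("all matrices must be square and equally sized")
  M <- Reduce(`+`, lapply(G_list, abs)) / length(G_list)
  isi_single(M)
}

#' Global mix-demix products for simulated data
#'
#' Forms `G[[k]] = W[[k]] %*% A_eff[[k]]` where `A_eff` is the mixing as
#' seen by the demixing: when the data were whitened, the whitener is
#' folded in (`A_eff[[k]] = whitener[[k]] %*% A[[k]]`).
#'
#' @param W A `demixing_set`.
#' @param truth A `ground_truth` (or a list of mixing matrices).
#' @param whiteners Optional list of whitening matrices, or a
#'   `whitened_stack`.
#' @return List of `K` square matrices.
#' @export
mix_demix_products <- function(W, truth, whiteners = NULL) {
  stopifnot(inherits(W, "demixing_set"))
  A <- if (inherits(truth, "ground_truth")) truth$A else truth
  if (length(A) != W$K) stop("mixing count does not match demixing set")
  if (inherits(whiteners, "whitened_stack")) whiteners <- whiteners$whiteners
  lapply(seq_len(W$K), function(k) {
    Ak <- if (is.null(whiteners)) A[[k]] else whiteners[[k]] %*% A[[k]]
    W$W[[k]] %*% Ak
  })
}

# equiprobable (rank-based) bin assignment; B bins over T points
.equibin <- function(y, bins) {
  r <- rank(y, ties.method = "first")
  pmin(ceiling(bins * r / length(y)), bins)
}

# plug-in discrete mutual information (natural log) of two bin vectors
.plugin_mi <- function(bi, bj, bins) {
  tab <- table(factor(bi, levels = seq_len(bins)),
               factor(bj, levels = seq_len(bins)))
  p <- tab / sum(tab)
  pi <- rowSums(p); pj <- colSums(p)
  nz <- p > 0
  sum(p[nz] * (log(p[nz]) - log(outer(pi, pj))[nz]))
}

#' Normalized mutual information between two estimated sources
#'
#' `2 * I(y_i, y_j) / (I(y_i, y_i) + I(y_j, y_j))`, where `I` is plug-in
#' discrete mutual information over equiprobable (rank-based) bins with
#' natural logarithms, and the self-information `I(y, y)` is the
#' discretized entropy. Rank-based bins make the measure invariant to
#' monotone increasing (hence affine, up to sign) transformations. Values
#' lie in `[0, 1]`; near 0 indicates well-separated sources.
#'
#' @param y_i,y_j Numeric vectors of equal length `T`, non-constant.
#' @param bins Number of bins per variable; defaults to
#'   `floor(T^(1/3))`. The plug-in estimator's bias for independent inputs
#'   is about `(bins - 1)^2 / (2 T)` nats, so the cube-root rule keeps
#'   spurious dependence below ~1e-3 while the joint histogram still
#'   averages well over `T^(1/3)` counts per cell.
#' @return Scalar in `[0, 1]`.
#' @export
normalized_mi <- function(y_i, y_j, bins = NULL) {
  y_i <- as.numeric(y_i); y_j <- as.numeric(y_j)
  Tn <- length(y_i)
  if (length(y_j) != Tn) stop("`y_i` and `y_j` must have equal length")
  if (stats::var(y_i) == 0 || stats::var(y_j) == 0)
    stop("constant input: mutual information is undefined")
  if (is.null(bins)) bins <- max(2L, floor(Tn^(1 / 3)))
  bins <- as.integer(bins)
  if (Tn < 10L * bins)
    stop("need T >= 10 * bins samples for a stable estimate")
  bi <- .equibin(y_i, bins); bj <- .equibin(y_j, bins)
  hi <- .plugin_mi(bi, bi, bins)
  hj <- .plugin_mi(bj, bj, bins)
  mij <- .plugin_mi(bi, bj, bins)
  max(0, min(1, 2 * mij / (hi + hj)))
}

#' Average pairwise normalized mutual information within a dataset
#'
#' Mean of [normalized_mi()] over all pairs of distinct rows of `Y`; a
#' summary of residual dependence among a dataset's estimated sources
#' (lower is better separation). The measure is symmetric, so the ordered
#' and unordered means coincide.
#'
#' @param Y `N x T` matrix of estimated sources (rows), `N >= 2`.
#' @param bins Passed to [normalized_mi()].
#' @return Scalar in `[0, 1]`.
#' @export
average_pairwise_nmi <- function(Y, bins = NULL) {
  if (!is.matrix(Y) || nrow(Y) < 2L)
    stop("`Y` must be a matrix with at least 2 rows")
  N <- nrow(Y)
  vals <- c()
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    vals <- c(vals, normalized_mi(Y[i, ], Y[j, ], bins))
  mean(vals)
}

#' One-sample t-maps with FDR control
#'
#' Per-voxel one-sample t statistics across subjects (`t = mean /
#' (sd / sqrt(K))`, `K - 1` degrees of freedom), two-sided p-values, and
#' Benjamini-Hochberg significance flags at level `q`. A voxel with zero
#' variance but nonzero mean has an infinite t (p = 0, maximal rank); an
#' all-zero voxel is undefined (`NaN` t, `NA` flag) and is excluded from
#' the FDR ranking.
#'
#' @param component_maps `K x V` matrix: one subject's component map per
#'   row, `K >= 3`.
#' @param q FDR level, default 0.05.
#' @return List with `t`, `p`, `p_adjusted`, `significant` (logical,
#'   `NA` where undefined), and `df`.
#' @export
one_sample_tmap <- function(component_maps, q = 0.05) {
  X <- as.matrix(component_maps)
  K <- nrow(X)
  if (K < 3L) stop("need at least 3 subjects (rows)")
  if (q <= 0 || q >= 1) stop("`q` must lie in (0, 1)")
  m <- colMeans(X)
  s <- sqrt(colSums((X - rep(m, each = K))^2) / (K - 1))
  tval <- m / (s / sqrt(K))          # Inf when s == 0, m != 0; NaN when both 0
  p <- 2 * stats::pt(-abs(tval), df = K - 1)
  ok <- !is.nan(tval)
  padj <- rep(NA_real_, length(tval))
  padj[ok] <- stats::p.adjust(p[ok], method = "BH")
  sig <- rep(NA, length(tval))
  sig[ok] <- padj[ok] <= q
  list(t = tval, p = p, p_adjusted = padj, significant = sig, df = K - 1)
}
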
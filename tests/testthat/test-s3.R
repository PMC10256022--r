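test_that("spectral gap ratio has its closed form on rank-one covariances", {
  for (mu in c(0.3, 0.5, 0.8)) for (K in c(2, 10, 100)) {
    expect_equal(spectral_gap_ratio(make_shared_covariance(mu, K)),
                 K * mu / (K * mu + 1 - mu), tolerance = 1e-10)
  }
  expect_equal(spectral_gap_ratio(make_shared_covariance(0.8, 100)),
               80 / 80.2, tolerance = 1e-10)
  expect_equal(spectral_gap_ratio(make_shared_covariance(0.5, 10)),
               5 / 5.5, tolerance = 1e-10)
  expect_identical(spectral_gap_ratio(diag(4)), 0)
  expect_error(spectral_gap_ratio(matrix(1, 1, 1)), "K = 1")
  expect_error(spectral_gap_ratio(matrix(0, 3, 3)), "positive")
})

test_that("partition routes by strict threshold and preserves order", {
  p <- partition_scvs(c(0.99, 0.50), threshold = 0.86)
  expect_equal(p$shared_idx, 1L)
  expect_equal(p$nonshared_idx, 2L)
  # exact tie goes non-shared
  p <- partition_scvs(c(0.86, 0.87), threshold = 0.86)
  expect_equal(p$shared_idx, 2L)
  expect_equal(p$nonshared_idx, 1L)
  # all shared: empty non-shared set
  p <- partition_scvs(c(0.9, 0.95, 0.99), threshold = 0.86)
  expect_equal(p$Nns, 0L)
  expect_equal(p$shared_idx, 1:3)
  # covariance input path
  covs <- list(make_shared_covariance(0.8, 10), diag(10))
  p <- partition_scvs(covs)
  expect_equal(p$shared_idx, 1L)
})

test_that("raising the threshold never grows the shared set", {
  set.seed(30)
  sigma <- runif(20)
  prev <- Inf
  for (d in c(0.2, 0.5, 0.86, 0.95)) {
    ns <- partition_scvs(sigma, d)$Ns
    expect_lte(ns, prev)
    prev <- ns
  }
})

test_that("composed demixing equals the explicitly chained maps", {
  set.seed(31)
  N <- 5; K <- 3
  W1 <- new_demixing_set(lapply(1:K, function(k) {
    M <- matrix(rnorm(N * N), N, N); M / sqrt(rowSums(M^2))
  }))
  part <- partition_scvs(c(0.9, 0.3, 0.95, 0.2, 0.1), 0.86)  # shared 1,3
  Ws <- new_demixing_set(lapply(1:K, function(k) matrix(rnorm(4), 2, 2)))
  Wns <- new_demixing_set(lapply(1:K, function(k) matrix(rnorm(9), 3, 3)))
  Wt <- compose_demixing(W1, part, Ws, Wns)
  X <- lapply(1:K, function(k) matrix(rnorm(N * 40), N))
  perm <- c(part$shared_idx, part$nonshared_idx)
  for (k in 1:K) {
    Y1 <- W1$W[[k]] %*% X[[k]]
    chained <- rbind(Ws$W[[k]] %*% Y1[part$shared_idx, ],
                     Wns$W[[k]] %*% Y1[part$nonshared_idx, ])
    expect_lt(max(abs(Wt$W[[k]] %*% X[[k]] - chained)), 1e-10)
  }
  # identity final stages reduce to pure reordering
  Ids <- new_demixing_set(lapply(1:K, function(k) diag(2)))
  Idns <- new_demixing_set(lapply(1:K, function(k) diag(3)))
  Wt0 <- compose_demixing(W1, part, Ids, Idns)
  for (k in 1:K)
    expect_equal(Wt0$W[[k]], W1$W[[k]][perm, ])
  # empty non-shared subspace: composition uses the shared block alone
  part_all <- partition_scvs(rep(0.95, N), 0.86)
  Ws_full <- new_demixing_set(lapply(1:K, function(k) matrix(rnorm(N * N), N)))
  Wt1 <- compose_demixing(W1, part_all, Ws_full, NULL)
  for (k in 1:K)
    expect_lt(max(abs(Wt1$W[[k]] - Ws_full$W[[k]] %*% W1$W[[k]])), 1e-12)
})

test_that("the full pipeline recovers the planted partition and is linear", {
  # K = 8 keeps the weakest planted level (mu = 0.5) safely above the
  # threshold: population gap ratio 8*0.5/(8*0.5 + 0.5) = 0.889 > 0.86
  sim <- make_scenario(6, 8, 3, T = 1500, seed = 33)
  res <- run_iva_s3(sim$whitened, settings = fast_settings(max_iter = 48))
  expect_equal(res$partition$Ns, 3L)
  # end-to-end linearity: total demixing reproduces the final sources
  Yhat <- apply_demixing(res$total_demixing, sim$whitened)
  for (k in seq_along(Yhat))
    expect_lt(max(abs(Yhat[[k]] - res$final_sources[[k]])), 1e-10)
  # stage-3 refinement does not hurt the overall separation much and the
  # composed result beats the unrefined stage-1 estimate on this data
  expect_lt(scenario_isi(res$total_demixing, sim), 0.1)
})

test_that("stage-3 refinement does not increase the within-subspace cost", {
  sim <- make_scenario(4, 4, 2, T = 1200, seed = 34)
  res <- run_iva_s3(sim$whitened, settings = fast_settings(max_iter = 32))
  for (st in list(res$stage3_shared, res$stage3_nonshared)) {
    if (is.null(st)) next
    expect_true(all(diff(st$cost_trace) <= 1e-10))
  }
})

test_that("an all-non-shared input routes everything to the IVA-G branch", {
  sim <- make_scenario(4, 5, 0, T = 1500, seed = 35)
  res <- run_iva_s3(sim$whitened, settings = fast_settings(max_iter = 48))
  expect_equal(res$partition$Ns, 0L)
  expect_null(res$stage3_shared)
  expect_lt(scenario_isi(res$total_demixing, sim), 0.1)
})

test_that("the pipeline is deterministic given data and settings", {
  sim <- make_scenario(4, 4, 2, T = 1000, seed = 36)
  st <- fast_settings(max_iter = 24)
  a <- run_iva_s3(sim$whitened, settings = st)
  b <- run_iva_s3(sim$whitened, settings = st)
  expect_identical(a$total_demixing$W, b$total_demixing$W)
  expect_identical(a$sigma, b$sigma)
})

test_that("threshold domain is validated", {
  sim <- make_scenario(2, 2, 1, T = 300, seed = 37)
  expect_error(run_iva_s3(sim$whitened, threshold = 1.2), "threshold")
  expect_error(partition_scvs(c(0.5), threshold = 0), "threshold")
})
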
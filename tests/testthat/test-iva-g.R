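test_that("scv_covariance matches the direct time-domain estimator", {
  sim <- make_scenario(2, 2, 1, T = 500, seed = 20)
  C <- stacked_covariance(sim$whitened)
  W <- sumcorr_demixing(C)
  Y <- apply_demixing(W, sim$whitened)
  for (n in 1:2) {
    Yn <- do.call(rbind, lapply(Y, function(Yk) Yk[n, ]))
    Ync <- Yn - rowMeans(Yn)
    oracle <- tcrossprod(Ync) / (ncol(Yn) - 1)
    expect_lt(max(abs(scv_covariance(W, C, n) - oracle)), 1e-10)
  }
  # identity demixing on block-diagonal covariance: independent datasets
  Cid <- structure(list(matrix = diag(4), N = 2L, K = 2L),
                   class = "stacked_cov")
  Wid <- new_demixing_set(list(diag(2), diag(2)))
  expect_equal(scv_covariance(Wid, Cid, 1), diag(2))
  # duplicated datasets: all-ones SCV covariance
  Cdup <- structure(
    list(matrix = rbind(cbind(diag(2), diag(2)),
                        cbind(diag(2), diag(2))), N = 2L, K = 2L),
    class = "stacked_cov")
  expect_equal(scv_covariance(Wid, Cdup, 1), matrix(1, 2, 2))
})

test_that("the cost takes its closed-form values at trivial points", {
  # N = 1, K = 1, unit everything: half of log(2 pi e)
  C1 <- structure(list(matrix = diag(1), N = 1L, K = 1L),
                  class = "stacked_cov")
  W1 <- new_demixing_set(list(matrix(1, 1, 1)))
  expect_equal(iva_g_cost(W1, C1, jitter = 0), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-12)
  # identity demixing, identity stacked covariance: N K log(2 pi e) / 2
  Cid <- structure(list(matrix = diag(6), N = 3L, K = 2L),
                   class = "stacked_cov")
  Wid <- new_demixing_set(list(diag(3), diag(3)))
  expect_equal(iva_g_cost(Wid, Cid, jitter = 0),
               3 * 2 * log(2 * pi * exp(1)) / 2, tolerance = 1e-12)
  # singular demixing signals an infinite cost, not an error
  Wsing <- new_demixing_set(list(matrix(1, 3, 3), diag(3)))
  expect_identical(iva_g_cost(Wsing, Cid), Inf)
})

test_that("determinant and eigenvalue-product forms of the cost agree", {
  set.seed(23)
  for (rep in 1:5) {
    sim <- make_scenario(2, 2, 1, T = 400, seed = 23 + rep)
    C <- stacked_covariance(sim$whitened)
    W <- new_demixing_set(lapply(1:2, function(k) {
      M <- matrix(rnorm(4), 2, 2)
      M / sqrt(rowSums(M^2))
    }))
    detform <- iva_g_cost(W, C, jitter = 0)
    lambdas <- unlist(lapply(1:2, function(n)
      eigen(scv_covariance(W, C, n), symmetric = TRUE,
            only.values = TRUE)$values))
    eigform <- 2 * 2 * log(2 * pi * exp(1)) / 2 +
      0.5 * sum(log(lambdas)) -
      sum(vapply(W$W, function(Wk) log(abs(det(Wk))), numeric(1)))
    expect_equal(detform, eigform, tolerance = 1e-8)
  }
})

test_that("the optimizer's cost trace is non-increasing", {
  sim <- make_scenario(4, 3, 0, T = 1500, seed = 25)
  res <- iva_g_optimize(sim$whitened,
                        settings = fast_settings(seed = 2))
  expect_true(all(diff(res$cost_trace) <= 1e-10))
  expect_lte(res$n_iter, 64L)
})

test_that("permuting the initial rows permutes the solution equivalently", {
  sim <- make_scenario(3, 3, 0, T = 1200, seed = 26)
  W0 <- sumcorr_demixing(stacked_covariance(sim$whitened))
  perm <- c(3, 1, 2)
  W0p <- new_demixing_set(lapply(W0$W, function(Wk) Wk[perm, ]))
  st <- fast_settings(max_iter = 32)
  a <- iva_g_optimize(sim$whitened, W0, st)
  b <- iva_g_optimize(sim$whitened, W0p, st)
  # cyclic sweeps visit rows in their stored order, so the permuted run
  # follows a permuted trajectory: agreement is at optimizer precision
  for (k in 1:3)
    expect_lt(max(abs(b$demixing$W[[k]] - a$demixing$W[[k]][perm, ])),
              1e-3)
  expect_equal(tail(a$cost_trace, 1), tail(b$cost_trace, 1),
               tolerance = 1e-6)
})

test_that("starting near the optimum stays near it", {
  sim <- make_scenario(3, 3, 0, T = 20000, seed = 27)
  # ground-truth inverse mixing (through the whitener), rows normalized
  Wtrue <- new_demixing_set(lapply(1:3, function(k) {
    M <- solve(sim$whitened$whiteners[[k]] %*% sim$truth$A[[k]])
    M / sqrt(rowSums(M^2))
  }))
  isi0 <- scenario_isi(Wtrue, sim)
  res <- iva_g_optimize(sim$whitened, Wtrue, fast_settings(max_iter = 16))
  # the finite-sample cost optimum sits near (not at) the truth: the
  # refined solution may drift from the exact inverse only marginally
  expect_lte(scenario_isi(res$demixing, sim), isi0 + 5e-3)
  expect_lt(scenario_isi(res$demixing, sim), 0.02)
})

test_that("output rows are unit norm and results are seed-deterministic", {
  sim <- make_scenario(3, 3, 1, T = 1000, seed = 28)
  st <- fast_settings(max_iter = 16, seed = 4)
  a <- iva_g_optimize(sim$whitened, settings = st)
  b <- iva_g_optimize(sim$whitened, settings = st)
  expect_identical(a$demixing$W, b$demixing$W)
  for (k in 1:3)
    expect_equal(rowSums(a$demixing$W[[k]]^2), rep(1, 3),
                 tolerance = 1e-12)
})

test_that("settings are validated", {
  expect_error(ivag_settings(max_iter = 0), "max_iter")
  expect_error(ivag_settings(tol = 0), "tol")
  expect_error(ivag_settings(step0 = -1), "step0")
})
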
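test_that("the prediction step matches its defining equations", {
  model <- as_model(A = diag(2), H = diag(2), W = matrix(0, 2, 2),
                    Q = diag(2))
  st <- list(x_hat = c(1, -2), P = diag(c(3, 4)))
  pr <- kf_predict(st, model)
  expect_equal(pr$x_hat_minus, c(1, -2))
  expect_equal(pr$P_minus, diag(c(3, 4)))

  W <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  model0 <- as_model(A = matrix(0, 2, 2), H = diag(2), W = W, Q = diag(2))
  pr0 <- kf_predict(st, model0)
  expect_equal(pr0$x_hat_minus, c(0, 0))
  expect_equal(pr0$P_minus, W)
})

test_that("the update step matches the analytic scalar cases", {
  # P- = 1, H = 1, Q = 1: gain is one half
  m <- as_model(A = matrix(1), H = matrix(1), W = matrix(0), Q = matrix(1))
  up <- kf_update(0, matrix(1), z = 2, m, return_extras = TRUE)
  expect_equal(as.numeric(up$K), 0.5)
  expect_equal(as.numeric(up$P), 0.5)
  expect_equal(up$x_hat, 1)          # 0 + 0.5 * (2 - 0)
  expect_equal(up$innovation, 2)

  # perfect observation: Q = 0 forces the estimate onto the measurement
  m0 <- as_model(A = matrix(1), H = matrix(1), W = matrix(0), Q = matrix(0))
  up0 <- kf_update(5, matrix(4), z = -1, m0, return_extras = TRUE)
  expect_equal(as.numeric(up0$K), 1)
  expect_equal(up0$x_hat, -1)
  expect_equal(as.numeric(up0$P), 0)

  expect_error(kf_update(0, matrix(1), z = c(1, 2), m), "length 2")
})

test_that("covariance stays symmetric PSD and update never loses information", {
  sys <- random_system(4, 6, 200, seed = 31)
  model <- as_model(sys$A, sys$H, sys$W, sys$Q)
  state <- list(x_hat = sys$x0, P = sys$P0)
  for (k in seq_len(200)) {
    pr <- kf_predict(state, model)
    state <- kf_update(pr$x_hat_minus, pr$P_minus, sys$Z[, k], model)
    expect_lt(max(abs(state$P - t(state$P))), 1e-10)
    ev <- eigen(state$P, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9)
    expect_lte(sum(diag(state$P)), sum(diag(pr$P_minus)) + 1e-12)
  }
  expect_true(all(is.finite(state$P)))
})

test_that("batch filtering matches the independently coded recursion", {
  for (i in 1:20) {
    sys <- random_system(sample(2:6, 1), sample(2:16, 1), 300, seed = 100 + i)
    model <- as_model(sys$A, sys$H, sys$W, sys$Q, P0 = sys$P0)
    tr <- run_filter(model, sys$Z, x0 = sys$x0)
    ref <- oracle_kalman(sys$A, sys$H, sys$W, sys$Q, sys$Z, sys$x0, sys$P0)
    expect_lt(max(abs(tr$X_hat - ref)), 1e-10)
  }
})

test_that("the Joseph-form update agrees with the standard form", {
  sys <- random_system(3, 5, 100, seed = 77)
  model <- as_model(sys$A, sys$H, sys$W, sys$Q, P0 = sys$P0)
  t1 <- run_filter(model, sys$Z, x0 = sys$x0)
  t2 <- run_filter(model, sys$Z, x0 = sys$x0, joseph = TRUE)
  expect_lt(max(abs(t1$X_hat - t2$X_hat)), 1e-10)
  expect_lt(max(abs(t1$P - t2$P)), 1e-10)
})

test_that("noiseless self-consistent data is decoded exactly", {
  sp <- make_stable_spec(4, 8, 0.9, 0, T_steps = 300L, seed = 2)
  sim <- simulate_lds(sp)
  model <- train_kalman(list(Z = sim$Z, X = sim$X, M = 300L),
                        center = FALSE, ridge = 0)
  tr <- run_filter(model, sim$Z)
  expect_lt(max(abs(tr$X_hat[, -1] - sim$X[, -1])), 1e-8)
})

test_that("an empty observation matrix yields an empty trace", {
  sys <- random_system(3, 4, 10, seed = 5)
  model <- as_model(sys$A, sys$H, sys$W, sys$Q, P0 = sys$P0)
  tr <- run_filter(model, matrix(0, 4, 0))
  expect_equal(tr$n_steps, 0L)
  expect_equal(dim(tr$X_hat), c(3L, 0L))
})

test_that("the error covariance converges to the Riccati fixed point", {
  sp <- make_stable_spec(4, 6, 0.9, 0.2, T_steps = 2000L, seed = 13)
  sim <- simulate_lds(sp)
  model <- as_model(sp$A, sp$H, sp$W, sp$Q, P0 = diag(4))
  tr <- run_filter(model, sim$Z, keep_covariances = TRUE)
  covs <- tr$covariances
  M <- length(covs)
  expect_lt(norm(covs[[M]] - covs[[M - 1]], "F"), 1e-10)
  # one-step Riccati residual at the limit
  P <- covs[[M]]
  A <- sp$A; H <- sp$H
  Pm <- A %*% P %*% t(A) + sp$W
  S <- H %*% Pm %*% t(H) + sp$Q
  P_next <- Pm - Pm %*% t(H) %*% solve(S) %*% H %*% Pm
  expect_lt(norm(P_next - P, "F"), 1e-8)
})

test_that("fitted dynamics beat an equivalently inflated random walk", {
  sp <- make_stable_spec(6, 16, 0.95, 0.1, T_steps = 2000L, seed = 3)
  sim <- simulate_lds(sp)
  cc_of <- function(model) {
    tr <- run_filter(model, sim$Z)
    mean(vapply(1:6, function(d) cor(tr$X_hat[d, ], sim$X[d, ]), numeric(1)))
  }
  cc_true <- cc_of(as_model(sp$A, sp$H, sp$W, sp$Q, P0 = diag(6)))
  # identity dynamics with W inflated to preserve the marginal state spread
  Sx <- tcrossprod(sim$X) / ncol(sim$X)
  D <- sp$A - diag(6)
  W_inf <- sp$W + D %*% Sx %*% t(D)
  cc_rw <- cc_of(as_model(diag(6), sp$H, (W_inf + t(W_inf)) / 2, sp$Q,
                          P0 = diag(6)))
  expect_gt(cc_true, cc_rw)
})

test_that("centered models restore means on output", {
  pair <- quick_pair(8)
  model <- train_kalman(pair)
  tr <- run_filter(model, pair$Z)
  # decoded angles live near the training posture, not near zero
  expect_lt(max(abs(rowMeans(tr$X_hat) - model$x_mean)), 10)
  expect_identical(run_filter(model, pair$Z)$X_hat, tr$X_hat)
})
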
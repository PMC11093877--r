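test_that("state-transition fit recovers exact linear dynamics", {
  # geometric sequence: scalar A
  A <- fit_state_transition(matrix(c(1, 0.5, 0.25), 1), ridge = 0)
  expect_equal(as.numeric(A), 0.5, tolerance = 1e-12)

  # 90-degree rotation from four points on the unit circle
  X <- cbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  A <- fit_state_transition(X, ridge = 0)
  expect_equal(unname(A), rbind(c(0, -1), c(1, 0)), tolerance = 1e-10)

  expect_error(fit_state_transition(matrix(1:4, 2, 2)), "n \\+ 1")
})

test_that("observation fit recovers exact linear maps", {
  set.seed(4)
  X <- matrix(rnorm(3 * 50), 3, 50)
  expect_equal(unname(fit_observation(2 * X, X, ridge = 0)), diag(2, 3),
               tolerance = 1e-10)

  Xc <- matrix(2, 1, 10)  # single constant nonzero state row
  expect_equal(as.numeric(fit_observation(3 * Xc, Xc, ridge = 0)), 3,
               tolerance = 1e-12)

  H0 <- matrix(rnorm(5 * 3), 5, 3)
  expect_lt(max(abs(fit_observation(H0 %*% X, X, ridge = 0) - H0)), 1e-10)
})

test_that("fitters agree with the SVD-pseudoinverse oracle", {
  for (i in 1:30) {
    set.seed(i)
    n <- sample(2:6, 1); m <- sample(2:16, 1); M <- 500
    X <- matrix(rnorm(n * M), n, M)
    Z <- matrix(rnorm(m * n), m, n) %*% X + 0.1 * matrix(rnorm(m * M), m, M)
    expect_lt(max(abs(fit_state_transition(X, ridge = 0) - oracle_fit_A(X))), 1e-8)
    expect_lt(max(abs(fit_observation(Z, X, ridge = 0) - oracle_fit_H(Z, X))), 1e-8)
  }
})

test_that("fitted matrices are least-squares optima", {
  set.seed(12)
  sp <- make_stable_spec(3, 5, 0.9, 0.2, T_steps = 400L, seed = 12)
  sim <- simulate_lds(sp)
  A <- fit_state_transition(sim$X, ridge = 0)
  H <- fit_observation(sim$Z, sim$X, ridge = 0)
  X1 <- sim$X[, -400]; X2 <- sim$X[, -1]
  ssr_A <- sum((X2 - A %*% X1)^2)
  ssr_H <- sum((sim$Z - H %*% sim$X)^2)
  for (i in 1:20) {
    dA <- matrix(rnorm(9, sd = 0.01), 3, 3)
    dH <- matrix(rnorm(15, sd = 0.01), 5, 3)
    expect_gte(sum((X2 - (A + dA) %*% X1)^2), ssr_A)
    expect_gte(sum((sim$Z - (H + dH) %*% sim$X)^2), ssr_H)
  }
})

test_that("noise covariance estimates are symmetric, PSD, and exact in the noiseless limit", {
  sp <- make_stable_spec(3, 5, 0.9, 0, T_steps = 200L, seed = 2)
  sim <- simulate_lds(sp)
  A <- fit_state_transition(sim$X, ridge = 0)
  H <- fit_observation(sim$Z, sim$X, ridge = 0)
  nc <- estimate_noise_covariances(sim$X, sim$Z, A, H)
  expect_lt(max(abs(nc$W)), 1e-12)
  expect_lt(max(abs(nc$Q)), 1e-12)

  spn <- make_stable_spec(3, 5, 0.9, 0.3, T_steps = 400L, seed = 3)
  simn <- simulate_lds(spn)
  ncn <- estimate_noise_covariances(simn$X, simn$Z, spn$A, spn$H)
  expect_lt(max(abs(ncn$W - t(ncn$W))), 1e-10)
  expect_lt(max(abs(ncn$Q - t(ncn$Q))), 1e-10)
  expect_gte(min(eigen(ncn$W, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_gte(min(eigen(ncn$Q, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(estimate_noise_covariances(simn$X[, 1, drop = FALSE],
                                          simn$Z[, 1, drop = FALSE],
                                          spn$A, spn$H), "at least 2")
})

test_that("noise covariances are recovered from moderate samples", {
  n <- 2; m <- 3
  sp <- make_stable_spec(n, m, 0.9, 0.1, T_steps = 20000L, seed = 6)
  sp$W <- diag(0.01, n); sp$Q <- diag(0.04, m)
  sim <- simulate_lds(sp)
  nc <- estimate_noise_covariances(sim$X, sim$Z, sp$A, sp$H)
  expect_lt(norm(nc$W - sp$W, "F") / norm(sp$W, "F"), 0.1)
  expect_lt(norm(nc$Q - sp$Q, "F") / norm(sp$Q, "F"), 0.1)
})

test_that("parameter estimates improve with the training horizon", {
  for (seed in 1:5) {
    err <- vapply(c(1000L, 45000L), function(T_steps) {
      sp <- make_stable_spec(6, 16, 0.95, 0.1, T_steps = T_steps, seed = seed)
      sim <- simulate_lds(sp)
      norm(fit_state_transition(sim$X) - sp$A, "F")
    }, numeric(1))
    expect_lt(err[2], err[1])
  }
})

test_that("training is deterministic and records the centering convention", {
  pair <- quick_pair(5)
  m1 <- train_kalman(pair)
  m2 <- train_kalman(pair)
  expect_identical(m1, m2)
  expect_true(m1$centered)
  expect_equal(m1$x_mean, rowMeans(pair$X))
  expect_equal(m1$z_mean, rowMeans(pair$Z))
  expect_identical(m1$M_train, pair$M)
  # centered refit of the uncentered matrices reproduces the same A
  Xc <- pair$X - rowMeans(pair$X)
  expect_equal(m1$A, fit_state_transition(Xc))

  mu <- train_kalman(pair, center = FALSE)
  expect_false(mu$centered)
  expect_false(identical(mu$A, m1$A))
})

test_that("a zero-variance state row is reported", {
  pair <- quick_pair(6)
  pair$X[2, ] <- 15  # a DOF that never moves
  expect_warning(train_kalman(pair), "zero variance")
})
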
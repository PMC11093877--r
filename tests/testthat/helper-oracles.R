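# Independent oracles used across the suite. These deliberately avoid the
# package's own solver paths: least squares goes through an SVD
# pseudoinverse (pracma), the Kalman recursion is a plain textbook loop with
# solve(), and the correlation oracle is direct summation.

# Least-squares A: x_{k+1} ~ A x_k via pseudoinverse of the lagged states.
oracle_fit_A <- function(X) {
  M <- ncol(X)
  X1 <- X[, -M, drop = FALSE]
  X2 <- X[, -1L, drop = FALSE]
  X2 %*% pracma::pinv(X1)
}

# Least-squares H: z_k ~ H x_k via pseudoinverse.
oracle_fit_H <- function(Z, X) {
  Z %*% pracma::pinv(X)
}

# Textbook Kalman recursion, written directly from the predict/update
# equations with an explicit solve() of the innovation covariance.
oracle_kalman <- function(A, H, W, Q, Z, x0, P0) {
  n <- nrow(A); m <- nrow(H); M <- ncol(Z)
  X_hat <- matrix(0, n, M)
  x <- x0; P <- P0
  I_n <- diag(n)
  for (k in seq_len(M)) {
    xm <- A %*% x
    Pm <- A %*% P %*% t(A) + W
    S <- H %*% Pm %*% t(H) + Q
    K <- Pm %*% t(H) %*% solve(S)
    x <- xm + K %*% (Z[, k] - H %*% xm)
    P <- (I_n - K %*% H) %*% Pm
    X_hat[, k] <- x
  }
  X_hat
}

# Pearson correlation by direct evaluation of the defining sums.
oracle_cc <- function(a, b) {
  am <- sum(a) / length(a)
  bm <- sum(b) / length(b)
  num <- sum((a - am) * (b - bm))
  num / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# Random well-conditioned system with PD noise, for filter equivalence runs.
random_system <- function(n, m, M, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  A <- A * (0.9 / max(Mod(eigen(A, only.values = TRUE)$values)))
  H <- matrix(rnorm(m * n), m, n)
  W <- crossprod(matrix(rnorm(n * n), n, n)) / n + diag(0.05, n)
  Q <- crossprod(matrix(rnorm(m * m), m, m)) / m + diag(0.05, m)
  Z <- matrix(rnorm(m * M), m, M)
  list(A = A, H = H, W = W, Q = Q, Z = Z,
       x0 = rnorm(n), P0 = diag(n))
}

# Wrap raw matrices as a kalman_model (uncentered) for driving the filter.
as_model <- function(A, H, W, Q, P0 = NULL) {
  n <- nrow(A); m <- nrow(H)
  structure(list(A = A, H = H, W = W, Q = Q,
                 x_mean = rep(0, n), z_mean = rep(0, m),
                 centered = FALSE, P0 = P0,
                 M_train = 0L, dof_names = NULL, channel_names = NULL),
            class = "kalman_model")
}

# Small synthetic session + feature pair for end-to-end tests.
quick_pair <- function(seed, duration_s = 20, cfg = read_pipeline_config()) {
  s <- generate_session(duration_s = duration_s, seed = seed)
  preprocess_session(s, cfg)
}
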
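#' Kalman prediction step
#'
#' Propagates the posterior of step k-1 through the state dynamics:
#' \deqn{\hat x^-_k = A \hat x_{k-1}, \qquad P^-_k = A P_{k-1} A^T + W.}
#' `P_minus` is symmetrized before return. `kf_predict` and [kf_update()]
#' are pure single-step functions so a caller can drive the decoder window
#' by window in real time; [run_filter()] is the batch wrapper.
#'
#' @param state list with `x_hat` (length-n posterior mean) and `P`
#'   (n x n posterior covariance).
#' @param model a [train_kalman()] model (only A and W are used).
#'
#' @return List with `x_hat_minus` and `P_minus`.
#' @export
kf_predict <- function(state, model) {
  A <- model$A
  x_minus <- as.numeric(A %*% state$x_hat)
  P_minus <- .sym(A %*% state$P %*% t(A) + model$W)
  list(x_hat_minus = x_minus, P_minus = P_minus)
}

#' Kalman update step
#'
#' Corrects the a priori estimate with the innovation of the new observation:
#' \deqn{K = P^- H^T (H P^- H^T + Q)^{-1}}
#' \deqn{\hat x = \hat x^- + K (z - H \hat x^-), \qquad P = (I - K H) P^-.}
#' The innovation covariance is factorized by Cholesky (never explicitly
#' inverted); on failure a single jitter of `1e-10 * trace(S)/m` is added to
#' its diagonal, then the step fails with a conditioning report. `P` is
#' symmetrized; set `joseph = TRUE` for the Joseph-form covariance update
#' \eqn{(I-KH) P^- (I-KH)^T + K Q K^T}, which is more robust for
#' ill-conditioned systems.
#'
#' @param x_hat_minus a priori state mean.
#' @param P_minus a priori covariance.
#' @param z length-m observation vector (in the model's centered coordinates
#'   when driving the step functions directly on a centered model).
#' @param model a [train_kalman()] model (only H and Q are used).
#' @param joseph use the Joseph-form covariance update (default FALSE).
#' @param return_extras also return the gain and innovation (default FALSE).
#'
#' @return List with `x_hat`, `P`, and when requested `K`, `innovation`.
#' @export
kf_update <- function(x_hat_minus, P_minus, z, model, joseph = FALSE,
                      return_extras = FALSE) {
  H <- model$H; Q <- model$Q
  m <- nrow(H); n <- ncol(H)
  if (length(z) != m) {
    stop(sprintf("observation has length %d but the model expects %d", length(z), m),
         call. = FALSE)
  }
  PHt <- P_minus %*% t(H)
  S <- .sym(H %*% PHt + Q)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) {
    S <- S + diag(1e-10 * sum(diag(S)) / m, m)
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) {
      stop(sprintf("innovation covariance is singular even after jitter (rcond %.3e)",
                   rcond(S)), call. = FALSE)
    }
  }
  # K = PHt S^{-1} via two triangular solves
  K <- t(backsolve(R, forwardsolve(t(R), t(PHt))))
  innov <- as.numeric(z - H %*% x_hat_minus)
  x_hat <- as.numeric(x_hat_minus + K %*% innov)
  IKH <- diag(n) - K %*% H
  P <- if (joseph) {
    .sym(IKH %*% P_minus %*% t(IKH) + K %*% Q %*% t(K))
  } else {
    .sym(IKH %*% P_minus)
  }
  out <- list(x_hat = x_hat, P = P)
  if (return_extras) {
    out$K <- K
    out$innovation <- innov
  }
  out
}

#' Decode a feature sequence with the Kalman recursion
#'
#' Runs predict/update over every column of `Z`. For a mean-centered model
#' the observation mean is subtracted internally and the state mean added
#' back to the outputs, so inputs and outputs are always in original units
#' (MAV features in, joint angles in degrees out). Fully deterministic.
#'
#' Initialization defaults: `x0` is the training mean state (zero in
#' centered coordinates) and `P0` the empirical covariance of the centered
#' training states (falling back to W), a diffuse-but-data-scaled start that
#' converges within a few steps.
#'
#' @param model a [train_kalman()] model.
#' @param Z m x M matrix of observation columns (or a `training_pair`, whose
#'   `Z` is used).
#' @param x0 optional initial state (original units).
#' @param P0 optional initial error covariance.
#' @param joseph use the Joseph-form covariance update (default FALSE).
#' @param keep_gains record per-step Kalman gains (default FALSE).
#' @param keep_innovations record per-step innovations (default FALSE).
#' @param keep_covariances record per-step posterior covariances
#'   (default FALSE).
#'
#' @return An object of class `kf_trace`: `X_hat` (n x M posterior state
#'   estimates, means restored), `P` (final posterior covariance), `n_steps`,
#'   `dof_names`, and optional `gains`, `innovations`, `covariances` lists.
#' @export
run_filter <- function(model, Z, x0 = NULL, P0 = NULL, joseph = FALSE,
                       keep_gains = FALSE, keep_innovations = FALSE,
                       keep_covariances = FALSE) {
  stopifnot(inherits(model, "kalman_model"))
  if (inherits(Z, "training_pair")) Z <- Z$Z
  Z <- as.matrix(Z)
  m <- nrow(model$H); n <- ncol(model$H)
  if (ncol(Z) > 0L && nrow(Z) != m) {
    stop(sprintf("Z has %d rows but the model expects %d features", nrow(Z), m),
         call. = FALSE)
  }
  M <- ncol(Z)
  if (model$centered) Z <- Z - model$z_mean
  x <- if (is.null(x0)) {
    rep(0, n)                     # training mean in centered coordinates
  } else if (model$centered) {
    as.numeric(x0) - model$x_mean
  } else {
    as.numeric(x0)
  }
  P <- if (is.null(P0)) model$P0 %||% model$W else .sym(as.matrix(P0))
  X_hat <- matrix(0, n, M)
  gains <- if (keep_gains) vector("list", M) else NULL
  innovs <- if (keep_innovations) matrix(0, m, M) else NULL
  covs <- if (keep_covariances) vector("list", M) else NULL
  state <- list(x_hat = x, P = P)
  extras <- keep_gains || keep_innovations
  for (k in seq_len(M)) {
    pr <- kf_predict(state, model)
    state <- kf_update(pr$x_hat_minus, pr$P_minus, Z[, k], model,
                       joseph = joseph, return_extras = extras)
    X_hat[, k] <- state$x_hat
    if (keep_gains) gains[[k]] <- state$K
    if (keep_innovations) innovs[, k] <- state$innovation
    if (keep_covariances) covs[[k]] <- state$P
  }
  if (model$centered && M > 0L) X_hat <- X_hat + model$x_mean
  structure(list(X_hat = X_hat, P = state$P, n_steps = M,
                 dof_names = model$dof_names,
                 gains = gains, innovations = innovs, covariances = covs),
            class = "kf_trace")
}

#' @export
print.kf_trace <- function(x, ...) {
  cat(sprintf("<kf_trace> %d DOFs x %d steps\n", nrow(x$X_hat), x$n_steps))
  invisible(x)
}
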
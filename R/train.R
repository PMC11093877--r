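#' Fit the state-transition matrix by least squares
#'
#' Solves \eqn{\min_A \sum_{k=1}^{M-1} \|x_{k+1} - A x_k\|^2} in closed form:
#' with \eqn{X_1 = [x_1 \ldots x_{M-1}]} and \eqn{X_2 = [x_2 \ldots x_M]},
#' \deqn{A = X_2 X_1^T (X_1 X_1^T)^{-1}.}
#' The Gram matrix is ridge-regularized by `ridge * trace / n` before the
#' Cholesky solve; a near-singular Gram matrix triggers a warning with its
#' reciprocal condition number and a pseudoinverse fallback.
#'
#' @param X n x M state matrix (one column per time step, M >= n + 1).
#' @param ridge relative ridge regularization (default 1e-8; 0 disables).
#'
#' @return n x n state-transition matrix A.
#' @export
fit_state_transition <- function(X, ridge = 1e-8) {
  X <- as.matrix(X)
  n <- nrow(X); M <- ncol(X)
  if (M < n + 1L) {
    stop(sprintf("need at least n + 1 = %d columns to fit A, got %d", n + 1L, M),
         call. = FALSE)
  }
  X1 <- X[, -M, drop = FALSE]
  X2 <- X[, -1L, drop = FALSE]
  .solve_gram_right(tcrossprod(X2, X1), tcrossprod(X1), ridge,
                    what = "state Gram matrix X1 X1'")
}

#' Fit the observation matrix by least squares
#'
#' Solves \eqn{\min_H \sum_{k=1}^{M} \|z_k - H x_k\|^2} in closed form:
#' \deqn{H = Z X^T (X X^T)^{-1}.}
#' Regularization and fallback behave as in [fit_state_transition()].
#'
#' @param Z m x M observation matrix.
#' @param X n x M state matrix (same column count as Z).
#' @param ridge relative ridge regularization (default 1e-8; 0 disables).
#'
#' @return m x n observation matrix H.
#' @export
fit_observation <- function(Z, X, ridge = 1e-8) {
  Z <- as.matrix(Z); X <- as.matrix(X)
  if (ncol(Z) != ncol(X)) {
    stop(sprintf("Z has %d columns but X has %d", ncol(Z), ncol(X)), call. = FALSE)
  }
  if (ncol(X) < nrow(X)) {
    stop(sprintf("need at least n = %d columns to fit H, got %d", nrow(X), ncol(X)),
         call. = FALSE)
  }
  .solve_gram_right(tcrossprod(Z, X), tcrossprod(X), ridge,
                    what = "state Gram matrix X X'")
}

#' Estimate noise covariances from fit residuals
#'
#' Given fitted A and H, the process and observation noise covariances are
#' the residual second-moment matrices
#' \deqn{W = (X_2 - A X_1)(X_2 - A X_1)^T / (M - 1)}
#' \deqn{Q = (Z - H X)(Z - H X)^T / M}
#' symmetrized and eigenvalue-clipped to the PSD cone (finite-sample residual
#' covariances can be numerically indefinite).
#'
#' @param X n x M state matrix.
#' @param Z m x M observation matrix.
#' @param A fitted state-transition matrix.
#' @param H fitted observation matrix.
#'
#' @return List with symmetric PSD matrices `W` (n x n) and `Q` (m x m).
#' @export
estimate_noise_covariances <- function(X, Z, A, H) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  M <- ncol(X)
  if (M < 2L) stop("need at least 2 time steps to estimate W", call. = FALSE)
  if (ncol(Z) != M) stop("Z and X must have the same column count", call. = FALSE)
  RW <- X[, -1L, drop = FALSE] - A %*% X[, -M, drop = FALSE]
  RQ <- Z - H %*% X
  W <- .psd_clip(tcrossprod(RW) / (M - 1))
  Q <- .psd_clip(tcrossprod(RQ) / M)
  list(W = W, Q = Q)
}

#' Train the Kalman decoding model
#'
#' Fits all parameters of the linear-Gaussian decoder from an aligned
#' feature/state pair: A and H by closed-form least squares, then W and Q
#' from the residuals. Because MAV features are strictly positive and joint
#' angles have a nonzero rest offset, the training-set row means of X and Z
#' are subtracted before fitting by default (`center = TRUE`); the filter
#' then operates in centered coordinates and restores the means on output.
#'
#' The returned model also records `P0`, the empirical covariance of the
#' centered training states, used as the default initial error covariance of
#' the filter.
#'
#' @param pair a [extract_training_pair()] result (or compatible list with
#'   `Z`, `X`, `M`).
#' @param center subtract training means before fitting (default TRUE).
#' @param ridge relative ridge regularization for the two fitters
#'   (default 1e-8).
#'
#' @return An object of class `kalman_model`: A, H, W, Q, x_mean, z_mean,
#'   centered, P0, M_train, dof/channel names.
#' @export
train_kalman <- function(pair, center = TRUE, ridge = 1e-8) {
  stopifnot(is.list(pair), !is.null(pair$Z), !is.null(pair$X))
  Z <- as.matrix(pair$Z); X <- as.matrix(pair$X)
  M <- ncol(X)
  if (ncol(Z) != M) stop("pair$Z and pair$X must share a column count", call. = FALSE)
  x_mean <- rowMeans(X)
  z_mean <- rowMeans(Z)
  if (center) {
    Xc <- X - x_mean
    Zc <- Z - z_mean
  } else {
    Xc <- X; Zc <- Z
  }
  sdX <- apply(Xc, 1L, stats::sd)
  if (any(sdX == 0)) {
    warning(sprintf("state rows with zero variance: %s; their dynamics are not identifiable",
                    paste(which(sdX == 0), collapse = ", ")), call. = FALSE)
  }
  A <- fit_state_transition(Xc, ridge = ridge)
  H <- fit_observation(Zc, Xc, ridge = ridge)
  nc <- estimate_noise_covariances(Xc, Zc, A, H)
  P0 <- if (M > 1L) .psd_clip(tcrossprod(Xc) / (M - 1)) else nc$W
  structure(
    list(A = A, H = H, W = nc$W, Q = nc$Q,
         x_mean = x_mean, z_mean = z_mean, centered = isTRUE(center),
         P0 = P0, M_train = as.integer(M),
         dof_names = pair$dof_names %||% default_dof_names(nrow(X)),
         channel_names = pair$channel_names %||% sprintf("emg%02d", seq_len(nrow(Z)))),
    class = "kalman_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kalman_model <- function(x, ...) {
  cat(sprintf("<kalman_model> %d states (DOFs), %d observations (features), trained on %d windows%s\n",
              nrow(x$A), nrow(x$H), x$M_train,
              if (x$centered) ", mean-centered" else ""))
  invisible(x)
}
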
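#' Specify a linear-Gaussian dynamical system
#'
#' Bundles the parameters of the state-space model
#' \deqn{x_{k+1} = A x_k + w_k, \qquad w_k \sim N(0, W)}
#' \deqn{z_k = H x_k + v_k, \qquad v_k \sim N(0, Q)}
#' used both to simulate synthetic training data and as ground truth in
#' parameter-recovery experiments. In the decoding application the state
#' \eqn{x_k} holds joint angles (one entry per degree of freedom) and the
#' observation \eqn{z_k} holds windowed sEMG amplitude features.
#'
#' @param A n x n state-transition matrix.
#' @param H m x n observation matrix mapping states to observations.
#' @param W n x n symmetric positive-semidefinite process noise covariance.
#' @param Q m x m symmetric positive-semidefinite observation noise covariance.
#' @param x0 length-n initial state vector.
#' @param T_steps number of time steps to simulate (>= 2).
#' @param seed integer RNG seed; all stochastic draws of a simulation flow
#'   from this single seed.
#'
#' @return An object of class `lds_spec`.
#' @seealso [simulate_lds()], [make_stable_spec()]
#' @export
lds_spec <- function(A, H, W, Q, x0, T_steps, seed = 1L) {
  A <- as.matrix(A); H <- as.matrix(H)
  W <- as.matrix(W); Q <- as.matrix(Q)
  x0 <- as.numeric(x0)
  n <- nrow(A)
  m <- nrow(H)
  if (ncol(A) != n) stop("A must be square", call. = FALSE)
  if (ncol(H) != n) stop(sprintf("H has %d columns but the state dimension is %d",
                                 ncol(H), n), call. = FALSE)
  if (length(x0) != n) stop("x0 length must equal the state dimension", call. = FALSE)
  .check_psd(W, "W")
  .check_psd(Q, "Q")
  if (nrow(W) != n) stop("W dimension must equal the state dimension", call. = FALSE)
  if (nrow(Q) != m) stop("Q dimension must equal the observation dimension", call. = FALSE)
  T_steps <- .stopifnot_scalar_int(T_steps, "T_steps", lower = 2L)
  structure(
    list(A = A, H = H, W = W, Q = Q, x0 = x0,
         n_states = n, n_obs = m, T_steps = T_steps,
         seed = as.integer(seed)),
    class = "lds_spec")
}

#' Construct a random stable system specification
#'
#' Draws a random state-transition matrix and rescales it to a requested
#' spectral radius below one (so simulated trajectories are stationary), a
#' random full-column-rank observation matrix, and isotropic-scale PSD noise
#' covariances. Deterministic in `seed`.
#'
#' @param n_states state dimension (the decoding application uses 6).
#' @param n_obs observation dimension (the decoding application uses 16).
#' @param spectral_radius target spectral radius of A, in (0, 1).
#' @param noise_scale nonnegative scale of the noise covariances; 0 gives a
#'   noiseless system.
#' @param T_steps number of steps recorded in the spec (default 1000).
#' @param seed integer RNG seed.
#'
#' @return An `lds_spec`.
#' @export
make_stable_spec <- function(n_states, n_obs, spectral_radius = 0.95,
                             noise_scale = 0.1, T_steps = 1000L, seed = 1L) {
  n_states <- .stopifnot_scalar_int(n_states, "n_states")
  n_obs <- .stopifnot_scalar_int(n_obs, "n_obs")
  if (spectral_radius <= 0 || spectral_radius >= 1) {
    stop("spectral_radius must lie strictly between 0 and 1", call. = FALSE)
  }
  if (noise_scale < 0) stop("noise_scale must be nonnegative", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  A <- matrix(stats::rnorm(n_states^2), n_states, n_states)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  A <- A * (spectral_radius / rho)
  repeat {
    H <- matrix(stats::rnorm(n_obs * n_states), n_obs, n_states)
    if (qr(H)$rank == min(n_obs, n_states)) break
  }
  GW <- matrix(stats::rnorm(n_states^2), n_states, n_states)
  GQ <- matrix(stats::rnorm(n_obs^2), n_obs, n_obs)
  W <- .sym(noise_scale * tcrossprod(GW) / n_states)
  Q <- .sym(noise_scale * tcrossprod(GQ) / n_obs)
  x0 <- stats::rnorm(n_states)
  lds_spec(A = A, H = H, W = W, Q = Q, x0 = x0, T_steps = T_steps, seed = seed)
}

#' Simulate a linear-Gaussian dynamical system
#'
#' Runs the recursion \eqn{x_{k+1} = A x_k + w_k}, \eqn{z_k = H x_k + v_k}
#' for `spec$T_steps` steps starting from `spec$x0` (which is `x_1`).
#' Reproducible: the same spec (including seed) yields bit-identical output.
#'
#' @param spec an [lds_spec()].
#'
#' @return A list with `X` (n x T matrix of states, columns x_1..x_T) and
#'   `Z` (m x T matrix of observations, columns z_1..z_T).
#' @export
simulate_lds <- function(spec) {
  stopifnot(inherits(spec, "lds_spec"))
  n <- spec$n_states; m <- spec$n_obs; T_steps <- spec$T_steps
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  sqW <- .psd_sqrt(spec$W)
  sqQ <- .psd_sqrt(spec$Q)
  # draw all noise up front from the single generator: reproducible and fast
  Wn <- sqW %*% matrix(stats::rnorm(n * (T_steps - 1L)), n, T_steps - 1L)
  Vn <- sqQ %*% matrix(stats::rnorm(m * T_steps), m, T_steps)
  X <- matrix(0, n, T_steps)
  X[, 1L] <- spec$x0
  A <- spec$A
  for (k in seq_len(T_steps - 1L)) {
    X[, k + 1L] <- A %*% X[, k] + Wn[, k]
  }
  Z <- spec$H %*% X + Vn
  list(X = X, Z = Z)
}

# Save/restore the global RNG state so simulators with their own seed do not
# disturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
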
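# Internal numerical helpers shared across modules.

# Exact symmetrization; cheap insurance after every covariance product.
.sym <- function(M) (M + t(M)) / 2

# Project a nearly-symmetric matrix onto the PSD cone by eigenvalue clipping.
# `floor` > 0 adds a jitter floor so downstream Cholesky factorizations succeed.
.psd_clip <- function(M, floor = 0) {
  M <- .sym(M)
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  .sym(e$vectors %*% (vals * t(e$vectors)))
}

# Symmetric PSD square root used to sample from N(0, M) with possibly
# singular M (eigenvalues clipped at 0).
.psd_sqrt <- function(M) {
  e <- eigen(.sym(M), symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Validate that `M` is symmetric within sym_tol and PSD within eig_tol,
# naming the offending matrix in the error message.
.check_psd <- function(M, name, sym_tol = 1e-12, eig_tol = -1e-10) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop(sprintf("%s must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(M - t(M))) > sym_tol) {
    stop(sprintf("%s is not symmetric (max asymmetry %.3e)", name,
                 max(abs(M - t(M)))), call. = FALSE)
  }
  ev <- eigen(.sym(M), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < eig_tol) {
    stop(sprintf("%s is not positive semidefinite (min eigenvalue %.3e)",
                 name, min(ev)), call. = FALSE)
  }
  invisible(TRUE)
}

# Right division B = C %*% solve(G) for a symmetric PSD Gram matrix G, with
# ridge regularization scaled by trace(G)/dim and a pseudoinverse fallback.
# This is the solver behind both least-squares fitters.
.solve_gram_right <- function(C, G, ridge = 1e-8, what = "Gram matrix") {
  d <- nrow(G)
  reg <- .sym(G) + diag(ridge * sum(diag(G)) / d, d)
  rc <- rcond(reg)
  if (!is.finite(rc) || rc < 1e-12) {
    warning(sprintf(
      "%s is near rank-deficient (reciprocal condition number %.3e); using pseudoinverse",
      what, rc), call. = FALSE)
    return(C %*% MASS::ginv(reg))
  }
  R <- tryCatch(chol(reg), error = function(e) NULL)
  if (is.null(R)) {
    warning(sprintf(
      "%s Cholesky factorization failed (rcond %.3e); using pseudoinverse",
      what, rc), call. = FALSE)
    return(C %*% MASS::ginv(reg))
  }
  C %*% chol2inv(R)
}

.stopifnot_scalar_int <- function(x, name, lower = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < lower) {
    stop(sprintf("%s must be a single integer >= %d", name, lower), call. = FALSE)
  }
  as.integer(x)
}
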
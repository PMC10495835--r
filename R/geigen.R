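#' Symmetric-definite generalized eigendecomposition
#'
#' Solves `A v = lambda B v` for symmetric A and symmetric positive-definite
#' B via Cholesky whitening: with `B = R'R`, the standard symmetric problem
#' `inv(R') A inv(R) u = lambda u` is solved and `v = inv(R) u`. Eigenvalues
#' are returned in decreasing order; each eigenvector's sign is fixed so its
#' largest-magnitude coefficient is positive.
#'
#' @param A,B symmetric matrices; B positive definite.
#' @return list `values` (decreasing), `vectors` (columns).
#' @export
geigen_sym <- function(A, B) {
  A <- (A + t(A)) / 2
  B <- (B + t(B)) / 2
  R <- tryCatch(chol(B), error = function(e)
    stop("matrix B is not positive definite; add shrinkage regularization"))
  Ri <- backsolve(R, diag(nrow(B)))
  M <- t(Ri) %*% A %*% Ri
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- Ri %*% e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(values = e$values, vectors = V)
}

#' Scalar shrinkage of a covariance/scatter matrix
#'
#' Convex combination of the matrix with a scaled identity,
#' `(1 - gamma) * S + gamma * mean(diag(S)) * I`, the usual guard against
#' rank deficiency when channels outnumber effective observations.
#'
#' @param S symmetric matrix.
#' @param gamma shrinkage intensity in `[0, 1]`.
#' @return regularized matrix.
#' @export
shrink_cov <- function(S, gamma) {
  if (gamma < 0 || gamma > 1) stop("shrinkage must lie in [0, 1]")
  if (gamma == 0) return(S)
  (1 - gamma) * S + gamma * mean(diag(S)) * diag(nrow(S))
}
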
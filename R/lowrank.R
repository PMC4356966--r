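# Spectral machinery: diagonal shift to positive semi-definiteness,
# eigendecomposition with a deterministic sign convention, Eckart-Young
# rank-r truncation, and reconstruction of the connectivity matrix from
# loadings.

check_symmetric <- function(A, tol = 1e-8) {
  A <- as.matrix(A)
  if (!all(is.finite(A))) stop("matrix has non-finite entries")
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > tol) {
    stop("matrix must be symmetric")
  }
  (A + t(A)) / 2
}

#' Shift the diagonal of a connectivity matrix to positive semi-definiteness
#'
#' The diagonal of an Ising connectivity matrix carries no information, so
#' it can be chosen freely.  Adding `shift = max(0, -lambda_min(A))` to the
#' diagonal makes all eigenvalues non-negative while conserving every
#' off-diagonal entry, which is the precondition for factorising the matrix
#' as `E E^T` in the latent representation.  The minimal shift is used, so
#' the smallest eigenvalue of the result is exactly zero (up to roundoff).
#'
#' @param A symmetric numeric matrix.
#' @return A list with `A_psd` (the shifted matrix) and `shift` (the scalar
#'   added to the diagonal).
#' @export
shift_diagonal <- function(A) {
  A <- check_symmetric(A)
  lmin <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  shift <- max(0, -lmin)
  list(A_psd = A + diag(shift, nrow(A)), shift = shift)
}

#' Eigendecomposition with deterministic sign convention
#'
#' Eigenpairs are returned sorted by descending eigenvalue.  The sign of
#' each eigenvector is fixed by making its largest-magnitude entry positive,
#' which resolves the sign indeterminacy reproducibly.  For (near-)tied
#' eigenvalues any orthonormal basis of the eigenspace may be returned;
#' compare projectors, not individual vectors, in that case.
#'
#' @param A_psd symmetric numeric matrix (typically the output of
#'   [shift_diagonal()]).
#' @return An object of class `ising_spectrum`: list with `Q` (orthonormal
#'   eigenvector columns) and `lambda` (non-increasing eigenvalues).
#' @export
ising_spectrum <- function(A_psd) {
  A_psd <- check_symmetric(A_psd)
  e <- eigen(A_psd, symmetric = TRUE)
  Q <- e$vectors
  for (k in seq_len(ncol(Q))) {
    j <- which.max(abs(Q[, k]))
    if (Q[j, k] < 0) Q[, k] <- -Q[, k]
  }
  structure(list(Q = Q, lambda = e$values), class = "ising_spectrum")
}

#' Eckart-Young rank-r loadings
#'
#' Keeps the top `r` eigenpairs of a positive semi-definite matrix and
#' forms the loading matrix \eqn{E = Q_r \Lambda_r^{1/2}}, so that
#' \eqn{E E^\top} is the best rank-`r` approximation in the least-squares
#' (Frobenius) sense.  Row `i` of `E` is the loading vector \eqn{e_i} of
#' node `i` in the latent representation.
#'
#' @param spec an [ising_spectrum()].
#' @param r target rank, `1 <= r <= n`.
#' @param shift the diagonal shift that produced the decomposed matrix
#'   (carried along for bookkeeping; defaults to 0).
#' @return Object of class `ising_loadings`: list with `E` (`n x r`), `r`
#'   and `shift`.
#' @export
low_rank_loadings <- function(spec, r, shift = 0) {
  stopifnot(inherits(spec, "ising_spectrum"))
  n <- length(spec$lambda)
  if (r < 1 || r > n || r != round(r)) {
    stop(sprintf("rank must be an integer in 1..%d", n))
  }
  top <- spec$lambda[seq_len(r)]
  if (any(top < -1e-10)) {
    stop("retained eigenvalue is negative; apply shift_diagonal() first")
  }
  E <- spec$Q[, seq_len(r), drop = FALSE] %*% diag(sqrt(pmax(top, 0)), r)
  ising_loadings(E, shift = shift)
}

#' @rdname low_rank_loadings
#' @param E a loading matrix supplied directly (one row per node).
#' @export
ising_loadings <- function(E, shift = 0) {
  E <- as.matrix(E)
  if (!all(is.finite(E))) stop("loadings must be finite")
  structure(list(E = E, r = ncol(E), shift = shift), class = "ising_loadings")
}

as_loading_matrix <- function(E) {
  if (inherits(E, "ising_loadings")) E$E else as.matrix(E)
}

#' Reconstruct a connectivity matrix from loadings
#'
#' Returns \eqn{E E^\top}, the rank-`r` approximation to the (shifted)
#' connectivity matrix.  With `components = TRUE` the list of rank-one
#' matrices \eqn{E_{\cdot k} E_{\cdot k}^\top} whose sum it is is attached,
#' one per latent dimension, for component-wise reporting.
#'
#' @param loadings an [ising_loadings()] object or a plain loading matrix.
#' @param components if `TRUE`, attach the per-component rank-one matrices
#'   as attribute `"components"`.
#' @return Symmetric `n x n` matrix.
#' @export
reconstruct_connectivity <- function(loadings, components = FALSE) {
  E <- as_loading_matrix(loadings)
  A <- tcrossprod(E)
  if (components) {
    attr(A, "components") <- lapply(seq_len(ncol(E)), function(k) {
      tcrossprod(E[, k])
    })
  }
  A
}
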
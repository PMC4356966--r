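# Posterior predictive checks on the sufficient statistic S.  Replicated
# datasets are generated through the latent model at selected posterior
# draws; the expected replicated S is compared with the observed S through
# the residual matrix and the correlation of strictly-lower-triangle
# entries.

#' Replicate a dataset from the latent model
#'
#' Given loadings, main effects and one latent vector per replication,
#' nodes are drawn independently with
#' \eqn{P(\sigma_{pi} = +1) = \mathrm{logistic}(2(e_i\cdot\theta_p + b_i))}.
#'
#' @param loadings an [ising_loadings()] or plain `n x r` matrix.
#' @param b main-effect vector.
#' @param theta `N x r` matrix of latent vectors.
#' @param seed optional integer seed.
#' @return `N x n` matrix of +1/-1 states.
#' @export
replicate_dataset <- function(loadings, b, theta, seed = NULL) {
  E <- as_loading_matrix(loadings)
  theta <- as.matrix(theta)
  if (ncol(theta) != ncol(E)) stop("theta columns must match loading columns")
  if (length(b) != nrow(E)) stop("length(b) must match rows of E")
  N <- nrow(theta)
  n <- nrow(E)
  draw <- function() {
    p <- stats::plogis(2 * sweep(theta %*% t(E), 2, b, "+"))
    m <- matrix(2 * (stats::runif(N * n) < p) - 1, N, n)
    m
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Posterior predictive check on the sufficient statistic
#'
#' Selects `n_rep` equally spaced post-burn-in draws, generates one
#' replicated dataset from each (with the latent matrix freshly drawn from
#' its exact full conditional at that draw's parameters, unless
#' `redraw_theta = FALSE` and stored latent draws are available), and
#' averages the replicated sufficient statistics.  Reported are the
#' residual matrix `S - S_rep` and the correlation between the
#' strictly-lower-triangle entries of `S` and `S_rep`; the diagonal (the
#' constant `N`) is excluded.
#'
#' @param data `N x n` matrix of +1/-1 states the model was fitted to.
#' @param chains an `ising_chains` object from [fit_lowrank_ising()].
#' @param n_rep number of posterior draws used.
#' @param seed integer seed for the replication randomness.
#' @param redraw_theta if `TRUE` (default), draw fresh latent matrices at
#'   each selected draw, propagating latent uncertainty; if `FALSE`, reuse
#'   the stored latent draws (requires `store_theta = TRUE` at fit time).
#' @return Object of class `ising_ppc`: `S`, `S_rep`, `residual`,
#'   `correlation`, `rank`, `n_rep`.
#' @export
ppc_check <- function(data, chains, n_rep = 50, seed = 1, redraw_theta = TRUE) {
  data <- check_dataset(data)
  stopifnot(inherits(chains, "ising_chains"))
  if (n_rep < 1) stop("n_rep must be at least 1")
  kept <- if (is.null(chains$E)) 0L else nrow(chains$E)
  if (kept < 1) stop("chains are empty")
  if (!redraw_theta && is.null(chains$theta)) {
    stop("redraw_theta = FALSE requires chains fitted with store_theta = TRUE")
  }
  n <- chains$n
  r <- chains$rank
  idx <- unique(round(seq(1, kept, length.out = min(n_rep, kept))))
  S <- sufficient_statistic(data)
  withr::with_seed(seed, {
    S_acc <- matrix(0, n, n)
    for (d in idx) {
      E_d <- matrix(chains$E[d, ], n, r)
      b_d <- chains$b[d, ]
      theta <- if (redraw_theta) {
        draw_theta(E_d, data)
      } else {
        matrix(chains$theta[d, , ], ncol = r)
      }
      S_acc <- S_acc + sufficient_statistic(replicate_dataset(E_d, b_d, theta))
    }
    S_rep <- S_acc / length(idx)
    lt <- lower.tri(S)
    structure(list(S = S, S_rep = S_rep, residual = S - S_rep,
                   correlation = stats::cor(S[lt], S_rep[lt]),
                   rank = r, n_rep = length(idx)),
              class = "ising_ppc")
  })
}

#' @export
print.ising_ppc <- function(x, ...) {
  cat(sprintf(paste0("Posterior predictive check (rank %d, %d draws): ",
                     "lower-triangle correlation %.4f\n"),
              x$rank, x$n_rep, x$correlation))
  invisible(x)
}

#' Lower-triangle scatter export of a posterior predictive check
#'
#' Two-column table of the strictly-lower-triangle entries of `S` and
#' `S_rep`, ready for scatter plotting against the first bisection.
#'
#' @param ppc an `ising_ppc` object.
#' @return `data.frame` with columns `S_lower` and `S_rep_lower`.
#' @export
ppc_scatter <- function(ppc) {
  stopifnot(inherits(ppc, "ising_ppc"))
  lt <- lower.tri(ppc$S)
  data.frame(S_lower = ppc$S[lt], S_rep_lower = ppc$S_rep[lt])
}
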
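# Synthetic network generators for the two flavours of Ising application --
# nearest-neighbour lattices (near-linear eigenvalue spectrum) and dense
# low-rank networks (a dominant all-positive component plus zero-sum
# contrasts) -- and an exact data-augmented Gibbs sampler that scales to
# networks far beyond the enumeration limit.

#' Nearest-neighbour lattice network
#'
#' A `side x side` square lattice with equal couplings on 4-neighbour
#' edges (toroidal if `wrap = TRUE`) and zero main effects.  Its
#' eigenvalue spectrum is near-linear: no small set of components
#' dominates, the signature of physics-flavour Ising applications.
#'
#' @param side lattice side length, at least 2.
#' @param coupling interaction strength on each edge.
#' @param wrap if `TRUE`, opposite edges are identified (torus).
#' @return An [ising_model()] with `n = side^2` nodes.
#' @export
make_lattice <- function(side, coupling = 0.5, wrap = FALSE) {
  if (side < 2) stop("side must be at least 2")
  n <- side^2
  idx <- function(row, col) (row - 1) * side + col
  A <- matrix(0, n, n)
  for (row in seq_len(side)) {
    for (col in seq_len(side)) {
      i <- idx(row, col)
      if (col < side) A[i, idx(row, col + 1)] <- coupling
      else if (wrap && side > 2) A[i, idx(row, 1)] <- coupling
      if (row < side) A[i, idx(row + 1, col)] <- coupling
      else if (wrap && side > 2) A[i, idx(1, col)] <- coupling
    }
  }
  A <- pmax(A, t(A))
  ising_model(b = rep(0, n), A = A)
}

#' Dense low-rank network
#'
#' Generates a network whose connectivity is `E E^T` (diagonal zeroed)
#' with the component structure typical of dense social-science networks:
#' the first column of `E` is all-positive (a general factor), and columns
#' `2..r` are zero-sum block contrasts that give sets of nodes higher
#' positive interactions amongst themselves and negative interactions
#' across sets.  Components are parameterised by their eigenvalues
#' (squared column norms), so the network's latent geometry is independent
#' of `n`: individual couplings scale as `1/n`, the mean-field convention.
#' The defaults place the general factor moderately above the mean-field
#' critical point (`lambda = 1.8`) with contrasts well separated from the
#' residual scree.  Main effects are small, uniform in
#' `b_scale * c(-1, 1)`.  The true loading matrix is returned for
#' recovery studies.
#'
#' @param n node count.
#' @param r rank (number of components), `1 <= r <= n`.
#' @param general_eigenvalue squared norm of the all-positive first
#'   component; entry heterogeneity is uniform within a 0.7-1.3 band.
#' @param contrast_eigenvalue squared norm of the first contrast
#'   component; later contrasts decay geometrically by `contrast_decay`.
#' @param contrast_decay eigenvalue ratio between successive contrasts.
#' @param b_scale half-width of the main-effect band.
#' @param seed integer seed.
#' @return List with `model` (an [ising_model()]) and `E_true` (`n x r`).
#' @export
make_dense_lowrank <- function(n, r, general_eigenvalue = 1.8,
                               contrast_eigenvalue = 0.9,
                               contrast_decay = 0.8, b_scale = 0.05,
                               seed = 1) {
  if (r < 1 || r > n) stop("need 1 <= r <= n")
  if (general_eigenvalue <= 0 || contrast_eigenvalue < 0) {
    stop("component eigenvalues must be positive")
  }
  withr::with_seed(seed, {
    E <- matrix(0, n, r)
    u <- stats::runif(n, 0.7, 1.3)
    E[, 1] <- u * sqrt(general_eigenvalue / sum(u^2))
    if (r > 1) {
      for (k in 2:r) {
        block <- max(1, floor(n / 2^(k - 1)))
        sgn <- rep(rep(c(1, -1), each = block), length.out = n)
        col <- sgn * stats::runif(n, 0.5, 1)
        col <- col - mean(col)   # exact zero-sum contrast
        lam_k <- contrast_eigenvalue * contrast_decay^(k - 2)
        E[, k] <- col * sqrt(lam_k / sum(col^2))
      }
    }
    b <- stats::runif(n, -b_scale, b_scale)
    A <- tcrossprod(E)
    diag(A) <- 0
    list(model = ising_model(b = b, A = A), E_true = E)
  })
}

#' Exact sampling through the latent representation
#'
#' Data-augmented Gibbs sampling of the joint `(sigma, theta)`
#' distribution: both conditionals are tractable
#' (`sigma | theta` factorises over nodes, `theta | sigma` is
#' `N(E^T sigma, I_r)`), so no partition function is needed and the
#' sampler scales to arbitrary `n`.  By default one independent chain is
#' run per replication (`burn_in` sweeps each), guaranteeing exchangeable
#' replications; alternatively one long chain is thinned.
#'
#' @param loadings an [ising_loadings()] or plain `n x r` matrix
#'   (typically from [low_rank_loadings()] applied to the target model's
#'   shifted connectivity matrix).
#' @param b main-effect vector.
#' @param N number of replications.
#' @param burn_in Gibbs sweeps per chain (independent mode) or discarded
#'   from the front (thinned mode).
#' @param seed optional integer seed.
#' @param method `"independent"` (default) or `"thinned"`.
#' @param thin sweeps between stored states in thinned mode.
#' @return `N x n` matrix of +1/-1 states.
#' @export
generate_augmented <- function(loadings, b, N, burn_in = 200, seed = NULL,
                               method = c("independent", "thinned"),
                               thin = 10) {
  E <- as_loading_matrix(loadings)
  method <- match.arg(method)
  n <- nrow(E)
  r <- ncol(E)
  if (length(b) != n) stop("length(b) must match rows of E")
  if (r < 1) stop("rank must be at least 1")
  run <- function() {
    if (method == "independent") {
      sigma <- matrix(sample(c(-1, 1), N * n, replace = TRUE), N, n)
      for (sweep_i in seq_len(burn_in)) {
        theta <- sigma %*% E + matrix(stats::rnorm(N * r), N)
        p <- stats::plogis(2 * sweep(theta %*% t(E), 2, b, "+"))
        sigma <- matrix(2 * (stats::runif(N * n) < p) - 1, N, n)
      }
      sigma
    } else {
      sigma <- sample(c(-1, 1), n, replace = TRUE)
      out <- matrix(NA_real_, N, n)
      stored <- 0
      sweep_i <- 0
      while (stored < N) {
        sweep_i <- sweep_i + 1
        theta <- drop(crossprod(E, sigma)) + stats::rnorm(r)
        p <- stats::plogis(2 * (drop(E %*% theta) + b))
        sigma <- 2 * (stats::runif(n) < p) - 1
        if (sweep_i > burn_in && (sweep_i - burn_in) %% thin == 0) {
          stored <- stored + 1
          out[stored, ] <- sigma
        }
      }
      out
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
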
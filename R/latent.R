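# Latent-variable representation of the Ising model.  Writing the shifted
# connectivity matrix as E E^T and applying the Gaussian identity
# exp(||E^T sigma||^2 / 2) = E[exp(sigma^T E theta)], theta ~ N(0, I_r),
# makes the nodes conditionally independent given theta: the conditional
# p(sigma | theta) is a multidimensional 2PL item response model and the
# partition function survives only as the normalising constant of the
# latent density f(theta | W).

log2cosh <- function(x) abs(x) + log1p(exp(-2 * abs(x)))

#' Conditional state probability given the latent variables
#'
#' \eqn{p(\sigma\mid\theta) = \prod_i
#'   \exp(\sigma_i(e_i\cdot\theta + b_i)) / (2\cosh(e_i\cdot\theta + b_i))}:
#' all nodes are independent conditionally on the full set of latent
#' variables.  With equal loadings in one dimension this is the Rasch model.
#'
#' @param loadings an [ising_loadings()] object or plain `n x r` matrix.
#' @param b main-effect vector, length `n`.
#' @param theta latent vector, length `r`.
#' @param sigma +1/-1 state vector.
#' @return The conditional probability, a number in (0, 1).
#' @export
irt_prob <- function(loadings, b, theta, sigma) {
  E <- as_loading_matrix(loadings)
  n <- nrow(E)
  if (length(b) != n) stop(sprintf("length(b) = %d but E has %d rows", length(b), n))
  if (length(theta) != ncol(E)) {
    stop(sprintf("length(theta) = %d but E has %d columns", length(theta), ncol(E)))
  }
  sigma <- check_state(sigma, n)
  eta <- drop(E %*% theta) + b
  exp(sum(sigma * eta - log2cosh(eta)))
}

#' Unnormalised log-density of the latent variables
#'
#' \eqn{\log f(\theta\mid W) = -\|\theta\|^2/2 +
#'   \sum_i \log 2\cosh(e_i\cdot\theta + b_i) + \mathrm{const}}, where the
#' omitted constant involves the partition function.  `log 2 cosh` is
#' evaluated in overflow-safe form.
#'
#' @inheritParams irt_prob
#' @return The unnormalised log-density at `theta`.
#' @export
latent_logdensity <- function(loadings, b, theta) {
  E <- as_loading_matrix(loadings)
  if (length(b) != nrow(E)) stop("length(b) must match rows of E")
  if (length(theta) != ncol(E)) stop("length(theta) must match columns of E")
  eta <- drop(E %*% theta) + b
  -0.5 * sum(theta^2) + sum(log2cosh(eta))
}

gh_grid <- function(r, nodes) {
  gh <- pracma::gaussHermite(nodes)
  # rescale the physicists' rule to expectation under N(0, 1)
  x <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  if (r == 1) {
    list(theta = matrix(x, ncol = 1), w = w)
  } else {
    g <- expand.grid(x, x)
    list(theta = as.matrix(g), w = as.vector(outer(w, w)))
  }
}

#' Marginal state probabilities by Gauss-Hermite quadrature
#'
#' Integrates the conditional IRT likelihood over the latent distribution
#' on a tensor Gauss-Hermite grid and normalises over all `2^n` states.
#' This is the quadrature oracle for the central identity of the latent
#' representation: the marginal must reproduce the exact Ising
#' probabilities of the model with connectivity `E E^T`.  Deliberately
#' limited to `r <= 2` and `n <= 20`; it exists to check the algebra, not
#' to scale.
#'
#' @inheritParams irt_prob
#' @param sigma a state vector or matrix of states (one per row).
#' @param gh_nodes quadrature nodes per latent dimension.
#' @return Marginal probabilities, one per supplied state.
#' @export
marginal_prob_quadrature <- function(loadings, b, sigma, gh_nodes = 64) {
  E <- as_loading_matrix(loadings)
  n <- nrow(E)
  r <- ncol(E)
  if (r > 2) stop("quadrature oracle supports r <= 2 only")
  check_enum(n)
  if (!is.matrix(sigma)) sigma <- matrix(sigma, nrow = 1)
  states <- enumerate_states(n)
  grid <- gh_grid(r, gh_nodes)
  # u(sigma) = E_theta[ prod_i exp(sigma_i (e_i.theta + b_i)) ]
  eta <- grid$theta %*% t(E)                     # G x n, plus b per column
  eta <- sweep(eta, 2, b, "+")
  log_u_all <- function(S) {
    # log sum_g w_g exp(S %*% eta_g); work state-block-wise in log space
    M <- S %*% t(eta)                            # states x G
    mx <- apply(M, 1, max)
    mx + log((exp(M - mx) %*% grid$w)[, 1])
  }
  lu <- log_u_all(states)
  lz <- {
    m <- max(lu)
    m + log(sum(exp(lu - m)))
  }
  exp(log_u_all(sigma) - lz)
}

#' Full-conditional posterior of a replication's latent vector
#'
#' Given the state \eqn{\sigma} of one replication, the latent vector has
#' the exact multivariate-normal full conditional
#' \eqn{\theta \mid \sigma \sim N(E^\top\sigma, I_r)}; the main effects
#' cancel.  This closed form is what makes the Gibbs half-step for the
#' latent variables trivial.
#'
#' @inheritParams irt_prob
#' @return List with `mean` (length `r`) and `covariance` (the `r x r`
#'   identity).
#' @export
theta_posterior <- function(loadings, sigma) {
  E <- as_loading_matrix(loadings)
  sigma <- check_state(sigma, nrow(E))
  list(mean = drop(crossprod(E, sigma)), covariance = diag(ncol(E)))
}

#' Curie-Weiss latent log-density
#'
#' For the fully connected network with all pairwise interactions equal to
#' `a/n` (mean-field scaling) and zero main effects, the latent
#' representation is rank one with common loading `sqrt(a/n)`, giving
#' \deqn{\log f(\theta) = -\theta^2/2 + n \log 2\cosh(\sqrt{a/n}\,\theta) + c.}
#' The curvature at the origin is `a - 1` for every `n`, so the density is
#' unimodal for `a < 1` and bimodal for `a > 1`: the mean-field phase
#' transition sits at `a = 1` independent of network size.
#'
#' @param a non-negative coupling strength.
#' @param n node count, at least 2.
#' @param theta numeric vector of evaluation points.
#' @return Unnormalised log-density values at `theta`.
#' @export
curie_weiss_logdensity <- function(a, n, theta) {
  if (a < 0) stop("coupling a must be non-negative")
  if (n < 2) stop("n must be at least 2")
  -0.5 * theta^2 + n * log2cosh(sqrt(a / n) * theta)
}

#' Count modes of a gridded log-density
#'
#' Counts strict interior local maxima of log-density values on a uniform
#' grid, merging plateaus whose values differ by less than `1e-12`.
#' Boundary grid points never count as modes.  The grid must span at least
#' 8 standard-normal standard deviations with at least 2001 points so that
#' closely spaced modes are resolved.
#'
#' @param theta uniform grid of evaluation points.
#' @param logf log-density values at `theta`.
#' @return Integer mode count.
#' @export
count_modes <- function(theta, logf) {
  if (length(theta) != length(logf)) stop("theta and logf must have equal length")
  if (length(theta) < 2001) stop("grid too coarse: need at least 2001 points")
  if (diff(range(theta)) < 8) stop("grid must span at least 8 standard deviations")
  # merge plateaus: collapse runs of values equal to within 1e-12
  keep <- c(TRUE, abs(diff(logf)) > 1e-12)
  v <- logf[keep]
  k <- length(v)
  if (k < 3) return(if (k == 1) 1L else 0L)
  sum(v[2:(k - 1)] > v[1:(k - 2)] & v[2:(k - 1)] > v[3:k])
}
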
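# Exact Ising-model computations.  Everything here enumerates states and is
# therefore restricted to small networks (n <= 20); it defines the model and
# serves as the brute-force oracle for the latent representation and the
# sampler.

.ENUM_LIMIT <- 20L

#' Construct an Ising model
#'
#' An Ising model over `n` binary (+1/-1) nodes is parameterised by a vector
#' of main effects `b` and a symmetric connectivity matrix `A` of pairwise
#' interactions.  The probability of a state \eqn{\sigma \in \{-1,+1\}^n} is
#' \deqn{p(\sigma) \propto \exp(b^\top \sigma + \tfrac12 \sigma^\top A \sigma).}
#' The diagonal of `A` contributes only a constant (\eqn{\sigma_i^2 = 1}) and
#' is therefore not identifiable: all probabilities are invariant under
#' `A + c I`.
#'
#' @param b numeric vector of main effects, length `n`.
#' @param A symmetric numeric `n x n` matrix of pairwise interactions.
#' @return An object of class `ising_model` with elements `n`, `b`, `A`.
#' @examples
#' m <- ising_model(b = c(0, 0), A = matrix(c(0, 1, 1, 0), 2))
#' ising_probability(m, c(1, 1))
#' @export
ising_model <- function(b, A) {
  b <- as.numeric(b)
  A <- as.matrix(A)
  n <- length(b)
  if (nrow(A) != n || ncol(A) != n) {
    stop(sprintf("dimension mismatch: length(b) = %d but A is %d x %d",
                 n, nrow(A), ncol(A)))
  }
  if (!all(is.finite(b)) || !all(is.finite(A))) {
    stop("model parameters must be finite")
  }
  if (max(abs(A - t(A))) > 1e-12) {
    stop("A must be symmetric (tolerance 1e-12)")
  }
  structure(list(n = n, b = b, A = A), class = "ising_model")
}

#' @export
print.ising_model <- function(x, ...) {
  cat(sprintf("Ising model: %d nodes, %d non-zero pairwise interactions\n",
              x$n, sum(x$A[upper.tri(x$A)] != 0)))
  invisible(x)
}

check_state <- function(sigma, n) {
  sigma <- as.numeric(sigma)
  if (length(sigma) != n) {
    stop(sprintf("state has length %d but the model has %d nodes",
                 length(sigma), n))
  }
  if (!all(sigma %in% c(-1, 1))) stop("state entries must be -1 or +1")
  sigma
}

check_enum <- function(n, hint = "use the latent representation and the sampler instead") {
  if (n > .ENUM_LIMIT) {
    stop(sprintf("exact enumeration is limited to n <= %d (got n = %d); %s",
                 .ENUM_LIMIT, n, hint))
  }
}

#' Enumerate all states of a small network
#'
#' Returns the complete `2^n x n` table of +1/-1 state vectors, the raw
#' material of every enumeration oracle in the package.
#'
#' @param n node count, at most 20.
#' @return Numeric matrix with `2^n` rows; each row a state.
#' @export
enumerate_states <- function(n) {
  check_enum(n)
  m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(m) <- NULL
  m
}

#' Unnormalised log-weight of a state
#'
#' Computes \eqn{b^\top\sigma + \tfrac12 \sigma^\top A \sigma}, the diagonal
#' of `A` included as written (it adds the constant `trace(A)/2`, which
#' cancels in every probability).
#'
#' @param model an [ising_model()].
#' @param sigma a +1/-1 state vector, or a matrix with one state per row.
#' @return Numeric vector of log-weights, one per state.
#' @export
log_weight <- function(model, sigma) {
  stopifnot(inherits(model, "ising_model"))
  if (is.matrix(sigma)) {
    if (ncol(sigma) != model$n) {
      stop(sprintf("states have %d columns but the model has %d nodes",
                   ncol(sigma), model$n))
    }
    drop(sigma %*% model$b) + 0.5 * rowSums((sigma %*% model$A) * sigma)
  } else {
    sigma <- check_state(sigma, model$n)
    sum(model$b * sigma) + 0.5 * sum(sigma * (model$A %*% sigma))
  }
}

#' Log partition function by enumeration
#'
#' The partition function \eqn{Z} sums the unnormalised weights over all
#' `2^n` states.  Accumulation is done in log-space with max-subtraction so
#' that strong couplings do not overflow.  Only available for `n <= 20`.
#'
#' @inheritParams log_weight
#' @return `log Z` as a single number.
#' @export
log_partition_function <- function(model) {
  stopifnot(inherits(model, "ising_model"))
  check_enum(model$n)
  lw <- log_weight(model, enumerate_states(model$n))
  m <- max(lw)
  m + log(sum(exp(lw - m)))
}

#' @rdname log_partition_function
#' @export
partition_function <- function(model) {
  exp(log_partition_function(model))
}

#' Exact state probabilities by enumeration
#'
#' @inheritParams log_weight
#' @return Probabilities in (0, 1), one per supplied state.
#' @export
ising_probability <- function(model, sigma) {
  exp(log_weight(model, sigma) - log_partition_function(model))
}

#' Full-conditional probability of a single node
#'
#' The conditional distribution of node `i` given the rest is a logistic
#' regression: \eqn{P(\sigma_i = +1 \mid \sigma_{\setminus i}) =
#' \mathrm{logistic}(2(b_i + \sum_{j \ne i} A_{ij}\sigma_j))}.  In spectral
#' form the predictor is rewritten through the eigendecomposition of the
#' diagonally shifted connectivity matrix: the log-odds become
#' \eqn{2(b_i + \sum_r \lambda_r q_{ir} t^{(i)}_r)} where
#' \eqn{t^{(i)}_r = \sum_j q_{jr}\sigma_j - \sigma_i q_{ir}} is the r-th
#' principal-component rest-score.  Both parameterisations agree exactly
#' because the diagonal shift leaves off-diagonal entries untouched.
#'
#' @inheritParams log_weight
#' @param i node index in `1:n`.
#' @param method `"direct"` (default) or `"spectral"`.
#' @return `P(sigma_i = +1 | rest)`, a number in (0, 1).
#' @export
full_conditional <- function(model, sigma, i, method = c("direct", "spectral")) {
  method <- match.arg(method)
  sigma <- check_state(sigma, model$n)
  if (length(i) != 1 || i < 1 || i > model$n || i != round(i)) {
    stop(sprintf("node index must be a single integer in 1..%d", model$n))
  }
  if (method == "direct") {
    eta <- model$b[i] + sum(model$A[i, -i] * sigma[-i])
  } else {
    sd <- shift_diagonal(model$A)
    sp <- ising_spectrum(sd$A_psd)
    t_full <- drop(crossprod(sp$Q, sigma))        # principal-component scores
    rest <- t_full - sigma[i] * sp$Q[i, ]          # rest-scores
    # the shift changes only the diagonal, which the rest-score excludes
    eta <- model$b[i] + sum(sp$lambda * sp$Q[i, ] * rest)
  }
  stats::plogis(2 * eta)
}

#' Exact sampling from a small Ising model
#'
#' Enumeration-based inverse-CDF sampling: all `2^n` probabilities are
#' computed and `N` states drawn from the resulting categorical
#' distribution.  For larger networks use [generate_augmented()].
#'
#' @inheritParams log_weight
#' @param N number of independent replications.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return `N x n` matrix of +1/-1 states.
#' @export
sample_exact <- function(model, N, seed = NULL) {
  check_enum(model$n, hint = "use generate_augmented() for large networks")
  stopifnot(N >= 1)
  states <- enumerate_states(model$n)
  lw <- log_weight(model, states)
  p <- exp(lw - max(lw))
  draw <- function() states[sample.int(nrow(states), N, replace = TRUE, prob = p), , drop = FALSE]
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Sufficient statistic for the connectivity matrix
#'
#' \eqn{S = \sum_p \sigma_p \sigma_p^\top}: symmetric, integer-valued,
#' diagonal equal to the replication count `N`.  `S` is sufficient for the
#' connectivity matrix and is the target of the posterior predictive checks
#' in [ppc_check()].
#'
#' @param data `N x n` matrix of +1/-1 states.
#' @return Symmetric `n x n` matrix.
#' @export
sufficient_statistic <- function(data) {
  data <- check_dataset(data)
  crossprod(data)
}

check_dataset <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 1) stop("dataset must contain at least one replication")
  if (!all(data %in% c(-1, 1))) stop("dataset entries must be -1 or +1")
  storage.mode(data) <- "double"
  data
}
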
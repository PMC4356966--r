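# Shared fixtures: small random models and enumeration-based oracles.

# random symmetric connectivity with zero diagonal
random_model <- function(n, scale = 0.5, b_scale = 0.5) {
  X <- matrix(stats::rnorm(n * n, 0, scale), n, n)
  A <- (X + t(X)) / 2
  diag(A) <- 0
  ising_model(b = stats::runif(n, -b_scale, b_scale), A = A)
}

# enumeration oracle for the full conditional of node i
enum_conditional <- function(model, sigma, i) {
  sp <- sigma; sp[i] <- 1
  sm <- sigma; sm[i] <- -1
  p <- unname(ising_probability(model, unname(rbind(sp, sm))))
  p[1] / (p[1] + p[2])
}

# grid-normalised CDF of a scalar partial conditional
grid_cdf <- function(grid, fam, prior, kind) {
  lp <- partial_logdensity(grid, fam, prior, kind)
  d <- exp(lp - max(lp))
  cumsum(d) / sum(d)
}

# Kolmogorov-Smirnov distance between samples and a gridded CDF
ks_to_grid <- function(draws, grid, cdf) {
  max(abs(stats::ecdf(draws)(grid) - cdf))
}

# run a fixed-curves Metropolis-Hastings chain
run_scalar_chain <- function(w0, prior, fam, steps, kind = "b") {
  draws <- numeric(steps)
  acc <- 0
  w <- w0
  for (k in seq_len(steps)) {
    st <- mh_step(w, prior, fam, kind)
    w <- st$w
    acc <- acc + st$accepted
    draws[k] <- w
  }
  list(draws = draws, acceptance = acc / steps)
}
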
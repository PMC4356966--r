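test_that("conditional IRT probabilities factorise and normalise", {
  n <- 4
  E0 <- matrix(0, n, 1)
  for (k in 1:3) {
    s <- c(1, -1, 1, -1) * (-1)^k
    expect_equal(irt_prob(E0, rep(0, n), 0, s), 2^-n)
  }

  # per-node factor at +1 and -1 sums to one
  withr::with_seed(2, {
    E <- matrix(stats::rnorm(2), 1, 2)
    b <- stats::rnorm(1)
    th <- stats::rnorm(2)
    expect_equal(irt_prob(E, b, th, 1) + irt_prob(E, b, th, -1), 1)
  })

  # equal loadings: Rasch model, depends on sigma only through its sum
  withr::with_seed(4, {
    n <- 6
    E <- matrix(0.4, n, 1)
    b <- rep(0.1, n)
    th <- 0.8
    s <- c(1, 1, -1, 1, -1, -1)
    for (k in 1:5) {
      expect_equal(irt_prob(E, b, th, sample(s)), irt_prob(E, b, th, s))
    }
  })
})

test_that("latent log-density has the stated kernel and integrates to sqrt(2*pi)*Z", {
  n <- 5
  E0 <- matrix(0, n, 1)
  th <- c(-2, 0, 1.3)
  for (t in th) {
    expect_equal(latent_logdensity(E0, rep(0, n), t), -t^2 / 2 + n * log(2))
  }

  withr::with_seed(6, {
    E <- matrix(stats::runif(n, -0.5, 0.5), n, 1)
    expect_equal(latent_logdensity(E, rep(0, n), 1.7),
                 latent_logdensity(E, rep(0, n), -1.7))

    # grid integral against the enumerated partition function
    b <- stats::runif(n, -0.4, 0.4)
    m <- ising_model(b, tcrossprod(E))
    grid <- seq(-14, 14, length.out = 6001)
    h <- diff(grid[1:2])
    total <- sum(exp(sapply(grid, function(t) latent_logdensity(E, b, t)))) * h
    expect_equal(total, sqrt(2 * pi) * partition_function(m),
                 tolerance = 1e-6)
  })

  # stable far in the tails
  expect_true(is.finite(latent_logdensity(matrix(2, 3, 1), rep(0, 3), 400)))
})

test_that("quadrature marginal reproduces exact Ising probabilities", {
  n <- 6
  expect_equal(marginal_prob_quadrature(matrix(0, n, 1), rep(0, n),
                                        rep(1, n)),
               2^-n, tolerance = 1e-10)

  withr::with_seed(9, {
    E <- matrix(stats::runif(8, -0.4, 0.4), 8, 1)
    b <- stats::runif(8, -0.5, 0.5)
    S <- enumerate_states(8)
    expect_lt(max(abs(marginal_prob_quadrature(E, b, S) -
                        ising_probability(ising_model(b, tcrossprod(E)), S))),
              1e-6)

    E2 <- matrix(stats::runif(12, -0.4, 0.4), 6, 2)
    b2 <- stats::runif(6, -0.3, 0.3)
    S6 <- enumerate_states(6)
    expect_lt(max(abs(marginal_prob_quadrature(E2, b2, S6) -
                        ising_probability(ising_model(b2, tcrossprod(E2)), S6))),
              1e-6)
  })
  expect_error(marginal_prob_quadrature(matrix(0, 4, 3), rep(0, 4),
                                        rep(1, 4)), "r <= 2")
})

test_that("latent posterior is N(E^T sigma, I) including against quadrature", {
  withr::with_seed(12, {
    E <- matrix(stats::runif(6, -0.6, 0.6), 6, 1)
    post <- theta_posterior(E, rep(1, 6))
    expect_equal(post$mean, colSums(E))
    expect_equal(post$covariance, diag(1))

    s <- sample(c(-1, 1), 6, replace = TRUE)
    expect_equal(theta_posterior(E, -s)$mean, -theta_posterior(E, s)$mean)

    # 1-D grid: density prop. to p(sigma|theta) * exp(latent log-density)
    b <- stats::runif(6, -0.3, 0.3)
    grid <- seq(-10, 10, length.out = 8001)
    g <- vapply(grid, function(t) {
      irt_prob(E, b, t, s) * exp(latent_logdensity(E, b, t))
    }, numeric(1))
    g <- g / sum(g)
    mu <- sum(grid * g)
    v <- sum(grid^2 * g) - mu^2
    expect_equal(mu, drop(crossprod(E, s)), tolerance = 1e-4)
    expect_equal(v, 1, tolerance = 1e-4)
  })
})

test_that("Curie-Weiss density has curvature a - 1 at the origin", {
  th <- c(-1.2, 0, 2.4)
  expect_equal(curie_weiss_logdensity(0, 7, th), -th^2 / 2 + 7 * log(2))
  expect_equal(curie_weiss_logdensity(1.4, 9, 1.1),
               curie_weiss_logdensity(1.4, 9, -1.1))

  h <- 1e-4
  for (a in c(0.25, 0.8, 1, 1.7)) {
    for (n in c(2, 10, 50)) {
      curv <- (curie_weiss_logdensity(a, n, h) -
                 2 * curie_weiss_logdensity(a, n, 0) +
                 curie_weiss_logdensity(a, n, -h)) / h^2
      expect_equal(curv, a - 1, tolerance = 1e-5)
    }
  }
  expect_error(curie_weiss_logdensity(-0.1, 5, 0), "non-negative")
})

test_that("mode counting brackets the mean-field transition", {
  grid <- seq(-10, 10, length.out = 4001)
  expect_equal(count_modes(grid, -grid^2 / 2), 1L)
  expect_equal(count_modes(grid, curie_weiss_logdensity(0.5, 20, grid)), 1L)
  expect_equal(count_modes(grid, curie_weiss_logdensity(1.5, 20, grid)), 2L)
  expect_error(count_modes(grid[1:100], -grid[1:100]^2), "coarse")
  expect_error(count_modes(seq(-2, 2, length.out = 3000),
                           rep(0, 3000)), "span")
})

test_that("density shape follows the coupling strength", {
  grid <- seq(-12, 12, length.out = 6001)
  # near-normal at weak coupling: small excess kurtosis
  g <- exp(curie_weiss_logdensity(0.25, 20, grid))
  g <- g / sum(g)
  mu <- sum(grid * g)
  v <- sum((grid - mu)^2 * g)
  kurt <- sum((grid - mu)^4 * g) / v^2 - 3
  expect_lt(abs(kurt), 0.05)

  # mode separation grows with a beyond the transition
  sep <- vapply(c(1.2, 1.5, 2, 3), function(a) {
    lf <- curie_weiss_logdensity(a, 20, grid)
    peaks <- grid[which(diff(sign(diff(lf))) == -2) + 1]
    diff(range(peaks))
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
})
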
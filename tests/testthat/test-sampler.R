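test_that("latent draws have the exact normal full conditional", {
  withr::with_seed(31, {
    N <- 4000
    d <- matrix(sample(c(-1, 1), N * 3, replace = TRUE), N, 3)
    th0 <- draw_theta(matrix(0, 3, 2), d, seed = 1)
    expect_equal(dim(th0), c(N, 2))
    expect_true(all(abs(colMeans(th0)) < 4 / sqrt(N)))
    expect_identical(th0, draw_theta(matrix(0, 3, 2), d, seed = 1))

    # repeated redraws at a fixed state centre on E^T sigma
    E <- matrix(stats::runif(6, -0.5, 0.5), 3, 2)
    s <- matrix(c(1, -1, 1), 1)
    redraws <- draw_theta(E, s[rep(1, N), ])
    expect_true(all(abs(colMeans(redraws) - drop(crossprod(E, drop(s)))) <
                      4 / sqrt(N)))
  })
})

test_that("observation curves reproduce the IRT node probabilities", {
  withr::with_seed(33, {
    n <- 5; N <- 40; r <- 2
    E <- matrix(stats::rnorm(n * r, 0, 0.4), n, r)
    b <- stats::runif(n, -0.5, 0.5)
    d <- matrix(sample(c(-1, 1), N * n, replace = TRUE), N, n)
    theta <- draw_theta(E, d)

    irt_node_loglik <- function(i, bi, Ei) {
      Emod <- E; Emod[i, ] <- Ei
      eta <- drop(theta %*% Emod[i, ]) + bi
      sum(stats::plogis(2 * d[, i] * eta, log.p = TRUE))
    }

    for (w in c(-0.8, 0.3, 1.1)) {
      fam_b <- obs_cdf_family("b", 2, theta = theta, loadings = E, b = b,
                              data = d)
      lhs <- sum(ifelse(fam_b$y == 1,
                        stats::plogis(w, fam_b$location, fam_b$scale, log.p = TRUE),
                        stats::plogis(w, fam_b$location, fam_b$scale,
                                      lower.tail = FALSE, log.p = TRUE)))
      expect_equal(lhs, irt_node_loglik(2, w, E[2, ]), tolerance = 1e-12)

      # loading update, including the flipped construction for negative theta
      fam_e <- obs_cdf_family("e", 3, 2, theta = theta, loadings = E, b = b,
                              data = d)
      expect_true(any(theta[, 2] < 0))
      lhs_e <- sum(ifelse(fam_e$y == 1,
                          stats::plogis(w, fam_e$location, fam_e$scale, log.p = TRUE),
                          stats::plogis(w, fam_e$location, fam_e$scale,
                                        lower.tail = FALSE, log.p = TRUE)))
      Ei <- E[3, ]; Ei[2] <- w
      expect_equal(lhs_e, irt_node_loglik(3, b[3], Ei), tolerance = 1e-12)
    }

    # theta exactly zero: replication dropped
    theta0 <- theta; theta0[7, 1] <- 0
    fam0 <- obs_cdf_family("e", 1, 1, theta = theta0, loadings = E, b = b,
                           data = d)
    expect_length(fam0$location, N - 1)
  })
})

test_that("order-statistic proposal has rank total-score + 1", {
  pr <- ising_prior()
  withr::with_seed(35, {
    for (k in 1:30) {
      N <- sample(1:20, 1)
      fam <- list(location = stats::rnorm(N), scale = stats::runif(N, 0.2, 2),
                  y = stats::rbinom(N, 1, 0.5))
      prop <- os_propose(pr, fam)
      # exactly y_plus of the other draws fall below the proposal
      expect_equal(sum(prop$x), sum(fam$y))
      expect_length(prop$others, N)
    }

    # no observations: the prior draw itself comes back
    fam0 <- list(location = numeric(0), scale = numeric(0), y = numeric(0))
    prop0 <- os_propose(pr, fam0)
    expect_equal(prop0$j, 0L)

    # identical curves, maximal score: the maximum of the draws
    fam_max <- list(location = rep(0, 6), scale = rep(1, 6), y = rep(1, 6))
    for (k in 1:10) {
      p <- os_propose(list(rdraw = function(m) stats::rlogis(m),
                           logdens = function(w) stats::dlogis(w, log = TRUE),
                           logcdf = function(w, lower = TRUE) {
                             stats::plogis(w, lower.tail = lower, log.p = TRUE)
                           }),
                      fam_max)
      expect_equal(sum(p$x), 6)   # everything else below the proposal
    }
  })
})

test_that("independence MH accepts always when target equals proposal", {
  pr <- ising_prior()
  fam0 <- list(location = numeric(0), scale = numeric(0), y = numeric(0))
  withr::with_seed(37, {
    res <- run_scalar_chain(0.3, pr, fam0, 2000)
    expect_equal(res$acceptance, 1)
    # draws are then i.i.d. prior samples
    expect_equal(mean(res$draws), 0, tolerance = 0.15)
  })
})

test_that("scalar chains match the grid-normalised partial conditional", {
  withr::with_seed(39, {
    n <- 5; N <- 300
    E <- matrix(stats::runif(n, 0.1, 0.5), n, 1)
    b <- stats::runif(n, -0.3, 0.3)
    d <- generate_augmented(E, b, N, burn_in = 100)
    theta <- draw_theta(E, d)
    pr <- ising_prior()

    fam_b <- obs_cdf_family("b", 2, theta = theta, loadings = E, b = b,
                            data = d)
    grid <- seq(-2.5, 2.5, length.out = 3001)
    res <- run_scalar_chain(0, pr, fam_b, 4000)
    ks <- ks_to_grid(res$draws[1001:4000], grid, grid_cdf(grid, fam_b, pr, "b"))
    expect_lt(ks, 0.05)

    fam_e <- obs_cdf_family("e", 4, 1, theta = theta, loadings = E, b = b,
                            data = d)
    res_e <- run_scalar_chain(E[4, 1], pr, fam_e, 4000)
    ks_e <- ks_to_grid(res_e$draws[1001:4000], grid,
                       grid_cdf(grid, fam_e, pr, "e"))
    expect_lt(ks_e, 0.05)
  })
})

test_that("the full fit runs without ever enumerating states", {
  withr::with_seed(41, {
    # n beyond the enumeration limit: any partition-function call would stop
    n <- 25
    E <- matrix(stats::runif(n, 0.05, 0.25), n, 1)
    d <- generate_augmented(E, rep(0, n), 200, burn_in = 80)
    ch <- fit_lowrank_ising(d, rank = 1, iterations = 60, burn_in = 20,
                            seed = 2)
    expect_s3_class(ch, "ising_chains")
    expect_equal(nrow(ch$b), 40)
    expect_true(all(ch$acceptance$b >= 0 & ch$acceptance$b <= 1))
    expect_true(all(ch$acceptance$E >= 0 & ch$acceptance$E <= 1))
    # main effects are pinned down more sharply than loadings
    expect_gt(mean(ch$acceptance$b), mean(ch$acceptance$E))
  })
  expect_error(fit_lowrank_ising(matrix(numeric(0), 0, 3), 1), "at least one")
  expect_error(fit_lowrank_ising(matrix(c(1, -1), 1), 1, iterations = 5,
                                 burn_in = 9), "burn_in")
})

test_that("fits are reproducible and summaries rotation-invariant", {
  withr::with_seed(43, {
    fx <- make_dense_lowrank(8, 1, seed = 3)
    d <- generate_augmented(ising_loadings(fx$E_true), fx$model$b, 300,
                            burn_in = 100)
    ch1 <- fit_lowrank_ising(d, rank = 1, iterations = 80, burn_in = 30,
                             seed = 9)
    ch2 <- fit_lowrank_ising(d, rank = 1, iterations = 80, burn_in = 30,
                             seed = 9)
    expect_identical(ch1$E, ch2$E)
    expect_identical(ch1$b, ch2$b)

    Ad <- connectivity_draws(ch1)
    expect_equal(dim(Ad), c(50, 8, 8))
    sm <- summary(ch1)
    expect_equal(sm$A_mean, t(sm$A_mean))
  })
})

test_that("Curie-Weiss posterior concentrates near an independent network's zero coupling", {
  withr::with_seed(45, {
    n <- 10
    d <- matrix(sample(c(-1, 1), 400 * n, replace = TRUE), 400, n)
    fit <- fit_curie_weiss(d, iterations = 1200, burn_in = 300, seed = 5)
    expect_true(all(fit$a >= 0))
    expect_lt(stats::quantile(fit$a, 0.95), 0.35)
    expect_lt(mean(fit$a), 0.2)
  })
})

test_that("warm start lands near the self-consistent latent scale", {
  withr::with_seed(47, {
    fx <- make_dense_lowrank(12, 1, seed = 21)
    d <- generate_augmented(ising_loadings(fx$E_true), fx$model$b, 800,
                            burn_in = 150)
    ws <- warm_start(d, 1)
    expect_equal(dim(ws$E), c(12, 1))
    lam_hat <- sum(ws$E^2)
    lam_true <- sum(fx$E_true^2)
    expect_gt(lam_hat, lam_true / 3)
    expect_lt(lam_hat, lam_true * 3)
  })
})
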
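test_that("linear predictor assembles term by term and shares the parent
           effect under the shared model", {
  geog <- tiny_geog()
  ds <- tiny_dataset(geog)
  zero <- parameter_state(geog)
  for (spec in list(model_spec("independent"), model_spec("shared"))) {
    for (lev in 1:2) {
      eta <- linear_predictor(zero, ds, geog, lev, spec)
      expect_equal(eta, rep(0, length(eta)))
      expect_equal(stats::plogis(eta), rep(0.5, length(eta)))
    }
  }

  # only v2 nonzero: each fine unit inherits its parent's value (shared)
  st <- parameter_state(geog, v2 = c(0.7, -0.3))
  eta_sh <- linear_predictor(st, ds, geog, 1, model_spec("shared"))
  expect_equal(eta_sh, c(0.7, -0.3)[geog$parent_index])
  expect_equal(linear_predictor(st, ds, geog, 2, model_spec("shared")),
               c(0.7, -0.3))
  # and the independent model ignores it at the fine level
  expect_equal(linear_predictor(st, ds, geog, 1, model_spec("independent")),
               rep(0, 6))

  # brute-force sum oracle on a random state
  set.seed(3)
  st <- parameter_state(geog, beta01 = rnorm(1), beta02 = rnorm(1),
                        beta11 = rnorm(1), beta12 = rnorm(1),
                        v1 = rnorm(6), v2 = rnorm(2),
                        eps1 = rnorm(6), eps2 = rnorm(2))
  spec <- model_spec("shared")
  eta1 <- linear_predictor(st, ds, geog, 1, spec)
  for (i in 1:6) {
    expect_equal(eta1[i],
                 st$beta01 + st$beta11 * ds$level1$x[i] + st$v1[i] +
                   st$eps1[i] + st$v2[geog$parent_index[i]])
  }
  eta2 <- linear_predictor(st, ds, geog, 2, spec)
  for (j in 1:2) {
    expect_equal(eta2[j],
                 st$beta02 + st$beta12 * ds$level2$x[j] + st$v2[j] +
                   st$eps2[j])
  }

  st_bad <- st; st_bad$v1 <- st$v1[-1]
  expect_error(linear_predictor(st_bad, ds, geog, 1, spec), "level 1")
})

test_that("ICAR log density: forced arithmetic and translation invariance", {
  path <- list(a = "b", b = c("a", "c"), c = "b")
  # v = (0,1,3): pairwise sum 1 + 4 = 5; sigma 1, rank N - c = 2
  expect_equal(icar_logpdf(c(0, 1, 3), path, 1), -2.5)
  # constant field: only the scale term survives
  expect_equal(icar_logpdf(rep(4, 3), path, 2), -2 * log(2))
  expect_error(icar_logpdf(c(0, 1, 3), path, 0), "positive")

  set.seed(5)
  for (rep in 1:10) {
    nb <- random_sym_graph(6, p = 0.4)
    comp <- bfs_components(nb)
    v <- rnorm(6)
    shift <- v
    for (k in unique(comp)) {
      members <- which(comp == k)
      if (length(members) >= 2) shift[members] <- shift[members] + rnorm(1)
    }
    expect_equal(icar_logpdf(shift, nb, 0.8), icar_logpdf(v, nb, 0.8),
                 tolerance = 1e-10)
  }
})

test_that("ICAR log density matches the dense pseudo-inverse Gaussian on the
           sum-to-zero subspace", {
  skip_if_not_installed("MASS")
  set.seed(8)
  for (rep in 1:10) {
    nb <- random_sym_graph(6, p = 0.5)
    if (any(vapply(nb, length, integer(1)) == 0)) next
    L <- graph_laplacian(nb)
    sigma <- runif(1, 0.3, 2)
    # centered vectors in the span of the nonzero eigenvectors
    pinvL <- MASS::ginv(L)
    prec <- MASS::ginv(sigma^2 * pinvL)  # back to L / sigma^2
    v1 <- rnorm(6); v1 <- v1 - mean(v1)
    v2 <- rnorm(6); v2 <- v2 - mean(v2)
    lhs <- icar_logpdf(v1, nb, sigma) - icar_logpdf(v2, nb, sigma)
    rhs <- -0.5 * (drop(v1 %*% prec %*% v1) - drop(v2 %*% prec %*% v2))
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("ICAR full conditional is (neighbour mean, sigma^2/degree) and
           agrees with the joint density on small graphs", {
  nb <- list(a = c("b", "c"), b = "a", c = "a")
  fc <- icar_full_conditional("a", c(0, 1, 3), nb, 2)
  expect_equal(fc$mean, 2)      # mean of neighbours (1, 3)
  expect_equal(fc$variance, 2)  # 4 / 2
  fc1 <- icar_full_conditional("b", c(7, 0, 3), nb, 1.5)
  expect_equal(fc1$mean, 7)
  expect_equal(fc1$variance, 1.5^2)

  # conditional-from-joint oracle: every graph on <= 4 nodes, sampled
  # graphs on 5 and 6 nodes, every unit including islands
  check_graph <- function(nb, v, sigma) {
    for (i in seq_along(nb)) {
      oracle <- cond_from_joint(i, v, nb, sigma)
      fc <- icar_full_conditional(i, v, nb, sigma)
      expect_lt(abs(fc$mean - oracle$mean), 1e-8)
      expect_lt(abs(fc$variance - oracle$variance), 1e-8 * fc$variance)
    }
  }
  set.seed(13)
  for (n in 2:4) {
    for (nb in all_graphs(n)) check_graph(nb, rnorm(n), runif(1, 0.5, 2))
  }
  for (n in 5:6) {
    for (rep in 1:40) {
      check_graph(random_sym_graph(n, p = 0.4), rnorm(n), runif(1, 0.5, 2))
    }
  }
})

test_that("binomial log likelihood matches the pmf and is concave in eta", {
  geog <- toy_geog()
  ds0 <- multiscale_dataset(
    data.frame(unit_id = c("a", "b"), y = 0L, n = 0L, x = c(-1, 1)), geog)
  st <- parameter_state(geog)
  expect_equal(binomial_loglik(st, ds0, geog, 1, model_spec("independent")), 0)

  ds1 <- multiscale_dataset(
    data.frame(unit_id = c("a", "b"), y = c(1L, 0L), n = c(2L, 0L),
               x = c(-1, 1)), geog)
  expect_equal(binomial_loglik(st, ds1, geog, 1, model_spec("independent")),
               log(0.5))

  set.seed(21)
  geog6 <- tiny_geog()
  ds <- tiny_dataset(geog6)
  st <- parameter_state(geog6, beta01 = rnorm(1), beta11 = rnorm(1),
                        v1 = rnorm(6), eps1 = rnorm(6))
  spec <- model_spec("independent")
  eta <- linear_predictor(st, ds, geog6, 1, spec)
  expect_equal(binomial_loglik(st, ds, geog6, 1, spec),
               sum(stats::dbinom(ds$level1$y, ds$level1$n,
                                 stats::plogis(eta), log = TRUE)))

  # concavity via second differences at random points
  ll <- function(e) sum(ds$level1$y * e - ds$level1$n * log1p(exp(e)))
  for (rep in 1:20) {
    e0 <- rnorm(6, sd = 2); h <- rnorm(6)
    second <- ll(e0 + 0.01 * h) + ll(e0 - 0.01 * h) - 2 * ll(e0)
    expect_lte(second, 1e-10)
  }
})

test_that("log posterior assembles its terms and respects the prior support", {
  geog <- tiny_geog()
  ds <- tiny_dataset(geog)
  spec <- model_spec("shared")
  st <- parameter_state(geog, sigma_v1 = spec$sd_prior_upper + 1)
  expect_identical(log_posterior(st, ds, geog, spec), -Inf)

  set.seed(31)
  st <- parameter_state(geog, beta01 = rnorm(1), beta02 = rnorm(1),
                        beta11 = rnorm(1), beta12 = rnorm(1),
                        v1 = rnorm(6), v2 = rnorm(2),
                        eps1 = rnorm(6), eps2 = rnorm(2),
                        sigma_v1 = 0.7, sigma_v2 = 1.2,
                        sigma_eps1 = 0.4, sigma_eps2 = 0.9)
  manual <- binomial_loglik(st, ds, geog, 1, spec) +
    binomial_loglik(st, ds, geog, 2, spec) +
    icar_logpdf(st$v1, geog$fine_adjacency, st$sigma_v1) +
    icar_logpdf(st$v2, geog$coarse_adjacency, st$sigma_v2) +
    sum(stats::dnorm(st$eps1, 0, st$sigma_eps1, log = TRUE)) +
    sum(stats::dnorm(st$eps2, 0, st$sigma_eps2, log = TRUE)) +
    stats::dnorm(st$beta11, 0, spec$slope_prior_sd, log = TRUE) +
    stats::dnorm(st$beta12, 0, spec$slope_prior_sd, log = TRUE)
  expect_equal(log_posterior(st, ds, geog, spec), manual)

  # with v2 = 0 the sharing term vanishes: both models agree
  st$v2 <- c(0, 0)
  expect_equal(log_posterior(st, ds, geog, model_spec("shared")),
               log_posterior(st, ds, geog, model_spec("independent")))

  # recentring v into the intercept leaves the log posterior unchanged
  st2 <- st
  m <- mean(st2$v1)
  st2$v1 <- st2$v1 - m
  st2$beta01 <- st2$beta01 + m
  expect_equal(log_posterior(st2, ds, geog, spec),
               log_posterior(st, ds, geog, spec), tolerance = 1e-10)
})

test_that("covariate standardization uses the sample sd and rejects
           degenerate input", {
  s <- standardize_covariate(c(1, 2, 3))
  expect_equal(s$x, c(-1, 0, 1))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  set.seed(41)
  z <- standardize_covariate(rnorm(50, 40, 10))
  expect_equal(mean(z$x), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$x), 1, tolerance = 1e-12)
  expect_error(standardize_covariate(rep(5, 10)), "degenerate")
  expect_error(standardize_covariate(3), "at least 2")
})
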
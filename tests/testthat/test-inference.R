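test_that("intercept-only reduction recovers the pooled empirical logit", {
  geog <- toy_geog()
  ds <- toy_dataset(y = c(410, 380), n = c(5000, 4600))
  fit <- run_mcmc(ds, geog, model_spec("independent"),
                  mcmc_config(n_chains = 1, n_iter = 12000, burn_in = 2000,
                              seed = 2),
                  update = list(v = FALSE, eps = FALSE, sigma = FALSE,
                                slope = FALSE))
  b <- fit$chains[[1]][, "beta01"]
  mle <- stats::qlogis(sum(ds$level1$y) / sum(ds$level1$n))
  expect_equal(mean(b), mle, tolerance = 0.01)
})

test_that("fixed seed reproduces every draw bit for bit", {
  geog <- make_lattice_geography(4, 4, 2, 2)
  ds <- simulate_dataset(geog, simulation_truth(trials_mean = 50), seed = 9)
  cfg <- mcmc_config(n_chains = 2, n_iter = 400, burn_in = 200, seed = 77)
  f1 <- run_mcmc(ds, geog, model_spec("shared"), cfg)
  f2 <- run_mcmc(ds, geog, model_spec("shared"), cfg)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$deviance, f2$deviance)
  cfg2 <- cfg; cfg2$seed <- 78L
  f3 <- run_mcmc(ds, geog, model_spec("shared"), cfg2)
  expect_false(identical(f1$chains[[1]], f3$chains[[1]]))
})

test_that("run with n_iter = burn_in keeps provenance but no draws", {
  geog <- toy_geog()
  ds <- toy_dataset()
  fit <- run_mcmc(ds, geog, model_spec("independent"),
                  mcmc_config(n_chains = 1, n_iter = 50, burn_in = 50,
                              seed = 1))
  expect_identical(nrow(fit$chains[[1]]), 0L)
  expect_identical(fit$config$seed, 1L)
  expect_error(posterior_summary(fit), "empty retained sample")
})

test_that("stored spatial-effect draws honour the centering constraint", {
  geog <- make_lattice_geography(4, 4, 2, 2)
  ds <- simulate_dataset(geog, simulation_truth(trials_mean = 100), seed = 5)
  fit <- run_mcmc(ds, geog, model_spec("shared"),
                  mcmc_config(n_chains = 1, n_iter = 500, burn_in = 250,
                              seed = 3))
  d <- fit$chains[[1]]
  v1 <- d[, grep("^v1\\[", colnames(d)), drop = FALSE]
  v2 <- d[, grep("^v2\\[", colnames(d)), drop = FALSE]
  expect_lt(max(abs(rowMeans(v1))), 1e-10)
  expect_lt(max(abs(rowMeans(v2))), 1e-10)
})

test_that("adapted proposal blocks end near their acceptance targets", {
  geog <- make_lattice_geography(8, 8, 4, 4)
  ds <- simulate_dataset(geog, simulation_truth(trials_mean = 300), seed = 6)
  fit <- run_mcmc(ds, geog, model_spec("shared"),
                  mcmc_config(n_chains = 1, n_iter = 2000, burn_in = 1000,
                              seed = 8))
  acc <- fit$acceptance[[1]]
  for (blk in c("eps1", "eps2", "beta1", "beta2", "sigma")) {
    expect_gt(acc[[blk]], 0.1)
    expect_lt(acc[[blk]], 0.7)
  }
})

test_that("Gelman-Rubin factor behaves on known chain configurations", {
  geog <- toy_geog()
  spec <- model_spec("independent")
  make <- function(chains) {
    multiscaleCAR:::new_posterior_samples(
      chains = chains, deviance = list(), config = mcmc_config(seed = 1),
      spec = spec,
      geog_info = list(n_fine = 2, n_coarse = 2, fine_ids = geog$fine_ids,
                       coarse_ids = geog$coarse_ids),
      acceptance = list(), data_std = NULL)
  }
  cols <- multiscaleCAR:::hyper_params()
  mk_chain <- function(vals) {
    m <- matrix(vals, nrow = length(vals), ncol = 8)
    colnames(m) <- cols
    m
  }

  set.seed(12)
  iid <- make(lapply(1:3, function(i) mk_chain(rnorm(5000))))
  r <- gelman_rubin(iid)
  expect_true(all(r > 0.99 & r < 1.01))

  flat <- make(list(mk_chain(rep(1, 100)), mk_chain(rep(2, 100))))
  expect_true(all(is.infinite(gelman_rubin(flat))))

  sep <- make(list(mk_chain(rnorm(2000)), mk_chain(rnorm(2000, mean = 5))))
  expect_true(all(gelman_rubin(sep) > 1.1))

  one <- make(list(mk_chain(rnorm(100))))
  expect_error(gelman_rubin(one), "at least 2 chains")
})

test_that("posterior summary matches a sort-based percentile oracle", {
  geog <- toy_geog()
  spec <- model_spec("independent")
  draws <- matrix(0, nrow = 100, ncol = 8 + 2 * (2 + 2))
  draws[, 1] <- 1:100
  draws[, 2] <- 7  # constant parameter
  s <- manual_samples(draws, geog, spec)
  out <- posterior_summary(s, c("beta01", "beta02"))

  # independent type-7 interpolation arithmetic on the sorted 1..100
  q7 <- function(sorted, p) {
    h <- (length(sorted) - 1) * p + 1
    lo <- floor(h)
    sorted[lo] + (h - lo) * (sorted[min(lo + 1, length(sorted))] - sorted[lo])
  }
  expect_equal(out$mean[1], mean(1:100))
  expect_equal(out$q2.5[1], q7(1:100, 0.025))
  expect_equal(out$q97.5[1], q7(1:100, 0.975))
  expect_equal(out$mean[2], 7)
  expect_equal(out$sd[2], 0)
  expect_equal(out$q2.5[2], 7)
  expect_equal(out$q97.5[2], 7)

  expect_error(posterior_summary(s, "beta99"), "unknown parameter")
})

test_that("fit on simulated data reports a self-consistent slope summary", {
  geog <- make_lattice_geography(6, 6, 3, 3)
  ds <- simulate_dataset(geog, simulation_truth(trials_mean = 400), seed = 14)
  fit <- run_mcmc(ds, geog, model_spec("shared"),
                  mcmc_config(n_chains = 2, n_iter = 1200, burn_in = 600,
                              seed = 15))
  s <- posterior_summary(fit, "beta11")
  expect_true(s$q2.5 <= s$mean && s$mean <= s$q97.5)
  pool <- do.call(rbind, fit$chains)[, "beta11"]
  expect_equal(s$mean, mean(pool))
})
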
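test_that("odds-ratio back-transformation reproduces the worked examples", {
  county <- odds_ratio_per_unit(-0.09, 10.659)
  expect_equal(county$transformed_rounded, -0.008)
  expect_equal(county$odds_ratio_rounded, 0.992)
  expect_equal(percent_change(county$odds_ratio_rounded), 0.8)

  district <- odds_ratio_per_unit(-0.06, 8.264)
  expect_equal(district$odds_ratio_rounded, 0.993)
  expect_equal(percent_change(district$odds_ratio_rounded), 0.7)

  null <- odds_ratio_per_unit(0, 5)
  expect_equal(null$odds_ratio, 1)
  expect_equal(percent_change(1), 0)

  expect_error(odds_ratio_per_unit(-0.1, 0), "positive")
  expect_error(odds_ratio_per_unit(-0.1, -2), "positive")
  expect_error(percent_change(-1), "positive")
})

test_that("risk surface: all-zero draws give 0.5 everywhere with ordered,
           in-range intervals", {
  geog <- tiny_geog()
  ds <- tiny_dataset(geog)
  spec <- model_spec("shared")
  npar <- 8 + 2 * (6 + 2)
  s0 <- manual_samples(matrix(0, 30, npar), geog, spec)
  surf <- risk_surface(s0, ds, geog, spec)
  expect_equal(surf$post_mean_p, rep(0.5, 8))
  expect_equal(nrow(surf), 8)

  set.seed(9)
  draws <- matrix(rnorm(50 * npar, sd = 0.3), 50, npar)
  s <- manual_samples(draws, geog, spec)
  surf <- risk_surface(s, ds, geog, spec)
  expect_true(all(surf$post_mean_p > 0 & surf$post_mean_p < 1))
  expect_true(all(surf$q2.5 <= surf$post_mean_p))
  expect_true(all(surf$post_mean_p <= surf$q97.5))
})

test_that("surface roughness sums squared differences over unique edges", {
  path <- list(a = "b", b = c("a", "c"), c = "b")
  expect_equal(surface_roughness(c(0, 1, 3), path), 1 + 4)
  expect_equal(surface_roughness(rep(2, 3), path), 0)
})

test_that("the odds-ratio table is the back-transform of the posterior-mean
           slope with the stored standardization record", {
  geog <- tiny_geog()
  spec <- model_spec("shared")
  npar <- 8 + 2 * (6 + 2)
  set.seed(10)
  draws <- matrix(0, 200, npar)
  draws[, 3] <- rnorm(200, -0.09, 0.02)  # beta11
  draws[, 4] <- rnorm(200, -0.06, 0.03)  # beta12
  s <- manual_samples(draws, geog, spec,
                      std = list(level1 = list(mean = 40, sd = 10.659),
                                 level2 = list(mean = 40, sd = 8.264)))
  tab <- odds_ratio_table(s)
  expect_equal(tab$odds_ratio[1],
               round(exp(mean(draws[, 3]) / 10.659), 3))
  expect_equal(tab$odds_ratio[2],
               round(exp(mean(draws[, 4]) / 8.264), 3))
  expect_equal(tab$pct_change, percent_change(tab$odds_ratio))
})

test_that("CLI pipeline: simulate, fit, assess, report round trip", {
  out <- withr::local_tempdir()
  cfg_file <- file.path(out, "config.yaml")
  writeLines(c(
    "simulate:",
    "  n_rows: 4",
    "  n_cols: 4",
    "  block_rows: 2",
    "  block_cols: 2",
    "  truth:",
    "    trials_mean: 80",
    "mcmc:",
    "  n_chains: 2",
    "  n_iter: 400",
    "  burn_in: 200"
  ), cfg_file)

  expect_identical(suppressMessages(cli_main(
    c("simulate", "--config", cfg_file, "--seed", "3", "--out", out))), 0L)
  for (f in c("fine.csv", "coarse.csv", "fine.gal", "coarse.gal",
              "nesting.csv", "truth.json")) {
    expect_true(file.exists(file.path(out, f)))
  }
  # the emitted files reconstruct a valid geography/dataset
  geog <- multiscale_geography(
    read_adjacency(file.path(out, "fine.gal"), "gal"),
    read_adjacency(file.path(out, "coarse.gal"), "gal"),
    read_nesting(file.path(out, "nesting.csv")))
  expect_length(validate_geography(geog)$violations, 0)
  ds <- read_dataset(file.path(out, "fine.csv"), geog,
                     file.path(out, "coarse.csv"))
  expect_equal(sum(ds$level2$y), sum(ds$level1$y))

  for (model in c("shared", "independent")) {
    expect_identical(suppressMessages(cli_main(
      c("fit", "--config", cfg_file, "--seed", "3", "--model", model,
        "--out", out))), 0L)
    expect_true(file.exists(file.path(out, paste0("fit_", model, ".rds"))))
    expect_true(file.exists(
      file.path(out, paste0("convergence_", model, ".csv"))))
  }
  expect_identical(suppressMessages(cli_main(
    c("assess", "--config", cfg_file, "--seed", "3", "--out", out))), 0L)
  expect_true(file.exists(file.path(out, "assessment.csv")))
  expect_true(file.exists(file.path(out, "comparison.csv")))

  expect_identical(suppressMessages(cli_main(
    c("report", "--config", cfg_file, "--seed", "3", "--model", "shared",
      "--out", out))), 0L)
  or_tab <- utils::read.csv(file.path(out, "odds_ratio_shared.csv"),
                            comment.char = "#")
  fb <- readRDS(file.path(out, "fit_shared.rds"))
  expect_equal(
    or_tab$odds_ratio[1],
    round(exp(mean(do.call(rbind, fb$samples$chains)[, "beta11"]) /
                fb$samples$standardization$level1$sd), 3))
  # outputs carry the seed in their header comment
  expect_match(readLines(file.path(out, "assessment.csv"), n = 1), "seed=3")
})

test_that("CLI failure modes exit with status 2", {
  out <- withr::local_tempdir()
  cfg_file <- file.path(out, "bad.yaml")
  writeLines(c(
    "simulate:",
    "  n_rows: 4",
    "  n_cols: 4",
    "  block_rows: 2",
    "  block_cols: 2",
    "mcmc:",
    "  n_chains: 1",
    "  n_iter: 100",
    "  burn_in: 100"
  ), cfg_file)
  expect_identical(suppressMessages(cli_main(
    c("fit", "--config", cfg_file, "--seed", "1", "--out", out))), 2L)

  expect_identical(suppressMessages(cli_main(c("frobnicate"))), 2L)
  expect_identical(suppressMessages(cli_main(
    c("fit", "--config", "/nonexistent.yaml"))), 2L)
  expect_identical(suppressMessages(cli_main(
    c("report", "--config", cfg_file, "--seed", "1", "--out",
      file.path(out, "empty")))), 2L)
})
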
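#' Nested lattice geography
#'
#' Builds a rectangular grid of fine units with rook adjacency, partitioned
#' into rectangular blocks that form the coarse level; coarse adjacency is
#' rook adjacency of the block grid (equivalently, blocks sharing a fine
#' edge). A desk-scale stand-in for a county-in-district map.
#'
#' @param n_rows,n_cols Grid dimensions (fine units = `n_rows * n_cols`).
#' @param block_rows,block_cols Block dimensions; must divide the grid
#'   dimensions.
#' @return A `multiscale_geography`; fine units carry a `coords` attribute
#'   (row/column) used by the covariate gradient option of
#'   [simulate_dataset()].
#' @export
make_lattice_geography <- function(n_rows, n_cols, block_rows, block_cols) {
  if (n_rows %% block_rows != 0L || n_cols %% block_cols != 0L) {
    stop("block dimensions must divide the grid dimensions", call. = FALSE)
  }
  n1 <- n_rows * n_cols
  fine_ids <- sprintf("c%03d", seq_len(n1))
  cell_row <- rep(seq_len(n_rows), each = n_cols)
  cell_col <- rep(seq_len(n_cols), times = n_rows)
  fine_adj <- lattice_adjacency(cell_row, cell_col, fine_ids)

  br <- (cell_row - 1L) %/% block_rows
  bc <- (cell_col - 1L) %/% block_cols
  nbc <- n_cols %/% block_cols
  block_of <- br * nbc + bc + 1L
  n2 <- (n_rows %/% block_rows) * nbc
  coarse_ids <- sprintf("d%02d", seq_len(n2))
  blk_row <- (seq_len(n2) - 1L) %/% nbc + 1L
  blk_col <- (seq_len(n2) - 1L) %% nbc + 1L
  coarse_adj <- lattice_adjacency(blk_row, blk_col, coarse_ids)

  parent <- stats::setNames(coarse_ids[block_of], fine_ids)
  geog <- multiscale_geography(fine_adj, coarse_adj, parent)
  attr(geog, "coords") <- data.frame(row = cell_row, col = cell_col)
  geog
}

# rook adjacency from integer coordinates
lattice_adjacency <- function(rows, cols, ids) {
  key <- paste(rows, cols)
  idx <- stats::setNames(seq_along(ids), key)
  nb <- lapply(seq_along(ids), function(i) {
    cand <- c(paste(rows[i] - 1L, cols[i]), paste(rows[i] + 1L, cols[i]),
              paste(rows[i], cols[i] - 1L), paste(rows[i], cols[i] + 1L))
    ids[idx[cand[cand %in% names(idx)]]]
  })
  stats::setNames(nb, ids)
}

#' Synthetic irregular two-level geography at the Georgia scale
#'
#' A deterministic synthetic stand-in for the Georgia county/public-health
#' district map: 159 fine units nested in 18 coarse units (about nine
#' children per parent). The fine graph is a 13 x 13 rook lattice with the
#' last 10 cells of its boustrophedon (snake) ordering removed, leaving a
#' connected planar graph of 159 cells; coarse units are 18 contiguous runs
#' of the snake ordering (fifteen of size 9, three of size 8), and coarse
#' adjacency is induced by cross-district fine edges. It reproduces the
#' scale and nesting arithmetic of the real map, not its shape.
#'
#' @return A `multiscale_geography` with 159 fine and 18 coarse units.
#' @export
make_georgia_like_geography <- function() {
  side <- 13L
  # snake order over the full grid, then keep the first 159 cells
  order_idx <- unlist(lapply(seq_len(side), function(r) {
    cols <- if (r %% 2L == 1L) seq_len(side) else rev(seq_len(side))
    (r - 1L) * side + cols
  }))
  keep <- order_idx[seq_len(159L)]
  cell_row <- (keep - 1L) %/% side + 1L
  cell_col <- (keep - 1L) %% side + 1L
  fine_ids <- sprintf("c%03d", seq_len(159L))
  fine_adj <- lattice_adjacency(cell_row, cell_col, fine_ids)

  sizes <- c(rep(9L, 15L), rep(8L, 3L))
  parent_idx <- rep(seq_len(18L), times = sizes)
  coarse_ids <- sprintf("d%02d", seq_len(18L))
  parent <- stats::setNames(coarse_ids[parent_idx], fine_ids)
  coarse_adj <- induced_coarse_adjacency(fine_adj, parent, coarse_ids)
  geog <- multiscale_geography(fine_adj, coarse_adj, parent)
  attr(geog, "coords") <- data.frame(row = cell_row, col = cell_col)
  geog
}

# coarse units are adjacent iff some cross-unit fine edge links them
induced_coarse_adjacency <- function(fine_adj, parent, coarse_ids) {
  nb <- stats::setNames(rep(list(character(0)), length(coarse_ids)),
                        coarse_ids)
  for (i in names(fine_adj)) {
    pi <- parent[[i]]
    for (j in fine_adj[[i]]) {
      pj <- parent[[j]]
      if (pi != pj) nb[[pi]] <- union(nb[[pi]], pj)
    }
  }
  nb
}

#' Draw from the intrinsic CAR prior
#'
#' Samples the improper ICAR field restricted to the sum-to-zero subspace of
#' each connected component: with graph Laplacian `L = D - W`, the draw is
#' the degenerate Gaussian with covariance `sigma_v^2 * pinv(L)`, built from
#' the eigendecomposition of each component's Laplacian (eigenvectors with
#' nonzero eigenvalue, scaled by `1/sqrt(lambda)`). The result sums to zero
#' within every component; islands are set to zero.
#'
#' @param adjacency Named list of neighbour id vectors.
#' @param sigma_v Positive standard deviation.
#' @return Numeric vector in adjacency order.
#' @export
sample_icar <- function(adjacency, sigma_v) {
  if (sigma_v <= 0) stop("sigma_v must be positive", call. = FALSE)
  ids <- names(adjacency)
  comp <- adjacency_components(adjacency)
  v <- stats::setNames(numeric(length(ids)), ids)
  for (cm in unique(comp)) {
    members <- ids[comp == cm]
    m <- length(members)
    if (m < 2L) next
    W <- matrix(0, m, m, dimnames = list(members, members))
    for (i in members) W[i, intersect(adjacency[[i]], members)] <- 1
    L <- diag(rowSums(W)) - W
    eg <- eigen(L, symmetric = TRUE)
    pos <- eg$values > 1e-9 * max(eg$values)
    z <- stats::rnorm(sum(pos)) / sqrt(eg$values[pos])
    v[members] <- sigma_v * as.vector(eg$vectors[, pos, drop = FALSE] %*% z)
  }
  unname(v)
}

#' Ground truth for a simulation
#'
#' Fixes the data-generating conditions: regression coefficients on the
#' standardized-covariate scale, random-effect standard deviations at both
#' levels, the trials-per-unit distribution, the raw covariate distribution
#' (median household income in thousands of dollars), and which model
#' generates the fine-level risks. Defaults give a baseline risk of about
#' 8% (log-odds -2.2, the low-birth-weight ballpark), a modest negative
#' income effect, and field standard deviations matching the shared-model
#' fit to the Georgia data (small extra fine-level variation on top of a
#' dominant district-level spatial field).
#'
#' @param beta01,beta02 Intercepts (default -2.2 each).
#' @param beta11,beta12 Slopes per SD of the standardized covariate
#'   (default -0.1 fine, -0.06 coarse).
#' @param sigma_v1,sigma_eps1 Fine-level CH and UH standard deviations
#'   (default 0.06, 0.12).
#' @param sigma_v2,sigma_eps2 Coarse-level CH and UH standard deviations
#'   (default 0.32, 0.04).
#' @param trials_mean Mean trials (births) per fine unit (default 500).
#' @param trials_dist `"poisson"` (default) or `"constant"`.
#' @param x_mean,x_sd Raw covariate mean and SD (default 40 and 10, in
#'   thousands of dollars).
#' @param x_gradient Optional smooth west-east covariate gradient per
#'   column of the lattice, in raw units (default 0).
#' @param model_kind Generating model, `"shared"` (default) or
#'   `"independent"`.
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(beta01 = -2.2, beta02 = -2.2, beta11 = -0.1,
                             beta12 = -0.06, sigma_v1 = 0.06, sigma_eps1 = 0.12,
                             sigma_v2 = 0.32, sigma_eps2 = 0.04,
                             trials_mean = 500,
                             trials_dist = c("poisson", "constant"),
                             x_mean = 40, x_sd = 10, x_gradient = 0,
                             model_kind = c("shared", "independent")) {
  structure(
    list(beta01 = beta01, beta02 = beta02, beta11 = beta11, beta12 = beta12,
         sigma_v1 = sigma_v1, sigma_eps1 = sigma_eps1, sigma_v2 = sigma_v2,
         sigma_eps2 = sigma_eps2, trials_mean = trials_mean,
         trials_dist = match.arg(trials_dist), x_mean = x_mean, x_sd = x_sd,
         x_gradient = x_gradient, model_kind = match.arg(model_kind)),
    class = "simulation_truth"
  )
}

#' Simulate an aggregation-consistent two-level dataset
#'
#' Generates fine-level data from the chosen model and produces the coarse
#' level the way nested administrative data arise: coarse outcomes and
#' trials are sums over each coarse unit's children and the coarse covariate
#' is the mean, so the coarse-level model is (as with real aggregated data)
#' an approximating model. Fine covariates are Normal with an optional
#' smooth spatial gradient; spatial effects are ICAR draws at the truth's
#' standard deviations; exchangeable effects are iid Normal (uncentred -
#' centring is an inferential device, not part of the generative process);
#' fine outcomes are Binomial with logit risk from [linear_predictor()].
#'
#' @param geog A `multiscale_geography`.
#' @param truth A `simulation_truth`.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   datasets.
#' @return A `multiscale_dataset` with attribute `truth`: the generating
#'   `parameter_state`, the drawn random effects, `model_kind` and `seed`.
#' @export
simulate_dataset <- function(geog, truth = simulation_truth(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n1 <- length(geog$fine_ids)
  x1_raw <- stats::rnorm(n1, truth$x_mean, truth$x_sd)
  coords <- attr(geog, "coords")
  if (truth$x_gradient != 0 && !is.null(coords)) {
    x1_raw <- x1_raw + truth$x_gradient * (coords$col - mean(coords$col))
  }
  n_trials <- switch(truth$trials_dist,
    poisson = pmax(1L, stats::rpois(n1, truth$trials_mean)),
    constant = rep(as.integer(truth$trials_mean), n1)
  )
  v1 <- sample_icar(geog$fine_adjacency, truth$sigma_v1)
  v2 <- sample_icar(geog$coarse_adjacency, truth$sigma_v2)
  eps1 <- stats::rnorm(n1, 0, truth$sigma_eps1)
  eps2 <- stats::rnorm(length(geog$coarse_ids), 0, truth$sigma_eps2)
  state <- parameter_state(
    geog, beta01 = truth$beta01, beta02 = truth$beta02,
    beta11 = truth$beta11, beta12 = truth$beta12,
    v1 = v1, v2 = v2, eps1 = eps1, eps2 = eps2,
    sigma_v1 = truth$sigma_v1, sigma_v2 = truth$sigma_v2,
    sigma_eps1 = truth$sigma_eps1, sigma_eps2 = truth$sigma_eps2)
  spec <- model_spec(truth$model_kind)

  # dataset shell (y = 0) to evaluate the predictor on standardized x
  shell <- multiscale_dataset(
    data.frame(unit_id = geog$fine_ids, y = 0L, n = n_trials, x = x1_raw,
               stringsAsFactors = FALSE), geog)
  eta1 <- linear_predictor(state, shell, geog, 1, spec)
  y1 <- stats::rbinom(n1, n_trials, stats::plogis(eta1))
  ds <- multiscale_dataset(
    data.frame(unit_id = geog$fine_ids, y = y1, n = n_trials, x = x1_raw,
               stringsAsFactors = FALSE), geog)
  attr(ds, "truth") <- list(state = state, truth = truth,
                            model_kind = truth$model_kind, seed = seed)
  ds
}

#' Parameter-recovery and model-selection experiment
#'
#' Repeatedly simulates data under the shared model at desk scale, fits both
#' the shared and independent models, and scores: bias and 95% interval
#' coverage of the intercepts, slopes and standard deviations; the maximum
#' Gelman-Rubin factor over the hyperparameters; which model is preferred
#' by fine-level DIC and MSPE; and the spatial roughness of each model's
#' fine-level risk surface (the shared model's smoothing effect).
#'
#' @param n_replicates Number of simulate-and-fit replicates (default 20).
#' @param geog Geography (default: 12 x 12 lattice in 9 blocks of 4 x 4).
#' @param truth A `simulation_truth` (default: shared model,
#'   `beta11 = -0.1`, about 500 trials per unit).
#' @param config An `mcmc_config` for each fit (default 3 chains x 3000
#'   iterations, 1500 burn-in).
#' @param seed Master seed; all replicate seeds derive from it.
#' @return A `recovery_report`: per-replicate results data frame plus
#'   aggregate coverage rates and preference frequencies.
#' @export
recovery_experiment <- function(n_replicates = 20,
                                geog = make_lattice_geography(12, 12, 4, 4),
                                truth = simulation_truth(),
                                config = mcmc_config(n_chains = 3,
                                                     n_iter = 3000,
                                                     burn_in = 1500),
                                seed = 1) {
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 4L * n_replicates), ncol = 4L)
  tracked <- c("beta01", "beta11", "beta12", "sigma_v1", "sigma_eps1",
               "sigma_v2", "sigma_eps2")
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    ds <- simulate_dataset(geog, truth, seed = rep_seeds[r, 1L])
    cfg_sh <- config; cfg_sh$seed <- rep_seeds[r, 2L]
    cfg_in <- config; cfg_in$seed <- rep_seeds[r, 3L]
    fit_sh <- run_mcmc(ds, geog, model_spec("shared"), cfg_sh)
    fit_in <- run_mcmc(ds, geog, model_spec("independent"), cfg_in)
    summ <- posterior_summary(fit_sh, tracked)
    rhat <- suppressWarnings(gelman_rubin(fit_sh))
    rep_sh <- assess_model(fit_sh, ds, geog, model_spec("shared"),
                           seed = rep_seeds[r, 4L])
    rep_in <- assess_model(fit_in, ds, geog, model_spec("independent"),
                           seed = rep_seeds[r, 4L])
    surf_sh <- risk_surface(fit_sh, ds, geog, model_spec("shared"))
    surf_in <- risk_surface(fit_in, ds, geog, model_spec("independent"))
    p_sh <- surf_sh$post_mean_p[surf_sh$level == 1]
    p_in <- surf_in$post_mean_p[surf_in$level == 1]
    row <- data.frame(replicate = r, stringsAsFactors = FALSE)
    for (p in tracked) {
      s <- summ[summ$parameter == p, ]
      tv <- truth[[p]]
      row[[paste0(p, "_est")]] <- s$mean
      row[[paste0(p, "_bias")]] <- s$mean - tv
      row[[paste0(p, "_cover")]] <- s$q2.5 <= tv && tv <= s$q97.5
    }
    row$rhat_max <- max(rhat)
    row$dic1_shared <- rep_sh$level1$DIC
    row$dic1_independent <- rep_in$level1$DIC
    row$dic2_shared <- rep_sh$level2$DIC
    row$dic2_independent <- rep_in$level2$DIC
    row$mspe1_shared <- rep_sh$level1$MSPE
    row$mspe1_independent <- rep_in$level1$MSPE
    row$mspe2_shared <- rep_sh$level2$MSPE
    row$mspe2_independent <- rep_in$level2$MSPE
    row$roughness_shared <- surface_roughness(p_sh, geog$fine_adjacency)
    row$roughness_independent <- surface_roughness(p_in, geog$fine_adjacency)
    rows[[r]] <- row
  }
  results <- do.call(rbind, rows)
  structure(
    list(
      results = results,
      truth = truth,
      coverage = vapply(tracked, function(p) {
        mean(results[[paste0(p, "_cover")]])
      }, numeric(1)),
      dic_pref_shared = mean(results$dic1_shared < results$dic1_independent),
      mspe_pref_shared = mean(results$mspe1_shared < results$mspe1_independent),
      smoother_shared = mean(results$roughness_shared <=
                               results$roughness_independent),
      rhat_max = max(results$rhat_max),
      n_replicates = n_replicates,
      seed = seed
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: %d replicates (seed %d)\n",
              x$n_replicates, x$seed))
  cat("  95% CI coverage:",
      paste(sprintf("%s=%.2f", names(x$coverage), x$coverage),
            collapse = " "), "\n")
  cat(sprintf("  shared preferred by fine-level DIC: %.0f%%, by MSPE: %.0f%%\n",
              100 * x$dic_pref_shared, 100 * x$mspe_pref_shared))
  cat(sprintf("  max Rhat over replicates: %.3f\n", x$rhat_max))
  invisible(x)
}
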
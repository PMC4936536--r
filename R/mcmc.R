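#' MCMC run configuration
#'
#' Defaults follow the study protocol: three chains of 30,000 iterations
#' each, the first 15,000 discarded as burn-in and no thinning, so that
#' posterior summaries rest on 45,000 retained draws.
#'
#' @param n_chains Number of chains (default 3).
#' @param n_iter Iterations per chain (default 30000).
#' @param burn_in Burn-in iterations discarded per chain (default 15000).
#' @param thin Thinning interval (default 1).
#' @param seed Integer seed governing all randomness of the run.
#' @param adapt_target_site Acceptance-rate target for single-site updates
#'   (default 0.44).
#' @param adapt_target_block Acceptance-rate target for block updates
#'   (default 0.234).
#' @param adapt_window Number of burn-in iterations during which proposal
#'   scales adapt (Robbins-Monro); frozen afterwards. Defaults to the whole
#'   burn-in.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 30000, burn_in = 15000,
                        thin = 1, seed = 1, adapt_target_site = 0.44,
                        adapt_target_block = 0.234, adapt_window = burn_in) {
  stopifnot(n_chains >= 1, thin >= 1, n_iter >= 1, burn_in >= 0)
  if (burn_in > n_iter) {
    stop("burn_in must not exceed n_iter", call. = FALSE)
  }
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         burn_in = as.integer(burn_in), thin = as.integer(thin),
         seed = as.integer(seed), adapt_target_site = adapt_target_site,
         adapt_target_block = adapt_target_block,
         adapt_window = as.integer(adapt_window)),
    class = "mcmc_config"
  )
}

param_names <- function(geog) {
  c("beta01", "beta02", "beta11", "beta12",
    "sigma_v1", "sigma_v2", "sigma_eps1", "sigma_eps2",
    paste0("v1[", geog$fine_ids, "]"),
    paste0("v2[", geog$coarse_ids, "]"),
    paste0("eps1[", geog$fine_ids, "]"),
    paste0("eps2[", geog$coarse_ids, "]"))
}

hyper_params <- function() {
  c("beta01", "beta02", "beta11", "beta12",
    "sigma_v1", "sigma_v2", "sigma_eps1", "sigma_eps2")
}

adjacency_csr <- function(nb) {
  ids <- names(nb)
  idx <- integer(0)
  ptr <- integer(length(ids) + 1L)
  for (i in seq_along(ids)) {
    nbrs <- match(nb[[i]], ids) - 1L
    idx <- c(idx, nbrs)
    ptr[i + 1L] <- ptr[i] + length(nbrs)
  }
  list(idx = as.integer(idx), ptr = as.integer(ptr))
}

new_posterior_samples <- function(chains, deviance, config, spec, geog_info,
                                  acceptance, data_std) {
  structure(
    list(chains = chains, deviance = deviance, config = config, spec = spec,
         geog_info = geog_info, acceptance = acceptance,
         standardization = data_std),
    class = "posterior_samples"
  )
}

#' Sample the posterior by Metropolis-within-Gibbs
#'
#' One sweep updates, in order: every spatial effect `v_ik` by single-site
#' Metropolis with an independence proposal drawn from its ICAR full
#' conditional (so the acceptance ratio reduces to the binomial likelihood
#' ratio); every exchangeable effect `eps_ik` by single-site random-walk
#' Metropolis; the intercept and slope jointly per level by random-walk
#' Metropolis; each standard deviation by random walk on the log scale with
#' rejection outside the uniform prior support; and finally a recentring
#' move that shifts each `v_k` to mean zero while absorbing the shift into
#' the intercept(s), which is posterior-invariant because the improper ICAR
#' density is translation-invariant (skipped at a level whose graph has
#' islands). Proposal scales adapt toward the configured acceptance targets
#' during burn-in only. Chains start from beta = 0 jittered with
#' Normal(0, 1) per chain, `v = eps = 0`, `sigma = 1`, unless `init`
#' overrides. Identical seeds give bit-identical draws.
#'
#' @param data A `multiscale_dataset`.
#' @param geog A `multiscale_geography`.
#' @param spec A `model_spec`.
#' @param config An `mcmc_config`.
#' @param update Named list of logical flags to freeze parameter blocks
#'   (used for reductions and oracle tests): `v`, `eps`, `beta`, `slope`,
#'   `sigma`; all `TRUE` by default.
#' @param init Optional `parameter_state` overriding the default initial
#'   values (the per-chain jitter is still applied to free intercepts and
#'   slopes when `n_chains > 1`).
#' @return An object of class `posterior_samples`: retained draws per chain
#'   (matrix iteration x parameter), per-iteration deviance per level,
#'   acceptance rates, and the config/seed provenance.
#' @export
run_mcmc <- function(data, geog, spec, config = mcmc_config(),
                     update = list(), init = NULL) {
  val <- validate_geography(geog)
  if (length(val$violations)) {
    stop("invalid geography: ", paste(val$violations, collapse = "; "),
         call. = FALSE)
  }
  up <- utils::modifyList(
    list(v = TRUE, eps = TRUE, beta = TRUE, slope = TRUE, sigma = TRUE),
    update)

  d1 <- data$level1; d2 <- data$level2
  if (length(d1$y) != length(geog$fine_ids) ||
      length(d2$y) != length(geog$coarse_ids)) {
    stop("dataset dimensions do not match the geography", call. = FALSE)
  }

  csr1 <- adjacency_csr(geog$fine_adjacency)
  csr2 <- adjacency_csr(geog$coarse_adjacency)
  rank1 <- length(geog$fine_ids) - n_nonisland_components(geog$fine_adjacency)
  rank2 <- length(geog$coarse_ids) -
    n_nonisland_components(geog$coarse_adjacency)
  recenter1 <- up$v && length(attr(geog$fine_adjacency, "islands")) == 0L
  recenter2 <- up$v && length(attr(geog$coarse_adjacency, "islands")) == 0L
  flags <- list(v = up$v, eps = up$eps, beta = up$beta, slope = up$slope,
                sigma = up$sigma, recenter1 = recenter1, recenter2 = recenter2)

  base_init <- if (is.null(init)) parameter_state(geog) else init

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  jitter <- matrix(stats::rnorm(4L * config$n_chains), nrow = config$n_chains)

  lc1 <- sum(lchoose(d1$n, d1$y))
  lc2 <- sum(lchoose(d2$n, d2$y))
  pn <- param_names(geog)

  chains <- vector("list", config$n_chains)
  devs <- vector("list", config$n_chains)
  accs <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    ci <- base_init
    if (config$n_chains > 1L && up$beta) {
      ci$beta01 <- ci$beta01 + jitter[ch, 1L]
      ci$beta02 <- ci$beta02 + jitter[ch, 2L]
      if (up$slope) {
        ci$beta11 <- ci$beta11 + jitter[ch, 3L]
        ci$beta12 <- ci$beta12 + jitter[ch, 4L]
      }
    }
    lp0 <- log_posterior(ci, data, geog, spec)
    if (!is.finite(lp0)) {
      stop("non-finite log posterior at the initial state", call. = FALSE)
    }
    set.seed(chain_seeds[ch])
    res <- .mwg_sampler(
      as.numeric(d1$y), as.numeric(d1$n), as.numeric(d1$x),
      as.numeric(d2$y), as.numeric(d2$n), as.numeric(d2$x),
      csr1$idx, csr1$ptr, csr2$idx, csr2$ptr,
      as.integer(geog$parent_index - 1L),
      spec$model_kind == "shared",
      spec$sd_prior_upper, spec$slope_prior_sd,
      config$n_iter, config$burn_in, config$thin,
      min(config$adapt_window, config$burn_in),
      config$adapt_target_site, config$adapt_target_block,
      rank1, rank2,
      ci, flags, lc1, lc2)
    colnames(res$draws) <- pn
    chains[[ch]] <- res$draws
    devs[[ch]] <- list(level1 = res$dev1, level2 = res$dev2)
    accs[[ch]] <- res$acceptance
  }

  new_posterior_samples(
    chains = chains, deviance = devs, config = config, spec = spec,
    geog_info = list(n_fine = length(geog$fine_ids),
                     n_coarse = length(geog$coarse_ids),
                     fine_ids = geog$fine_ids, coarse_ids = geog$coarse_ids),
    acceptance = accs,
    data_std = data$standardization)
}

#' @export
print.posterior_samples <- function(x, ...) {
  m <- if (length(x$chains)) nrow(x$chains[[1L]]) else 0L
  cat(sprintf(
    "posterior_samples: %d chain(s) x %d retained draws, %d parameters\n",
    length(x$chains), m, if (m > 0) ncol(x$chains[[1L]]) else 0L))
  cat(sprintf("  model: %s | seed: %d\n", x$spec$model_kind, x$config$seed))
  invisible(x)
}

pooled_draws <- function(samples, params = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  d <- do.call(rbind, samples$chains)
  if (is.null(d) || nrow(d) == 0L) {
    stop("empty retained sample", call. = FALSE)
  }
  if (!is.null(params)) {
    bad <- setdiff(params, colnames(d))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           "; available: ", paste(utils::head(colnames(d), 12), collapse = ", "),
           ", ...", call. = FALSE)
    }
    d <- d[, params, drop = FALSE]
  }
  d
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical multi-chain diagnostic: with `m` retained draws per chain,
#' within-chain variance `W` (mean of the per-chain variances) and
#' between-chain variance `B` (`m` times the variance of the chain means),
#' `Rhat = sqrt((m-1)/m + B/(m*W))`. Values near 1 indicate convergence;
#' chains stuck at distinct constants give `W = 0` and `Rhat = Inf`.
#'
#' @param samples A `posterior_samples` with at least 2 chains and 10
#'   retained draws per chain.
#' @param params Character vector of parameter names (default: the eight
#'   hyperparameters).
#' @return Named numeric vector of scale reduction factors.
#' @export
gelman_rubin <- function(samples, params = hyper_params()) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (length(samples$chains) < 2L) {
    stop("Gelman-Rubin needs at least 2 chains; ",
         "re-run with n_chains >= 2 or use a split-chain variant",
         call. = FALSE)
  }
  m <- nrow(samples$chains[[1L]])
  if (m < 10L) stop("need at least 10 retained draws per chain", call. = FALSE)
  bad <- setdiff(params, colnames(samples$chains[[1L]]))
  if (length(bad)) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  vapply(params, function(p) {
    x <- vapply(samples$chains, function(ch) ch[, p], numeric(m))
    W <- mean(apply(x, 2L, stats::var))
    B <- m * stats::var(colMeans(x))
    if (W == 0) {
      if (B == 0) return(1)
      return(Inf)
    }
    sqrt((m - 1) / m + B / (m * W))
  }, numeric(1))
}

#' Posterior summary table
#'
#' Pooled across chains: posterior mean, standard deviation and equal-tailed
#' 95% interval (empirical 2.5 and 97.5 percentiles) per parameter.
#'
#' @param samples A `posterior_samples`.
#' @param params Parameter names (default: the eight hyperparameters).
#' @param digits Optional rounding for display; `NULL` leaves values exact.
#' @return Data frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`.
#' @export
posterior_summary <- function(samples, params = hyper_params(),
                              digits = NULL) {
  d <- pooled_draws(samples, params)
  out <- data.frame(
    parameter = colnames(d),
    mean = colMeans(d),
    sd = apply(d, 2L, stats::sd),
    q2.5 = apply(d, 2L, stats::quantile, probs = 0.025, names = FALSE),
    q97.5 = apply(d, 2L, stats::quantile, probs = 0.975, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(digits)) out[-1L] <- round(out[-1L], digits)
  out
}

# per-draw linear predictor matrix (pooled draws x units) at one level
posterior_eta <- function(samples, data, geog, spec, level) {
  d <- pooled_draws(samples)
  ld <- level_data(data, level)
  if (level == 2) {
    vcols <- paste0("v2[", geog$coarse_ids, "]")
    ecols <- paste0("eps2[", geog$coarse_ids, "]")
    eta <- d[, vcols, drop = FALSE] + d[, ecols, drop = FALSE] +
      d[, "beta02"] + outer(d[, "beta12"], ld$x)
  } else {
    vcols <- paste0("v1[", geog$fine_ids, "]")
    ecols <- paste0("eps1[", geog$fine_ids, "]")
    eta <- d[, vcols, drop = FALSE] + d[, ecols, drop = FALSE] +
      d[, "beta01"] + outer(d[, "beta11"], ld$x)
    if (spec$model_kind == "shared") {
      v2 <- d[, paste0("v2[", geog$coarse_ids, "]"), drop = FALSE]
      eta <- eta + v2[, geog$parent_index, drop = FALSE]
    }
  }
  unname(eta)
}

#' Export posterior draws in long format
#'
#' @param samples A `posterior_samples`.
#' @param params Parameter names (default: the eight hyperparameters).
#' @return Data frame with columns `chain`, `iteration`, `parameter`,
#'   `value`.
#' @export
draws_long <- function(samples, params = hyper_params()) {
  stopifnot(inherits(samples, "posterior_samples"))
  do.call(rbind, lapply(seq_along(samples$chains), function(ch) {
    d <- samples$chains[[ch]][, params, drop = FALSE]
    data.frame(
      chain = ch,
      iteration = rep(seq_len(nrow(d)), times = ncol(d)),
      parameter = rep(colnames(d), each = nrow(d)),
      value = as.vector(d),
      stringsAsFactors = FALSE
    )
  }))
}
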
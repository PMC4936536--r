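#' Specify a multiscale convolution model
#'
#' Both models place, at each scale level k, a binomial likelihood
#' `y_ik ~ Bin(n_ik, p_ik)` with
#' `logit(p_ik) = beta0k + beta1k * x_ik + v_ik + eps_ik`,
#' where `v_k` is spatially correlated heterogeneity (intrinsic CAR prior)
#' and `eps_k` is exchangeable uncorrelated heterogeneity. The
#' `"independent"` model keeps the two levels unlinked; the `"shared"`
#' model adds the parent coarse unit's spatial effect `v_{parent(i),2}` to
#' every nested fine unit's linear predictor, so counties inherit their
#' district's spatially structured component and the two scales are fitted
#' jointly.
#'
#' Priors: flat on the intercepts, Normal(0, `slope_prior_sd`^2) on the
#' slopes, Uniform(0, `sd_prior_upper`) on all four standard deviations.
#'
#' @param model_kind `"independent"` or `"shared"`.
#' @param sd_prior_upper Upper bound of the uniform prior on every random
#'   effect standard deviation (default 100).
#' @param slope_prior_sd Standard deviation of the vague normal prior on the
#'   slopes (default 1000).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model_kind = c("independent", "shared"),
                       sd_prior_upper = 100, slope_prior_sd = 1000) {
  model_kind <- match.arg(model_kind)
  stopifnot(sd_prior_upper > 0, slope_prior_sd > 0)
  structure(
    list(model_kind = model_kind, link = "logit",
         sd_prior_upper = sd_prior_upper, slope_prior_sd = slope_prior_sd),
    class = "model_spec"
  )
}

#' One point in parameter space
#'
#' Container for the full parameter vector of either model: intercepts and
#' slopes per level (log-odds scale; slopes per SD of the standardized
#' covariate), the spatially correlated (`v`) and uncorrelated (`eps`)
#' heterogeneity vectors at both levels, and the four standard deviations.
#'
#' @param geog A `multiscale_geography` fixing the vector lengths.
#' @param beta01,beta02 Intercepts (fine, coarse level).
#' @param beta11,beta12 Slopes (fine, coarse level).
#' @param v1,v2 Spatially structured effects; default 0.
#' @param eps1,eps2 Exchangeable effects; default 0.
#' @param sigma_v1,sigma_v2,sigma_eps1,sigma_eps2 Standard deviations;
#'   default 1.
#' @return An object of class `parameter_state`.
#' @export
parameter_state <- function(geog, beta01 = 0, beta02 = 0, beta11 = 0,
                            beta12 = 0, v1 = NULL, v2 = NULL, eps1 = NULL,
                            eps2 = NULL, sigma_v1 = 1, sigma_v2 = 1,
                            sigma_eps1 = 1, sigma_eps2 = 1) {
  n1 <- length(geog$fine_ids)
  n2 <- length(geog$coarse_ids)
  zero_or <- function(v, n, what) {
    if (is.null(v)) return(numeric(n))
    if (length(v) != n) {
      stop(sprintf("%s must have length %d, got %d", what, n, length(v)),
           call. = FALSE)
    }
    as.numeric(v)
  }
  structure(
    list(beta01 = beta01, beta02 = beta02, beta11 = beta11, beta12 = beta12,
         v1 = zero_or(v1, n1, "v1"), v2 = zero_or(v2, n2, "v2"),
         eps1 = zero_or(eps1, n1, "eps1"), eps2 = zero_or(eps2, n2, "eps2"),
         sigma_v1 = sigma_v1, sigma_v2 = sigma_v2,
         sigma_eps1 = sigma_eps1, sigma_eps2 = sigma_eps2),
    class = "parameter_state"
  )
}

level_data <- function(data, level) {
  if (!level %in% c(1, 2)) stop("level must be 1 or 2", call. = FALSE)
  if (level == 1) data$level1 else data$level2
}

#' Linear predictor of a multiscale model
#'
#' Computes the per-unit log-odds at the requested level. At level 2 both
#' models use `beta02 + beta12 * x + v2 + eps2`. At level 1 the independent
#' model uses `beta01 + beta11 * x + v1 + eps1`; the shared model adds the
#' parent coarse unit's spatial effect, which is common to every fine unit
#' nested within it.
#'
#' @param state A `parameter_state`.
#' @param data A `multiscale_dataset`.
#' @param geog A `multiscale_geography`.
#' @param level 1 (fine) or 2 (coarse).
#' @param spec A `model_spec`.
#' @return Numeric vector of linear predictors in canonical unit order.
#' @export
linear_predictor <- function(state, data, geog, level, spec) {
  d <- level_data(data, level)
  if (level == 2) {
    check_len(state$v2, length(geog$coarse_ids), "v2", level)
    eta <- state$beta02 + state$beta12 * d$x + state$v2 + state$eps2
  } else {
    check_len(state$v1, length(geog$fine_ids), "v1", level)
    eta <- state$beta01 + state$beta11 * d$x + state$v1 + state$eps1
    if (spec$model_kind == "shared") {
      check_len(state$v2, length(geog$coarse_ids), "v2", level)
      eta <- eta + state$v2[geog$parent_index]
    }
  }
  unname(eta)
}

check_len <- function(v, n, what, level) {
  if (length(v) != n) {
    stop(sprintf("level %d: %s has length %d, expected %d",
                 level, what, length(v), n), call. = FALSE)
  }
}

#' Log density of the intrinsic CAR prior (up to a constant)
#'
#' The ICAR prior on a vector `v` over an adjacency graph is the improper
#' pairwise-difference Gaussian
#' `-(1/(2 sigma_v^2)) * sum_{i<j, j ~ i} (v_i - v_j)^2`, with scale term
#' `-(N - c) * log(sigma_v)` where `c` is the number of connected components
#' (the rank deficiency of the pairwise precision). Island units (no
#' neighbours) contribute nothing to the pairwise sum; they instead carry a
#' proper `Normal(0, sigma_v^2)` term, consistent with the island full
#' conditional used by the sampler.
#'
#' @param v Numeric vector, one value per unit in adjacency order.
#' @param adjacency Named list of neighbour id vectors.
#' @param sigma_v Positive standard deviation.
#' @return Log density up to an additive constant.
#' @export
icar_logpdf <- function(v, adjacency, sigma_v) {
  if (sigma_v <= 0) stop("sigma_v must be positive", call. = FALSE)
  ids <- names(adjacency)
  if (length(v) != length(ids)) {
    stop(sprintf("v has length %d but adjacency has %d units",
                 length(v), length(ids)), call. = FALSE)
  }
  idx <- stats::setNames(seq_along(ids), ids)
  q <- 0
  for (i in seq_along(ids)) {
    nbrs <- idx[adjacency[[i]]]
    if (length(nbrs)) {
      js <- nbrs[nbrs > i]
      if (length(js)) q <- q + sum((v[i] - v[js])^2)
    } else {
      q <- q + v[i]^2  # proper prior for islands
    }
  }
  rank <- length(ids) - n_nonisland_components(adjacency)
  -q / (2 * sigma_v^2) - rank * log(sigma_v)
}

#' ICAR full conditional of one unit
#'
#' Under the ICAR prior, the conditional distribution of `v_i` given the
#' rest is Normal with mean the average of its neighbours' values and
#' variance `sigma_v^2 / degree(i)`. Islands get the proper conditional
#' `Normal(0, sigma_v^2)`.
#'
#' @param i Unit index or id.
#' @param v Numeric vector of current values, adjacency order.
#' @param adjacency Named list of neighbour id vectors.
#' @param sigma_v Positive standard deviation.
#' @return List with `mean` and `variance`.
#' @export
icar_full_conditional <- function(i, v, adjacency, sigma_v) {
  if (sigma_v <= 0) stop("sigma_v must be positive", call. = FALSE)
  ids <- names(adjacency)
  if (is.character(i)) i <- match(i, ids)
  if (is.na(i) || i < 1 || i > length(ids)) {
    stop("unknown unit index", call. = FALSE)
  }
  nbrs <- match(adjacency[[i]], ids)
  if (length(nbrs) == 0L) {
    return(list(mean = 0, variance = sigma_v^2))
  }
  list(mean = mean(v[nbrs]), variance = sigma_v^2 / length(nbrs))
}

#' Binomial log likelihood at one level
#'
#' `sum_i [ log C(n_i, y_i) + y_i * eta_i - n_i * log(1 + exp(eta_i)) ]`,
#' evaluated with a softplus form that is stable for large `|eta|`.
#'
#' @inheritParams linear_predictor
#' @return Log likelihood (includes the binomial normalizing constant).
#' @export
binomial_loglik <- function(state, data, geog, level, spec) {
  d <- level_data(data, level)
  eta <- linear_predictor(state, data, geog, level, spec)
  sum(lchoose(d$n, d$y) + d$y * eta - d$n * softplus(eta))
}

softplus <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

#' Log posterior of a multiscale model (up to a constant)
#'
#' Sum of the binomial log likelihoods at both levels, the ICAR log
#' densities of `v1` and `v2`, iid Normal terms for `eps1` and `eps2`, and
#' vague normal slope priors; intercepts are flat and the uniform priors on
#' the standard deviations contribute a constant inside their support.
#' Returns `-Inf` outside the prior support (any sigma outside
#' `(0, sd_prior_upper)`), which signals rejection to samplers.
#'
#' @inheritParams linear_predictor
#' @return Log posterior density up to an additive constant.
#' @export
log_posterior <- function(state, data, geog, spec) {
  sds <- c(state$sigma_v1, state$sigma_v2, state$sigma_eps1, state$sigma_eps2)
  if (any(sds <= 0) || any(sds >= spec$sd_prior_upper)) return(-Inf)
  binomial_loglik(state, data, geog, 1, spec) +
    binomial_loglik(state, data, geog, 2, spec) +
    icar_logpdf(state$v1, geog$fine_adjacency, state$sigma_v1) +
    icar_logpdf(state$v2, geog$coarse_adjacency, state$sigma_v2) +
    sum(stats::dnorm(state$eps1, 0, state$sigma_eps1, log = TRUE)) +
    sum(stats::dnorm(state$eps2, 0, state$sigma_eps2, log = TRUE)) +
    stats::dnorm(state$beta11, 0, spec$slope_prior_sd, log = TRUE) +
    stats::dnorm(state$beta12, 0, spec$slope_prior_sd, log = TRUE)
}
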
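#' Odds ratio per raw covariate unit
#'
#' Slopes are estimated on the standardized covariate scale; to interpret
#' them on the raw scale (for income in thousands of dollars, "per $1,000
#' increase"), the slope estimate is divided by the covariate's standard
#' deviation and exponentiated: `OR = exp(beta_std / sd_x)`.
#'
#' @param beta_std Slope on the standardized-covariate scale (e.g. the
#'   posterior mean).
#' @param sd_x Standard deviation of the raw covariate (from the dataset's
#'   standardization record).
#' @return List with `transformed` (the unrounded `beta_std / sd_x`),
#'   `odds_ratio` (unrounded), and `transformed_rounded` /
#'   `odds_ratio_rounded` at 3 decimals (the reporting convention).
#' @export
odds_ratio_per_unit <- function(beta_std, sd_x) {
  if (!is.finite(sd_x) || sd_x <= 0) {
    stop("sd_x must be a positive number", call. = FALSE)
  }
  transformed <- beta_std / sd_x
  or <- exp(transformed)
  list(transformed = transformed,
       odds_ratio = or,
       transformed_rounded = round(transformed, 3),
       odds_ratio_rounded = round(or, 3))
}

#' Percent change in the odds implied by an odds ratio
#'
#' `(1 - OR) * 100`, rounded to 1 decimal; positive values are a decrease
#' in the odds, negative values an increase.
#'
#' @param odds_ratio Positive odds ratio (vectorized).
#' @return Percent change (1 decimal).
#' @export
percent_change <- function(odds_ratio) {
  if (any(!is.finite(odds_ratio) | odds_ratio <= 0)) {
    stop("odds_ratio must be positive", call. = FALSE)
  }
  round((1 - odds_ratio) * 100, 1)
}

#' Posterior risk surface at both levels
#'
#' Per-unit posterior mean probability `E[logit^-1(eta_i) | data]` with an
#' equal-tailed 95% interval, at both scale levels - the per-unit numeric
#' analogue of a probability-of-outcome map. Under the shared model the
#' fine-level surface is typically spatially smoother than under the
#' independent model (compare with [surface_roughness()]).
#'
#' @param samples A `posterior_samples`.
#' @param data,geog,spec As in [linear_predictor()].
#' @return Data frame with columns `unit_id`, `level`, `post_mean_p`,
#'   `q2.5`, `q97.5`.
#' @export
risk_surface <- function(samples, data, geog, spec) {
  out <- lapply(c(1, 2), function(lev) {
    p <- stats::plogis(posterior_eta(samples, data, geog, spec, lev))
    ids <- if (lev == 1) geog$fine_ids else geog$coarse_ids
    data.frame(
      unit_id = ids,
      level = lev,
      post_mean_p = colMeans(p),
      q2.5 = apply(p, 2L, stats::quantile, probs = 0.025, names = FALSE),
      q97.5 = apply(p, 2L, stats::quantile, probs = 0.975, names = FALSE),
      stringsAsFactors = FALSE
    )
  })
  rbind(out[[1L]], out[[2L]])
}

#' Spatial roughness of a per-unit surface
#'
#' Sum over adjacent pairs (each counted once) of the squared difference of
#' the surface values: `sum_{i~j, i<j} (p_i - p_j)^2`. Smaller values mean
#' a spatially smoother surface.
#'
#' @param values Numeric vector in adjacency order.
#' @param adjacency Named list of neighbour id vectors.
#' @return Non-negative scalar.
#' @export
surface_roughness <- function(values, adjacency) {
  ids <- names(adjacency)
  stopifnot(length(values) == length(ids))
  idx <- stats::setNames(seq_along(ids), ids)
  r <- 0
  for (i in seq_along(ids)) {
    js <- idx[adjacency[[i]]]
    js <- js[js > i]
    if (length(js)) r <- r + sum((values[i] - values[js])^2)
  }
  r
}

#' Odds-ratio table from a fitted model
#'
#' Back-transforms the posterior-mean slopes to the raw covariate scale
#' using the standardization records stored with the samples, and reports
#' both the point back-transformation of the posterior mean (the headline
#' number) and the posterior mean / 95% interval of the draw-wise
#' transform `exp(beta / sd_x)` (the fully Bayesian alternative).
#'
#' @param samples A `posterior_samples`.
#' @return Data frame, one row per level.
#' @export
odds_ratio_table <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  d <- pooled_draws(samples, c("beta11", "beta12"))
  sds <- c(samples$standardization$level1$sd,
           samples$standardization$level2$sd)
  do.call(rbind, lapply(1:2, function(lev) {
    beta <- d[, lev]
    pt <- odds_ratio_per_unit(mean(beta), sds[lev])
    draws_or <- exp(beta / sds[lev])
    data.frame(
      level = lev,
      slope_mean = round(mean(beta), 2),
      sd_x = sds[lev],
      transformed = pt$transformed_rounded,
      odds_ratio = pt$odds_ratio_rounded,
      pct_change = percent_change(pt$odds_ratio_rounded),
      or_post_mean = round(mean(draws_or), 3),
      or_q2.5 = round(unname(stats::quantile(draws_or, 0.025)), 3),
      or_q97.5 = round(unname(stats::quantile(draws_or, 0.975)), 3),
      stringsAsFactors = FALSE
    )
  }))
}
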
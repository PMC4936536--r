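#' Deviance at one level
#'
#' `-2` times the binomial log likelihood, including the binomial
#' normalizing constant (constant across models fitted to the same data, so
#' harmless for comparison).
#'
#' @inheritParams linear_predictor
#' @return Deviance (numeric scalar).
#' @export
deviance_at <- function(state, data, geog, spec, level) {
  -2 * binomial_loglik(state, data, geog, level, spec)
}

deviance_from_eta <- function(eta, ld) {
  -2 * sum(lchoose(ld$n, ld$y) + ld$y * eta - ld$n * softplus(eta))
}

#' DIC at one level
#'
#' Deviance information criterion from the per-iteration deviances stored
#' during sampling: `Dbar` is the posterior mean deviance, the plug-in
#' deviance `Dhat` is evaluated at the posterior mean of the level's linear
#' predictor (plug-in on the eta scale, standard for hierarchical GLMs),
#' `pD = Dbar - Dhat` is the effective number of parameters, and
#' `DIC = Dbar + pD`. Negative `pD` (a known DIC pathology under strong
#' posterior asymmetry) is flagged with a warning, not an error.
#'
#' @param samples A `posterior_samples` for the model under assessment.
#' @param data,geog,spec,level As in [linear_predictor()].
#' @return List with `Dbar`, `pD`, `DIC`.
#' @export
dic <- function(samples, data, geog, spec, level) {
  stopifnot(inherits(samples, "posterior_samples"))
  key <- if (level == 2) "level2" else "level1"
  dev <- unlist(lapply(samples$deviance, `[[`, key), use.names = FALSE)
  if (length(dev) == 0L) stop("empty retained sample", call. = FALSE)
  dbar <- mean(dev)
  eta_bar <- colMeans(posterior_eta(samples, data, geog, spec, level))
  dhat <- deviance_from_eta(eta_bar, level_data(data, level))
  pd <- dbar - dhat
  if (pd < 0) {
    warning("negative pD at level ", level,
            " (DIC pathology); interpret with care", call. = FALSE)
  }
  list(Dbar = dbar, pD = pd, DIC = dbar + pd)
}

#' Posterior-predictive mean squared prediction error
#'
#' For each retained draw `s` a replicate outcome vector is simulated,
#' `y_rep_i^(s) ~ Binomial(n_i, p_i^(s))`, and the MSPE is the average over
#' draws and units of `(y_rep_i^(s) - y_i)^2`. Reproducible for a fixed
#' `seed`.
#'
#' @param samples A `posterior_samples`.
#' @param data,geog,spec,level As in [linear_predictor()].
#' @param seed Integer seed for the replicate draws.
#' @return MSPE (numeric scalar, >= 0).
#' @export
mspe <- function(samples, data, geog, spec, level, seed = 1) {
  p <- stats::plogis(posterior_eta(samples, data, geog, spec, level))
  ld <- level_data(data, level)
  nun <- ncol(p)
  ndr <- nrow(p)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  yrep <- matrix(
    stats::rbinom(ndr * nun, size = rep(ld$n, each = ndr), prob = as.vector(p)),
    nrow = ndr)
  mean((yrep - rep(ld$y, each = ndr))^2)
}

#' Assess one fitted model at both levels
#'
#' @param samples A `posterior_samples`.
#' @param data,geog,spec As in [linear_predictor()].
#' @param seed Seed for the MSPE replicate draws.
#' @param model_label Row label used by [compare_models()].
#' @return An `assessment_report`: per level `Dbar`, `pD`, `DIC`, `MSPE`.
#' @export
assess_model <- function(samples, data, geog, spec, seed = 1,
                         model_label = spec$model_kind) {
  per_level <- lapply(c(1, 2), function(lev) {
    d <- dic(samples, data, geog, spec, lev)
    d$MSPE <- mspe(samples, data, geog, spec, lev, seed = seed + lev)
    d
  })
  names(per_level) <- c("level1", "level2")
  structure(
    list(model = model_label, level1 = per_level$level1,
         level2 = per_level$level2,
         n_units = c(samples$geog_info$n_fine, samples$geog_info$n_coarse)),
    class = "assessment_report"
  )
}

#' @export
print.assessment_report <- function(x, ...) {
  cat("assessment_report:", x$model, "\n")
  for (lev in c("level1", "level2")) {
    cat(sprintf("  %s: Dbar=%.2f pD=%.2f DIC=%.2f MSPE=%.2f\n",
                lev, x[[lev]]$Dbar, x[[lev]]$pD, x[[lev]]$DIC, x[[lev]]$MSPE))
  }
  invisible(x)
}

#' Compare fitted models by DIC and MSPE
#'
#' Lays the per-level `Dbar`/`pD`/`DIC`/`MSPE` of two or more assessed
#' models side by side, computes DIC differences against the first model at
#' each level, and flags an improvement when the DIC difference reaches 3
#' (differences of 3-7 are conventionally taken as a real improvement).
#' Lower DIC and lower MSPE are preferred.
#'
#' @param reports List of `assessment_report` objects fitted to the same
#'   data.
#' @return List with `table` (data frame, one row per model x level),
#'   `preferred` (model label with lowest fine-level DIC, or `NA` on a tie)
#'   and `improvement` (logical: DIC difference >= 3 at the fine level).
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2L) {
    stop("need at least two assessment reports", call. = FALSE)
  }
  stopifnot(all(vapply(reports, inherits, logical(1), "assessment_report")))
  sizes <- vapply(reports, function(r) paste(r$n_units, collapse = "/"),
                  character(1))
  if (length(unique(sizes)) != 1L) {
    stop("reports were not computed on the same data (unit counts differ)",
         call. = FALSE)
  }
  rows <- do.call(rbind, lapply(reports, function(r) {
    do.call(rbind, lapply(c("level1", "level2"), function(lev) {
      data.frame(model = r$model, level = lev,
                 Dbar = r[[lev]]$Dbar, pD = r[[lev]]$pD,
                 DIC = r[[lev]]$DIC, MSPE = r[[lev]]$MSPE,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  dic1 <- rows$DIC[rows$level == "level1"]
  diff1 <- max(dic1) - min(dic1)
  preferred <- if (diff1 == 0) NA_character_ else {
    rows$model[rows$level == "level1"][which.min(dic1)]
  }
  list(table = rows,
       dic_difference = c(level1 = diff1,
                          level2 = {
                            d2 <- rows$DIC[rows$level == "level2"]
                            max(d2) - min(d2)
                          }),
       preferred = preferred,
       improvement = diff1 >= 3)
}
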
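#' Standardize a covariate
#'
#' Centers and scales a covariate to mean 0, sd 1 using the sample standard
#' deviation (denominator N-1), keeping the standardization record so that
#' slope estimates can later be back-transformed to the covariate's raw
#' units (see [odds_ratio_per_unit()]).
#'
#' @param x_raw Numeric vector, length >= 2, non-constant.
#' @return List with `x` (standardized values), `mean` and `sd`.
#' @export
standardize_covariate <- function(x_raw) {
  if (length(x_raw) < 2L) {
    stop("standardization needs at least 2 units", call. = FALSE)
  }
  m <- mean(x_raw)
  s <- stats::sd(x_raw)
  if (!is.finite(s) || s <= 0) {
    stop("degenerate covariate: standard deviation is zero", call. = FALSE)
  }
  list(x = (x_raw - m) / s, mean = m, sd = s)
}

#' Assemble a two-level dataset
#'
#' Builds the per-level outcome/trial/covariate vectors the models consume.
#' The fine level is supplied as a data frame with columns `unit_id`, `y`
#' (case counts, e.g. low-birth-weight births), `n` (trial counts, e.g.
#' total births) and `x` (covariate, e.g. median household income in
#' thousands of dollars). The coarse level may be supplied the same way; if
#' omitted it is derived by aggregation, the way nested administrative data
#' arise: coarse `y` and `n` are sums over each coarse unit's children and
#' coarse `x` is the mean. Covariates are standardized per level and the
#' standardization records kept.
#'
#' @param fine Data frame with columns `unit_id`, `y`, `n`, `x` for every
#'   fine unit.
#' @param geog A `multiscale_geography`.
#' @param coarse Optional data frame with the same columns for every coarse
#'   unit; derived by aggregation when `NULL`.
#' @return An object of class `multiscale_dataset`: per level `y`, `n`,
#'   `x_raw`, `x` (standardized) in canonical unit order, plus
#'   `standardization` records (`mean`, `sd` per level).
#' @export
multiscale_dataset <- function(fine, geog, coarse = NULL) {
  fine <- check_level_frame(fine, geog$fine_ids, "fine")
  if (is.null(coarse)) {
    coarse <- data.frame(
      unit_id = geog$coarse_ids,
      y = unname(aggregate_to_coarse(stats::setNames(fine$y, fine$unit_id),
                                     geog, "sum")),
      n = unname(aggregate_to_coarse(stats::setNames(fine$n, fine$unit_id),
                                     geog, "sum")),
      x = unname(aggregate_to_coarse(stats::setNames(fine$x, fine$unit_id),
                                     geog, "mean")),
      stringsAsFactors = FALSE
    )
  }
  coarse <- check_level_frame(coarse, geog$coarse_ids, "coarse")
  s1 <- standardize_covariate(fine$x)
  s2 <- standardize_covariate(coarse$x)
  structure(
    list(
      level1 = list(ids = fine$unit_id, y = fine$y, n = fine$n,
                    x_raw = fine$x, x = s1$x),
      level2 = list(ids = coarse$unit_id, y = coarse$y, n = coarse$n,
                    x_raw = coarse$x, x = s2$x),
      standardization = list(
        level1 = list(mean = s1$mean, sd = s1$sd),
        level2 = list(mean = s2$mean, sd = s2$sd)
      )
    ),
    class = "multiscale_dataset"
  )
}

check_level_frame <- function(df, ids, what) {
  need <- c("unit_id", "y", "n", "x")
  if (!all(need %in% names(df))) {
    stop(what, " data must have columns unit_id, y, n, x", call. = FALSE)
  }
  missing <- setdiff(ids, df$unit_id)
  if (length(missing)) {
    stop(what, " data missing unit(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[match(ids, df$unit_id), need, drop = FALSE]
  if (any(df$y < 0 | df$n < 0 | df$y > df$n)) {
    stop(what, " data: need 0 <= y <= n for every unit", call. = FALSE)
  }
  if (any(df$y != round(df$y)) || any(df$n != round(df$n))) {
    stop(what, " data: y and n must be integer counts", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a two-level dataset from per-level CSV files
#'
#' Each file is a CSV with header `unit_id,y,n,x`. The coarse-level file is
#' optional; when absent the coarse data are produced by aggregation (sum
#' for `y` and `n`, mean for `x`).
#'
#' @param fine_path CSV path for the fine level.
#' @param geog A `multiscale_geography`.
#' @param coarse_path Optional CSV path for the coarse level.
#' @return A `multiscale_dataset`.
#' @export
read_dataset <- function(fine_path, geog, coarse_path = NULL) {
  fine <- utils::read.csv(fine_path, stringsAsFactors = FALSE,
                          comment.char = "#")
  coarse <- if (!is.null(coarse_path)) {
    utils::read.csv(coarse_path, stringsAsFactors = FALSE,
                    comment.char = "#")
  }
  multiscale_dataset(fine, geog, coarse)
}

#' @export
print.multiscale_dataset <- function(x, ...) {
  cat(sprintf(
    "multiscale_dataset: %d fine units (total y=%d, n=%d), %d coarse units\n",
    length(x$level1$ids), sum(x$level1$y), sum(x$level1$n),
    length(x$level2$ids)))
  cat(sprintf("  covariate sd: %.3f (fine), %.3f (coarse)\n",
              x$standardization$level1$sd, x$standardization$level2$sd))
  invisible(x)
}
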
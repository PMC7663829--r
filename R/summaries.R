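draw_columns <- function(draws, effect) {
  n <- switch(effect, alpha = draws$dims$I, beta = draws$dims$J,
              gamma = draws$dims$K)
  draws$draws[, paste0(effect, "[", seq_len(n), "]"), drop = FALSE]
}

level_labels <- function(draws, dimension) {
  switch(dimension,
         age = draws$labels$age,
         period = as.character(draws$labels$years),
         cohort = paste0(draws$labels$birth_start, "-",
                         draws$labels$birth_end))
}

#' Posterior effect curves with 95% credible intervals
#'
#' For each of the age, period and cohort effects, the pointwise posterior
#' mean, median and central 95% interval per level, computed from the
#' recentered draws on the original measurement scale. These are the curves
#' conventionally plotted in APC analyses as a solid line with a shaded
#' credible band.
#'
#' @param draws an [apc_draws] object.
#' @param prob central interval probability (default 0.95).
#' @return A named list (`age`, `period`, `cohort`) of data.frames with
#'   columns `level`, `label`, `mean`, `median`, `lower`, `upper`.
#' @export
effect_curves <- function(draws, prob = 0.95) {
  stopifnot(inherits(draws, "apc_draws"))
  a <- (1 - prob) / 2
  one <- function(effect, dimension) {
    m <- draw_columns(draws, effect)
    q <- apply(m, 2, stats::quantile, probs = c(a, 0.5, 1 - a), names = FALSE)
    data.frame(level = seq_len(ncol(m)),
               label = level_labels(draws, dimension),
               mean = colMeans(m), median = q[2, ],
               lower = q[1, ], upper = q[3, ], row.names = NULL)
  }
  list(age = one("alpha", "age"),
       period = one("beta", "period"),
       cohort = one("gamma", "cohort"))
}

#' Estimated biomarker values per age, period or cohort
#'
#' Collapses the fitted model onto one dimension on the original measurement
#' scale. For the age dimension the estimated value for age group `i` is
#' `delta-hat + alpha-hat_i + median(beta-hat) + median(gamma-hat)`: the
#' posterior-mean intercept and focal effect, plus the median *across
#' levels* of the posterior means of the two non-focal effects. The period
#' and cohort dimensions are defined analogously. Even-count medians use the
#' midpoint convention.
#'
#' @param draws an [apc_draws] object.
#' @param dimension `"age"`, `"period"` or `"cohort"`.
#' @param point point estimate per level fed into the formula:
#'   `"mean"` (posterior means, the default) or `"median"` (per-level
#'   posterior medians, a documented alternative reading).
#' @return A data.frame with columns `level`, `label`, `value` (biomarker
#'   units) and attributes `biomarker`/`unit` carried from the fit.
#' @export
estimated_values <- function(draws, dimension = c("age", "period", "cohort"),
                             point = c("mean", "median")) {
  stopifnot(inherits(draws, "apc_draws"))
  dimension <- match.arg(dimension)
  point <- match.arg(point)
  pt <- function(m) if (point == "mean") colMeans(m)
                    else apply(m, 2, stats::median)
  est <- list(alpha = pt(draw_columns(draws, "alpha")),
              beta = pt(draw_columns(draws, "beta")),
              gamma = pt(draw_columns(draws, "gamma")))
  delta_hat <- if (point == "mean") mean(draws$draws[, "delta"])
               else stats::median(draws$draws[, "delta"])
  focal <- switch(dimension, age = "alpha", period = "beta", cohort = "gamma")
  others <- setdiff(c("alpha", "beta", "gamma"), focal)
  value <- delta_hat + est[[focal]] +
    stats::median(est[[others[1]]]) + stats::median(est[[others[2]]])
  out <- data.frame(level = seq_along(value),
                    label = level_labels(draws, dimension),
                    value = unname(value), row.names = NULL)
  attr(out, "biomarker") <- draws$biomarker
  attr(out, "unit") <- draws$unit
  out
}

#' Observed per-age-group series and age-standardized series
#'
#' Descriptive (model-free) exports of a grid: the observed yearly series
#' for each age group, long format, and the directly age-standardized yearly
#' series under the given weights.
#'
#' @param grid an [apc_grid].
#' @param weights standard age weights passed to [age_standardize()]
#'   (default equal).
#' @return A list with `by_age` (columns `age`, `year`, `value`; observed
#'   cells only) and `standardized` (columns `year`, `value`, `NA` where any
#'   age group is missing).
#' @export
descriptive_series <- function(grid, weights = NULL) {
  stopifnot(inherits(grid, "apc_grid"))
  obs <- which(!is.na(grid$values), arr.ind = TRUE)
  by_age <- data.frame(age = rownames(grid$values)[obs[, 1]],
                       year = grid$years[obs[, 2]],
                       value = grid$values[obs])
  by_age <- by_age[order(by_age$age, by_age$year), , drop = FALSE]
  rownames(by_age) <- NULL
  list(by_age = by_age, standardized = age_standardize(grid, weights))
}

#' Plot posterior effect curves
#'
#' One panel per dimension: posterior point estimate as a solid line with
#' the shaded 95% credible band; the cohort axis is labelled by birth year.
#' Output is deterministic given the summaries.
#'
#' @param curves output of [effect_curves()].
#' @param file output figure path (extension selects the device, e.g.
#'   `.png` or `.pdf`).
#' @param title optional figure title (e.g. the biomarker label).
#' @param width,height device size in inches.
#' @return `file`, invisibly.
#' @export
plot_effects <- function(curves, file, title = NULL,
                         width = 10, height = 3.5) {
  stopifnot(is.list(curves),
            all(c("age", "period", "cohort") %in% names(curves)))
  panel <- function(d, dimension, xlab) {
    if (!nrow(d)) stop("empty ", dimension, " summary")
    d$x <- switch(dimension,
                  age = d$level,
                  period = as.numeric(d$label),
                  cohort = as.numeric(sub("-.*", "", d$label)))
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           fill = "grey70", alpha = 0.6) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
      ggplot2::labs(x = xlab, y = "effect",
                    subtitle = paste(dimension, "effect")) +
      ggplot2::theme_minimal()
    if (dimension == "age")
      p <- p + ggplot2::scale_x_continuous(breaks = d$level,
                                           labels = d$label)
    p
  }
  fig <- patchwork::wrap_plots(
    panel(curves$age, "age", "age group"),
    panel(curves$period, "period", "year"),
    panel(curves$cohort, "cohort", "birth year"),
    nrow = 1)
  if (!is.null(title))
    fig <- fig + patchwork::plot_annotation(title = title)
  dir <- dirname(file)
  if (!dir.exists(dir)) stop("unwritable path: directory ", dir,
                             " does not exist")
  ggplot2::ggsave(file, fig, width = width, height = height, dpi = 150)
  invisible(file)
}
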
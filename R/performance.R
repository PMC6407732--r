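#' Search-performance summary per condition
#'
#' Summarises trial records into the three performance measures: median
#' reaction time, error rate (proportion of incorrect responses), and the
#' number of targets found per second (correct trials divided by the summed
#' search time), which folds speed and accuracy into one efficiency figure.
#'
#' @param trials A trial-record tibble with `condition`, `rt`, `correct`.
#' @param by Grouping column (defaults to `condition`).
#' @return A tibble with one row per group: `n_trials`, `median_rt`,
#'   `error_rate`, `targets_per_second`.
#' @export
performance_summary <- function(trials, by = "condition") {
  stopifnot(nrow(trials) >= 1, all(c(by, "rt", "correct") %in%
                                     names(trials)))
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      median_rt = stats::median(.data$rt),
      error_rate = mean(!.data$correct),
      targets_per_second = sum(.data$correct) / sum(.data$rt),
      .groups = "drop"
    )
}

#' Heat map of dwell locations
#'
#' Sums an isotropic Gaussian kernel centred on each dwell location over a
#' raster covering the display, then zeroes everything below `floor` times
#' the map's maximum so that only the meaningful mass remains visible.
#'
#' @param points A tibble with dwell centroid columns `x`, `y` (degrees).
#' @param sigma Kernel standard deviation in degrees.
#' @param floor Proportion of the maximum below which the map is cut to 0.
#' @param xlim,ylim Display extent in degrees.
#' @param resolution Raster cell size in degrees.
#' @return A tibble of class `gaze_heatmap` with columns `x`, `y`,
#'   `density`; attributes `sigma` and `floor`.
#' @export
overlap_heatmap <- function(points, sigma = 1.0, floor = 0.10,
                            xlim = c(-12.9, 12.9), ylim = c(-12.9, 12.9),
                            resolution = 0.2) {
  stopifnot(sigma > 0, floor >= 0, floor <= 1)
  gx <- seq(xlim[1], xlim[2], by = resolution)
  gy <- seq(ylim[1], ylim[2], by = resolution)
  if (is.null(points) || nrow(points) == 0) {
    z <- matrix(0, length(gx), length(gy))
  } else {
    fx <- exp(-outer(gx, points$x, "-")^2 / (2 * sigma^2))
    fy <- exp(-outer(gy, points$y, "-")^2 / (2 * sigma^2))
    z <- fx %*% t(fy)
    z[z < floor * max(z)] <- 0
  }
  out <- tibble::tibble(
    x = rep(gx, times = length(gy)),
    y = rep(gy, each = length(gx)),
    density = as.vector(z)
  )
  attr(out, "sigma") <- sigma
  attr(out, "floor") <- floor
  class(out) <- c("gaze_heatmap", class(tibble::tibble()))
  out
}

#' Correlation between pair overlap and collaboration ratings
#'
#' Pearson correlation between per-pair dwell-overlap proportions and the
#' pair's questionnaire collaboration ratings, with the t statistic
#' `t = r * sqrt(df / (1 - r^2))` on `df = n - 2` degrees of freedom.
#'
#' @param overlap Numeric vector of per-pair overlap proportions.
#' @param ratings Numeric vector of per-pair collaboration ratings.
#' @return A one-row tibble: `r`, `statistic` (t), `df`, `p_value`, `n`.
#' @export
rating_overlap_correlation <- function(overlap, ratings) {
  stopifnot(length(overlap) == length(ratings))
  n <- length(overlap)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(overlap) == 0 || stats::sd(ratings) == 0) {
    stop("undefined metric: a variable has zero variance", call. = FALSE)
  }
  r <- stats::cor(overlap, ratings)
  df <- n - 2
  t_stat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(
    r = r, statistic = t_stat, df = df,
    p_value = 2 * stats::pt(-abs(t_stat), df), n = n
  )
}
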
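#' Boxplot statistics
#'
#' The boxplot convention used for all non-time-series summaries: the box
#' runs from the 25th (`q1`) to the 75th (`q3`) percentile (linear
#' interpolation between order statistics), whiskers extend to the most
#' extreme data points within `q1 - 1.5 iqr` and `q3 + 1.5 iqr`, and values
#' beyond the whiskers are listed individually as outliers.
#'
#' @param values A non-empty numeric vector.
#' @return A one-row tibble: `n`, `median`, `q1`, `q3`, `iqr`,
#'   `whisker_lo`, `whisker_hi`, `n_outliers`, and `outliers` (list column).
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no data", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  tibble::tibble(
    n = length(values),
    median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
    whisker_lo = min(values[inside]),
    whisker_hi = max(values[inside]),
    n_outliers = sum(!inside),
    outliers = list(sort(values[!inside]))
  )
}

new_search_test <- function(method, statistic, statistic_name, p_value,
                            effect_size, effect_name, n, extra = list()) {
  structure(
    c(list(method = method, statistic = statistic,
           statistic_name = statistic_name, p_value = p_value,
           effect_size = effect_size, effect_name = effect_name, n = n),
      extra),
    class = "search_test"
  )
}

#' @export
print.search_test <- function(x, ...) {
  cat(sprintf("%s\n  %s = %.4g, p = %.4g, %s = %.3g (n = %d)\n",
              x$method, x$statistic_name, x$statistic, x$p_value,
              x$effect_name, x$effect_size, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy search_test
tidy.search_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p.value = x$p_value,
    effect_size = x$effect_size,
    effect_name = x$effect_name,
    n = x$n
  )
}

#' @export
#' @method glance search_test
glance.search_test <- function(x, ...) tidy(x)

#' Paired Wilcoxon signed-rank test with the PS_dep effect size
#'
#' Signed-rank test on paired differences `x - y` (mid-ranks for tied
#' magnitudes, zero differences dropped from the test), with the
#' paired-dominance effect size `PS_dep = n+ / N`: the number of strictly
#' positive differences over the total number of pairs, zeros included in
#' the denominator.  P-values are exact for 25 or fewer non-zero
#' differences without ties, and use the normal approximation with
#' continuity correction otherwise.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A `search_test` object (fields `statistic` = V, `p_value`,
#'   `effect_size` = PS_dep, `n`); use [tidy()] for a tibble.  When every
#'   difference is zero the test is undefined (`NA` statistic and p) and
#'   PS_dep is 0.
#' @export
wilcoxon_psdep <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  n_all <- length(d)
  if (n_all < 1) stop("no paired data", call. = FALSE)
  ps_dep <- sum(d > 0) / n_all
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(new_search_test("Wilcoxon signed-rank (paired)", NA_real_, "V",
                           NA_real_, ps_dep, "ps_dep", n_all))
  }
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    stats::wilcox.test(nz, exact = exact, correct = TRUE)
  )
  new_search_test("Wilcoxon signed-rank (paired)",
                  unname(wt$statistic), "V", wt$p.value,
                  ps_dep, "ps_dep", n_all,
                  extra = list(n_nonzero = length(nz), exact = exact))
}

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Kruskal-Wallis rank test across independent groups (tie-corrected H,
#' chi-square p on k - 1 degrees of freedom), with the effect size obtained
#' by transforming H to an F value - the `(1 - p)` quantile of the
#' `F(k - 1, N - k)` distribution - and computing
#' `eta^2 = F df1 / (F df1 + df2)`.
#'
#' @param values Either a list of numeric group vectors, or a numeric
#'   vector accompanied by `groups`.
#' @param groups Group labels when `values` is a single vector.
#' @return A `search_test` object (`statistic` = H, `effect_size` = eta^2);
#'   use [tidy()] for a tibble.
#' @export
kruskal_eta2 <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    if (length(values) < 2) stop("need at least 2 groups", call. = FALSE)
    if (any(vapply(values, length, 1L) == 0)) {
      stop("empty group", call. = FALSE)
    }
    groups <- rep(seq_along(values), vapply(values, length, 1L))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  n_total <- length(values)
  k <- nlevels(groups)
  df1 <- k - 1
  df2 <- n_total - k
  if (length(unique(values)) == 1) {
    # every observation tied: no rank variance, H = 0 by convention
    return(new_search_test("Kruskal-Wallis", 0, "H", 1, 0, "eta_squared",
                           n_total, extra = list(df1 = df1, df2 = df2,
                                                 f_value = 0)))
  }
  kt <- stats::kruskal.test(values, groups)
  if (df2 >= 1) {
    f_value <- stats::qf(1 - kt$p.value, df1, df2)
    eta2 <- (f_value * df1) / (f_value * df1 + df2)
  } else {
    # no residual degrees of freedom: H and p are defined, eta^2 is not
    f_value <- NA_real_
    eta2 <- NA_real_
  }
  new_search_test("Kruskal-Wallis", unname(kt$statistic), "H",
                  kt$p.value, eta2, "eta_squared", n_total,
                  extra = list(df1 = df1, df2 = df2, f_value = f_value))
}

#' Seeded percentile bootstrap
#'
#' Resamples the data with replacement and returns the percentile interval
#' of the statistic (2.5% and 97.5% quantiles for the default 95% level).
#' Deterministic for a fixed seed.
#'
#' @param values A non-empty numeric vector.
#' @param statistic A function of a numeric vector returning a scalar.
#' @param n_boot Bootstrap iterations.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return A one-row tibble: `estimate`, `lo`, `hi`, `n`, `n_boot`.
#' @export
percentile_bootstrap <- function(values, statistic = mean, n_boot = 1000,
                                 seed = 1, conf = 0.95) {
  stopifnot(length(values) >= 1)
  statistic <- match.fun(statistic)
  est <- statistic(values)
  qs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      statistic(values[sample.int(length(values), replace = TRUE)])
    }, numeric(1))
  })
  ci <- stats::quantile(boots, qs, names = FALSE)
  tibble::tibble(estimate = est, lo = ci[1], hi = ci[2],
                 n = length(values), n_boot = n_boot)
}
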
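#' Fair share of a specialty's weekly workload
#'
#' The perfectly fair distribution of one week's workload in a specialty
#' gives every navigator the same share: the specialty total divided by
#' the number of navigators.
#'
#' @param loads Numeric vector of per-navigator workload totals for one
#'   week (actual encounter counts or predicted workloads). Must be
#'   non-empty and non-negative.
#' @return The equal share, `sum(loads) / length(loads)`.
#' @seealso [unfairness()]
#' @examples
#' fair_share(c(2, 4))   # 3
#' fair_share(c(0, 0, 6)) # 2
#' @export
fair_share <- function(loads) {
  loads <- check_loads(loads)
  sum(loads) / length(loads)
}

#' Weekly workload unfairness within a specialty
#'
#' The unfairness of one week's workload distribution is the average of
#' the absolute differences between each navigator's actual (or
#' predicted) workload and the specialty's fair share that week. It is 0
#' exactly when every navigator carries the same load, and it grows with
#' the mean absolute deviation from the equal split.
#'
#' The same statistic applies to integer encounter counts and to
#' real-valued predicted workloads.
#'
#' @inheritParams fair_share
#' @return Non-negative mean absolute deviation from the fair share.
#' @examples
#' unfairness(c(5, 5, 5)) # 0
#' unfairness(c(2, 4))    # 1
#' unfairness(c(0, 0, 6)) # 8/3
#' @export
unfairness <- function(loads) {
  loads <- check_loads(loads)
  mean(abs(loads - sum(loads) / length(loads)))
}

check_loads <- function(loads) {
  loads <- as.numeric(loads)
  if (length(loads) == 0) {
    stop("malformed specialty: empty load vector", call. = FALSE)
  }
  if (anyNA(loads)) stop("loads must not contain NA", call. = FALSE)
  if (any(loads < 0)) {
    stop("workload counts cannot be negative", call. = FALSE)
  }
  loads
}

#' Summarize a weekly series: mean, SD, and 95% CI
#'
#' Summarizes a series of weekly unfairness values (or any numeric
#' series) by its mean, sample standard deviation (n - 1 denominator),
#' and a 95% confidence interval of the form
#' `mean +/- 1.98 * sd / sqrt(n)`. The 1.98 multiplier is used verbatim,
#' as is conventional in this setting, rather than a t-quantile.
#'
#' @param values Numeric vector, length >= 2.
#' @return An object of class `series_summary`: a list with elements
#'   `mean`, `sd`, `n`, `ci_low`, `ci_high`.
#' @examples
#' summarize_series(c(0, 2)) # half-width 1.98 * sd/sqrt(2) = 1.98
#' @export
summarize_series <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  n <- length(values)
  if (n < 2) stop("need at least 2 values (SD undefined)", call. = FALSE)
  m <- mean(values)
  s <- sd(values)
  hw <- 1.98 * s / sqrt(n)
  structure(
    list(mean = m, sd = s, n = n, ci_low = m - hw, ci_high = m + hw),
    class = "series_summary"
  )
}

#' @export
print.series_summary <- function(x, digits = 4, ...) {
  cat(sprintf(
    "mean %.*f, SD %.*f (n = %d), 95%% CI [%.*f, %.*f]\n",
    digits, x$mean, digits, x$sd, x$n, digits, x$ci_low, digits, x$ci_high
  ))
  invisible(x)
}

#' @export
as.data.frame.series_summary <- function(x, ...) {
  data.frame(mean = x$mean, sd = x$sd, n = x$n,
             ci_low = x$ci_low, ci_high = x$ci_high)
}
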
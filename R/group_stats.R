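# Group-level statistics: living-only daily averaging, normalization to a
# control group, two-sample comparisons, and Tukey box-plot summaries.

#' Living-only daily group mean of a metric
#'
#' Per experiment day, the mean and SEM of a daily metric over the flies alive
#' on that day. Dead flies never contribute; days with no living fly carry no
#' value.
#'
#' @param summaries Row-bound [summarize_daily()] output for all flies of one
#'   group.
#' @param metric Column name, e.g. `"activity"`, `"sleep"`, `"sleep_short"`.
#' @param group Group label stored in the result.
#' @return A data.frame of class `group_daily`: `group`, `day`, `mean`, `sem`,
#'   `n`. `sem` is 0 by convention when `n = 1` (flagged by the `n` column).
#' @export
daily_living_mean <- function(summaries, metric = "activity", group = "group") {
  stopifnot(metric %in% names(summaries))
  alive <- summaries[summaries$alive & !is.na(summaries[[metric]]), ,
                     drop = FALSE]
  days <- sort(unique(alive$day))
  rows <- lapply(days, function(d) {
    v <- alive[[metric]][alive$day == d]
    data.frame(group = group, day = d, mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(0), day = integer(0),
                      mean = numeric(0), sem = numeric(0), n = integer(0))
  }
  class(out) <- c("group_daily", "data.frame")
  out
}

#' Daily series relative to a control group
#'
#' Per day, `100 * group mean / control mean` (control = 100%). Days on which
#' the control mean is 0 are undefined and flagged. Range summaries over day
#' windows are reported under both conventions, since they differ when daily
#' ratios vary: `mean_of_ratios` (the mean of the per-day percentages) and
#' `ratio_of_means` (100 x ratio of the range-averaged means).
#'
#' @param group,control [daily_living_mean()] outputs with overlapping days.
#' @param day_ranges A named list of integer day vectors over which to
#'   summarise, default the exercise-phase and post-phase windows
#'   `list(days_1_12 = 1:12, days_13_20 = 13:20)`.
#' @return A list: `daily` (data.frame `day`, `percent`, `undefined`) and
#'   `ranges` (data.frame `range`, `mean_of_ratios`, `ratio_of_means`).
#' @export
relative_to_control <- function(group, control,
                                day_ranges = list(days_1_12 = 1:12,
                                                  days_13_20 = 13:20)) {
  days <- intersect(group$day, control$day)
  if (length(days) == 0) stop("no overlapping day coverage")
  g <- group$mean[match(days, group$day)]
  c0 <- control$mean[match(days, control$day)]
  undefined <- c0 == 0
  pct <- ifelse(undefined, NA_real_, 100 * g / c0)
  daily <- data.frame(day = days, percent = pct, undefined = undefined)
  ranges <- do.call(rbind, lapply(names(day_ranges), function(nm) {
    sel <- daily$day %in% day_ranges[[nm]] & !daily$undefined
    gm <- mean(g[sel])
    cm <- mean(c0[sel])
    data.frame(range = nm,
               mean_of_ratios = if (any(sel)) mean(daily$percent[sel]) else NA_real_,
               ratio_of_means = if (any(sel) && cm > 0) 100 * gm / cm else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(daily = daily, ranges = ranges)
}

#' Significance stars for a p-value
#'
#' `*` for p < 0.05, `**` for p < 0.01, `***` for p < 0.001, `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Two-sample group comparison
#'
#' Two-tailed Student's t-test (Welch by default; pooled variance available)
#' or Mann-Whitney U test. The Mann-Whitney test uses the exact null
#' distribution when the combined sample size is at most 20 and there are no
#' ties, and the normal approximation with tie correction otherwise (the
#' default behavior of [stats::wilcox.test()]).
#'
#' @param a,b Numeric vectors of per-fly values, each of length >= 2.
#' @param test `"welch"`, `"student"` (pooled variance), or `"mann-whitney"`.
#' @return A list: `test`, `statistic`, `p`, `stars`.
#' @export
compare_groups <- function(a, b, test = c("welch", "student", "mann-whitney")) {
  test <- match.arg(test)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (test %in% c("welch", "student")) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: no variance in either sample
      p <- if (mean(a) == mean(b)) 1 else 0
      return(list(test = test, statistic = if (p == 1) 0 else Inf, p = p,
                  stars = p_stars(p)))
    }
    fit <- stats::t.test(a, b, var.equal = (test == "student"),
                         alternative = "two.sided")
    list(test = test, statistic = unname(fit$statistic), p = fit$p.value,
         stars = p_stars(fit$p.value))
  } else {
    exact <- (length(a) + length(b)) <= 20
    fit <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    list(test = test, statistic = unname(fit$statistic), p = fit$p.value,
         stars = p_stars(fit$p.value))
  }
}

#' Tukey box-plot summary
#'
#' Median, quartiles (linear-interpolation quantiles, R type 7), whiskers at
#' the most extreme points within 1.5 x IQR of the box, and the points beyond
#' the whiskers as outliers.
#'
#' @param values Numeric vector, length >= 1.
#' @return A list: `n`, `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
box_summary <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]))
}
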
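# Kaplan-Meier estimation, median survival, prolongation, and the two-group
# log-rank (Mantel-Cox) test, computed from per-fly death/censor times.

#' Build survival records from death calls
#'
#' @param deaths A list of [call_death()] results.
#' @param fly_ids Character labels, one per death call.
#' @param group Group label(s), recycled.
#' @param drop_never_active Drop flies flagged `"never_active"` (no movement
#'   in the whole recording; their time origin is undefined). Default `TRUE`;
#'   dropped flies are reported in the `dropped` attribute.
#' @return A data.frame of class `survival_records`: `fly_id`, `group`,
#'   `time` (days), `event` (logical).
#' @export
survival_records <- function(deaths, fly_ids = NULL, group = "group",
                             drop_never_active = TRUE) {
  if (inherits(deaths, "death_call")) deaths <- list(deaths)
  n <- length(deaths)
  if (is.null(fly_ids)) fly_ids <- sprintf("fly%02d", seq_len(n))
  out <- data.frame(
    fly_id = fly_ids,
    group = rep_len(group, n),
    time = vapply(deaths, function(d) d$days, numeric(1)),
    event = vapply(deaths, function(d) d$event, logical(1)),
    flag = vapply(deaths, function(d) d$flag, character(1)),
    stringsAsFactors = FALSE
  )
  dropped <- character(0)
  if (drop_never_active) {
    bad <- out$flag == "never_active"
    dropped <- out$fly_id[bad]
    out <- out[!bad, , drop = FALSE]
  }
  out$flag <- NULL
  class(out) <- c("survival_records", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival starts at 1, is non-increasing, and constant between event times;
#' censored subjects leave the risk set after their censoring time. The median
#' is the smallest time at which the survival estimate drops to 0.5 or below;
#' if the curve never reaches 0.5 the median is not reached (`NA`). With no
#' censoring the estimate equals the empirical survivor function.
#'
#' @param records A data.frame with numeric `time` and logical/0-1 `event`
#'   columns (e.g. from [survival_records()]).
#' @return An object of class `km_curve`: list with `time` (distinct event
#'   times), `n_risk`, `n_event`, `surv` (S(t) just after each event time),
#'   `median`, and `n`.
#' @examples
#' km <- km_estimate(data.frame(time = c(1, 2, 3, 4), event = TRUE))
#' km$median  # 2: smallest time with S(t) <= 0.5
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1, all(records$time > 0))
  time <- records$time
  event <- as.logical(records$event)
  ev_times <- sort(unique(time[event]))
  n <- length(time)
  surv <- numeric(length(ev_times))
  n_risk <- integer(length(ev_times))
  n_event <- integer(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk[i] <- sum(time >= t)
    n_event[i] <- sum(time == t & event)
    s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  med <- if (any(surv <= 0.5 + 1e-12)) {
    ev_times[which(surv <= 0.5 + 1e-12)[1]]
  } else {
    NA_real_
  }
  structure(list(time = ev_times, n_risk = n_risk, n_event = n_event,
                 surv = surv, median = med, n = n),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times, median = %s\n",
              x$n, length(x$time),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Standard two-sample log-rank chi-square with 1 degree of freedom; tied
#' event times are handled through the hypergeometric variance. The statistic
#' is symmetric in group order and invariant to a common rescaling of times.
#'
#' @param group_a,group_b Data.frames with `time` and `event` columns.
#' @return A list: `chisq`, `p`, `df` (= 1), `observed` and `expected` events
#'   per group.
#' @export
logrank_test <- function(group_a, group_b) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0) {
    stop("both groups must contain at least one subject")
  }
  time <- c(group_a$time, group_b$time)
  event <- as.logical(c(group_a$event, group_b$event))
  grp <- rep(c(0L, 1L), c(nrow(group_a), nrow(group_b)))
  if (!any(event)) stop("no events in either group")
  ev_times <- sort(unique(time[event]))
  o_a <- e_a <- v <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n_a <- sum(at_risk & grp == 0L)
    d_tot <- sum(time == t & event)
    d_a <- sum(time == t & event & grp == 0L)
    o_a <- o_a + d_a
    e_a <- e_a + d_tot * n_a / n_tot
    if (n_tot > 1) {
      v <- v + d_tot * (n_a / n_tot) * (1 - n_a / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  o_b <- sum(event[grp == 1L])
  e_b <- sum(event) - e_a
  chisq <- if (v > 0) (o_a - e_a)^2 / v else 0
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  list(chisq = chisq, p = p, df = 1L,
       observed = c(a = o_a, b = o_b), expected = c(a = e_a, b = e_b))
}

#' Median survival prolongation
#'
#' Difference and percent change of the treated median relative to the control
#' median. Example: medians 28.5 vs 21.5 days give a prolongation of 7.0 days
#' (32.6%).
#'
#' @param treated_median,control_median Median survival times (days); `NA`
#'   (median not reached) propagates.
#' @return A list: `difference_days`, `percent`.
#' @export
median_prolongation <- function(treated_median, control_median) {
  if (is.na(treated_median) || is.na(control_median)) {
    return(list(difference_days = NA_real_, percent = NA_real_))
  }
  stopifnot(control_median > 0)
  d <- treated_median - control_median
  list(difference_days = d, percent = 100 * d / control_median)
}
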
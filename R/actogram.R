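# ZT-aligned actogram matrices, average daily activity profiles, and their
# rendering with light/dark environmental bars.

#' Build a ZT-aligned actogram matrix
#'
#' One row per experiment day, 288 columns of 5-min bins with column 1 at ZT0
#' (column k covers ZT minutes `[5(k-1), 5k)`). Partial edge days are padded
#' with `NA`; masked bins become `NA` as well, so the matrix total equals the
#' series total over whole days.
#'
#' @param series An [activity_series()]; rebinned to 5 min if its bin width
#'   divides 5, otherwise it must already be at 5-min bins.
#' @param exercise Optional [stimulus_schedule()]; its active days become the
#'   `exercise_day` row annotation.
#' @return A numeric matrix of class `actogram_matrix` with `dimnames` row
#'   labels `day<k>`, and attributes `zt_breaks` and `exercise_day` (logical
#'   per row).
#' @export
actogram_matrix <- function(series, exercise = NULL) {
  stopifnot(inherits(series, "activity_series"))
  if (series$bin_minutes != 5) {
    if (5 %% series$bin_minutes == 0) {
      series <- rebin(series, 5)
    } else {
      stop("series must be at (or rebinnable to) 5-min bins")
    }
  }
  counts <- ifelse(series$mask, series$counts, NA_real_)
  # pad to whole ZT0-anchored days
  zt0 <- zt_hours(series$start, series$schedule)
  lead <- as.integer(round(zt0 * 12))            # 5-min bins before the first bin
  n <- lead + length(counts)
  n_days <- ceiling(n / 288)
  padded <- rep(NA_real_, n_days * 288)
  padded[lead + seq_along(counts)] <- counts
  m <- matrix(padded, nrow = n_days, ncol = 288, byrow = TRUE)
  rownames(m) <- sprintf("day%d", seq_len(n_days))
  ex_day <- if (!is.null(exercise)) seq_len(n_days) %in% exercise$active_days
            else rep(FALSE, n_days)
  structure(m, class = c("actogram_matrix", "matrix"),
            zt_breaks = seq(0, 24, by = 5 / 60)[1:288],
            exercise_day = ex_day)
}

#' Render an actogram
#'
#' Single-plotted actogram (one row of bars per day; double plotting by
#' option), with a yellow/gray LD environmental bar on top and a red marker
#' band over the exercise window on the active exercise days. The output is
#' deterministic for a fixed input and device settings. Missing bins are
#' rendered as gaps, not zeros.
#'
#' @param mat An [actogram_matrix()].
#' @param schedule A [light_schedule()] for the LD bar.
#' @param exercise Optional [stimulus_schedule()] for the red exercise marker.
#' @param file Output path; the device is chosen from the extension (`.png`
#'   or `.svg`).
#' @param double_plot If `TRUE`, plot each row as day d followed by day d+1
#'   (48 h per row).
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return Invisibly, `file`.
#' @export
render_actogram <- function(mat, schedule = light_schedule(),
                            exercise = NULL, file,
                            double_plot = FALSE,
                            width = if (grepl("\\.svg$", file)) 7 else 700,
                            height = if (grepl("\\.svg$", file)) 9 else 900) {
  stopifnot(inherits(mat, "actogram_matrix"))
  if (grepl("\\.svg$", file)) {
    grDevices::svg(file, width = width, height = height)
  } else {
    grDevices::png(file, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  n_days <- nrow(mat)
  hours_per_row <- if (double_plot) 48 else 24
  ex_day <- attr(mat, "exercise_day")
  ymax <- max(mat, 1, na.rm = TRUE)
  graphics::par(mar = c(3, 4, 2, 1))
  graphics::plot(NA, xlim = c(0, hours_per_row), ylim = c(n_days + 1.2, 0),
                 xlab = "ZT (h)", ylab = "day", xaxs = "i", yaxs = "i",
                 axes = FALSE)
  graphics::axis(1, at = seq(0, hours_per_row, by = 6))
  graphics::axis(2, at = seq_len(n_days) - 0.5, labels = seq_len(n_days),
                 las = 1, cex.axis = 0.7)
  # LD environmental bar above the rows (row y in [-0.0 .. ]): lights-on
  # yellow, dark gray
  reps <- if (double_plot) 2 else 1
  for (r in seq_len(reps)) {
    off <- (r - 1) * 24
    graphics::rect(off + 0, -0.0, off + schedule$hours_light, -0.0 + 0.2,
                   col = "gold", border = NA)
    graphics::rect(off + schedule$hours_light, 0, off + 24, 0.2,
                   col = "gray60", border = NA)
  }
  draw_day <- function(day, x_off) {
    v <- mat[day, ]
    x <- attr(mat, "zt_breaks") + x_off
    ok <- !is.na(v)
    h <- 0.85 * v / ymax
    graphics::rect(x[ok], day, x[ok] + 5 / 60, day - h[ok],
                   col = "black", border = NA)
    if (!is.null(exercise) && ex_day[day]) {
      graphics::rect(x_off + exercise$start_zt, day - 0.9,
                     x_off + exercise$start_zt + exercise$duration_min / 60,
                     day, border = "red", col = NA, lwd = 1.2)
    }
  }
  for (d in seq_len(n_days)) {
    draw_day(d, 0)
    if (double_plot && d < n_days) draw_day(d + 1, 24)
  }
  graphics::box()
  invisible(file)
}

#' Average daily activity profile
#'
#' Mean beam-crossing counts per ZT-aligned 5-min bin across flies and days
#' (288 values), restricted to fly-days on which the fly was alive, mirroring
#' the living-only averaging of the daily group statistics.
#'
#' @param series_list A list of [activity_series()].
#' @param deaths Optional list of [call_death()] results (one per series);
#'   computed if `NULL`.
#' @param day_range Integer vector of experiment days to include, e.g. `1:12`.
#' @return Numeric vector of length 288 (mean counts per 5-min bin), with
#'   attribute `n_fly_days`.
#' @export
daily_profile <- function(series_list, deaths = NULL, day_range = 1:12) {
  if (inherits(series_list, "activity_series")) series_list <- list(series_list)
  if (is.null(deaths)) deaths <- lapply(series_list, call_death)
  acc <- matrix(0, 0, 288)
  for (i in seq_along(series_list)) {
    m <- actogram_matrix(series_list[[i]])
    death_day <- if (deaths[[i]]$event) floor(deaths[[i]]$days) + 1 else Inf
    keep <- intersect(day_range, seq_len(nrow(m)))
    keep <- keep[keep < death_day]
    # only whole days (no NA padding) enter the profile
    keep <- keep[rowSums(is.na(m[keep, , drop = FALSE])) == 0]
    if (length(keep)) acc <- rbind(acc, m[keep, , drop = FALSE])
  }
  if (nrow(acc) == 0) {
    return(structure(rep(NA_real_, 288), n_fly_days = 0L))
  }
  structure(colMeans(acc), n_fly_days = nrow(acc))
}
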
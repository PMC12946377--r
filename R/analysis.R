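## Summary outputs: growth trajectories, feed conversion ratios and error
## metrics against a reference series.

#' Per-day population summary
#'
#' Mean and sample (n-1) standard deviation of body mass and fork length
#' for each day present in a record table.
#'
#' @param records A record data frame (columns `day`, `W_g`, `FL_cm`).
#' @return Data frame with columns `day`, `n`, `mean_W_g`, `sd_W_g`,
#'   `mean_FL_cm`, `sd_FL_cm`.
#' @examples
#' recs <- data.frame(day = c(1, 1), id = 1:2, W_g = c(1, 3),
#'                    FL_cm = c(4, 5))
#' summarize_growth(recs)
#' @export
summarize_growth <- function(records) {
  stopifnot(all(c("day", "W_g", "FL_cm") %in% names(records)))
  days <- sort(unique(records$day))
  out <- do.call(rbind, lapply(days, function(d) {
    r <- records[records$day == d, ]
    data.frame(day = d, n = nrow(r),
               mean_W_g = mean(r$W_g),
               sd_W_g = if (nrow(r) > 1) sd(r$W_g) else 0,
               mean_FL_cm = mean(r$FL_cm),
               sd_FL_cm = if (nrow(r) > 1) sd(r$FL_cm) else 0)
  }))
  rownames(out) <- NULL
  out
}

#' Feed conversion ratio per interval
#'
#' FCR = feed mass supplied / population wet-mass gain, per day interval.
#' The numerator is the scheduled per-individual ration (times the feed
#' multiplier, times the number of fish) summed over the interval's days;
#' the denominator is the net population mass gain from the interval's
#' start (state at `start_day - 1`, so day-0 records are used for the
#' first interval) to its end. Intervals with non-positive gain get an
#' `NA` FCR and are flagged, never infinite.
#'
#' @param records A record table including day-0 rows (see
#'   [run_simulation()]).
#' @param schedule The feeding schedule used (columns `day`,
#'   `feed_per_individual_g`).
#' @param intervals List of `c(start_day, end_day)` pairs, or `NULL` to
#'   split the simulated range into `interval_length`-day intervals.
#' @param interval_length Default interval length in days.
#' @param feed_multiplier Feeding-level multiplier applied to the
#'   schedule.
#' @return Data frame with columns `start_day`, `end_day`,
#'   `feed_mass_total_g`, `mass_gain_total_g`, `fcr`, `defined`.
#' @examples
#' recs <- data.frame(day = rep(0:2, each = 2), id = rep(1:2, 3),
#'                    W_g = c(10, 10, 12, 12, 15, 15))
#' sch <- make_schedule("constant_g", n_days = 2, grams = 3)
#' compute_fcr(recs, sch, intervals = list(c(1, 2)), n_individuals = 2)
#' @param n_individuals Number of fish fed; defaults to the number of
#'   distinct ids in `records`.
#' @export
compute_fcr <- function(records, schedule, intervals = NULL,
                        interval_length = 30, feed_multiplier = 1,
                        n_individuals = NULL) {
  stopifnot(all(c("day", "W_g") %in% names(records)))
  max_day <- max(records$day)
  if (is.null(n_individuals))
    n_individuals <- length(unique(records$id))
  if (is.null(intervals)) {
    starts <- seq(1, max_day, by = interval_length)
    intervals <- lapply(starts, function(s)
      c(s, min(s + interval_length - 1, max_day)))
  }
  total_W <- function(d) sum(records$W_g[records$day == d])
  out <- do.call(rbind, lapply(intervals, function(iv) {
    s <- iv[1]; e <- iv[2]
    if (s < 1 || e > max_day || !(s - 1) %in% records$day)
      stop("interval [", s, ", ", e, "] outside the simulated range")
    days <- schedule$day >= s & schedule$day <= e
    fed <- sum(schedule$feed_per_individual_g[days]) * feed_multiplier *
      n_individuals
    gain <- total_W(e) - total_W(s - 1)
    data.frame(start_day = s, end_day = e, feed_mass_total_g = fed,
               mass_gain_total_g = gain,
               fcr = if (gain > 0) fed / gain else NA_real_,
               defined = gain > 0)
  }))
  rownames(out) <- NULL
  out
}

#' Error metrics against a reference series
#'
#' For each day present in both series: the absolute error
#' `|simulated - reference|` and the absolute percentage error
#' `|simulated - reference| * 100 / reference`.
#'
#' @param sim_series Data frame with columns `day` and `value`
#'   (simulated).
#' @param ref_series Data frame with columns `day` and `value`
#'   (reference); values must be nonzero for the percentage error.
#' @return Data frame with columns `day`, `sim`, `ref`, `abs_error`,
#'   `abs_pct_error`.
#' @examples
#' error_metrics(data.frame(day = 1, value = 120),
#'               data.frame(day = 1, value = 100))
#' @export
error_metrics <- function(sim_series, ref_series) {
  stopifnot(all(c("day", "value") %in% names(sim_series)),
            all(c("day", "value") %in% names(ref_series)))
  m <- merge(sim_series, ref_series, by = "day",
             suffixes = c("_sim", "_ref"))
  if (nrow(m) == 0) stop("no matched days between the two series")
  if (any(m$value_ref == 0))
    stop("reference values must be nonzero for the percentage error")
  data.frame(day = m$day, sim = m$value_sim, ref = m$value_ref,
             abs_error = abs(m$value_sim - m$value_ref),
             abs_pct_error = abs(m$value_sim - m$value_ref) * 100 /
               m$value_ref)
}
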
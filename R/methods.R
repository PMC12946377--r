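## S3 methods for simulation results.

#' @export
print.trout_sim <- function(x, ...) {
  n <- x$config$n_individuals
  nd <- x$config$n_days
  final <- x$records[x$records$day == nd, ]
  cat("Coupled schooling / DEB aquaculture simulation\n")
  cat(sprintf("  %d fish, %d days, %.1f K, feed multiplier %.2f, seed %d\n",
              n, nd, x$config$temperature_K, x$config$feed_multiplier,
              x$config$seed))
  cat(sprintf("  final body mass:  %.2f +/- %.2f g\n",
              mean(final$W_g), sd(final$W_g)))
  cat(sprintf("  final fork length: %.2f +/- %.2f cm\n",
              mean(final$FL_cm), sd(final$FL_cm)))
  invisible(x)
}

#' Per-day growth summary
#'
#' Population mean and sample (n-1) standard deviation of body mass and
#' fork length for each simulated day.
#'
#' @param object A `trout_sim` object.
#' @param ... Unused.
#' @return A data frame (`day`, `n`, `mean_W_g`, `sd_W_g`, `mean_FL_cm`,
#'   `sd_FL_cm`), also of class `summary.trout_sim`.
#' @export
summary.trout_sim <- function(object, ...) {
  out <- summarize_growth(object$records)
  class(out) <- c("summary.trout_sim", class(out))
  out
}

#' @export
print.summary.trout_sim <- function(x, ...) {
  cat("Per-day population summary (first/last days shown)\n")
  y <- x
  class(y) <- "data.frame"
  n <- nrow(y)
  show <- if (n > 12) rbind(head(y, 6), tail(y, 6)) else y
  print(show, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot growth trajectories
#'
#' Mean body-mass (or fork-length) trajectory with a +/- 1 s.d. band.
#'
#' @param x A `trout_sim` object.
#' @param what `"mass"` or `"length"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the per-day summary.
#' @export
plot.trout_sim <- function(x, what = c("mass", "length"), ...) {
  what <- match.arg(what)
  s <- summarize_growth(x$records)
  m <- if (what == "mass") s$mean_W_g else s$mean_FL_cm
  dev <- if (what == "mass") s$sd_W_g else s$sd_FL_cm
  ylab <- if (what == "mass") "body mass (g)" else "fork length (cm)"
  graphics::plot(s$day, m, type = "l", lwd = 2, xlab = "day", ylab = ylab,
                 ylim = range(m - dev, m + dev), ...)
  graphics::lines(s$day, m + dev, lty = 2)
  graphics::lines(s$day, pmax(m - dev, 0), lty = 2)
  invisible(s)
}

#' @export
print.trout_sensitivity <- function(x, ...) {
  cat("Feeding-level sensitivity analysis\n")
  for (i in seq_along(x$runs)) {
    run <- x$runs[[i]]
    final <- run$records[run$records$day == run$config$n_days, ]
    cat(sprintf("  x%-4s  final mean W %7.2f g, mean FL %5.2f cm\n",
                names(x$runs)[i], mean(final$W_g), mean(final$FL_cm)))
  }
  invisible(x)
}

#' Summary of a sensitivity analysis
#'
#' @param object A `trout_sensitivity` object.
#' @param ... Unused.
#' @return Data frame with one row per multiplier: final mean/s.d. of body
#'   mass and fork length.
#' @export
summary.trout_sensitivity <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$runs), function(i) {
    run <- object$runs[[i]]
    final <- run$records[run$records$day == run$config$n_days, ]
    data.frame(multiplier = object$multipliers[i],
               mean_W_g = mean(final$W_g), sd_W_g = sd(final$W_g),
               mean_FL_cm = mean(final$FL_cm), sd_FL_cm = sd(final$FL_cm))
  }))
}

#' @export
plot.trout_sensitivity <- function(x, ...) {
  ss <- lapply(x$runs, function(r) summarize_growth(r$records))
  ylim <- range(unlist(lapply(ss, function(s) s$mean_W_g)))
  graphics::plot(NA, xlim = range(ss[[1]]$day), ylim = ylim,
                 xlab = "day", ylab = "mean body mass (g)", ...)
  for (i in seq_along(ss))
    graphics::lines(ss[[i]]$day, ss[[i]]$mean_W_g, lty = i, lwd = 2)
  graphics::legend("topleft", legend = paste0("x", names(x$runs)),
                   lty = seq_along(ss), lwd = 2, bty = "n")
  invisible(ss)
}
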
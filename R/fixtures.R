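## Synthetic input generators: populations, feeding schedules and small
## test scenes.  Everything is reproducible under a seed and passes the
## package's own validators.

#' Generate an initial population of fork lengths
#'
#' Draws `n` fork lengths from a normal distribution truncated below at
#' `fl_min` (values at or below it are resampled). Defaults reproduce the
#' reference initial stock: 212 fish, 5.68 +/- 0.69 cm.
#'
#' @param n Number of fish.
#' @param fl_mean,fl_sd Mean and s.d. (cm).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @param fl_min Lower truncation bound (cm).
#' @return Numeric vector of fork lengths (cm).
#' @examples
#' make_population(5, seed = 1)
#' @export
make_population <- function(n = 212, fl_mean = 5.68, fl_sd = 0.69,
                            seed = NULL, fl_min = 1) {
  stopifnot(n >= 1, fl_mean > 0, fl_sd >= 0)
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister",
                               normal.kind = "Inversion")
  fl <- rnorm(n, fl_mean, fl_sd)
  while (any(bad <- fl <= fl_min))
    fl[bad] <- rnorm(sum(bad), fl_mean, fl_sd)
  fl
}

#' Generate a feeding schedule
#'
#' Builds a day-indexed per-individual feeding schedule. Patterns:
#' `constant_g` feeds a fixed mass per fish per day; `percent_bw` feeds a
#' fixed fraction of the projected mean body mass, with the projection
#' advanced one DEB day at a time assuming the ration is fully consumed;
#' `table` passes through user-supplied values. Feed labels follow the
#' day ranges of the default feed-type table (days past its end keep the
#' last feed).
#'
#' @param pattern One of `"constant_g"`, `"percent_bw"`, `"table"`.
#' @param n_days Number of days to cover.
#' @param grams Per-individual daily feed mass (g) for `constant_g`.
#' @param fraction Ration as a fraction of mean body mass for
#'   `percent_bw`.
#' @param values Per-day per-individual masses (g) for `table`.
#' @param fl_mean Initial mean fork length (cm) for the `percent_bw`
#'   projection.
#' @param temperature_K Water temperature for the projection.
#' @param feed_table Feed-type table (see [feed_types()]).
#' @param deb A [deb_params()] object (projection only).
#' @return A schedule data frame (`day`, `feed_per_individual_g`,
#'   `feed_label`).
#' @examples
#' make_schedule("constant_g", n_days = 5, grams = 0.1)
#' make_schedule("percent_bw", n_days = 5, fraction = 0.03)
#' @export
make_schedule <- function(pattern = c("constant_g", "percent_bw", "table"),
                          n_days, grams = NULL, fraction = NULL,
                          values = NULL, fl_mean = 5.68,
                          temperature_K = 283.15,
                          feed_table = feed_types(), deb = deb_params()) {
  pattern <- match.arg(pattern)
  stopifnot(n_days >= 1)
  days <- seq_len(n_days)
  labels <- vapply(days, function(d)
    feed_for_day(d, feed_table)$label, character(1))
  mass <- switch(pattern,
    constant_g = {
      stopifnot(!is.null(grams), grams >= 0)
      rep(grams, n_days)
    },
    percent_bw = {
      stopifnot(!is.null(fraction), fraction >= 0)
      W <- mass_from_fl(fl_mean, deb)
      state <- init_state_from_mass(W, params = deb)
      out <- numeric(n_days)
      for (d in days) {
        out[d] <- fraction * W
        feed <- feed_for_day(d, feed_table)
        state <- integrate_day(state, out[d], feed, temperature_K, deb,
                               substeps = 24)
        W <- mass_from_state(state, deb)
      }
      out
    },
    table = {
      stopifnot(!is.null(values), length(values) == n_days,
                all(values >= 0))
      as.numeric(values)
    })
  data.frame(day = days, feed_per_individual_g = mass,
             feed_label = labels, stringsAsFactors = FALSE)
}

#' Build a small deterministic test scene
#'
#' Miniature configurations of fish and pellets for unit tests. Without a
#' seed, fish are placed collinearly along the x axis at mid-depth, 5 cm
#' apart and centred on the tank axis, with zero velocity; pellets sit near
#' the surface above the tank centre. With a seed, positions are drawn
#' uniformly (reproducibly) instead.
#'
#' @param n_fish,n_pellets Counts (>= 0).
#' @param geometry A [tank_geometry()] object.
#' @param seed Optional seed for randomized placement.
#' @param fl_cm Fork length given to every fish (cm).
#' @param pellet_g Pellet weight (g).
#' @return List with data frames `agents` (id, x, y, z, vx, vy, vz,
#'   mass_g, fl_cm) and `pellets` (x, y, z, weight_g, active).
#' @examples
#' make_toy_scene(3, 1)
#' @export
make_toy_scene <- function(n_fish, n_pellets, geometry = tank_geometry(),
                           seed = NULL, fl_cm = 6, pellet_g = 0.005) {
  stopifnot(n_fish >= 0, n_pellets >= 0)
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister",
                               normal.kind = "Inversion")
  if (n_fish > 0) {
    if (is.null(seed)) {
      xs <- (seq_len(n_fish) - (n_fish + 1) / 2) * 0.05
      xyz <- cbind(x = xs, y = 0, z = geometry$depth / 2)
    } else {
      xyz <- uniform_tank_positions(n_fish, geometry)
    }
    agents <- data.frame(id = seq_len(n_fish), x = xyz[, 1], y = xyz[, 2],
                         z = xyz[, 3], vx = 0, vy = 0, vz = 0,
                         mass_g = mass_from_fl(fl_cm),
                         fl_cm = fl_cm)
  } else {
    agents <- data.frame(id = integer(), x = numeric(), y = numeric(),
                         z = numeric(), vx = numeric(), vy = numeric(),
                         vz = numeric(), mass_g = numeric(),
                         fl_cm = numeric())
  }
  if (n_pellets > 0) {
    if (is.null(seed)) {
      px <- cbind(x = rep(0, n_pellets), y = 0,
                  z = geometry$depth - 0.01 * seq_len(n_pellets))
    } else {
      r <- geometry$radius / 3 * sqrt(runif(n_pellets))
      th <- runif(n_pellets, 0, 2 * pi)
      px <- cbind(x = r * cos(th), y = r * sin(th), z = geometry$depth)
    }
    pellets <- data.frame(x = px[, 1], y = px[, 2], z = px[, 3],
                          weight_g = pellet_g, active = TRUE)
  } else {
    pellets <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                          weight_g = numeric(), active = logical())
  }
  list(agents = agents, pellets = pellets)
}
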
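## Daily simulation loop: behavior day -> intake -> growth integration ->
## position randomization, repeated over the feeding schedule.

#' Simulation configuration
#'
#' Bundles everything a run needs: population size and initial-size
#' distribution, tank geometry, water temperature, behavioral and DEB
#' parameters, the feeding schedule and a seed. The defaults reproduce the
#' reference rearing setup: 212 rainbow trout of initial fork length
#' 5.68 +/- 0.69 cm in a 0.9 m diameter, 0.6 m deep tank at 10 degC.
#'
#' @param schedule Feeding schedule: a data frame with columns `day`
#'   (contiguous from 1), `feed_per_individual_g` and `feed_label`, e.g.
#'   from [make_schedule()] or [read_schedule()].
#' @param n_individuals Number of fish (held constant; no mortality).
#' @param tank A [tank_geometry()] object.
#' @param temperature_K Water temperature (K).
#' @param n_days Number of days to simulate; defaults to the schedule
#'   length.
#' @param behavior A [behavior_params()] object.
#' @param deb A [deb_params()] object.
#' @param feed_multiplier Scaling applied to every scheduled ration (the
#'   sensitivity-analysis dial).
#' @param seed Integer RNG seed; every source of randomness in a run flows
#'   from it.
#' @param fl_mean,fl_sd Mean and s.d. (cm) of the initial fork-length
#'   distribution.
#' @param reserve_fraction Initial fraction of body mass held as reserve
#'   (see [init_state_from_mass()]).
#' @param substeps RK4 substeps per growth day.
#' @param feed_table Feed-type table used to resolve schedule labels.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- simulation_config(make_schedule("constant_g", n_days = 3,
#'                                        grams = 0.1),
#'                          n_individuals = 10, seed = 1)
#' @export
simulation_config <- function(schedule, n_individuals = 212,
                              tank = tank_geometry(),
                              temperature_K = 283.15, n_days = NULL,
                              behavior = behavior_params(),
                              deb = deb_params(), feed_multiplier = 1.0,
                              seed = 1, fl_mean = 5.68, fl_sd = 0.69,
                              reserve_fraction = 0.3, substeps = 240,
                              feed_table = feed_types()) {
  stopifnot(n_individuals >= 1, feed_multiplier >= 0, temperature_K > 0)
  schedule <- resolve_schedule(schedule, feed_table)
  if (is.null(n_days)) n_days <- max(schedule$day)
  if (n_days < 1 || n_days > max(schedule$day))
    stop("n_days must be in 1..", max(schedule$day),
         " (the schedule's coverage)")
  structure(list(n_individuals = as.integer(n_individuals), tank = tank,
                 temperature_K = temperature_K, n_days = as.integer(n_days),
                 behavior = behavior, deb = deb, schedule = schedule,
                 feed_multiplier = feed_multiplier, seed = as.integer(seed),
                 fl_mean = fl_mean, fl_sd = fl_sd,
                 reserve_fraction = reserve_fraction,
                 substeps = substeps),
            class = "sim_config")
}

# Attach energy density and pellet weight to a schedule by feed label.
resolve_schedule <- function(schedule, feed_table = feed_types()) {
  req <- c("day", "feed_per_individual_g", "feed_label")
  if (!all(req %in% names(schedule)))
    stop("schedule must have columns: ", paste(req, collapse = ", "))
  if (!identical(as.integer(schedule$day), seq_len(nrow(schedule))))
    stop("schedule days must be contiguous from 1")
  if (any(schedule$feed_per_individual_g < 0))
    stop("scheduled feed masses must be >= 0")
  if (!all(c("energy_J_per_g", "pellet_g") %in% names(schedule))) {
    i <- match(schedule$feed_label, feed_table$label)
    if (anyNA(i))
      stop("unknown feed label(s): ",
           paste(unique(schedule$feed_label[is.na(i)]), collapse = ", "))
    schedule$energy_J_per_g <- feed_table$energy_J_per_g[i]
    schedule$pellet_g <- feed_table$pellet_g[i]
  }
  schedule
}

# Uniform positions inside the tank cylinder, 1 mm clear of the walls.
uniform_tank_positions <- function(n, tank) {
  m <- 1e-3
  r <- (tank$radius - m) * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th),
        z = runif(n, m, tank$depth - m))
}

#' Initialize a simulated population
#'
#' Samples fork lengths from a normal distribution truncated at > 1 cm
#' (resampling below), derives masses through the allometric relation,
#' partitions each mass into a DEB state, and scatters the fish uniformly
#' in the tank with zero velocity. Consumes the current RNG stream.
#'
#' @param config A [simulation_config()] object.
#' @return List with `agents` (data frame: id, x, y, z, vx, vy, vz, mass_g,
#'   fl_cm) and `state` (list G, E, V).
#' @examples
#' cfg <- simulation_config(make_schedule("constant_g", n_days = 1,
#'                                        grams = 0.1),
#'                          n_individuals = 5, seed = 1)
#' set.seed(cfg$seed)
#' initialize_population(cfg)
#' @export
initialize_population <- function(config) {
  n <- config$n_individuals
  fl <- make_population(n, config$fl_mean, config$fl_sd)
  W <- mass_from_fl(fl, config$deb)
  state <- init_state_from_mass(W, config$reserve_fraction, config$deb)
  xyz <- uniform_tank_positions(n, config$tank)
  agents <- data.frame(id = seq_len(n), x = xyz[, 1], y = xyz[, 2],
                       z = xyz[, 3], vx = 0, vy = 0, vz = 0,
                       mass_g = W, fl_cm = fl)
  list(agents = agents, state = state)
}

#' Randomize fish positions
#'
#' Redraws all positions uniformly inside the tank and zeroes velocities,
#' leaving masses, lengths and growth state untouched. Applied at the end
#' of every simulated day to avoid carry-over of spatial patterns.
#'
#' @param agents Agent data frame (see [initialize_population()]).
#' @param tank A [tank_geometry()] object.
#' @return The agent data frame with new positions and zero velocities.
#' @export
randomize_positions <- function(agents, tank = tank_geometry()) {
  xyz <- uniform_tank_positions(nrow(agents), tank)
  agents$x <- xyz[, 1]; agents$y <- xyz[, 2]; agents$z <- xyz[, 3]
  agents$vx <- 0; agents$vy <- 0; agents$vz <- 0
  agents
}

day_records <- function(day, agents, state, S, nf) {
  data.frame(day = day, id = agents$id, W_g = agents$mass_g,
             FL_cm = agents$fl_cm, G_J = state$G, E_J = state$E,
             V_cm3 = state$V, S_g = S, Nf = as.integer(nf))
}

#' Simulate one day
#'
#' One iteration of the daily loop: reset intake counters, run the
#' behavioral episode with the day's scheduled ration (times the feed
#' multiplier, times the number of fish), feed each individual's intake to
#' the growth integrator, update mass and fork length, and randomize
#' positions for the next day.
#'
#' @param day Day index (1-based; selects the schedule row and feed type).
#' @param pop Population list (`agents`, `state`).
#' @param config A [simulation_config()] object.
#' @return List with the updated `pop`, the day's `records` data frame and
#'   behavioral `diagnostics`.
#' @export
simulate_day <- function(day, pop, config) {
  sched <- config$schedule[day, ]
  feed <- feed_spec(sched$energy_J_per_g, sched$pellet_g, sched$feed_label)
  total <- sched$feed_per_individual_g * config$feed_multiplier *
    config$n_individuals
  beh <- run_behavior_day(
    as.matrix(pop$agents[, c("x", "y", "z")]),
    as.matrix(pop$agents[, c("vx", "vy", "vz")]),
    pop$agents$mass_g, pop$agents$fl_cm, total, feed,
    config$tank, config$behavior)
  S <- intake_mass(beh$nf, feed$pellet_g)
  state <- integrate_day(pop$state, S, feed, config$temperature_K,
                         config$deb, config$substeps)
  pop$state <- state
  pop$agents$mass_g <- mass_from_state(state, config$deb)
  pop$agents$fl_cm <- fl_from_mass(pop$agents$mass_g, config$deb)
  rec <- day_records(day, pop$agents, state, S, beh$nf)
  pop$agents <- randomize_positions(pop$agents, config$tank)
  diag <- data.frame(day = day, released = beh$released,
                     consumed = beh$consumed, expired = beh$expired,
                     remaining = beh$remaining,
                     max_speed_excess = beh$max_speed_excess,
                     max_intake_excess = beh$max_intake_excess,
                     max_containment_excess = beh$max_containment_excess)
  list(pop = pop, records = rec, diagnostics = diag)
}

#' Run a full simulation
#'
#' Runs the daily behavior-growth loop over the configured schedule and
#' returns a `trout_sim` object holding the per-individual per-day record
#' table (including a day-0 row per fish for the initial state), behavioral
#' diagnostics, and an end-of-run checkpoint from which the run can be
#' resumed.
#'
#' @param config A [simulation_config()] object.
#' @param checkpoint Optional checkpoint from a previous (shorter) run with
#'   the same configuration; simulation resumes after its last completed
#'   day and reproduces the uninterrupted run exactly.
#' @param quiet Suppress per-day progress messages.
#' @return An object of class `trout_sim` with components `records`,
#'   `diagnostics`, `config` and `checkpoint`.
#' @examples
#' cfg <- simulation_config(make_schedule("constant_g", n_days = 2,
#'                                        grams = 0.05),
#'                          n_individuals = 5, seed = 1)
#' sim <- run_simulation(cfg)
#' summary(sim)
#' @export
run_simulation <- function(config, checkpoint = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  records <- list()
  diags <- list()
  if (is.null(checkpoint)) {
    set.seed(config$seed, kind = "Mersenne-Twister",
             normal.kind = "Inversion")
    pop <- initialize_population(config)
    records[["0"]] <- day_records(0L, pop$agents, pop$state,
                                  rep(0, config$n_individuals),
                                  rep(0L, config$n_individuals))
    start <- 1L
  } else {
    assign(".Random.seed", checkpoint$rng_state, envir = globalenv())
    pop <- checkpoint$pop
    start <- checkpoint$day + 1L
  }
  if (start <= config$n_days) for (day in start:config$n_days) {
    step <- simulate_day(day, pop, config)
    pop <- step$pop
    records[[as.character(day)]] <- step$records
    diags[[as.character(day)]] <- step$diagnostics
    if (!quiet)
      message(sprintf("day %3d: mean W %.2f g, fed %d pellets, ate %d",
                      day, mean(pop$agents$mass_g),
                      step$diagnostics$released,
                      step$diagnostics$consumed))
  }
  structure(list(
    records = do.call(rbind, c(records, list(make.row.names = FALSE))),
    diagnostics = if (length(diags))
      do.call(rbind, c(diags, list(make.row.names = FALSE))) else NULL,
    config = config,
    checkpoint = list(day = config$n_days, pop = pop,
                      rng_state = get(".Random.seed",
                                      envir = globalenv()))),
    class = "trout_sim")
}

#' Feeding-level sensitivity analysis
#'
#' Repeats a simulation with the scheduled ration scaled by each
#' multiplier, using the same seed (hence an identical initial population
#' and random stream start) for every scenario.
#'
#' @param config A [simulation_config()] object.
#' @param multipliers Positive feeding-level multipliers.
#' @param quiet Suppress progress messages.
#' @return An object of class `trout_sensitivity`: a named list of
#'   `trout_sim` runs plus the multipliers.
#' @examples
#' cfg <- simulation_config(make_schedule("constant_g", n_days = 2,
#'                                        grams = 0.05),
#'                          n_individuals = 5, seed = 1)
#' sens <- run_sensitivity(cfg, c(0.7, 1.0, 1.3))
#' summary(sens)
#' @export
run_sensitivity <- function(config, multipliers = c(0.7, 1.0, 1.3),
                            quiet = TRUE) {
  stopifnot(all(multipliers > 0))
  runs <- lapply(multipliers, function(m) {
    cfg <- config
    cfg$feed_multiplier <- config$feed_multiplier * m
    run_simulation(cfg, quiet = quiet)
  })
  names(runs) <- format(multipliers)
  structure(list(runs = runs, multipliers = multipliers, config = config),
            class = "trout_sensitivity")
}
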
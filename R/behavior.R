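## Boids-style behavior model: R surface.
##
## The per-step loop of a behavioral day is implemented in C++
## (src/behavior.cpp); the functions here expose the individual model
## operations and a thin wrapper around the compiled day stepper.

unit_or_zero <- function(v) {
  v <- unname(v)
  n <- sqrt(sum(v^2))
  if (n == 0) c(0, 0, 0) else v / n
}

random_unit_vector <- function() {
  repeat {
    d <- runif(3, -1, 1)
    if (any(d != 0)) return(d / sqrt(sum(d^2)))
  }
}

#' Neighbors within the field of view
#'
#' Returns the indices of the agents visible from agent `i`: those within
#' `fov_radius_multiplier * FL` of it and outside the backward "dead space"
#' cone of half-angle `dead_space_half_angle` about the direction opposite
#' to its velocity. A stationary agent has no dead space.
#'
#' @param i Index (1-based) of the focal agent.
#' @param pos `n x 3` matrix of positions (m).
#' @param vel `n x 3` matrix of velocities (m/s).
#' @param fl_cm Fork lengths (cm).
#' @param params A [behavior_params()] object.
#' @return Integer vector of visible agent indices (possibly empty).
#' @examples
#' pos <- rbind(c(0, 0, 0), c(0.05, 0, 0), c(-0.05, 0, 0))
#' vel <- rbind(c(0.1, 0, 0), c(0, 0, 0), c(0, 0, 0))
#' neighbors_in_fov(1, pos, vel, fl_cm = c(6, 6, 6))  # behind agent 1 hidden
#' @export
neighbors_in_fov <- function(i, pos, vel, fl_cm, params = behavior_params()) {
  .cpp_neighbors_in_fov(as.integer(i), as.matrix(pos), as.matrix(vel),
                        as.numeric(fl_cm), params$fov_radius_multiplier,
                        params$dead_space_half_angle)
}

#' Behavioral rule forces
#'
#' Each rule yields a unit direction scaled by its weight `w`, so the
#' magnitude of every rule force is either `w` or 0.
#' `force_separation` points from the nearest visible neighbor toward the
#' focal fish; `force_cohesion` toward the centroid of visible neighbors;
#' `force_alignment` along the difference between the mean neighbor velocity
#' and the focal fish's own; `force_bound` from the nearest boundary point
#' toward the fish (zero when the boundary is outside the field of view);
#' `force_inertia` along the current velocity; `force_feed` toward the
#' nearest visible pellet; `force_random` along a uniform random direction.
#'
#' @param self_pos,nearest_pos,boundary_pos,pellet_pos 3-vectors (m).
#' @param self_vel 3-vector velocity (m/s).
#' @param visible Matrix (rows = visible neighbors) of positions.
#' @param visible_vels Matrix of visible neighbors' velocities.
#' @param w Rule weight (for `force_feed`, the mode-dependent feed weight).
#' @param fov_radius Field-of-view radius (m) used to gate the boundary
#'   force.
#' @param draws Three uniform draws on `[-1, 1]` (redrawn internally if all
#'   zero).
#' @return A 3-vector force.
#' @examples
#' force_separation(c(0, 0, 0), c(1, 0, 0), 1.0)
#' force_cohesion(c(0, 0, 0), rbind(c(2, 0, 0), c(4, 0, 0)), 0.2)
#' @export
force_separation <- function(self_pos, nearest_pos, w) {
  d <- unname(self_pos - nearest_pos)
  if (all(d == 0)) return(w * random_unit_vector())
  w * d / sqrt(sum(d^2))
}

#' @rdname force_separation
#' @export
force_cohesion <- function(self_pos, visible, w) {
  if (is.null(visible) || NROW(visible) == 0L) return(c(0, 0, 0))
  centroid <- colMeans(rbind(visible))
  w * unit_or_zero(centroid - self_pos)
}

#' @rdname force_separation
#' @export
force_alignment <- function(self_vel, visible_vels, w) {
  if (is.null(visible_vels) || NROW(visible_vels) == 0L) return(c(0, 0, 0))
  w * unit_or_zero(colMeans(rbind(visible_vels)) - self_vel)
}

#' @rdname force_separation
#' @export
force_bound <- function(self_pos, boundary_pos, w, fov_radius = Inf) {
  d <- self_pos - boundary_pos
  dist <- sqrt(sum(d^2))
  if (dist > fov_radius || dist == 0) return(c(0, 0, 0))
  w * d / dist
}

#' @rdname force_separation
#' @export
force_inertia <- function(self_vel, w) {
  w * unit_or_zero(self_vel)
}

#' @rdname force_separation
#' @export
force_feed <- function(self_pos, pellet_pos, w) {
  if (is.null(pellet_pos) || w == 0) return(c(0, 0, 0))
  w * unit_or_zero(pellet_pos - self_pos)
}

#' @rdname force_separation
#' @export
force_random <- function(draws = runif(3, -1, 1), w = 0.2) {
  if (all(draws == 0)) draws <- runif(3, -1, 1)
  w * draws / sqrt(sum(draws^2))
}

#' Total swimming force
#'
#' Component-wise sum of the seven rule forces.
#'
#' @param components List of 3-vector rule forces.
#' @return A 3-vector.
#' @examples
#' total_force(list(c(1, 0, 0), c(0, 0.2, 0)))
#' @export
total_force <- function(components) {
  Reduce(`+`, components, c(0, 0, 0))
}

#' Nearest tank boundary point
#'
#' The closest point to `pos` on the tank boundary, chosen among the radial
#' projection onto the cylindrical wall, the floor, and the surface. For a
#' point exactly on the tank axis the wall azimuth is drawn at random.
#'
#' @param pos 3-vector position inside the tank (m).
#' @param tank A [tank_geometry()] object.
#' @return A 3-vector boundary point.
#' @examples
#' nearest_boundary_point(c(0.40, 0, 0.30), tank_geometry())
#' @export
nearest_boundary_point <- function(pos, tank = tank_geometry()) {
  .cpp_nearest_boundary_point(as.numeric(pos), tank$radius, tank$depth)
}

#' Cap swimming speed
#'
#' Rescales `v` to magnitude `c_maxvel * TL` (TL in cm, converted to m,
#' giving a cap in m/s) when it exceeds that cap; direction is preserved.
#'
#' @param v 3-vector velocity (m/s).
#' @param tl_cm Total length (cm).
#' @param mode `"standard"` or `"feeding"`.
#' @param params A [behavior_params()] object.
#' @return The capped velocity.
#' @examples
#' cap_velocity(c(0.3, 0, 0), tl_cm = 10, mode = "standard")  # cap 0.15 m/s
#' @export
cap_velocity <- function(v, tl_cm, mode = c("standard", "feeding"),
                         params = behavior_params()) {
  mode <- match.arg(mode)
  cmax <- if (mode == "feeding") params$c_maxvel_feeding else
    params$c_maxvel_standard
  .cpp_cap_velocity(as.numeric(v), tl_cm, cmax)
}

#' One kinematic step
#'
#' Newtonian update at the behavioral time step: acceleration `F / W` (mass
#' in g), velocity updated then capped, position advanced with the new
#' velocity and projected back inside the tank if the step exits it.
#'
#' @param pos,vel 3-vectors (m, m/s).
#' @param F 3-vector total swimming force.
#' @param mass_g Body mass (g).
#' @param dt Time step (s).
#' @param tl_cm Total length (cm).
#' @param mode Behavioral mode (sets the speed cap).
#' @param tank A [tank_geometry()] object.
#' @param params A [behavior_params()] object.
#' @return List with elements `position` and `velocity`.
#' @examples
#' step_kinematics(c(0, 0, 0.3), c(0.1, 0, 0), c(0, 0, 0), 1, 0.05, 10)
#' @export
step_kinematics <- function(pos, vel, F, mass_g, dt, tl_cm,
                            mode = c("standard", "feeding"),
                            tank = tank_geometry(),
                            params = behavior_params()) {
  mode <- match.arg(mode)
  cmax <- if (mode == "feeding") params$c_maxvel_feeding else
    params$c_maxvel_standard
  .cpp_step_kinematics(as.numeric(pos), as.numeric(vel), as.numeric(F),
                       mass_g, dt, tl_cm, cmax, tank$radius, tank$depth)
}

#' Behavioral mode
#'
#' A fish is in feeding mode while feed is present in the tank and its
#' intake so far is below the daily cap `S_max = 0.04 * W` (4\% of body
#' mass); otherwise it is in standard mode.
#'
#' @param intake_g Intake so far today (g).
#' @param mass_g Body mass (g).
#' @param pellets_active Number of active pellets in the tank.
#' @return `"feeding"` or `"standard"`.
#' @examples
#' determine_mode(3.9, 100, pellets_active = 10)
#' determine_mode(4.0, 100, pellets_active = 10)
#' @export
determine_mode <- function(intake_g, mass_g, pellets_active) {
  if (pellets_active > 0 && intake_g < 0.04 * mass_g) "feeding" else
    "standard"
}

#' Sink and expire pellets
#'
#' Advances active pellets downward by `pellet_sink_speed * dt`; pellets
#' reaching the floor (`z <= 0`) become inactive. Inactive pellets are
#' never reactivated.
#'
#' @param pellets Data frame with columns `x`, `y`, `z`, `active`.
#' @param dt Time step (s).
#' @param params A [behavior_params()] object.
#' @return The updated pellet data frame.
#' @examples
#' p <- data.frame(x = 0, y = 0, z = 0.0004, active = TRUE)
#' update_pellets(p, dt = 0.05)
#' @export
update_pellets <- function(pellets, dt, params = behavior_params()) {
  act <- pellets$active
  pellets$z[act] <- pellets$z[act] - params$pellet_sink_speed * dt
  pellets$active[act & pellets$z <= 0] <- FALSE
  pellets
}

#' Pellet-fish encounter detection
#'
#' Credits each active pellet lying within `capture_radius_multiplier * FL`
#' of a fish that can still ingest a whole pellet without crossing its
#' daily cap (`intake + W_f <= S_max`). Each pellet is consumed by at most
#' one fish: the nearest eligible one, ties broken by lower id. Consumed
#' pellets are deactivated immediately.
#'
#' @param pos `n x 3` matrix of fish positions (m).
#' @param fl_cm Fork lengths (cm).
#' @param intake_g Per-fish intake so far (g).
#' @param mass_g Body masses (g), from which `S_max = 0.04 * W`.
#' @param nf Per-fish pellet counts so far.
#' @param pellets Data frame with columns `x`, `y`, `z`, `active`.
#' @param w_f Weight of one pellet (g).
#' @param params A [behavior_params()] object.
#' @return List with updated `nf`, `intake_g`, `pellets` and the number
#'   `consumed` in this call.
#' @examples
#' p <- data.frame(x = 0, y = 0, z = 0.3, active = TRUE)
#' detect_encounters(rbind(c(0, 0, 0.31)), 6, 0, 10, 0L, p, w_f = 0.005)
#' @export
detect_encounters <- function(pos, fl_cm, intake_g, mass_g, nf, pellets,
                              w_f, params = behavior_params()) {
  pos <- rbind(pos)
  res <- .cpp_detect_encounters(
    pos, as.numeric(fl_cm), as.numeric(intake_g), 0.04 * as.numeric(mass_g),
    as.integer(nf), cbind(pellets$x, pellets$y, pellets$z),
    as.logical(pellets$active), params$capture_radius_multiplier, w_f)
  pellets$active <- as.logical(res$active)
  list(nf = res$nf, intake_g = res$intake_g, pellets = pellets,
       consumed = res$consumed)
}

#' Per-day intake mass
#'
#' Total ingested mass from the pellet count: `S = N_f * W_f`.
#'
#' @param n_f Number of pellets encountered.
#' @param w_f Weight of one pellet (g).
#' @return Intake (g).
#' @examples
#' intake_mass(10, 0.005)
#' @export
intake_mass <- function(n_f, w_f) {
  stopifnot(all(n_f >= 0), w_f > 0)
  n_f * w_f
}

#' Run one behavioral day
#'
#' Steps all fish at `dt` for `behavior_duration` seconds. At
#' `feed_drop_time`, `floor(daily_feed_mass_total / W_f)` pellets are
#' released at the surface, uniformly within the central feeding circle,
#' and sink until eaten or expired at the floor. Returns each fish's pellet
#' count and intake for the day plus pellet bookkeeping and the inline
#' speed-cap / intake-cap / containment diagnostics (maximal excesses over
#' the whole day; at or below numerical noise in a correct run).
#'
#' @param pos,vel `n x 3` matrices of initial positions and velocities.
#' @param mass_g,fl_cm Body masses (g) and fork lengths (cm).
#' @param daily_feed_mass_total Total feed mass for the day (g); non-positive
#'   values release no pellets.
#' @param feed A [feed_spec()] object (pellet weight is taken from it).
#' @param tank A [tank_geometry()] object.
#' @param params A [behavior_params()] object.
#' @return List with `nf`, `intake_g`, final `position` and `velocity`,
#'   pellet counts `released`, `consumed`, `expired`, `remaining`, and the
#'   diagnostics `max_speed_excess`, `max_intake_excess`,
#'   `max_containment_excess`.
#' @examples
#' set.seed(1)
#' scene <- make_toy_scene(5, 0, seed = 1)
#' run_behavior_day(scene$agents[, c("x", "y", "z")],
#'                  scene$agents[, c("vx", "vy", "vz")],
#'                  scene$agents$mass_g, scene$agents$fl_cm,
#'                  daily_feed_mass_total = 0.05,
#'                  feed = feed_spec(14961.28, 0.005, "EPC-2"))
#' @export
run_behavior_day <- function(pos, vel, mass_g, fl_cm, daily_feed_mass_total,
                             feed, tank = tank_geometry(),
                             params = behavior_params()) {
  pos <- as.matrix(pos); vel <- as.matrix(vel)
  storage.mode(pos) <- "double"; storage.mode(vel) <- "double"
  par <- c(unclass(params),
           list(feed_area_radius = params$feed_area_radius_frac * tank$radius,
                tank_radius = tank$radius, tank_depth = tank$depth))
  total <- max(0, daily_feed_mass_total)
  .cpp_behavior_day(pos, vel, as.numeric(mass_g), as.numeric(fl_cm),
                    total, feed$pellet_g, par)
}
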
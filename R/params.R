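#' Tank geometry
#'
#' Circular rearing tank, described by its radius and water depth. The
#' vertical axis passes through the tank centre with `z = 0` at the floor
#' and `z = depth` at the water surface. Defaults match a 500-L tank of
#' inner diameter 0.9 m filled to 0.6 m.
#'
#' @param radius Tank radius in metres.
#' @param depth Water depth in metres.
#' @return An object of class `tank_geometry`.
#' @examples
#' tank_geometry()
#' @export
tank_geometry <- function(radius = 0.45, depth = 0.6) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0,
            is.numeric(depth), length(depth) == 1L, depth > 0)
  structure(list(radius = radius, depth = depth), class = "tank_geometry")
}

#' Behavioral model parameters
#'
#' Parameters of the Boids-style schooling and feeding model. Each of the
#' seven behavioral rules (separation, cohesion, alignment, boundary
#' avoidance, inertia, feed approach, random walk) contributes a unit
#' direction vector scaled by its weight; the weights are dimensionless.
#' The feed-approach weight and the maximum-speed coefficient depend on the
#' behavioral mode: `standard` when no feed is available (or the daily
#' intake cap of 4\% body mass is reached) and `feeding` otherwise.
#'
#' @param w_separation,w_cohesion,w_alignment,w_bound,w_inertia,w_random
#'   Non-negative rule weights (mode-independent).
#' @param w_feed_standard,w_feed_feeding Feed-approach weight in standard and
#'   feeding mode.
#' @param c_maxvel_standard,c_maxvel_feeding Maximum swimming speed in body
#'   (total) lengths per second for each mode.
#' @param dt Behavioral time step in seconds.
#' @param fov_radius_multiplier Field-of-view radius in fork lengths.
#' @param dead_space_half_angle Half-angle (degrees) of the backward blind
#'   cone about the direction opposite to the velocity.
#' @param capture_radius_multiplier Pellet capture radius in fork lengths.
#' @param pellet_sink_speed Pellet sinking speed, m/s.
#' @param behavior_duration Length of the behavioral episode, s.
#' @param feed_drop_time Time within the episode at which feed is released, s.
#' @param feed_area_radius_frac Radius of the circular feeding area at the
#'   surface, as a fraction of the tank radius.
#' @param tl_over_fl Conversion factor from fork length to total length
#'   (total length drives the speed cap).
#' @return An object of class `behavior_params`.
#' @examples
#' behavior_params()
#' @export
behavior_params <- function(w_separation = 1.0, w_cohesion = 0.2,
                            w_alignment = 0.2, w_bound = 1.5,
                            w_inertia = 0.2, w_feed_standard = 0.0,
                            w_feed_feeding = 3.0, w_random = 0.2,
                            c_maxvel_standard = 1.5, c_maxvel_feeding = 7.0,
                            dt = 0.05, fov_radius_multiplier = 2,
                            dead_space_half_angle = 30,
                            capture_radius_multiplier = 0.5,
                            pellet_sink_speed = 0.01,
                            behavior_duration = 120, feed_drop_time = 60,
                            feed_area_radius_frac = 1 / 3,
                            tl_over_fl = 1.0) {
  p <- list(w_separation = w_separation, w_cohesion = w_cohesion,
            w_alignment = w_alignment, w_bound = w_bound,
            w_inertia = w_inertia, w_feed_standard = w_feed_standard,
            w_feed_feeding = w_feed_feeding, w_random = w_random,
            c_maxvel_standard = c_maxvel_standard,
            c_maxvel_feeding = c_maxvel_feeding, dt = dt,
            fov_radius_multiplier = fov_radius_multiplier,
            dead_space_half_angle = dead_space_half_angle,
            capture_radius_multiplier = capture_radius_multiplier,
            pellet_sink_speed = pellet_sink_speed,
            behavior_duration = behavior_duration,
            feed_drop_time = feed_drop_time,
            feed_area_radius_frac = feed_area_radius_frac,
            tl_over_fl = tl_over_fl)
  weights <- p[c("w_separation", "w_cohesion", "w_alignment", "w_bound",
                 "w_inertia", "w_feed_standard", "w_feed_feeding",
                 "w_random")]
  if (any(unlist(weights) < 0)) stop("behavior weights must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  if (feed_drop_time >= behavior_duration)
    stop("feed_drop_time must be < behavior_duration")
  structure(p, class = "behavior_params")
}

#' Dynamic energy budget parameters
#'
#' Parameters of the individual growth model. The state of a fish is its
#' gut content G (J), reserve energy E (J) and structural volume V (cm^3);
#' assimilation drains the gut into reserve with efficiency `kappa_x`,
#' mobilized reserve is split by the kappa-rule between soma and the rest,
#' and structure pays a volume-specific maintenance cost. All rates are
#' referenced to `T_1` and scaled by an Arrhenius factor with temperature
#' `T_A`. The allometric coefficients `a_allom`, `b_allom` convert between
#' wet mass (g) and fork length (cm).
#'
#' @param T_A Arrhenius temperature, K.
#' @param T_1 Reference temperature, K.
#' @param kappa_x Digestion (assimilation) efficiency of food to reserve.
#' @param kappa Fraction of mobilized flux allocated to soma.
#' @param E_G Specific cost for structure, J/cm^3.
#' @param k_g Gut evacuation (assimilation) rate coefficient, 1/d.
#' @param v_dot Energy conductance, cm/d.
#' @param p_M Volume-specific somatic maintenance rate, J/cm^3/d.
#' @param w_Ed Molecular weight of reserve dry mass, g/mol.
#' @param d_Vw Specific density of wet structure, g/cm^3.
#' @param mu_E Chemical potential of reserve, J/mol.
#' @param d_Vd Specific density of dry structure, g/cm^3.
#' @param a_allom,b_allom Allometric length-mass coefficients
#'   (`W = a_allom * FL^b_allom`, W in g, FL in cm).
#' @return An object of class `deb_params`.
#' @examples
#' deb_params()
#' @export
deb_params <- function(T_A = 8000, T_1 = 293.15, kappa_x = 0.8,
                       kappa = 0.61916, E_G = 5267.56, k_g = 20,
                       v_dot = 0.032453, p_M = 343.884, w_Ed = 23.9,
                       d_Vw = 1.0, mu_E = 550000, d_Vd = 0.2,
                       a_allom = 0.01958, b_allom = 2.865) {
  p <- list(T_A = T_A, T_1 = T_1, kappa_x = kappa_x, kappa = kappa,
            E_G = E_G, k_g = k_g, v_dot = v_dot, p_M = p_M, w_Ed = w_Ed,
            d_Vw = d_Vw, mu_E = mu_E, d_Vd = d_Vd,
            a_allom = a_allom, b_allom = b_allom)
  if (any(unlist(p) <= 0)) stop("all DEB parameters must be > 0")
  if (kappa >= 1) stop("kappa must be in (0, 1)")
  if (kappa_x > 1) stop("kappa_x must be in (0, 1]")
  structure(p, class = "deb_params")
}

#' Feed specification
#'
#' A single feed type: pellet energy density and the weight of one pellet.
#'
#' @param energy_J_per_g Energy density of the feed, J/g.
#' @param pellet_g Weight of a single pellet, g.
#' @param label Feed name.
#' @return An object of class `feed_spec`.
#' @examples
#' feed_spec(14359.29, 0.072, "Masu-Kokei 4")
#' @export
feed_spec <- function(energy_J_per_g, pellet_g, label = "feed") {
  stopifnot(energy_J_per_g > 0, pellet_g > 0)
  structure(list(energy_J_per_g = energy_J_per_g, pellet_g = pellet_g,
                 label = label), class = "feed_spec")
}

#' Default feed-type table
#'
#' Commercial trout feeds used across the 203-day rearing period, with the
#' day ranges over which each was fed, the feed energy density and the
#' weight of a single pellet. Pellet size grows with the fish: five feeds
#' from 2 mg fry crumble to 110 mg grower pellets.
#'
#' @return A data frame with columns `label`, `day_start`, `day_end`,
#'   `energy_J_per_g` and `pellet_g`.
#' @examples
#' feed_types()
#' @export
feed_types <- function() {
  data.frame(
    label = c("Masu-Chigyo super EPC-1", "Masu-Chigyo super EPC-2",
              "Masu-Kokei 3", "Masu-Kokei 4", "Masu-Kokei 5"),
    day_start = c(1L, 33L, 61L, 74L, 177L),
    day_end = c(32L, 60L, 73L, 176L, 203L),
    energy_J_per_g = c(14961.28, 14961.28, 14359.29, 14359.29, 14359.29),
    pellet_g = c(0.002, 0.005, 0.022, 0.072, 0.110),
    stringsAsFactors = FALSE
  )
}

#' Feed type in use on a given day
#'
#' Looks up the feed fed on `day` in a feed-type table. Days after the last
#' tabulated range use the last feed type.
#'
#' @param day Integer day (1-based).
#' @param feed_table A table as returned by [feed_types()].
#' @return A [feed_spec()] object.
#' @examples
#' feed_for_day(40)
#' @export
feed_for_day <- function(day, feed_table = feed_types()) {
  stopifnot(day >= 1)
  i <- which(day >= feed_table$day_start & day <= feed_table$day_end)
  if (length(i) == 0L)
    i <- if (day > max(feed_table$day_end)) nrow(feed_table) else 1L
  i <- i[1L]
  feed_spec(feed_table$energy_J_per_g[i], feed_table$pellet_g[i],
            feed_table$label[i])
}
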
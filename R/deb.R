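## Dynamic energy budget growth model.
##
## State per fish: gut content G (J), reserve E (J), structural volume
## V (cm^3).  All functions are vectorized over individuals, so a whole
## population integrates in one call.

#' Arrhenius temperature correction
#'
#' Physiological rate at temperature `T`:
#' `k(T) = k1 * exp(T_A / T_1 - T_A / T)`, equal to `k1` at the reference
#' temperature `T_1` and strictly increasing in `T`.
#'
#' @param temp_K Absolute temperature (K).
#' @param k1 Rate at the reference temperature.
#' @param params A [deb_params()] object.
#' @return The corrected rate.
#' @examples
#' arrhenius_rate(293.15)  # 1 at the reference temperature
#' arrhenius_rate(283.15)  # 10 C, the rearing temperature
#' @export
arrhenius_rate <- function(temp_K, k1 = 1, params = deb_params()) {
  stopifnot(all(temp_K > 0))
  k1 * exp(params$T_A / params$T_1 - params$T_A / temp_K)
}

#' DEB mass fluxes
#'
#' `flux_px` is the food energy flux `S * E_f` (J/d) for a daily intake `S`
#' (g/d) of feed with energy density `E_f`; `flux_pa` the assimilation flux
#' `k_g * G` draining the gut; `flux_pc` the mobilization flux
#' `(E/V) * (E_G * v_dot * V^(2/3) + p_M * V) / (E_G + kappa * E/V)`; and
#' `flux_ps` the somatic maintenance flux `p_M * V`. All in J/d, at the
#' reference temperature.
#'
#' @param S Daily feed intake (g/d).
#' @param feed A [feed_spec()] object.
#' @param G,E,V State components (J, J, cm^3); vectorized.
#' @param params A [deb_params()] object.
#' @return Flux (J/d).
#' @examples
#' flux_px(1, feed_spec(14359.29, 0.072))
#' flux_pc(E = 1000, V = 1)
#' @export
flux_px <- function(S, feed) {
  stopifnot(all(S >= 0))
  S * feed$energy_J_per_g
}

#' @rdname flux_px
#' @export
flux_pa <- function(G, params = deb_params()) {
  stopifnot(all(G >= 0))
  params$k_g * G
}

#' @rdname flux_px
#' @export
flux_pc <- function(E, V, params = deb_params()) {
  if (any(V <= 0)) stop("structural volume must be > 0 (corrupted state?)")
  e <- E / V
  e * (params$E_G * params$v_dot * V^(2 / 3) + params$p_M * V) /
    (params$E_G + params$kappa * e)
}

#' @rdname flux_px
#' @export
flux_ps <- function(V, params = deb_params()) {
  if (any(V <= 0)) stop("structural volume must be > 0")
  params$p_M * V
}

#' DEB state derivatives
#'
#' Right-hand side of the growth ODE system, with every flux scaled by the
#' Arrhenius factor `k(T)`:
#' `dG/dt = k(T) (p_x - p_a)`,
#' `dE/dt = k(T) (kappa_x p_a - p_c)`,
#' `dV/dt = k(T) (kappa p_c - p_s) / E_G`.
#'
#' @param G,E,V State components (vectorized over individuals).
#' @param p_x Food energy flux (J/d), e.g. from [flux_px()].
#' @param temp_K Water temperature (K).
#' @param params A [deb_params()] object.
#' @return List with components `dG`, `dE`, `dV` (per day).
#' @examples
#' deb_derivatives(G = 0, E = 0, V = 1, p_x = 0, temp_K = 283.15)
#' @export
deb_derivatives <- function(G, E, V, p_x, temp_K, params = deb_params()) {
  k <- arrhenius_rate(temp_K, 1, params)
  pa <- flux_pa(G, params)
  pc <- flux_pc(E, V, params)
  ps <- flux_ps(V, params)
  list(dG = k * (p_x - pa),
       dE = k * (params$kappa_x * pa - pc),
       dV = k * (params$kappa * pc - ps) / params$E_G)
}

# Derivatives evaluated on a state clipped to the valid region; used for
# RK4 stage evaluations, where an intermediate stage may dip below zero.
deriv_clipped <- function(G, E, V, p_x, temp_K, params) {
  deb_derivatives(pmax(G, 0), pmax(E, 0), pmax(V, 1e-9), p_x, temp_K,
                  params)
}

#' Integrate one growth day
#'
#' Advances the DEB state over one day with classic 4th-order Runge-Kutta,
#' holding the food flux constant at `S_day * E_f` (J/d). After each
#' substep G and E are clipped at 0 and V at a small positive floor. The
#' default 240 substeps/day resolves the fast gut dynamics
#' (`k_g = 20`/d) to well below 1e-6 relative error (see the package
#' vignette for the step-size analysis).
#'
#' @param state List with numeric components `G`, `E`, `V` (vectorized over
#'   individuals).
#' @param S_day Daily intake per individual (g).
#' @param feed A [feed_spec()] object.
#' @param temp_K Water temperature (K).
#' @param params A [deb_params()] object.
#' @param substeps Number of RK4 substeps per day (>= 1).
#' @return The state list after one day.
#' @examples
#' st <- init_state_from_mass(2.94)
#' integrate_day(st, S_day = 0.1, feed = feed_spec(14961.28, 0.002),
#'               temp_K = 283.15)
#' @export
integrate_day <- function(state, S_day, feed, temp_K,
                          params = deb_params(), substeps = 240) {
  stopifnot(substeps >= 1, all(S_day >= 0))
  G <- state$G; E <- state$E; V <- state$V
  p_x <- flux_px(S_day, feed)
  h <- 1 / substeps
  for (s in seq_len(substeps)) {
    k1 <- deriv_clipped(G, E, V, p_x, temp_K, params)
    k2 <- deriv_clipped(G + h / 2 * k1$dG, E + h / 2 * k1$dE,
                        V + h / 2 * k1$dV, p_x, temp_K, params)
    k3 <- deriv_clipped(G + h / 2 * k2$dG, E + h / 2 * k2$dE,
                        V + h / 2 * k2$dV, p_x, temp_K, params)
    k4 <- deriv_clipped(G + h * k3$dG, E + h * k3$dE, V + h * k3$dV,
                        p_x, temp_K, params)
    G <- G + h / 6 * (k1$dG + 2 * k2$dG + 2 * k3$dG + k4$dG)
    E <- E + h / 6 * (k1$dE + 2 * k2$dE + 2 * k3$dE + k4$dE)
    V <- V + h / 6 * (k1$dV + 2 * k2$dV + 2 * k3$dV + k4$dV)
    if (!all(is.finite(G), is.finite(E), is.finite(V)))
      stop("non-finite DEB state during integration (substep ", s, ")")
    G <- pmax(G, 0); E <- pmax(E, 0); V <- pmax(V, 1e-9)
  }
  list(G = G, E = E, V = V)
}

#' Wet mass from the DEB state
#'
#' `W = d_Vw * V + E * (w_Ed * d_Vw) / (mu_E * d_Vd)`: structural wet mass
#' plus the wet-mass equivalent of reserve energy. Gut content does not
#' contribute to weighed mass.
#'
#' @param state List with components `E` and `V` (and optionally `G`).
#' @param params A [deb_params()] object.
#' @return Wet mass (g).
#' @examples
#' mass_from_state(list(G = 0, E = 0, V = 1))
#' @export
mass_from_state <- function(state, params = deb_params()) {
  params$d_Vw * state$V +
    state$E * params$w_Ed * params$d_Vw / (params$mu_E * params$d_Vd)
}

#' Allometric length-mass conversion
#'
#' `W = a * FL^b` and its inverse `FL = (W / a)^(1/b)`, with coefficients
#' estimated from paired length and mass measurements of the rearing stock.
#'
#' @param W Wet mass (g).
#' @param FL Fork length (cm).
#' @param params A [deb_params()] object.
#' @return `fl_from_mass`: fork length (cm); `mass_from_fl`: mass (g).
#' @examples
#' fl_from_mass(mass_from_fl(5.68))
#' @export
fl_from_mass <- function(W, params = deb_params()) {
  stopifnot(all(W > 0))
  (W / params$a_allom)^(1 / params$b_allom)
}

#' @rdname fl_from_mass
#' @export
mass_from_fl <- function(FL, params = deb_params()) {
  stopifnot(all(FL > 0))
  params$a_allom * FL^params$b_allom
}

#' Initialize a DEB state from wet mass
#'
#' Partitions an initial wet mass into reserve and structure so that
#' [mass_from_state()] of the result reproduces `W0`: a fraction
#' `reserve_fraction` of the mass is reserve (converted to J), the rest is
#' structure; the gut starts empty. The partition is an assumption of this
#' simulator, not an observable.
#'
#' @param W0 Initial wet mass (g); vectorized.
#' @param reserve_fraction Fraction of `W0` held as reserve, in `[0, 1)`.
#' @param params A [deb_params()] object.
#' @return A state list with components `G`, `E`, `V`.
#' @examples
#' init_state_from_mass(2.94, reserve_fraction = 0.3)
#' @export
init_state_from_mass <- function(W0, reserve_fraction = 0.3,
                                 params = deb_params()) {
  stopifnot(all(W0 > 0), reserve_fraction >= 0, reserve_fraction < 1)
  cc <- params$w_Ed * params$d_Vw / (params$mu_E * params$d_Vd)
  list(G = rep(0, length(W0)),
       E = reserve_fraction * W0 / cc,
       V = (1 - reserve_fraction) * W0 / params$d_Vw)
}
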
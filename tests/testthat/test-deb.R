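# DEB growth model: fluxes, temperature correction, integration, and the
# mass/length bookkeeping.

test_that("Arrhenius correction is 1 at the reference temperature and monotone", {
  expect_identical(arrhenius_rate(293.15), 1)
  # frozen from direct scalar evaluation of exp(T_A/T_1 - T_A/T)
  expect_equal(arrhenius_rate(283.15), 0.3814435316537, tolerance = 1e-10)
  temps <- seq(275, 300, by = 0.5)
  expect_true(all(diff(arrhenius_rate(temps)) > 0))
  expect_equal(arrhenius_rate(283.15, k1 = 2), 2 * arrhenius_rate(283.15))
})

test_that("mass fluxes follow their defining expressions", {
  mk4 <- feed_spec(14359.29, 0.072, "Masu-Kokei 4")
  expect_equal(flux_px(1, mk4), 14359.29)
  expect_equal(flux_px(0, mk4), 0)
  expect_equal(flux_px(0.5, feed_spec(14961.28, 0.005)), 7480.64)

  expect_equal(flux_pa(1), 20)
  expect_equal(flux_pa(0), 0)
  expect_equal(flux_pa(2 * 3.7), 2 * flux_pa(3.7))

  expect_equal(flux_pc(E = 0, V = 1), 0)
  # frozen from single-expression evaluation with the default constants
  expect_equal(flux_pc(E = 1000, V = 1), 87.4565334651555,
               tolerance = 1e-12)
  E_grid <- seq(0, 5000, by = 250)
  expect_true(all(diff(flux_pc(E_grid, V = 2)) > 0))
  expect_error(flux_pc(E = 1, V = 0), "volume")

  expect_equal(flux_ps(1), 343.884)
  expect_equal(flux_ps(2), 687.768)

  # all fluxes non-negative on valid states
  set.seed(8)
  G <- runif(20, 0, 1e4); E <- runif(20, 0, 1e5); V <- runif(20, 0.1, 50)
  expect_true(all(flux_pa(G) >= 0))
  expect_true(all(flux_pc(E, V) >= 0))
  expect_true(all(flux_ps(V) >= 0))
})

test_that("state derivatives combine fluxes with the temperature factor", {
  d <- deb_derivatives(G = 0, E = 0, V = 1, p_x = 0, temp_K = 283.15)
  expect_equal(d$dG, 0)
  expect_equal(d$dE, 0)
  expect_lt(d$dV, 0)  # pure maintenance shrinks structure

  # gut steady state when food flux equals assimilation
  d2 <- deb_derivatives(G = 5, E = 100, V = 1, p_x = flux_pa(5),
                        temp_K = 290)
  expect_equal(d2$dG, 0)

  # at the reference temperature the derivatives are the raw fluxes
  p <- deb_params()
  d3 <- deb_derivatives(G = 2, E = 50, V = 1.5, p_x = 100,
                        temp_K = p$T_1)
  expect_equal(d3$dG, 100 - flux_pa(2))
  expect_equal(d3$dE, p$kappa_x * flux_pa(2) - flux_pc(50, 1.5))
})

test_that("RK4 gut decay matches the analytic exponential", {
  k <- arrhenius_rate(283.15)
  st <- list(G = 1000, E = 500, V = 1)
  feed <- feed_spec(14961.28, 0.005)
  out <- integrate_day(st, S_day = 0, feed = feed, temp_K = 283.15)
  expect_equal(out$G, 1000 * exp(-k * 20), tolerance = 1e-6)
})

test_that("halving the substep roughly divides the RK4 error by 16", {
  k <- arrhenius_rate(283.15)
  st <- list(G = 1000, E = 0, V = 1)
  feed <- feed_spec(14961.28, 0.005)
  exact <- 1000 * exp(-k * 20)
  err <- function(n) abs(integrate_day(st, 0, feed, 283.15,
                                       substeps = n)$G - exact)
  # fourth-order convergence: ratio near 16, inflated slightly by
  # higher-order terms at this step size
  ratio <- err(10) / err(20)
  expect_gt(ratio, 8)
  expect_lt(ratio, 30)
})

test_that("gut plus reserve is conserved when only assimilation acts", {
  # kappa_x = 1 with vanishing mobilization and maintenance: the coupled
  # G/E system just moves energy from gut to reserve
  p <- deb_params(kappa_x = 1, v_dot = 1e-12, p_M = 1e-12)
  st <- list(G = 5000, E = 1000, V = 1)
  out <- integrate_day(st, 0, feed_spec(14961.28, 0.005), 283.15, p)
  expect_equal(out$G + out$E, 6000, tolerance = 1e-9)
})

test_that("final mass is non-decreasing in the daily ration", {
  feed <- feed_spec(14961.28, 0.005)
  final_mass <- sapply(c(0, 0.02, 0.05, 0.1, 0.2), function(S) {
    st <- init_state_from_mass(2.94)
    for (d in 1:10)
      st <- integrate_day(st, S, feed, 283.15)
    mass_from_state(st)
  })
  expect_true(all(diff(final_mass) >= 0))
})

test_that("one-day growth increases with temperature near 10 degrees C", {
  feed <- feed_spec(14961.28, 0.005)
  gain <- sapply(c(281.15, 283.15, 285.15), function(temp) {
    st <- init_state_from_mass(2.94)
    mass_from_state(integrate_day(st, 0.1, feed, temp))
  })
  expect_true(all(diff(gain) > 0))
})

test_that("mass never increases under sustained starvation", {
  st <- init_state_from_mass(2.94)
  feed <- feed_spec(14961.28, 0.005)
  W <- mass_from_state(st)
  for (d in 1:15) {
    st <- integrate_day(st, 0, feed, 283.15)
    W <- c(W, mass_from_state(st))
  }
  expect_true(all(diff(W) <= 1e-12))
})

test_that("wet mass combines structure and the reserve equivalent linearly", {
  expect_equal(mass_from_state(list(G = 0, E = 0, V = 1)), 1.0)
  # frozen arithmetic: 1 + 10000 * 23.9 / (550000 * 0.2)
  expect_equal(mass_from_state(list(G = 0, E = 10000, V = 1)),
               3.17272727272727, tolerance = 1e-12)
  s1 <- mass_from_state(list(E = 2000, V = 3))
  expect_equal(mass_from_state(list(E = 4000, V = 6)), 2 * s1)
})

test_that("allometric conversions are mutually inverse", {
  expect_equal(mass_from_fl(1), 0.01958)
  # frozen from power-law evaluation at the initial mean fork length
  expect_equal(mass_from_fl(5.68), 2.83805409609501, tolerance = 1e-12)
  FL <- seq(1, 60, by = 0.25)
  expect_equal(fl_from_mass(mass_from_fl(FL)), FL, tolerance = 1e-10)
})

test_that("initial states reproduce the target mass for any reserve split", {
  st0 <- init_state_from_mass(2.94, reserve_fraction = 0)
  expect_equal(st0$E, 0)
  expect_equal(st0$V, 2.94)

  st3 <- init_state_from_mass(2.94, reserve_fraction = 0.3)
  expect_equal(st3$V, 2.058)
  for (f in c(0, 0.1, 0.3, 0.6, 0.9))
    expect_equal(mass_from_state(init_state_from_mass(2.94, f)), 2.94,
                 tolerance = 1e-10)
})

test_that("integration rejects invalid inputs", {
  feed <- feed_spec(14961.28, 0.005)
  expect_error(integrate_day(list(G = 0, E = 0, V = 1), -1, feed, 283.15))
  expect_error(integrate_day(list(G = 0, E = 0, V = 1), 0, feed, 283.15,
                             substeps = 0))
})
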
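# Rule forces: unit-direction scaling, degenerate inputs, mode switching.

test_that("separation points away from the nearest neighbor with magnitude w", {
  expect_equal(force_separation(c(0, 0, 0), c(1, 0, 0), 1.0), c(-1, 0, 0))
  expect_equal(force_separation(c(0, 0, 0), c(0, 3, 4), 1.0),
               c(0, -0.6, -0.8))
  for (k in 1:5) {
    self <- runif(3); other <- runif(3)
    expect_equal(sqrt(sum(force_separation(self, other, 1.0)^2)), 1.0)
  }
  # coincident positions fall back to a random unit direction
  set.seed(1)
  f <- force_separation(c(1, 1, 1), c(1, 1, 1), 0.7)
  expect_equal(sqrt(sum(f^2)), 0.7)
})

test_that("cohesion points toward the centroid of visible neighbors", {
  expect_equal(force_cohesion(c(0, 0, 0), rbind(c(2, 0, 0), c(4, 0, 0)),
                              0.2),
               c(0.2, 0, 0))
  expect_equal(force_cohesion(c(0, 0, 0), NULL, 0.2), c(0, 0, 0))
  expect_equal(force_cohesion(c(0, 0, 0), matrix(numeric(), ncol = 3), 0.2),
               c(0, 0, 0))
  # centroid coinciding with self gives a zero vector
  expect_equal(force_cohesion(c(1, 0, 0), rbind(c(0, 0, 0), c(2, 0, 0)),
                              0.2),
               c(0, 0, 0))
  expect_equal(sqrt(sum(force_cohesion(c(0, 0, 1),
                                       rbind(c(1, 2, 3), c(-2, 1, 0)),
                                       0.2)^2)), 0.2)
})

test_that("alignment tracks the mean neighbor velocity difference", {
  expect_equal(force_alignment(c(0, 0, 0), rbind(c(1, 0, 0)), 0.2),
               c(0.2, 0, 0))
  expect_equal(force_alignment(c(1, 0, 0), rbind(c(1, 0, 0)), 0.2),
               c(0, 0, 0))
  expect_equal(force_alignment(c(0, 0, 0), NULL, 0.2), c(0, 0, 0))
})

test_that("boundary force is gated on the field of view", {
  expect_equal(force_bound(c(0.40, 0, 0.3), c(0.45, 0, 0.3), 1.5,
                           fov_radius = 0.12),
               c(-1.5, 0, 0))
  expect_equal(force_bound(c(0.40, 0, 0.3), c(0.45, 0, 0.3), 1.5,
                           fov_radius = 0.01),
               c(0, 0, 0))
  f <- force_bound(runif(3), runif(3) + 2, 1.5)
  expect_true(isTRUE(all.equal(sqrt(sum(f^2)), 1.5)) || all(f == 0))
})

test_that("inertia follows the current heading and vanishes at rest", {
  expect_equal(force_inertia(c(0, 2, 0), 0.2), c(0, 0.2, 0))
  expect_equal(force_inertia(c(0, 0, 0), 0.2), c(0, 0, 0))
})

test_that("feed attraction is mode-weighted and needs a visible pellet", {
  expect_equal(force_feed(c(0, 0, 0), c(0, 0, 1), 0.0), c(0, 0, 0))
  expect_equal(force_feed(c(0, 0, 0), c(0, 0, 1), 3.0), c(0, 0, 3.0))
  expect_equal(force_feed(c(0, 0, 0), NULL, 3.0), c(0, 0, 0))
})

test_that("random force has magnitude w and normalizes its draws", {
  expect_equal(force_random(c(1, 0, 0), 0.2), c(0.2, 0, 0))
  expect_equal(force_random(c(1, 1, 1), 0.2), 0.2 / sqrt(3) * c(1, 1, 1))
  set.seed(3)
  for (k in 1:10)
    expect_equal(sqrt(sum(force_random(w = 0.2)^2)), 0.2)
  # an all-zero draw is replaced, never propagated
  set.seed(4)
  expect_equal(sqrt(sum(force_random(c(0, 0, 0), 0.2)^2)), 0.2)
})

test_that("total force sums components and is permutation invariant", {
  z <- c(0, 0, 0)
  expect_equal(total_force(list(z, z, z)), z)
  expect_equal(total_force(list(c(1, 2, 3), z)), c(1, 2, 3))
  comps <- replicate(7, runif(3), simplify = FALSE)
  expect_equal(total_force(comps), total_force(rev(comps)))
})

test_that("nearest boundary point picks wall, floor or surface correctly", {
  tank <- tank_geometry(0.45, 0.6)
  expect_equal(nearest_boundary_point(c(0.40, 0, 0.30), tank),
               c(0.45, 0, 0.30))
  expect_equal(nearest_boundary_point(c(0, 0, 0.01), tank), c(0, 0, 0))
  expect_equal(nearest_boundary_point(c(0, 0, 0.59), tank), c(0, 0, 0.6))
  # on the axis at mid depth the wall point has a random azimuth but
  # lies on the wall circle at the same height
  set.seed(5)
  b <- nearest_boundary_point(c(0, 0, 0.3), tank_geometry(0.2, 0.6))
  expect_equal(sqrt(b[1]^2 + b[2]^2), 0.2)
  expect_equal(b[3], 0.3)
})

test_that("speed cap rescales only above the mode-dependent maximum", {
  expect_equal(cap_velocity(c(0.3, 0, 0), 10, "standard"), c(0.15, 0, 0))
  expect_equal(cap_velocity(c(0.3, 0, 0), 10, "feeding"), c(0.3, 0, 0))
  expect_equal(cap_velocity(c(0.01, 0.02, 0), 10, "standard"),
               c(0.01, 0.02, 0))
})

test_that("kinematic step follows F = W a with the new-velocity position update", {
  s <- step_kinematics(c(0, 0, 0.3), c(0.1, 0, 0), c(0, 0, 0),
                       mass_g = 1, dt = 0.05, tl_cm = 10)
  expect_equal(s$position, c(0.005, 0, 0.3))
  expect_equal(s$velocity, c(0.1, 0, 0))

  s <- step_kinematics(c(0, 0, 0.3), c(0, 0, 0), c(1, 0, 0),
                       mass_g = 1, dt = 0.05, tl_cm = 10)
  expect_equal(s$velocity, c(0.05, 0, 0))
  expect_equal(s$position, c(0.0025, 0, 0.3))  # moved with the new velocity

  s2 <- step_kinematics(c(0, 0, 0.3), c(0, 0, 0), c(1, 0, 0),
                        mass_g = 2, dt = 0.05, tl_cm = 10)
  expect_equal(s2$velocity[1], s$velocity[1] / 2)  # doubling mass halves a
})

test_that("positions leaving the tank are projected back inside", {
  tank <- tank_geometry(0.45, 0.6)
  s <- step_kinematics(c(0.449, 0, 0.3), c(1, 0, 0), c(0, 0, 0),
                       mass_g = 1, dt = 0.05, tl_cm = 100, tank = tank)
  r <- sqrt(s$position[1]^2 + s$position[2]^2)
  expect_lte(r, tank$radius)
  expect_lte(s$velocity[1], 0 + 1e-12)  # outward component zeroed
})

test_that("behavioral mode switches on feed presence and the 4% intake cap", {
  expect_equal(determine_mode(3.9, 100, pellets_active = 5), "feeding")
  expect_equal(determine_mode(4.0, 100, pellets_active = 5), "standard")
  expect_equal(determine_mode(0, 100, pellets_active = 0), "standard")
})
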
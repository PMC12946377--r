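# Pellet dynamics, encounter rules and the full behavioral day.

test_that("pellets sink at the configured speed and expire at the floor", {
  p <- data.frame(x = 0, y = 0, z = 0.5, active = TRUE)
  p2 <- update_pellets(p, dt = 0.05)
  expect_equal(p2$z, 0.5 - 0.01 * 0.05)
  expect_true(p2$active)

  low <- data.frame(x = 0, y = 0, z = 1e-5, active = TRUE)
  expect_false(update_pellets(low, dt = 0.05)$active)

  frozen <- behavior_params(pellet_sink_speed = 0)
  expect_equal(update_pellets(p, 0.05, frozen)$z, 0.5)

  # inactive pellets are never moved or reactivated
  dead <- data.frame(x = 0, y = 0, z = 0.5, active = FALSE)
  expect_identical(update_pellets(dead, 0.05), dead)
})

test_that("an encounter consumes the pellet and credits one fish", {
  pel <- data.frame(x = 0, y = 0, z = 0.30, active = TRUE)
  res <- detect_encounters(rbind(c(0, 0, 0.32)), fl_cm = 6, intake_g = 0,
                           mass_g = 10, nf = 0L, pellets = pel,
                           w_f = 0.005)
  expect_equal(res$nf, 1L)
  expect_equal(res$intake_g, 0.005)
  expect_false(res$pellets$active)
  expect_equal(res$consumed, 1L)
})

test_that("a fish at its intake cap leaves the pellet in the water", {
  pel <- data.frame(x = 0, y = 0, z = 0.30, active = TRUE)
  res <- detect_encounters(rbind(c(0, 0, 0.32)), fl_cm = 6,
                           intake_g = 0.4, mass_g = 10, nf = 3L,
                           pellets = pel, w_f = 0.005)
  expect_equal(res$nf, 3L)
  expect_true(res$pellets$active)
  expect_equal(res$consumed, 0L)
})

test_that("two fish in range yield exactly one credit, nearest first", {
  pel <- data.frame(x = 0, y = 0, z = 0.30, active = TRUE)
  pos <- rbind(c(0, 0, 0.32), c(0, 0, 0.31))  # fish 2 is nearer
  res <- detect_encounters(pos, fl_cm = c(6, 6), intake_g = c(0, 0),
                           mass_g = c(10, 10), nf = c(0L, 0L),
                           pellets = pel, w_f = 0.005)
  expect_equal(res$nf, c(0L, 1L))
  expect_equal(sum(res$nf), 1L)
  # exact tie (mirror-symmetric offsets) broken by the lower id
  pos_tie <- rbind(c(0.02, 0, 0.30), c(-0.02, 0, 0.30))
  pel2 <- data.frame(x = 0, y = 0, z = 0.30, active = TRUE)
  res2 <- detect_encounters(pos_tie, fl_cm = c(6, 6), intake_g = c(0, 0),
                            mass_g = c(10, 10), nf = c(0L, 0L),
                            pellets = pel2, w_f = 0.005)
  expect_equal(res2$nf, c(1L, 0L))
})

test_that("intake mass is the pellet count times the pellet weight", {
  expect_equal(intake_mass(10, 0.005), 0.05)
  expect_equal(intake_mass(0, 0.072), 0)
  expect_equal(intake_mass(3, 0.022), 0.066)
})

test_that("a behavior day releases floor(mass / pellet weight) pellets", {
  sc <- make_toy_scene(3, 0, seed = 11)
  out <- run_behavior_day(sc$agents[, c("x", "y", "z")],
                          sc$agents[, c("vx", "vy", "vz")],
                          sc$agents$mass_g, sc$agents$fl_cm,
                          daily_feed_mass_total = 15.264,
                          feed = feed_spec(14359.29, 0.072, "Masu-Kokei 4"))
  expect_equal(out$released, 212L)
  expect_equal(out$released, out$consumed + out$expired + out$remaining)
})

test_that("zero feed keeps every fish in standard mode with zero intake", {
  sc <- make_toy_scene(4, 0, seed = 12)
  out <- run_behavior_day(sc$agents[, c("x", "y", "z")],
                          sc$agents[, c("vx", "vy", "vz")],
                          sc$agents$mass_g, sc$agents$fl_cm,
                          daily_feed_mass_total = 0,
                          feed = feed_spec(14961.28, 0.005, "EPC-2"))
  expect_equal(out$released, 0L)
  expect_equal(out$intake_g, rep(0, 4))
  expect_equal(out$nf, rep(0L, 4))
  # standard-mode speed cap respected throughout
  expect_lte(out$max_speed_excess, 1e-12)
})

test_that("total intake never exceeds the mass released", {
  set.seed(20)
  sc <- make_toy_scene(10, 0, seed = 20)
  total <- 0.5
  out <- run_behavior_day(sc$agents[, c("x", "y", "z")],
                          sc$agents[, c("vx", "vy", "vz")],
                          sc$agents$mass_g, sc$agents$fl_cm,
                          daily_feed_mass_total = total,
                          feed = feed_spec(14961.28, 0.005, "EPC-2"))
  expect_lte(sum(out$intake_g), total + 1e-12)
  expect_equal(out$intake_g, out$nf * 0.005)
})

test_that("identical seeds reproduce a behavior day bit for bit", {
  sc <- make_toy_scene(8, 0, seed = 30)
  run_once <- function() {
    set.seed(99)
    run_behavior_day(sc$agents[, c("x", "y", "z")],
                     sc$agents[, c("vx", "vy", "vz")],
                     sc$agents$mass_g, sc$agents$fl_cm,
                     daily_feed_mass_total = 0.3,
                     feed = feed_spec(14961.28, 0.005, "EPC-2"))
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$nf, b$nf)
  expect_identical(a$position, b$position)
  expect_identical(a$velocity, b$velocity)
})
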
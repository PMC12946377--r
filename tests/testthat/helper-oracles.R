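# Brute-force field-of-view oracle: plain O(n^2) distance + angle check,
# independent of the package's spatial query.
fov_oracle <- function(i, pos, vel, fl_cm, fov_mult = 2, dead_deg = 30) {
  out <- integer(0)
  p <- pos[i, ]
  v <- vel[i, ]
  speed <- sqrt(sum(v^2))
  r <- fov_mult * fl_cm[i] / 100
  for (j in seq_len(nrow(pos))) {
    if (j == i) next
    d <- pos[j, ] - p
    dist <- sqrt(sum(d^2))
    if (dist > r) next
    if (dist > 0 && speed > 0) {
      cos_back <- sum(-d * v) / (dist * speed)
      if (cos_back > cos(dead_deg * pi / 180)) next  # in the dead cone
    }
    out <- c(out, j)
  }
  out
}

# A random cloud of agents inside the default tank, for property tests.
random_agent_cloud <- function(n, tank = tank_geometry()) {
  r <- tank$radius * 0.95 * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  pos <- cbind(r * cos(th), r * sin(th), runif(n, 0.01, tank$depth - 0.01))
  vel <- matrix(runif(3 * n, -0.1, 0.1), ncol = 3)
  # some stationary agents to exercise the no-dead-space branch
  vel[runif(n) < 0.2, ] <- 0
  list(pos = pos, vel = vel, fl_cm = runif(n, 4, 12))
}

# Small ready-made config for orchestrator-level tests.
tiny_config <- function(n_days = 2, n = 8, grams = 0.05, seed = 42, ...) {
  simulation_config(make_schedule("constant_g", n_days = n_days,
                                  grams = grams),
                    n_individuals = n, seed = seed, ...)
}
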
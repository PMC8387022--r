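test_that("normal surface force and the contact threshold angle", {
  cf <- contact_forces(F_T = 2, F_N = 1)
  expect_equal(cf$beta_th, atan(0.5))
  expect_equal(normal_surface_force(cf, cf$beta_th, "away"), 0,
               tolerance = 1e-12)
  expect_lt(normal_surface_force(cf, cf$beta_th * 0.5, "away"), 0)

  cf0 <- contact_forces(F_T = 2, F_N = 0)
  expect_equal(normal_surface_force(cf0, pi / 2, "away"), 2)
  # toward-wall orientation always presses harder
  b <- seq(0, pi / 2, length.out = 20)
  expect_true(all(normal_surface_force(cf, b, "toward") >=
                  normal_surface_force(cf, b, "away")))
})

test_that("the phase-curve family has the prescribed structure", {
  pc <- phase_curve(1, 10)
  expect_equal(pc$g(0), 0)
  expect_equal(pc$g(pi / 2), 0, tolerance = 1e-15)
  expect_equal(pc$g(-0.3), -pc$g(0.3))        # odd

  h <- 1e-5
  slope0 <- (pc$g(h) - pc$g(-h)) / (2 * h)
  slope_pi2 <- (pc$g(pi / 2 + h) - pc$g(pi / 2 - h)) / (2 * h)
  expect_equal(slope0, -1, tolerance = 1e-6)
  expect_equal(slope_pi2, 10, tolerance = 1e-6)

  relax <- integrate_wall_angle(pc, Omega = 0, beta0 = 0.3, duration = 15)
  expect_equal(relax$beta[length(relax$beta)], 0, tolerance = 1e-4)

  expect_error(phase_curve(-1, 10), "positive")
})

test_that("stable angle matches a dense grid scan and the rolling limit", {
  pc <- phase_curve(1, 10)
  sa <- stable_angle(pc, 0.3)
  # independent oracle: sign change on a dense grid + linear interpolation
  bg <- seq(1e-9, pi / 2, length.out = 200001)
  gv <- pc$g(bg) + 0.3
  i <- which(diff(sign(gv)) != 0)[1]
  root <- bg[i] - gv[i] * (bg[i + 1] - bg[i]) / (gv[i + 1] - gv[i])
  expect_equal(sa$beta_S, root, tolerance = 1e-6)

  expect_equal(stable_angle(pc, 0)$beta_S, 0)
  expect_equal(stable_angle(pc, -0.3)$beta_S, -sa$beta_S)
  expect_false(stable_angle(pc, 10)$exists)   # beyond the saddle-node

  expect_equal(stable_angle(pc, 0.3, rolling = 0.1)$beta_S_rolling,
               0.1 * sa$beta_S)
  expect_equal(stable_angle(pc, 0.3, rolling = 0)$beta_S_rolling, 0)
})

test_that("rolling produces a triangular wall angle with the predicted excursion", {
  pc <- phase_curve(1, 10)
  Omega <- 0.3; T_SR <- 1 / 9
  ev <- cumsum(rep(T_SR, ceiling(10 / T_SR)))
  roll <- rolling_process(ev, duration = 10)
  ode <- integrate_wall_angle(pc, Omega, rolling = roll, beta0 = 0,
                              duration = 10, dt = 5e-4)
  expect_equal(ode$peak_to_peak, Omega * T_SR, tolerance = 0.1)
  # mean near the rolling-averaged stable point (duty ~ 0)
  expect_lt(abs(ode$beta_mean), 0.1 * stable_angle(pc, Omega)$beta_S)
})

test_that("averaged stable angle converges to the duty-scaled value", {
  pc <- phase_curve(1, 10)
  Omega <- 0.1
  bs <- stable_angle(pc, Omega)$beta_S
  dev <- vapply(c(10, 40, 160), function(f_sw) {
    half <- 1 / (2 * f_sw)
    ev <- cumsum(rep(c(1.2 * half, 0.8 * half), ceiling(6 * f_sw)))
    roll <- rolling_process(ev, duration = max(ev))
    pt <- duty_average(roll)
    ode <- integrate_wall_angle(pc, Omega, rolling = roll,
                                beta0 = pt * bs, duration = min(6, max(ev)),
                                dt = min(1e-3, half / 10))
    abs(ode$beta_mean - pt * bs)
  }, numeric(1))
  expect_lt(dev[3], 0.05 * bs)
})

test_that("interaction classification follows the overlap taxonomy", {
  sc <- function(d) reservoir_scenario(R = 250, Rprime = 150, d = d)
  expect_equal(classify_interaction(sc(0), rolling = TRUE), "S1")
  expect_equal(classify_interaction(sc(0)), "S2")
  # tangency: d = R - R' gives s = R R' exactly (boundary -> S3)
  expect_equal(sc(100)$s, 250 * 150)
  expect_equal(classify_interaction(sc(100)), "S3")
  # s = 0 at d^2 = R^2 + R'^2 (boundary of S3/S4)
  expect_equal(sc(sqrt(250^2 + 150^2))$s, 0, tolerance = 1e-6)
  expect_equal(classify_interaction(sc(200)), "S3")
  expect_equal(classify_interaction(sc(300)), "S4")
})

test_that("mean first transition time matches formula and Monte-Carlo", {
  expect_equal(mean_first_transition_time(250, 150, 50), 100)
  Ds <- c(1, 2, 5, 10)
  expect_true(all(diff(vapply(Ds, function(D)
    mean_first_transition_time(60, 40, D), numeric(1))) < 0))
  expect_error(mean_first_transition_time(60, 40, 0), "positive")

  # first passage of a reflected Brownian d(t) from 0 to R - R'
  # (dt small enough that the Euler boundary-overshoot bias ~ a sqrt(D dt)/D
  # is buried in the Monte-Carlo error)
  a <- 10; D <- 5; dt <- 0.001; nw <- 500
  set.seed(42)
  nmax <- 60 * ceiling(a^2 / (2 * D) / dt)
  d <- numeric(nw)
  hit <- rep(NA_real_, nw)
  alive <- rep(TRUE, nw)
  for (n in seq_len(nmax)) {
    if (!any(alive)) break
    d[alive] <- abs(d[alive] + rnorm(sum(alive), 0, sqrt(2 * D * dt)))
    just <- alive & d >= a
    hit[just] <- n * dt
    alive <- alive & !just
  }
  hit <- hit[!is.na(hit)]
  se <- sd(hit) / sqrt(length(hit))
  expect_lt(abs(mean(hit) - a^2 / (2 * D)), 1.96 * se + 2 * dt)
})

test_that("the S3-to-S4 threshold matches the event-driven simulation", {
  pc <- phase_curve(1, 10)
  th <- omega_threshold(pc)
  expect_equal(th$Omega_th, (pi / 2) * 10 / 9, tolerance = 1e-12)
  # weak-zero-slope limit
  pc2 <- phase_curve(0.05, 50)
  expect_equal(omega_threshold(pc2)$Omega_th,
               (pi / 2) * 0.05, tolerance = 0.01)
  expect_error(omega_threshold(phase_curve(5, 4.9)), "degenerate")

  grid <- seq(0.5 * th$Omega_th, 1.5 * th$Omega_th,
              by = 0.01 * th$Omega_th)
  sim <- first_s4_omega(pc, grid)
  expect_equal(sim$Omega_first_S4, th$Omega_th, tolerance = 0.05)
})

test_that("detachment angle is independent of the incidence angle", {
  pc <- phase_curve(1, 10)
  Omega <- -0.3
  finals <- vapply(c(0.2, 0.5, 1.0), function(b0)
    integrate_wall_angle(pc, Omega, beta0 = b0,
                         duration = 30)$beta_mean, numeric(1))
  expect_lt(diff(range(finals)), 1e-3)
  expect_equal(finals[1], stable_angle(pc, Omega)$beta_S, tolerance = 1e-3)
})

test_that("state machine: frequent rolling absorbs everything into S1", {
  sc <- reservoir_scenario(R = 60, Rprime = 40, d = 0, D = 10)
  roll <- sample_rolling_intervals(0.11, 0.02, 120, seed = 7)
  hist <- run_state_machine(sc, rolling = roll, Omega = 3, duration = 120,
                            dt = 0.05, seed = 7)
  st <- hist$state
  first_s1 <- which(st == "S1")[1]
  expect_false(is.na(first_s1))
  expect_true(all(st[first_s1:length(st)] == "S1"))
})

test_that("state machine: non-rolling below threshold never reaches S4", {
  sc <- reservoir_scenario(R = 60, Rprime = 40, d = 0, D = 10)
  pc <- phase_curve(1, 10)
  hist <- run_state_machine(sc, Omega = 0.5, curve = pc, duration = 150,
                            dt = 0.05, seed = 3)
  expect_true(any(hist$state == "S3"))
  expect_false(any(hist$state == "S4"))

  # stationary without noise or rolling
  sc0 <- reservoir_scenario(R = 60, Rprime = 40, d = 10, D = 1e-12)
  h0 <- run_state_machine(sc0, Omega = 0.5, curve = pc, duration = 5,
                          dt = 0.05, seed = 1)
  expect_equal(length(unique(h0$state)), 1L)
  expect_lt(diff(range(h0$d)), 1e-3)
})

test_that("state machine: infrequent rolling makes transitions reversible", {
  sc <- reservoir_scenario(R = 60, Rprime = 40, d = 18, D = 2, V_r = 70)
  roll <- sample_rolling_intervals(10, 1, 1000, seed = 11)
  hist <- run_state_machine(sc, rolling = roll, Omega = 8, duration = 1000,
                            dt = 0.05, seed = 11)
  st <- hist$state
  tr <- paste(st[-length(st)], st[-1])
  expect_gt(sum(tr == "S2 S3"), 0)
  expect_gt(sum(tr == "S3 S2"), 0)
})

test_that("relocations increase the area swept by diffusion", {
  one <- swept_area_comparison(5, D = 5, mc = FALSE)
  expect_equal(one$proxy_reloc, one$proxy_plain)

  many <- swept_area_comparison(rep(2, 10), D = 5, mc = FALSE)
  expect_gt(many$proxy_reloc, many$proxy_plain)

  wins <- vapply(1:10, function(s) {
    r <- swept_area_comparison(rep(2, 8), D = 5, seed = s)
    r$cells_reloc > r$cells_plain
  }, logical(1))
  expect_gte(sum(wins), 9)
})
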
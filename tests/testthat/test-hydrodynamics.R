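test_that("the three-point-force swimmer is force-free with the beat torque", {
  sw <- force_swimmer(V_P = 80, delta_theta = 15 * pi / 180)
  expect_equal(colSums(sw$forces), c(0, 0), tolerance = 1e-12)
  tq <- sum(sw$points[, 1] * sw$forces[, 2] -
            sw$points[, 2] * sw$forces[, 1])
  d <- default_drag
  tau_expected <- sw$Omega * d$xi_N * sw$L^3 / 12
  expect_equal(tq, tau_expected, tolerance = 1e-9)
})

test_that("free-space field matches an independently coded Oseen sum", {
  sw <- force_swimmer(V_P = 80, delta_theta = 0.2, eps = 0)
  set.seed(1)
  q <- matrix(runif(20, -300, 300), ncol = 2)
  q <- q[sqrt(rowSums(q^2)) > 80, , drop = FALSE]
  u <- stokeslet_field(sw, q)$u
  # oracle: explicit Oseen tensor superposition written out longhand
  u_or <- matrix(0, nrow(q), 2)
  for (m in seq_len(nrow(q))) {
    for (i in seq_len(nrow(sw$points))) {
      r <- q[m, ] - sw$points[i, ]
      rn <- sqrt(sum(r^2))
      G <- (diag(2) / rn + outer(r, r) / rn^3) / (8 * pi * sw$mu)
      u_or[m, ] <- u_or[m, ] + G %*% sw$forces[i, ]
    }
  }
  expect_equal(u, u_or, tolerance = 1e-3)
})

test_that("Stokes linearity and mirror symmetry of the swimmer field", {
  sw1 <- force_swimmer(V_P = 40, delta_theta = 0)
  sw2 <- force_swimmer(V_P = 80, delta_theta = 0)
  q <- cbind(c(150, 200, -150), c(80, -120, 60))
  u1 <- stokeslet_field(sw1, q)$u
  u2 <- stokeslet_field(sw2, q)$u
  expect_equal(u2, 2 * u1, tolerance = 1e-10)

  # delta_theta = 0: mirror symmetry about the swimming axis (y -> -y)
  qm <- cbind(q[, 1], -q[, 2])
  um <- stokeslet_field(sw1, qm)$u
  expect_equal(um[, 1], u1[, 1], tolerance = 1e-9)
  expect_equal(um[, 2], -u1[, 2], tolerance = 1e-9)
})

test_that("the force-free far field decays at least as a dipole", {
  sw <- force_swimmer(V_P = 80, delta_theta = 0.1)
  r <- 10^seq(2.3, 3.3, length.out = 8)
  q <- cbind(r * cos(0.9), r * sin(0.9))
  u <- stokeslet_field(sw, q)$u
  mag <- sqrt(rowSums(u^2))
  slope <- coef(lm(log(mag) ~ log(r)))[2]
  expect_lt(slope, -2 + 0.1)
})

test_that("image systems enforce no-slip on plane and circular walls", {
  sw <- force_swimmer(V_P = 80, delta_theta = 0.2,
                      position = c(150, 0), orientation = pi / 2)
  plane <- list(type = "plane", point = c(0, 0), normal = c(1, 0))
  fp <- stokeslet_field(sw, cbind(300, 50), plane)
  expect_lt(fp$wall_residual, 1e-3)

  sw2 <- force_swimmer(V_P = 80, delta_theta = 0.2, position = c(40, 0),
                       orientation = pi / 2)
  circ <- list(type = "circle", center = c(0, 0), R = 250)
  fc <- stokeslet_field(sw2, cbind(0, 0), circ)
  expect_lt(fc$wall_residual, 1e-3)
})

test_that("superposed Stokeslet fields remain incompressible", {
  sw <- force_swimmer(V_P = 80, delta_theta = 0.2, position = c(40, 0))
  circ <- list(type = "circle", center = c(0, 0), R = 250)
  img <- rollnav:::wall_image_system(sw, circ, 160)
  src3 <- cbind(rbind(sw$points, img$src), 0)
  F3 <- cbind(rbind(sw$forces, img$F), 0)
  h <- 0.5
  pts <- rbind(c(120, 30, 0), c(-90, 80, 0), c(0, -140, 0))
  scale <- max(sqrt(rowSums(
    rollnav:::stokeslet_u3(src3, F3, pts, sw$mu, sw$eps)^2)))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    div <- 0
    for (ax in 1:3) {
      e <- c(0, 0, 0); e[ax] <- h
      u2 <- rollnav:::stokeslet_u3(src3, F3, rbind(p + e, p - e),
                                   sw$mu, sw$eps)
      div <- div + (u2[1, ax] - u2[2, ax]) / (2 * h)
    }
    expect_lt(abs(div) * h / scale, 1e-3)
  }
})

test_that("wall drift: attraction, closed-form shape, and distance decay", {
  plane <- list(type = "plane", point = c(0, 0), normal = c(1, 0))
  mk <- function(h, dth = 0) force_swimmer(V_P = 80, delta_theta = dth,
                                           position = c(h, 0),
                                           orientation = pi / 2)
  wd <- wall_drift(mk(150), plane)
  expect_gt(wd$U_wp, 0)                       # pusher: attracted
  expect_equal(wd$U_numeric, wd$U_wp, tolerance = 1e-9)

  # closed-form root: sin(2 dtheta) = 2/3 kills the drift
  dth0 <- asin(2 / 3) / 2
  expect_equal(wall_drift(mk(150, dth0), plane)$U_closed_form, 0,
               tolerance = 1e-9)

  # far-field decay in wall distance at least h^-2
  u1 <- wall_drift(mk(120), plane)$U_wp
  u2 <- wall_drift(mk(240), plane)$U_wp
  expect_gt(log(abs(u1 / u2)) / log(2), 2 - 0.2)

  expect_error(wall_drift(mk(50), plane), "lubrication")
})

test_that("rolling restores the symmetric-swimmer attraction", {
  dth <- 15 * pi / 180
  expect_equal(rolling_averaged_drift(2, dth, 0)$U_tilde, 2)
  expect_equal(rolling_averaged_drift(2, dth, 1)$U_tilde,
               2 * (1 - 1.5 * sin(2 * dth)))

  ev <- cumsum(rep(1 / 9, 90))
  roll <- rolling_process(ev, duration = 10)
  tt <- seq(0, 10, by = 1e-3)
  ra <- rolling_averaged_drift(2, dth, roll, times = tt)
  expect_equal(ra$U_time_stepped, ra$U_tilde, tolerance = 0.1)
})

test_that("orbit-averaged reservoir drift is far below the swimming speed", {
  od <- orbit_averaged_drift(V_P = 80, delta_theta = 15 * pi / 180,
                             R_reservoir = 250, orbit_radius = 40,
                             n_positions = 6, n_colloc = 96)
  expect_lt(od$wall_residual, 1e-2)
  expect_lt(od$U_mean, 1)
})
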
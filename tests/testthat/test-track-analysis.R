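test_that("circle fitting is exact, matches the circumcircle, and is robust", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  f <- fit_circle(5 + 20 * cos(th), -3 + 20 * sin(th))
  expect_equal(f$center, c(5, -3), tolerance = 1e-9)
  expect_equal(f$radius, 20, tolerance = 1e-9)

  # three points: closed-form circumcenter oracle
  P <- rbind(c(0, 0), c(4, 0), c(1, 3))
  ax <- P[1, 1]; ay <- P[1, 2]; bx <- P[2, 1]; by <- P[2, 2]
  cx <- P[3, 1]; cy <- P[3, 2]
  Dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
         (cx^2 + cy^2) * (ay - by)) / Dd
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
         (cx^2 + cy^2) * (bx - ax)) / Dd
  f3 <- fit_circle(P[, 1], P[, 2])
  expect_equal(f3$center, c(ux, uy), tolerance = 1e-9)
  expect_equal(f3$radius, sqrt((ax - ux)^2 + (ay - uy)^2),
               tolerance = 1e-9)

  set.seed(9)
  thn <- runif(1000, 0, 2 * pi)
  fn <- fit_circle(20 * cos(thn) + rnorm(1000, 0, 0.5),
                   20 * sin(thn) + rnorm(1000, 0, 0.5))
  expect_equal(fn$radius, 20, tolerance = 0.01)

  expect_error(fit_circle(1:10, 2 * (1:10) + 3), "collinear")
})

test_that("circle fitting is equivariant under rigid motions", {
  set.seed(2)
  th <- runif(200, 0, 2 * pi)
  x <- 20 * cos(th) + rnorm(200, 0, 0.3)
  y <- 20 * sin(th) + rnorm(200, 0, 0.3)
  f0 <- fit_circle(x, y)
  a <- 0.7; tx <- 12; ty <- -8
  xr <- cos(a) * x - sin(a) * y + tx
  yr <- sin(a) * x + cos(a) * y + ty
  fr <- fit_circle(xr, yr)
  expect_equal(fr$kappa, f0$kappa, tolerance = 1e-12)
  expect_equal(fr$center,
               c(cos(a) * f0$center[1] - sin(a) * f0$center[2] + tx,
                 sin(a) * f0$center[1] + cos(a) * f0$center[2] + ty),
               tolerance = 1e-9)
})

test_that("center MSD recovers the generator diffusion coefficient", {
  for (D in c(0.1, 1, 10)) {
    ctr <- make_brownian_centers(D, dt = 0.1, n = 20000,
                                 seed = round(10 * D) + 1)
    m <- center_msd(ctr$cx, ctr$cy, dt = 0.1, max_lag = 400,
                    fit_fraction = 0.01)
    expect_equal(m$D, D, tolerance = 0.2)
    expect_equal(m$loglog_slope, 1, tolerance = 0.15)
  }
})

test_that("ballistic motion shows the quadratic MSD signature", {
  tt <- seq(0, 99.9, by = 0.1)
  m <- center_msd(3 * tt, 4 * tt, dt = 0.1, max_lag = 100)
  expect_equal(m$loglog_slope, 2, tolerance = 1e-6)
  expect_error(center_msd(1:5, 1:5, dt = 1), "insufficient")
})

test_that("curvature SNR estimator matches its definition", {
  expect_true(snr_kappa(rep(0.01, 100))$infinite)
  set.seed(5)
  kap <- 0.01 * (1 + rnorm(1e5, 0, 0.1))
  expect_equal(snr_kappa(kap)$snr, 100, tolerance = 0.05)
  expect_error(snr_kappa(rep(0.01, 10)), "30")
  # invariance under time-unit rescaling (kappa is per length)
  expect_equal(snr_kappa(kap * 1)$snr, snr_kappa(kap)$snr)
})

test_that("normalized mean step size is inversely proportional to SNR", {
  snrs <- c(10, 100, 1000)
  vals <- vapply(seq_along(snrs), function(i) {
    trk <- make_track("PAM1", "circular", duration = 400,
                      seed = 20 + i, kappa = 0.01, snr = snrs[i])
    truth <- attr(trk, "truth")
    ctr <- centers_from_heading(trk, truth$V_P, truth$kappa * truth$V_P)
    normalized_mean_step(ctr, truth$kappa)
  }, numeric(1))
  slope <- coef(lm(log10(vals) ~ log10(snrs)))[2]
  expect_equal(unname(slope), -1, tolerance = 0.15)
})

test_that("wall metrics separate wall-following from touch-and-detach", {
  dt <- 0.04; V <- 70
  wall <- list(type = "line", point = c(0, 0), normal = c(0, 1))
  # S1-like: 1 s approach, then 3 s aligned wall-following
  t_app <- seq(0, 1 - dt, by = dt)
  app <- cbind(-V * cos(pi / 6) * rev(t_app),
               V * sin(pi / 6) * rev(t_app) + 2)
  t_fol <- seq(dt, 3, by = dt)
  fol <- cbind(V * t_fol, rep(2, length(t_fol)))
  xy <- rbind(app, fol)
  trk1 <- track(seq(0, by = dt, length.out = nrow(xy)), xy[, 1], xy[, 2])
  m1 <- wall_metrics(trk1, wall, tol = 5)
  expect_true(m1$contact)
  expect_equal(m1$T_D, 3, tolerance = 2 * dt / 3 + 0.1)
  expect_equal(m1$V_star, 1, tolerance = 0.1)
  expect_gt(m1$rho_star, 0.9)

  # S3-like: dip to the wall and leave again
  tt <- seq(0, 6, by = dt)
  y3 <- 40 * abs(tt - 3) / 3 + 1
  trk3 <- track(tt, V * tt * 0.6, y3)
  m3 <- wall_metrics(trk3, wall, tol = 5)
  expect_true(m3$contact)
  expect_lt(m3$rho_star, 0.3)

  far <- track(tt, V * tt, rep(100, length(tt)))
  expect_false(wall_metrics(far, wall, tol = 5)$contact)
})

test_that("thermal rotational diffusion sits at the stated order of magnitude", {
  tb <- thermal_rotational_diffusion(L = 80, d = 5, mu = 3.2e-3,
                                     temperature = 310)
  expect_equal(tb$order_of_magnitude, -6)

  # independent re-evaluation of the rod formula
  p <- 80 / 5
  D_or <- 3 * 1.380649e-23 * 310 *
    (log(p) - 0.662 + 0.917 / p - 0.050 / p^2) /
    (pi * 3.2e-3 * (80e-6)^3)
  expect_equal(tb$D_r, D_or, tolerance = 1e-12)

  tb2 <- thermal_rotational_diffusion(mu = 6.4e-3)
  expect_equal(tb2$D_r, tb$D_r / 2, tolerance = 1e-12)

  snr_th <- thermal_rotational_diffusion(kappa = 5e-3, V_P = 80)$snr_thermal
  expect_gt(snr_th, 1e4)
  expect_error(thermal_rotational_diffusion(L = 3, d = 5), "L > d")
})
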
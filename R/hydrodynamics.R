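#' Three-point-force Stokeslet swimmer
#'
#' Far-field model of an asymmetrically beating sperm as three point forces
#' acting on the fluid: the propulsive force `f` applied at the flagellum
#' center, the opposing drag force `f'` at the head (force-free condition),
#' and a perpendicular force pair `f''` encoding the flagellar torque. The
#' beat-asymmetry angle `delta_theta` (the average angle the cell sweeps per
#' beat) tilts the propulsion axis and sets the torque-pair magnitude
#' through the intrinsic angular velocity \eqn{\Omega = \Delta\tilde\theta\,
#' \omega / 2\pi} balanced against rotational drag.
#'
#' Forces are calibrated so that the free swimmer's resistive-force-theory
#' speed is `V_P`: \eqn{|f| = \xi_T L V_P}.
#'
#' @param V_P free propulsive speed (um/s).
#' @param delta_theta beat-asymmetry angle (rad).
#' @param drag a [drag_coefficients()].
#' @param L body length scale (um); the torque-pair spacing is `L/2`.
#' @param omega beat frequency (rad/s), used to convert `delta_theta` into
#'   an angular velocity.
#' @param position head position (um, length-2).
#' @param orientation swimming direction (rad).
#' @param eps Gaussian regularization width of each point force (um).
#' @return object of class `force_swimmer`: matrices `points` (n x 2, um)
#'   and `forces` (n x 2, pN, forces exerted on the fluid), plus `mu`,
#'   `eps`, `V_P`, `delta_theta`, `Omega`, `position`, `orientation`.
#' @export
force_swimmer <- function(V_P = 80, delta_theta = 0,
                          drag = drag_coefficients(), L = 60, omega = 70,
                          position = c(0, 0), orientation = 0, eps = 1) {
  f_mag <- drag$xi_T * L * V_P                  # pN
  Omega <- delta_theta * omega / (2 * pi)       # rad/s swept per beat
  tau_f <- Omega * drag$xi_N * L^3 / 12         # pN um
  ca <- cos(orientation); sa <- sin(orientation)
  Rb <- rbind(c(ca, -sa), c(sa, ca))            # body -> lab
  # body frame: head at 0, flagellum center behind at (-L/2, 0)
  pts_b <- rbind(c(0, 0), c(-L / 2, 0), c(0, 0), c(-L / 2, 0))
  dir_p <- c(cos(delta_theta), sin(delta_theta))
  # tilted propulsion/drag pair already carries torque (L/2) f sin(dtheta);
  # the perpendicular pair supplies the remainder so net torque = tau_f
  f_pair <- (tau_f - (L / 2) * f_mag * sin(delta_theta)) / (L / 2)
  f_b <- rbind(
    f_mag * dir_p,        # drag reaction at the head pushes fluid forward
    -f_mag * dir_p,       # propulsion pushes fluid backward at the tail
    c(0, f_pair),         # torque pair about the body axis
    c(0, -f_pair)
  )
  structure(list(
    points = t(position + Rb %*% t(pts_b)),
    forces = t(Rb %*% t(f_b)),
    mu = drag$mu, eps = eps, V_P = V_P, delta_theta = delta_theta,
    Omega = Omega, L = L, position = position, orientation = orientation
  ), class = "force_swimmer")
}

# Regularized 3D Stokeslet (Cortez blob of width eps). src: n x 3 points,
# F: n x 3 forces (pN), query: m x 3 (um); mu in Pa s (= pN s/um^2).
# Returns m x 3 velocities (um/s). The velocity field is divergence-free.
stokeslet_u3 <- function(src, F, query, mu, eps = 0) {
  m <- nrow(query)
  u <- matrix(0, m, 3)
  for (i in seq_len(nrow(src))) {
    rx <- query[, 1] - src[i, 1]
    ry <- query[, 2] - src[i, 2]
    rz <- query[, 3] - src[i, 3]
    r2 <- rx^2 + ry^2 + rz^2
    if (eps > 0) {
      d <- sqrt(r2 + eps^2)
      h1 <- (r2 + 2 * eps^2) / d^3
      h2 <- 1 / d^3
    } else {
      r <- sqrt(r2)
      h1 <- 1 / r
      h2 <- 1 / r^3
    }
    fr <- rx * F[i, 1] + ry * F[i, 2] + rz * F[i, 3]
    u[, 1] <- u[, 1] + h1 * F[i, 1] + h2 * fr * rx
    u[, 2] <- u[, 2] + h1 * F[i, 2] + h2 * fr * ry
    u[, 3] <- u[, 3] + h1 * F[i, 3] + h2 * fr * rz
  }
  u / (8 * pi * mu)
}

# in-plane (z = 0) wrapper: n x 2 sources/forces/queries
oseen_velocity <- function(src, F, query, mu, eps = 0) {
  stokeslet_u3(cbind(src, 0), cbind(F, 0), cbind(query, 0), mu, eps)[, 1:2,
                                                                     drop = FALSE]
}

#' Velocity field of the force swimmer
#'
#' Superposes regularized Stokeslets for the swimmer's forces, optionally
#' in the presence of a no-slip boundary. Boundaries are handled by an
#' image-system construction: a set of image Stokeslets is placed behind
#' the boundary and their strengths solved by least-squares collocation so
#' that the velocity vanishes on the wall (residuals are returned so the
#' no-slip quality can be asserted).
#'
#' @param swimmer a [force_swimmer()].
#' @param query m x 2 matrix of evaluation points (um).
#' @param boundary `NULL` (free space), or a list: `list(type = "plane",
#'   point =, normal =)` for a no-slip plane (normal pointing into the
#'   fluid), or `list(type = "circle", center =, R =)` for a no-slip
#'   circular reservoir wall enclosing the fluid.
#' @param n_colloc number of collocation points on the boundary.
#' @return list with `u` (m x 2 velocities, um/s), `wall_residual`
#'   (max |u| on the collocation points relative to the swimmer field
#'   scale; `NA` in free space), and `image` (image-system description).
#' @export
stokeslet_field <- function(swimmer, query, boundary = NULL,
                            n_colloc = 160) {
  stopifnot(inherits(swimmer, "force_swimmer"))
  query <- rbind(query)
  d2src <- sapply(seq_len(nrow(swimmer$points)), function(i)
    sqrt((query[, 1] - swimmer$points[i, 1])^2 +
         (query[, 2] - swimmer$points[i, 2])^2))
  if (any(d2src < swimmer$eps))
    warning("query point(s) inside the regularization core")
  u0 <- oseen_velocity(swimmer$points, swimmer$forces, query,
                       swimmer$mu, swimmer$eps)
  if (is.null(boundary))
    return(list(u = u0, wall_residual = NA_real_, image = NULL))
  img <- wall_image_system(swimmer, boundary, n_colloc)
  ui <- oseen_velocity(img$src, img$F, query, swimmer$mu, img$eps)
  list(u = u0 + ui, wall_residual = img$residual, image = img)
}

# Solve for image Stokeslet strengths cancelling the swimmer field on the
# boundary. Sources sit behind the wall at an offset comparable to the
# collocation spacing (method-of-images by collocation).
wall_image_system <- function(swimmer, boundary, n_colloc = 160) {
  sw_pts <- swimmer$points
  if (boundary$type == "plane") {
    nrm <- boundary$normal / sqrt(sum(boundary$normal^2))
    tang <- c(-nrm[2], nrm[1])
    # distance of the swimmer from the wall sets the collocation span
    h <- abs(sum((colMeans(sw_pts) - boundary$point) * nrm))
    span <- 12 * h
    s <- seq(-span, span, length.out = n_colloc)
    colloc <- t(boundary$point + outer(tang, s))
    off <- 2 * span / n_colloc * 4      # MFS sources well behind the wall
    src <- t(t(colloc) - nrm * off)
    n_src <- n_colloc
  } else if (boundary$type == "circle") {
    th <- seq(0, 2 * pi, length.out = n_colloc + 1)[-(n_colloc + 1)]
    colloc <- cbind(boundary$center[1] + boundary$R * cos(th),
                    boundary$center[2] + boundary$R * sin(th))
    n_src <- max(24L, floor(n_colloc * 2 / 3))
    ths <- seq(0, 2 * pi, length.out = n_src + 1)[-(n_src + 1)]
    Rs <- boundary$R * (1 + 4 * 2 * pi / n_src)  # sources well outside
    src <- cbind(boundary$center[1] + Rs * cos(ths),
                 boundary$center[2] + Rs * sin(ths))
  } else stop("unknown boundary type")

  eps_img <- swimmer$eps
  u_b <- oseen_velocity(swimmer$points, swimmer$forces, colloc,
                        swimmer$mu, swimmer$eps)
  rhs <- -c(u_b[, 1], u_b[, 2])
  # influence matrix: unit forces (x and y) at each image source
  nc <- nrow(colloc)
  A <- matrix(0, 2 * nc, 2 * n_src)
  for (j in seq_len(n_src)) {
    ux <- oseen_velocity(src[j, , drop = FALSE], matrix(c(1, 0), 1),
                         colloc, swimmer$mu, eps_img)
    uy <- oseen_velocity(src[j, , drop = FALSE], matrix(c(0, 1), 1),
                         colloc, swimmer$mu, eps_img)
    A[, j] <- c(ux[, 1], ux[, 2])
    A[, n_src + j] <- c(uy[, 1], uy[, 2])
  }
  coefs <- qr.coef(qr(A), rhs)
  coefs[is.na(coefs)] <- 0
  Fimg <- cbind(coefs[seq_len(n_src)], coefs[n_src + seq_len(n_src)])
  resid <- A %*% coefs - rhs
  scale <- max(sqrt(rowSums(u_b^2)))
  list(src = src, F = Fimg, eps = eps_img,
       residual = max(abs(resid)) / scale, colloc = colloc)
}

#' Wall-induced drift velocity
#'
#' Far-field drift of the swimmer toward a no-slip boundary. The numeric
#' route evaluates the image (wall-induced) part of the flow at the
#' swimmer's force points and averages it; the closed form is
#' \deqn{U_w = U_{wp}\,\bigl(1 - \tfrac{3}{2}\sin(2\Delta\tilde\theta)\bigr),}
#' where `U_wp` is the drift of the symmetric (`delta_theta = 0`) swimmer at
#' the same pose, computed numerically. Valid in the far field only: the
#' wall distance must exceed the swimmer length (the near field belongs to
#' the lubrication description).
#'
#' @param swimmer a [force_swimmer()].
#' @param boundary boundary description as in [stokeslet_field()].
#' @param n_colloc collocation points.
#' @return list with `U_numeric` (signed drift toward the wall, um/s),
#'   `U_closed_form`, `U_wp`, `drift_vector` (um/s), `wall_residual`.
#' @export
wall_drift <- function(swimmer, boundary, n_colloc = 160) {
  nrm <- wall_normal_at(swimmer, boundary)
  h <- wall_distance(swimmer, boundary)
  if (h <= swimmer$L)
    stop("near field (distance <= swimmer length): lubrication regime")
  u_img <- wall_induced_velocity(swimmer, boundary, n_colloc)
  U_num <- -sum(u_img * nrm)   # positive = toward the wall
  sw0 <- force_swimmer(V_P = swimmer$V_P, delta_theta = 0,
                       drag = drag_coefficients(mu = swimmer$mu),
                       L = swimmer$L, position = swimmer$position,
                       orientation = swimmer$orientation, eps = swimmer$eps)
  U_wp <- -sum(wall_induced_velocity(sw0, boundary, n_colloc) * nrm)
  list(U_numeric = U_num,
       U_closed_form = U_wp * (1 - 1.5 * sin(2 * swimmer$delta_theta)),
       U_wp = U_wp,
       drift_vector = u_img)
}

wall_induced_velocity <- function(swimmer, boundary, n_colloc = 160) {
  img <- wall_image_system(swimmer, boundary, n_colloc)
  body <- rbind(swimmer$points, swimmer$position)
  ui <- oseen_velocity(img$src, img$F, body, swimmer$mu, img$eps)
  colMeans(ui)
}

wall_normal_at <- function(swimmer, boundary) {
  if (boundary$type == "plane") {
    n <- boundary$normal / sqrt(sum(boundary$normal^2))
    n                                  # points into the fluid
  } else {
    v <- swimmer$position - boundary$center
    -v / sqrt(sum(v^2))                # inward normal; wall is outward
  }
}

wall_distance <- function(swimmer, boundary) {
  if (boundary$type == "plane") {
    n <- boundary$normal / sqrt(sum(boundary$normal^2))
    abs(sum((swimmer$position - boundary$point) * n))
  } else {
    boundary$R - sqrt(sum((swimmer$position - boundary$center)^2))
  }
}

#' Rolling-averaged wall drift
#'
#' Rolling flips the sign of the beat-asymmetry angle, so the instantaneous
#' drift is \eqn{U_{wp}(1 - \tfrac32\sin(2\Pi(t)\Delta\tilde\theta))} and
#' its time average is
#' \deqn{\tilde U_w = U_{wp}\bigl(1 - \tfrac{3}{2}\tilde\Pi
#'       \sin(2\Delta\tilde\theta)\bigr) \to U_{wp}
#'       \quad (\tilde\Pi \to 0):}
#' frequent rolling restores the full dipole attraction of a symmetric
#' swimmer.
#'
#' @param U_wp symmetric-swimmer drift (um/s).
#' @param delta_theta beat-asymmetry angle (rad).
#' @param rolling a [rolling_process()] or a numeric duty average.
#' @param times optional time grid on which a time-stepped average of the
#'   instantaneous closed form is also computed (cross-check).
#' @return list with `U_tilde` and, when `times` is given,
#'   `U_time_stepped`.
#' @export
rolling_averaged_drift <- function(U_wp, delta_theta, rolling,
                                   times = NULL) {
  pt <- duty_average(rolling)
  out <- list(U_tilde = U_wp * (1 - 1.5 * pt * sin(2 * delta_theta)))
  if (!is.null(times)) {
    stopifnot(inherits(rolling, "rolling_process"))
    p <- build_pi(rolling$events, times)$pi
    out$U_time_stepped <- mean(U_wp * (1 - 1.5 * sin(2 * p * delta_theta)))
  }
  out
}

#' Orbit-averaged drift magnitude in a circular reservoir
#'
#' Average magnitude of the wall-induced far-field drift over one full round
#' of a circular orbit near the reservoir center: at each orbit position the
#' swimmer is tangent to its circular path and the wall-induced flow at the
#' body is computed through the circular-wall image system.
#'
#' @param V_P free swimming speed (um/s).
#' @param delta_theta beat-asymmetry angle (rad).
#' @param R_reservoir reservoir radius (um).
#' @param orbit_radius radius of the swimmer's circular path (um).
#' @param n_positions orbit positions averaged over.
#' @param drag a [drag_coefficients()].
#' @param n_colloc collocation points on the reservoir wall.
#' @return list with `U_mean` (mean drift magnitude, um/s), `U_mag`
#'   (per-position magnitudes), `wall_residual` (worst case).
#' @export
orbit_averaged_drift <- function(V_P = 80, delta_theta = 15 * pi / 180,
                                 R_reservoir = 250, orbit_radius = 40,
                                 n_positions = 12,
                                 drag = drag_coefficients(),
                                 n_colloc = 160) {
  boundary <- list(type = "circle", center = c(0, 0), R = R_reservoir)
  phis <- seq(0, 2 * pi, length.out = n_positions + 1)[-(n_positions + 1)]
  mags <- numeric(n_positions); res <- numeric(n_positions)
  for (i in seq_along(phis)) {
    pos <- orbit_radius * c(cos(phis[i]), sin(phis[i]))
    sw <- force_swimmer(V_P = V_P, delta_theta = delta_theta, drag = drag,
                        position = pos, orientation = phis[i] + pi / 2)
    img <- wall_image_system(sw, boundary, n_colloc)
    body <- rbind(sw$points, sw$position)
    ui <- oseen_velocity(img$src, img$F, body, sw$mu, img$eps)
    mags[i] <- sqrt(sum(colMeans(ui)^2))
    res[i] <- img$residual
  }
  list(U_mean = mean(mags), U_mag = mags, wall_residual = max(res))
}
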
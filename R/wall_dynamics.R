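#' Contact forces at the wall
#'
#' A sperm touching a wall at incidence angle `beta` exerts a propulsive
#' force `F_T` along its axis and a perpendicular force `F_N` from the beat
#' asymmetry. The threshold angle \eqn{\beta_{th} = \arctan(F_N/F_T)}
#' separates contact from no-contact when the perpendicular force points
#' away from the wall.
#'
#' @param F_T propulsive force (pN).
#' @param F_N perpendicular force (pN), non-negative magnitude.
#' @return object of class `contact_forces` with `F_T`, `F_N`,
#'   `gamma_F = F_N/F_T`, `beta_th` (rad).
#' @export
contact_forces <- function(F_T, F_N) {
  if (F_T <= 0 || F_N < 0) stop("require F_T > 0 and F_N >= 0")
  structure(list(F_T = F_T, F_N = F_N, gamma_F = F_N / F_T,
                 beta_th = atan(F_N / F_T)), class = "contact_forces")
}

#' Normal surface force
#'
#' Zero-net-force balance at the wall:
#' away-from-wall perpendicular force, \eqn{N = F_T\sin\beta -
#' F_N\cos\beta}; toward-wall, \eqn{N = F_T\sin\beta + F_N\cos\beta}.
#' `N <= 0` means no wall contact (the S2 precursor).
#'
#' @param forces a [contact_forces()].
#' @param beta incidence angle (rad), in `[0, pi/2]`.
#' @param orientation `"away"` or `"toward"`: direction of the
#'   perpendicular force relative to the wall.
#' @return normal force `N` (pN); vectorized over `beta`.
#' @export
normal_surface_force <- function(forces, beta,
                                 orientation = c("away", "toward")) {
  orientation <- match.arg(orientation)
  stopifnot(all(beta >= 0 & beta <= pi / 2))
  s <- if (orientation == "away") -1 else 1
  forces$F_T * sin(beta) + s * forces$F_N * cos(beta)
}

#' Phase curve of wall-contact dynamics
#'
#' Near a wall the incidence angle obeys \eqn{\dot\beta = g(\beta) +
#' \Pi(t)\Omega}, where `g` is the wall-induced (lubrication) rotation of a
#' symmetric swimmer. The two-slope surrogate family used here is
#' \deqn{g(\beta) = -g_0'\sin\beta\cos\beta -
#'       (g_\pi' - g_0')\sin^3\beta\cos\beta,}
#' which is odd, vanishes at 0 and \eqn{\pi/2}, has `g'(0) = -g0_slope`
#' (stable alignment at 0 when `Omega = 0`) and `g'(pi/2) = gpi_slope`
#' (instability at \eqn{\beta_U = \pi/2}).
#'
#' @param g0_slope magnitude of the slope at 0 (1/s), positive.
#' @param gpi_slope slope at pi/2 (1/s), positive.
#' @return object of class `phase_curve`: the vectorized function `g`, the
#'   slopes, and `g_min` (most negative value of `g` on `(0, pi/2)`, the
#'   saddle-node limit for `Omega`).
#' @export
phase_curve <- function(g0_slope, gpi_slope) {
  if (g0_slope <= 0 || gpi_slope <= 0) stop("slopes must be positive")
  g <- function(beta)
    -g0_slope * sin(beta) * cos(beta) -
      (gpi_slope - g0_slope) * sin(beta)^3 * cos(beta)
  opt <- stats::optimize(g, c(0, pi / 2))
  structure(list(g = g, g0_slope = g0_slope, gpi_slope = gpi_slope,
                 g_min = opt$objective, beta_gmin = opt$minimum),
            class = "phase_curve")
}

#' @rdname phase_curve
#' @export
build_phase_curve <- phase_curve

#' Stable and unstable wall angles
#'
#' Without rolling the stable angle solves \eqn{g(\beta_S) = -\Omega} on the
#' stable branch (bracketed root finding); the unstable companion root
#' \eqn{\beta_U} lies between the curve minimum and \eqn{\pi/2}. With
#' rolling, the averaged stable angle is \eqn{\tilde\beta_S^* =
#' \tilde\Pi\,\beta_S}. Beyond the saddle-node (`|Omega| > |g_min|`) no
#' stable wall swimming exists.
#'
#' @param curve a [phase_curve()].
#' @param Omega intrinsic angular velocity (rad/s), sign = S4 (+) / S3 (-).
#' @param rolling optional [rolling_process()] or duty average.
#' @return list with `exists`, `beta_S`, `beta_U` (rad, signed like
#'   `Omega`), `beta_S_rolling` (`NA` without rolling), `pi_tilde`.
#' @export
stable_angle <- function(curve, Omega, rolling = NULL) {
  ao <- abs(Omega)
  if (ao == 0) {
    bs <- 0; bu <- pi / 2
  } else if (ao >= abs(curve$g_min)) {
    return(list(exists = FALSE, beta_S = NA_real_, beta_U = NA_real_,
                beta_S_rolling = NA_real_, pi_tilde = NA_real_))
  } else {
    f <- function(b) curve$g(b) + ao
    bs <- uniroot(f, c(1e-12, curve$beta_gmin), tol = 1e-12)$root
    bu <- uniroot(f, c(curve$beta_gmin, pi / 2 - 1e-12), tol = 1e-12)$root
  }
  sgn <- if (Omega < 0) -1 else 1
  pt <- if (is.null(rolling)) NA_real_ else duty_average(rolling)
  list(exists = TRUE, beta_S = sgn * bs, beta_U = sgn * bu,
       beta_S_rolling = if (is.null(rolling)) NA_real_ else pt * sgn * bs,
       pi_tilde = pt)
}

#' Integrate the wall-angle dynamics
#'
#' Fixed-step RK4 integration of \eqn{\dot\beta = g(\beta) + \Pi(t)\Omega}.
#' Under frequent rolling near the stable point the solution is a
#' triangular wave \eqn{\beta(t) \approx \Lambda(t)\Omega +
#' \tilde\beta_S^*} with peak-to-peak excursion \eqn{\Omega \tilde T_{SR}}.
#'
#' @param curve a [phase_curve()].
#' @param Omega intrinsic angular velocity (rad/s).
#' @param rolling optional [rolling_process()].
#' @param beta0 initial angle (rad).
#' @param duration,dt integration horizon and step (s).
#' @return list with `time`, `beta`, `beta_mean` (second-half average) and
#'   `peak_to_peak` (second-half excursion).
#' @export
integrate_wall_angle <- function(curve, Omega, rolling = NULL, beta0 = 0,
                                 duration = 10, dt = 1e-3) {
  tt <- seq(0, duration, by = dt)
  n <- length(tt)
  p <- if (is.null(rolling)) rep(1, n) else build_pi(events_in_grid(rolling$events, tt), tt)$pi
  beta <- numeric(n); beta[1] <- beta0
  for (i in seq_len(n - 1)) {
    f <- function(b) curve$g(b) + p[i] * Omega
    k1 <- f(beta[i]); k2 <- f(beta[i] + dt / 2 * k1)
    k3 <- f(beta[i] + dt / 2 * k2); k4 <- f(beta[i] + dt * k3)
    beta[i + 1] <- beta[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  half <- beta[tt >= duration / 2]
  list(time = tt, beta = beta, beta_mean = mean(half),
       peak_to_peak = diff(range(half)))
}

#' Reservoir scenario
#'
#' Geometry of a non-rolling sperm swimming on a circle of radius `Rprime`
#' inside a circular reservoir of radius `R`, with center separation `d`.
#' The overlap variable \deqn{s = \tfrac{1}{2}(R^2 + R'^2 - d^2)} encodes
#' whether and how the circular path meets the wall.
#'
#' @param R reservoir radius (um).
#' @param Rprime orbit radius (um), `0 < Rprime < R`.
#' @param d center separation (um).
#' @param D center diffusion coefficient (um^2/s).
#' @param V_r ballistic relocation speed at rolling events (um/s).
#' @return object of class `reservoir_scenario` with the geometry and `s`.
#' @export
reservoir_scenario <- function(R, Rprime, d = 0, D = 1, V_r = 70) {
  if (!(R > Rprime && Rprime > 0)) stop("require R > Rprime > 0")
  structure(list(R = R, Rprime = Rprime, d = d, D = D, V_r = V_r,
                 s = 0.5 * (R^2 + Rprime^2 - d^2)),
            class = "reservoir_scenario")
}

#' Classify a sperm-wall interaction state
#'
#' The S1-S4 taxonomy: rolling sperm align with the wall and follow it
#' (S1). Non-rolling sperm are classified by the overlap variable:
#' `s > R*Rprime` means the circular path misses the wall (S2);
#' `0 < s <= R*Rprime` means contact at an incidence angle above the
#' unstable angle, touch-and-detach (S3); `s <= 0` means tilted slow wall
#' swimming (S4). Boundary ties (`s = R*Rprime` to S3, `s = 0` to S4) are a
#' documented convention.
#'
#' @param scenario a [reservoir_scenario()].
#' @param rolling logical: is the sperm rolling?
#' @return one of `"S1" "S2" "S3" "S4"`.
#' @export
classify_interaction <- function(scenario, rolling = FALSE) {
  if (rolling) return("S1")
  s <- scenario$s; lim <- scenario$R * scenario$Rprime
  if (s > lim) "S2" else if (s > 0) "S3" else "S4"
}

#' Mean first transition time out of S2
#'
#' For a circular path starting concentric with the reservoir, the center
#' separation diffuses and first touches the wall (S2 to S3 transition)
#' after on average \deqn{\langle T\rangle = (R - R')^2 / 2D.}
#'
#' @param R,Rprime reservoir and orbit radii (um).
#' @param D center diffusion coefficient (um^2/s).
#' @return mean first transition time (s).
#' @export
mean_first_transition_time <- function(R, Rprime, D) {
  if (D <= 0) stop("D must be positive")
  (R - Rprime)^2 / (2 * D)
}

#' Angular-velocity threshold for the S3 to S4 transition
#'
#' After a first contact the sperm detaches at \eqn{\beta_s \approx
#' \Omega/|g'(0)|} and returns at the same angle; it passes the unstable
#' angle \eqn{\beta_u \approx \pi/2 + \Omega/g'(\pi/2)} — hence locks into
#' tilted wall swimming (S4) — when
#' \deqn{\Omega > \frac{\pi}{2}\,
#'       \frac{|g'(0)|\,g'(\pi/2)}{g'(\pi/2) - |g'(0)|}
#'       \approx \frac{\pi}{2}|g'(0)| \quad (|g'(0)| \ll g'(\pi/2)).}
#'
#' @param curve a [phase_curve()].
#' @param V_P optional speed (um/s) to also report the threshold curvature
#'   `kappa_th = Omega_th / V_P`.
#' @return list with `Omega_th` (rad/s), `Omega_th_approx`
#'   (`pi/2 * g0_slope`), and `kappa_th` (1/um or `NA`).
#' @export
omega_threshold <- function(curve, V_P = NULL) {
  g0 <- curve$g0_slope; gp <- curve$gpi_slope
  if (gp <= g0) stop("degenerate family: requires gpi_slope > g0_slope")
  om <- (pi / 2) * g0 * gp / (gp - g0)
  list(Omega_th = om, Omega_th_approx = (pi / 2) * g0,
       kappa_th = if (is.null(V_P)) NA_real_ else om / V_P)
}

#' Event-driven contact-detach-return threshold
#'
#' Simulates repeated contact cycles of a non-rolling sperm using the
#' linearized detachment law (detach at \eqn{\beta_s = \Omega/|g'(0)|},
#' return at the same incidence, unstable angle \eqn{\beta_u = \pi/2 +
#' \Omega/g'(\pi/2)}) over a grid of angular velocities, and returns the
#' smallest `Omega` whose cycle ends in S4.
#'
#' @param curve a [phase_curve()].
#' @param omega_grid angular velocities to scan (rad/s).
#' @param max_cycles contact cycles per `Omega`.
#' @return list with `Omega_first_S4` and the per-`Omega` outcome table.
#' @export
first_s4_omega <- function(curve, omega_grid, max_cycles = 10) {
  g0 <- curve$g0_slope; gp <- curve$gpi_slope
  state <- character(length(omega_grid))
  for (i in seq_along(omega_grid)) {
    om <- omega_grid[i]
    beta_in <- 0.1                       # first incidence, arbitrary
    st <- "S3"
    for (cycle in seq_len(max_cycles)) {
      beta_u <- pi / 2 + om / gp
      if (beta_in > beta_u) { st <- "S4"; break }
      beta_in <- om / g0                 # detach and return at beta_s
    }
    state[i] <- st
  }
  idx <- which(state == "S4")
  list(Omega_first_S4 = if (length(idx)) omega_grid[min(idx)] else NA_real_,
       outcomes = data.frame(Omega = omega_grid, state = state))
}

#' Run the sperm-wall state machine
#'
#' Evolves the orbit-center separation `d(t)` as a 1-D Brownian motion with
#' diffusion coefficient `D` (reflected at 0 and at the reservoir radius),
#' plus, at rolling events, ballistic relocations of length
#' `V_r * relocation_time` in a uniformly random direction. The state is
#' reclassified each step: a rolling sperm whose rolling is frequent
#' (`Omega * mu_SR < 2*pi`) becomes S1 upon first wall contact and stays
#' there; a non-rolling sperm's first contact pins its state through the
#' detachment-angle rule (S4 if `Omega` exceeds the curve threshold, S3
#' otherwise), since it returns to the wall at the angle at which it
#' detached; infrequent rolling keeps transitions reversible because
#' relocations reset the contact memory.
#'
#' @param scenario a [reservoir_scenario()].
#' @param rolling optional [rolling_process()].
#' @param Omega intrinsic angular velocity (rad/s).
#' @param curve a [phase_curve()] for the S3/S4 decision.
#' @param duration,dt horizon and step (s).
#' @param seed integer seed.
#' @param relocation_time duration of a ballistic relocation (s).
#' @return data.frame of class `state_history`: `time`, `state`, `d`, `s`.
#' @export
run_state_machine <- function(scenario, rolling = NULL, Omega = 0,
                              curve = phase_curve(1, 10), duration = 100,
                              dt = 0.05, seed = 1,
                              relocation_time = 0.2) {
  set.seed(seed)
  tt <- seq(0, duration, by = dt)
  n <- length(tt)
  ev <- if (is.null(rolling)) numeric(0) else rolling$events
  frequent <- !is.null(rolling) && is.finite(rolling$mu_SR) &&
    abs(Omega) * rolling$mu_SR < 2 * pi
  om_th <- omega_threshold(curve)$Omega_th
  d <- numeric(n); d[1] <- scenario$d
  st <- character(n)
  contacted <- FALSE
  lim <- scenario$R * scenario$Rprime
  ei <- 1
  for (i in seq_len(n)) {
    s_now <- 0.5 * (scenario$R^2 + scenario$Rprime^2 - d[i]^2)
    if (frequent) {
      if (!contacted && s_now <= lim) contacted <- TRUE
      st[i] <- if (contacted) "S1" else "S2"
    } else if (!is.null(rolling)) {
      # infrequent rolling: reversible classification by s
      st[i] <- if (s_now > lim) "S2" else if (s_now > 0) "S3" else "S4"
    } else {
      if (!contacted && s_now <= lim) contacted <- TRUE
      st[i] <- if (!contacted) "S2"
               else if (abs(Omega) > om_th) "S4" else "S3"
    }
    if (i < n) {
      jump <- 0
      while (ei <= length(ev) && ev[ei] <= tt[i + 1]) {
        if (!frequent) {
          j <- scenario$V_r * relocation_time
          phi <- runif(1, 0, 2 * pi)
          jump <- sqrt(d[i]^2 + j^2 + 2 * d[i] * j * cos(phi)) - d[i]
        }
        ei <- ei + 1
      }
      step <- if (frequent && contacted) 0 else
        rnorm(1, 0, sqrt(2 * scenario$D * dt))
      dn <- d[i] + step + jump
      dn <- abs(dn)                          # reflect at 0
      if (dn > scenario$R) dn <- 2 * scenario$R - dn
      d[i + 1] <- dn
    }
  }
  structure(data.frame(time = tt, state = st, d = d,
                       s = 0.5 * (scenario$R^2 + scenario$Rprime^2 - d^2)),
            class = c("state_history", "data.frame"))
}

#' Swept-area gain from intermittent relocations
#'
#' The area a diffusing circular path sweeps grows like the square root of
#' time, so splitting a long diffusive phase into `n` phases separated by
#' ballistic relocations multiplies coverage:
#' \eqn{\sum_i \sqrt{T_i} \ge \sqrt{\sum_i T_i}}. A grid-coverage
#' Monte-Carlo estimate (distinct cells visited by a diffusing disc, with
#' and without relocations between intervals) is returned alongside the
#' analytic proxies.
#'
#' @param T_intervals positive diffusion interval durations (s).
#' @param D diffusion coefficient (um^2/s).
#' @param mc run the Monte-Carlo coverage estimate?
#' @param seed integer seed.
#' @param dt Monte-Carlo step (s).
#' @param cell grid cell size (um).
#' @param relocation_length ballistic jump length between intervals (um).
#' @return list with `proxy_reloc` (`sum sqrt(T_i)`), `proxy_plain`
#'   (`sqrt(sum T_i)`), and when `mc`, `cells_reloc`, `cells_plain`.
#' @export
swept_area_comparison <- function(T_intervals, D, mc = TRUE, seed = 1,
                                  dt = 0.05, cell = NULL,
                                  relocation_length = NULL) {
  if (any(T_intervals <= 0)) stop("intervals must be positive")
  out <- list(proxy_reloc = sum(sqrt(T_intervals)),
              proxy_plain = sqrt(sum(T_intervals)))
  if (!mc) return(out)
  set.seed(seed)
  if (is.null(cell)) cell <- sqrt(2 * D * dt)
  if (is.null(relocation_length))
    relocation_length <- 6 * sqrt(2 * D * mean(T_intervals))
  walk <- function(relocate) {
    pos <- c(0, 0); cells <- character(0)
    for (Ti in T_intervals) {
      nstep <- max(2L, round(Ti / dt))
      steps <- matrix(rnorm(2 * nstep, 0, sqrt(2 * D * dt)), ncol = 2)
      path <- sweep(apply(steps, 2, cumsum), 2, pos, "+")
      cells <- c(cells, unique(paste(floor(path[, 1] / cell),
                                     floor(path[, 2] / cell))))
      pos <- path[nstep, ]
      if (relocate) {
        phi <- runif(1, 0, 2 * pi)
        pos <- pos + relocation_length * c(cos(phi), sin(phi))
      }
    }
    length(unique(cells))
  }
  out$cells_reloc <- walk(TRUE)
  out$cells_plain <- walk(FALSE)
  out
}
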
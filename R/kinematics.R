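#' Resistive-force-theory drag coefficients
#'
#' Anisotropic local drag per unit length for a slender flagellum. The
#' default closure is Gray-Hancock:
#' \deqn{\xi_T = \frac{2\pi\mu}{\ln(2\lambda/d) - 1/2}, \qquad \xi_N = 2\xi_T,}
#' with flagellum diameter `d`. Propulsion requires `xi_N > xi_T > 0`.
#' In these units (Pa s = pN s / um^2) forces come out in pN when lengths
#' are um and rates 1/s.
#'
#' @param mu ambient dynamic viscosity (Pa s). Default 3.2e-3, the standard
#'   TALP medium.
#' @param lambda wavelength of the flagellar wave (um).
#' @param d flagellum diameter (um).
#' @param ratio normal-to-tangential ratio `xi_N / xi_T`.
#' @param xi_T,xi_N explicit overrides (Pa s); when given, `ratio` and the
#'   Gray-Hancock formula are ignored.
#' @return object of class `drag_coefficients` with `xi_T`, `xi_N`, `mu`.
#' @export
drag_coefficients <- function(mu = 3.2e-3, lambda = 60, d = 0.4, ratio = 2,
                              xi_T = NULL, xi_N = NULL) {
  if (is.null(xi_T)) xi_T <- 2 * pi * mu / (log(2 * lambda / d) - 0.5)
  if (is.null(xi_N)) xi_N <- ratio * xi_T
  if (!(xi_N > xi_T && xi_T > 0))
    stop("drag anisotropy xi_N > xi_T > 0 is required for propulsion")
  structure(list(xi_T = xi_T, xi_N = xi_N, mu = mu),
            class = "drag_coefficients")
}

#' Flagellar torque from the zeroth harmonic
#'
#' Time-averaged torque generated by an asymmetric beat,
#' \deqn{\tau_f = (\xi_N - \xi_T)\,\omega k L\, a_0 \sum_n n\,\tilde a_n^2.}
#' Only the zeroth harmonic enters linearly: a symmetric beat (`a_0 = 0`) or
#' isotropic drag (`xi_N = xi_T`) produces no torque. Units are pN um for
#' amplitudes in um, `omega` in rad/s and drags in Pa s.
#'
#' @param spec a [beat_spec()].
#' @param drag a [drag_coefficients()].
#' @return torque (pN um), signed like `a_0`.
#' @export
flagellar_torque <- function(spec, drag) {
  stopifnot(inherits(spec, "beat_spec"), inherits(drag, "drag_coefficients"))
  a <- spec$amplitudes
  n <- seq_along(a) - 1
  (drag$xi_N - drag$xi_T) * spec$omega * spec$k * spec$L * a[1] *
    sum(n * a^2)
}

#' Solve the planar free swimmer
#'
#' Resistive-force-theory force and torque balance for a small-amplitude
#' travelling-wave beat. The closure used here (documented, not fitted):
#' propulsive thrust \eqn{(\xi_N-\xi_T)\langle \dot y\, y' \rangle} balanced
#' by tangential body drag \eqn{\xi_T L V_P} gives
#' \deqn{V_P = \left(\frac{\xi_N}{\xi_T} - 1\right)\frac{\omega k}{2}
#'       \sum_{n\ge1} n\, a_n^2;}
#' the flagellar torque balanced by rotational drag about the flagellum
#' midpoint (\eqn{\xi_N L^3/12}) gives
#' \deqn{\Omega = \frac{12\,\tau_f}{\xi_N L^3}
#'       = 24\,\frac{\xi_T}{\xi_N}\,\frac{a_0}{L^2}\,V_P,}
#' i.e. the stated proportionality \eqn{\Omega \propto
#' (\xi_T/\xi_N)(a_0/L^2)V_P} with closure constant 24.
#'
#' @param spec a [beat_spec()].
#' @param drag a [drag_coefficients()].
#' @param V_N perpendicular speed (um/s); zero at this order of the theory,
#'   kept as a settable field for the rheotaxis corrections.
#' @return object of class `swimmer_kinematics` with `V_P`, `V_N`, `Omega`,
#'   `kappa = Omega/V_P` (1/um), `tau_f` (pN um) and a `degenerate` flag
#'   (no propulsive harmonics).
#' @export
solve_planar_swimmer <- function(spec, drag, V_N = 0) {
  stopifnot(inherits(spec, "beat_spec"), inherits(drag, "drag_coefficients"))
  a <- spec$amplitudes
  n <- seq_along(a) - 1
  s2 <- sum(n * a^2)                 # n = 0 term drops out
  degenerate <- s2 <= 0
  V_P <- if (degenerate) 0 else
    (drag$xi_N / drag$xi_T - 1) * spec$omega * spec$k / 2 * s2
  tau_f <- flagellar_torque(spec, drag)
  Omega <- if (degenerate) 0 else 12 * tau_f / (drag$xi_N * spec$L^3)
  structure(list(
    V_P = V_P, V_N = V_N, Omega = Omega,
    kappa = if (V_P > 0) Omega / V_P else NA_real_,
    tau_f = tau_f, degenerate = degenerate
  ), class = "swimmer_kinematics")
}

#' @export
print.swimmer_kinematics <- function(x, ...) {
  cat("<swimmer_kinematics> V_P =", signif(x$V_P, 4), "um/s, Omega =",
      signif(x$Omega, 4), "rad/s, kappa =", signif(x$kappa, 4), "1/um\n")
  invisible(x)
}

#' Average progressive speed of a rolling swimmer
#'
#' A swimmer with intrinsic angular velocity `Omega` whose asymmetry
#' direction flips every `T_SR` seconds sweeps a triangular heading; the
#' magnitude of its net drift is
#' \deqn{\bar V = V_P \left| \frac{2 \sin(\Omega \tilde T_{SR}/2)}
#'       {\Omega \tilde T_{SR}} \right|.}
#' As \eqn{\Omega \tilde T_{SR} \to 0} (frequent rolling) the drift
#' approaches `V_P`; without rolling (`T_SR` infinite) the net drift of the
#' circular motion is 0.
#'
#' @param V_P propulsive speed (um/s).
#' @param Omega intrinsic angular velocity (rad/s).
#' @param T_SR mean rolling interval (s); may be `Inf`.
#' @return mean progressive speed (um/s).
#' @export
average_progressive_speed <- function(V_P, Omega, T_SR) {
  if (T_SR < 0) stop("T_SR must be non-negative")
  if (!is.finite(T_SR)) return(0)
  x <- Omega * T_SR
  if (x == 0) return(V_P)
  V_P * abs(2 * sin(x / 2) / x)
}

#' Planar track
#'
#' Time-stamped planar positions, the unit of exchange between the
#' simulator and the analysis stack. Times must be strictly increasing and
#' uniformly spaced.
#'
#' @param time times (s).
#' @param x,y positions (um).
#' @param heading optional heading (rad).
#' @param hli optional head-light-intensity channel (arbitrary units).
#' @return a data.frame of class `track` with attribute `dt`.
#' @export
track <- function(time, x, y, heading = NULL, hli = NULL) {
  stopifnot(length(time) == length(x), length(x) == length(y))
  dt <- diff(time)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (diff(range(dt)) > 1e-9) stop("frame interval must be uniform")
  df <- data.frame(time = time, x = x, y = y)
  if (!is.null(heading)) df$heading <- heading
  if (!is.null(hli)) df$hli <- hli
  structure(df, class = c("track", "data.frame"), dt = dt[1])
}

#' Integrate a swimmer trajectory
#'
#' Euler-Maruyama integration of
#' \deqn{\dot\theta = \Pi(t)\,\Omega\,(1 + \eta_0(t)), \qquad
#'       (\dot x, \dot y) = V_P(\cos\theta, \sin\theta),}
#' where \eqn{\eta_0} is the multiplicative zeroth-harmonic amplitude noise
#' with intensity `D0` (per-step Gaussian with sd `sqrt(D0/dt)`), and
#' \eqn{\Pi(t)} flips at the rolling events. Angles are radians,
#' counter-clockwise positive; positions in um.
#'
#' @param kin a [swimmer_kinematics()] (or any list with `V_P`, `Omega`).
#' @param rolling optional [rolling_process()].
#' @param D0 noise intensity of the zeroth-harmonic amplitude (1/s).
#' @param dt time step (s); `dt <= 0.01/max(|Omega|, omega_SR)` recommended.
#' @param duration total time (s).
#' @param seed integer seed (used for the heading noise).
#' @param x0,theta0 initial position (um) and heading (rad).
#' @return a [track()] including the `heading` column.
#' @export
integrate_trajectory <- function(kin, rolling = NULL, D0 = 0, dt, duration,
                                 seed = NULL, x0 = c(0, 0), theta0 = 0) {
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, duration, by = dt)
  n <- length(tt)
  p <- if (is.null(rolling)) rep(1, n) else build_pi(events_in_grid(rolling$events, tt), tt)$pi
  eta <- if (D0 > 0) rnorm(n - 1, 0, sqrt(D0 / dt)) else numeric(n - 1)
  dtheta <- p[-n] * kin$Omega * (1 + eta) * dt
  theta <- theta0 + c(0, cumsum(dtheta))
  xx <- x0[1] + c(0, cumsum(kin$V_P * cos(theta[-n]) * dt))
  yy <- x0[2] + c(0, cumsum(kin$V_P * sin(theta[-n]) * dt))
  track(tt, xx, yy, heading = theta)
}
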
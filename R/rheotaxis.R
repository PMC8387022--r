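#' Rheotaxis parameters
#'
#' Parameters of the Adler-type model for upstream orientation under simple
#' shear. The shear response enters through the product `A*gamma` (rad/s):
#' the restoring angular velocity is \eqn{\Omega_{RH} = -A\gamma\sin\theta},
#' with `theta = 0` heading upstream.
#'
#' @param A shear-response constant (um); the default is chosen so that
#'   `A*gamma = 10` rad/s at the default shear rate.
#' @param gamma shear rate (1/s); default 0.6, a very low shear at which
#'   sperm rheotaxis operates.
#' @param V_F external flow speed (um/s).
#' @param V_P,V_N,Omega swimmer propulsive speed, perpendicular speed
#'   (um/s) and intrinsic angular velocity (rad/s).
#' @return object of class `rheotaxis_params`.
#' @export
rheotaxis_params <- function(A = 10 / 0.6, gamma = 0.6, V_F = 10,
                             V_P = 70, V_N = 0, Omega = 0) {
  if (gamma < 0) stop("gamma must be non-negative")
  structure(list(A = A, gamma = gamma, V_F = V_F, V_P = V_P, V_N = V_N,
                 Omega = Omega), class = "rheotaxis_params")
}

#' Adler right-hand side
#'
#' Net angular velocity of a swimmer with intrinsic rotation `Omega` and
#' asymmetry direction `Pi` under shear:
#' \deqn{\dot\theta = -A\gamma\sin\theta + \Pi\,\Omega.}
#'
#' @param theta orientation relative to upstream (rad).
#' @param params a [rheotaxis_params()].
#' @param Pi switching value, +1 or -1.
#' @return `dtheta/dt` (rad/s); vectorized over `theta`.
#' @export
adler_rhs <- function(theta, params, Pi = 1) {
  -params$A * params$gamma * sin(theta) + Pi * params$Omega
}

#' Upstream fixed point of the Adler equation
#'
#' When \eqn{|\Omega| \le A\gamma} the swimmer phase-locks at
#' \deqn{\theta_{UP} = \arcsin(\Omega / A\gamma);} otherwise no fixed point
#' exists and the orientation winds continuously (tumbling). Stability of
#' the returned root is verified (\eqn{\dot\theta} crosses zero downward).
#'
#' @param params a [rheotaxis_params()].
#' @return list with `exists` (logical), `theta_UP` (rad or `NA`), `ratio`
#'   (`Omega/(A*gamma)`), `stable` (logical).
#' @export
upstream_fixed_point <- function(params) {
  if (params$gamma <= 0) stop("gamma must be positive for a fixed point")
  r <- params$Omega / (params$A * params$gamma)
  if (abs(r) > 1)
    return(list(exists = FALSE, theta_UP = NA_real_, ratio = r,
                stable = NA))
  th <- asin(r)
  eps <- 1e-6
  stable <- adler_rhs(th + eps, params) < 0 && adler_rhs(th - eps, params) > 0
  list(exists = TRUE, theta_UP = th, ratio = r, stable = stable)
}

#' Rolling-averaged upstream orientation
#'
#' With rolling, the instantaneous locked angle is
#' \eqn{\theta^*_{UP}(t) = \arcsin(\Pi(t)\Omega/A\gamma)}, whose time
#' average is \deqn{\tilde\theta_{UP} = \tilde\Pi \arcsin(\Omega/A\gamma).}
#' Frequent rolling (\eqn{\tilde\Pi \to 0}) drives the mean orientation to
#' zero, i.e. directly upstream.
#'
#' @param params a [rheotaxis_params()].
#' @param rolling a [rolling_process()], or a numeric duty average
#'   `pi_tilde` in `[-1, 1]`.
#' @param duration horizon used to compute the duty average from a rolling
#'   process (s).
#' @return list with `theta_tilde_UP` (rad), `pi_tilde`, `theta_UP`.
#' @export
rolling_averaged_orientation <- function(params, rolling, duration = NULL) {
  fp <- upstream_fixed_point(params)
  if (!fp$exists) stop("no upstream lock: |Omega| > A*gamma")
  pi_tilde <- duty_average(rolling, duration)
  list(theta_tilde_UP = pi_tilde * fp$theta_UP, pi_tilde = pi_tilde,
       theta_UP = fp$theta_UP)
}

#' Duty average of a switching process
#'
#' Time average \eqn{\tilde\Pi} of the switching function over the
#' observation window. Accepts a bare numeric duty average (returned
#' unchanged) so closed-form expressions can be evaluated directly.
#'
#' @param rolling a [rolling_process()] or a numeric in `[-1, 1]`.
#' @param duration averaging horizon (s); defaults to the process duration.
#' @return the duty average, in `[-1, 1]`.
#' @export
duty_average <- function(rolling, duration = NULL) {
  if (is.numeric(rolling)) {
    stopifnot(length(rolling) == 1, abs(rolling) <= 1)
    return(rolling)
  }
  stopifnot(inherits(rolling, "rolling_process"))
  dur <- if (!is.null(duration)) duration else rolling$duration
  tt <- seq(0, dur, length.out = 65536)
  build_pi(rolling$events[rolling$events <= dur], tt)$pi_tilde
}

#' Net upstream velocity
#'
#' Upstream drift of a phase-locked swimmer. With frequent rolling the mean
#' lock angle is small and
#' \deqn{\tilde V_{UP} = V_P\cos(\tilde\theta_{UP}) - V_F \approx V_P - V_F;}
#' without rolling the lock angle \eqn{\theta_{UP}} costs upstream speed:
#' exact form \eqn{V_P\cos\theta_{UP} - V_F} and quadratic expansion
#' \deqn{\tilde V_{UP} \approx V_P - V_F - \left( V_N\frac{\Omega}{A\gamma}
#'       + \frac{1}{2} V_P \left(\frac{\Omega}{A\gamma}\right)^2 \right).}
#'
#' @param params a [rheotaxis_params()].
#' @param rolling optional [rolling_process()] or duty average; when given,
#'   the rolling-averaged lock angle is used.
#' @return list with `V_UP_exact`, `V_UP_quadratic` (um/s), and the lock
#'   angle used (`theta`, rad).
#' @export
upstream_velocity <- function(params, rolling = NULL) {
  fp <- upstream_fixed_point(params)
  if (!fp$exists) stop("no upstream lock: |Omega| > A*gamma")
  r <- fp$ratio
  if (is.null(rolling)) {
    th <- fp$theta_UP
    quad <- params$V_P - params$V_F -
      (params$V_N * r + 0.5 * params$V_P * r^2)
  } else {
    pt <- duty_average(rolling)
    th <- pt * fp$theta_UP
    rq <- pt * r
    quad <- params$V_P - params$V_F -
      (params$V_N * rq + 0.5 * params$V_P * rq^2)
  }
  list(V_UP_exact = params$V_P * cos(th) - params$V_F,
       V_UP_quadratic = quad, theta = th)
}

#' Time-average of the Adler equation under switching
#'
#' Integrates \eqn{\dot\theta = -A\gamma\sin\theta + \Pi(t)\Omega} with a
#' piecewise-constant switching function (fixed-step fourth-order
#' Runge-Kutta) and returns the time-averaged orientation over the second
#' half of the run, for cross-checking the closed-form rolling average.
#'
#' @param params a [rheotaxis_params()].
#' @param rolling a [rolling_process()], or `NULL` for no switching.
#' @param duration integration time (s).
#' @param dt time step (s).
#' @param theta0 initial orientation (rad).
#' @return list with `theta_mean` (rad, second-half average), `theta`
#'   (full series), `time`.
#' @export
adler_time_average <- function(params, rolling = NULL, duration = 20,
                               dt = 1e-3, theta0 = 0) {
  tt <- seq(0, duration, by = dt)
  n <- length(tt)
  p <- if (is.null(rolling)) rep(1, n) else build_pi(events_in_grid(rolling$events, tt), tt)$pi
  Ag <- params$A * params$gamma; Om <- params$Omega
  theta <- numeric(n); theta[1] <- theta0
  for (i in seq_len(n - 1)) {
    f <- function(th) -Ag * sin(th) + p[i] * Om
    k1 <- f(theta[i]); k2 <- f(theta[i] + dt / 2 * k1)
    k3 <- f(theta[i] + dt / 2 * k2); k4 <- f(theta[i] + dt * k3)
    theta[i + 1] <- theta[i] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  half <- tt >= duration / 2
  list(theta_mean = mean(theta[half]), theta = theta, time = tt)
}
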
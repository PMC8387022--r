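#' Least-squares circle fit
#'
#' Algebraic (Kasa) circle fit: linear least squares on
#' \eqn{x^2 + y^2 = 2ax + 2by + c}, deterministic and exact on noiseless
#' circles. Degenerate (collinear) point sets raise an error.
#'
#' @param x,y point coordinates (um); `x` may be a [track()] in which case
#'   `y` is ignored.
#' @return object of class `circular_fit`: `center` (um), `radius` (um),
#'   `kappa = 1/radius` (1/um).
#' @export
fit_circle <- function(x, y = NULL) {
  if (inherits(x, "track")) { y <- x$y; x <- x$x }
  if (length(x) < 3) stop("need at least 3 points")
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  qrA <- qr(A)
  if (qrA$rank < 3) stop("degenerate fit: points are collinear")
  cf <- qr.coef(qrA, b)
  r2 <- cf[3] + cf[1]^2 + cf[2]^2
  if (!is.finite(r2) || r2 <= 0) stop("degenerate fit: points are collinear")
  r <- sqrt(unname(r2))
  structure(list(center = unname(c(cf[1], cf[2])), radius = r,
                 kappa = 1 / r),
            class = "circular_fit")
}

#' @export
print.circular_fit <- function(x, ...) {
  cat("<circular_fit> center (", signif(x$center[1], 6), ",",
      signif(x$center[2], 6), ") um, radius", signif(x$radius, 6),
      "um, kappa", signif(x$kappa, 6), "1/um\n")
  invisible(x)
}

#' Windowed circle fits along a track
#'
#' Fits circles in sliding windows to produce the curvature series
#' `kappa(t)` and the circular-path center series used for center-diffusion
#' analysis.
#'
#' @param trk a [track()].
#' @param window window length in frames.
#' @param step window step in frames.
#' @return data.frame with `time` (window center, s), `cx`, `cy` (um),
#'   `kappa` (1/um).
#' @export
windowed_circle_fit <- function(trk, window, step = window) {
  stopifnot(inherits(trk, "track"), window >= 3)
  n <- nrow(trk)
  starts <- seq(1, n - window + 1, by = step)
  res <- lapply(starts, function(i) {
    idx <- i:(i + window - 1)
    f <- tryCatch(fit_circle(trk$x[idx], trk$y[idx]),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(time = mean(trk$time[idx]), cx = f$center[1],
               cy = f$center[2], kappa = f$kappa)
  })
  do.call(rbind, res)
}

#' Discrete curvature series of a track
#'
#' Unsigned turning-angle curvature per step,
#' \eqn{\kappa_i = \Delta\theta_i / \Delta s_i}, from successive segment
#' headings. For a noisy-curvature circular swimmer this recovers the
#' instantaneous multiplicative curvature noise frame by frame.
#'
#' @param trk a [track()].
#' @return data.frame with `time` and `kappa` (1/um).
#' @export
track_curvature_series <- function(trk) {
  stopifnot(inherits(trk, "track"))
  dx <- diff(trk$x); dy <- diff(trk$y)
  th <- atan2(dy, dx)
  dth <- diff(th)
  dth <- atan2(sin(dth), cos(dth))       # wrap to (-pi, pi]
  ds <- sqrt(dx^2 + dy^2)
  ds_mid <- (ds[-1] + ds[-length(ds)]) / 2
  data.frame(time = trk$time[2:(nrow(trk) - 1)], kappa = dth / ds_mid)
}

#' Mean square displacement of a center series and diffusion coefficient
#'
#' MSD over lag times; the diffusion coefficient is estimated from the 2-D
#' convention `MSD = 4 D tau` by a linear fit through the origin over the
#' first `fit_fraction` of available lags. The log-log slope over the same
#' range reports ballistic (`~2`) versus diffusive (`~1`) scaling.
#'
#' @param cx,cy center coordinates (um); `cx` may be a data.frame holding
#'   `cx`, `cy` columns (as from [windowed_circle_fit()]).
#' @param dt sampling interval of the series (s).
#' @param max_lag maximum lag in samples; default a quarter of the series.
#' @param fit_fraction fraction of lags used in the fits (default 0.1 of
#'   the series length, at least 10 lags).
#' @return list with `lag` (s), `msd` (um^2), `D` (um^2/s),
#'   `loglog_slope`.
#' @export
center_msd <- function(cx, cy = NULL, dt, max_lag = NULL,
                       fit_fraction = 0.1) {
  if (is.data.frame(cx)) { cy <- cx$cy; cx <- cx$cx }
  n <- length(cx)
  if (is.null(max_lag)) max_lag <- floor(n / 4)
  max_lag <- min(max_lag, n - 1)
  if (max_lag < 10) stop("insufficient data: fewer than 10 lags")
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(k)
    mean((cx[(k + 1):n] - cx[1:(n - k)])^2 +
         (cy[(k + 1):n] - cy[1:(n - k)])^2), numeric(1))
  tau <- lags * dt
  nfit <- max(10L, floor(fit_fraction * n))
  nfit <- min(nfit, max_lag)
  sel <- seq_len(nfit)
  D <- sum(msd[sel] * tau[sel]) / (4 * sum(tau[sel]^2))  # through origin
  sl <- coef(lm(log(msd[sel]) ~ log(tau[sel])))[2]
  list(lag = tau, msd = msd, D = unname(D), loglog_slope = unname(sl))
}

#' Curvature signal-to-noise ratio
#'
#' \deqn{SNR = \tilde\kappa^2 / (\langle\kappa^2\rangle - \tilde\kappa^2).}
#' Lower SNR at identical mean curvature means faster diffusion of the
#' circular path's center. Zero curvature variance is flagged as an
#' infinite-SNR result rather than an error.
#'
#' @param kappa curvature samples (1/um).
#' @return list with `snr`, `kappa_mean`, `infinite` (logical).
#' @export
snr_kappa <- function(kappa) {
  if (length(kappa) < 30) stop("need at least 30 curvature samples")
  m <- mean(kappa)
  v <- mean(kappa^2) - m^2
  if (v <= 0) return(list(snr = Inf, kappa_mean = m, infinite = TRUE))
  list(snr = m^2 / v, kappa_mean = m, infinite = FALSE)
}

#' Normalized mean step size of the circular path's center
#'
#' Mean squared center displacement per sample, normalized by the mean
#' curvature: \eqn{\delta^2\kappa^2}. Across tracks of identical mean
#' curvature this quantity is inversely proportional to the curvature SNR.
#'
#' @param centers data.frame with `cx`, `cy` (um).
#' @param kappa_mean mean path curvature (1/um).
#' @return normalized mean squared step (dimensionless).
#' @export
normalized_mean_step <- function(centers, kappa_mean) {
  d2 <- diff(centers$cx)^2 + diff(centers$cy)^2
  mean(d2) * kappa_mean^2
}

#' Wall-interaction metrics of a track
#'
#' Detention is the first contiguous episode within `tol` of the wall.
#' `T_D` is its duration; `V*` the mean speed during detention divided by
#' the mean speed over the second preceding first contact; `rho*` the path
#' length travelled while on the wall divided by the total path length
#' from first contact to the end of the track (wall-followers stay near 1,
#' touch-and-detach sperm fall well below 1).
#'
#' @param trk a [track()].
#' @param wall list: `list(type = "circle", center =, R =)` or
#'   `list(type = "line", point =, normal =)`.
#' @param tol contact tolerance (um); default 5.
#' @return object of class `wall_metrics`: `T_D` (s), `V_star`, `rho_star`,
#'   `incidence_angle`, `detachment_angle` (rad), `contact` (logical).
#' @export
wall_metrics <- function(trk, wall, tol = 5) {
  stopifnot(inherits(trk, "track"))
  d <- if (wall$type == "circle")
    abs(wall$R - sqrt((trk$x - wall$center[1])^2 +
                      (trk$y - wall$center[2])^2))
  else {
    nrm <- wall$normal / sqrt(sum(wall$normal^2))
    abs((trk$x - wall$point[1]) * nrm[1] + (trk$y - wall$point[2]) * nrm[2])
  }
  on_wall <- d <= tol
  if (!any(on_wall))
    return(structure(list(contact = FALSE, T_D = 0, V_star = NA_real_,
                          rho_star = NA_real_, incidence_angle = NA_real_,
                          detachment_angle = NA_real_),
                     class = "wall_metrics"))
  dt <- attr(trk, "dt")
  i0 <- which(on_wall)[1]
  run <- i0
  while (run < nrow(trk) && on_wall[run + 1]) run <- run + 1
  T_D <- (run - i0) * dt
  seg_len <- c(0, sqrt(diff(trk$x)^2 + diff(trk$y)^2))
  v_on <- sum(seg_len[(i0 + 1):max(i0 + 1, run)]) / max(T_D, dt)
  pre <- trk$time >= trk$time[i0] - 1 & trk$time < trk$time[i0]
  v_pre <- if (sum(pre) >= 2) {
    idx <- which(pre)
    sum(seg_len[idx[-1]]) / (dt * (sum(pre) - 1))
  } else NA_real_
  path_after <- sum(seg_len[(i0 + 1):nrow(trk)])
  path_on <- sum(seg_len[which(on_wall & seq_len(nrow(trk)) > i0)])
  tangent_angle <- function(i) {
    j <- max(2, min(i, nrow(trk)))
    head_ang <- atan2(trk$y[j] - trk$y[j - 1], trk$x[j] - trk$x[j - 1])
    wall_tan <- if (wall$type == "circle") {
      v <- c(trk$x[j] - wall$center[1], trk$y[j] - wall$center[2])
      atan2(v[1], -v[2])                 # CCW tangent
    } else atan2(-wall$normal[1], wall$normal[2])
    a <- head_ang - wall_tan
    atan2(sin(a), cos(a))
  }
  structure(list(
    contact = TRUE, T_D = T_D,
    V_star = if (is.na(v_pre) || v_pre == 0) NA_real_ else v_on / v_pre,
    rho_star = if (path_after > 0) path_on / path_after else NA_real_,
    incidence_angle = tangent_angle(i0),
    detachment_angle = tangent_angle(run)
  ), class = "wall_metrics")
}

#' Thermal rotational diffusion bound
#'
#' Approximating the sperm as a rigid rod of length `L` and diameter `d`,
#' the rotational diffusion coefficient is
#' \deqn{D_r = \frac{3 k_B T\,(\ln p + \delta_r)}{\pi \mu L^3}, \qquad
#'       p = L/d,}
#' with the Tirado-Garcia de la Torre end correction
#' \eqn{\delta_r = -0.662 + 0.917/p - 0.050/p^2}. The implied curvature SNR
#' at mean curvature `kappa` accumulates the thermal heading variance
#' `2 D_r T` over one orbit (`T = 2 pi / (kappa V_P)`):
#' \eqn{SNR_{th} = \pi \kappa V_P / D_r}. For sperm-scale rods this bound
#' is orders of magnitude above measured path SNRs, so thermal noise cannot
#' explain the observed center diffusion.
#'
#' @param L rod length (um); default 80 (head plus flagellum).
#' @param d rod diameter (um); default 5.
#' @param mu viscosity (Pa s); default 3.2e-3 (TALP).
#' @param temperature absolute temperature (K); default 310 (37 C).
#' @param kappa optional mean path curvature (1/um) for the implied SNR.
#' @param V_P path speed used in the SNR estimate (um/s).
#' @return object of class `thermal_bound`: `D_r` (1/s),
#'   `order_of_magnitude` (`floor(log10 D_r)`), `snr_thermal` (or `NA`).
#' @export
thermal_rotational_diffusion <- function(L = 80, d = 5, mu = 3.2e-3,
                                         temperature = 310, kappa = NULL,
                                         V_P = 80) {
  if (L <= d || d <= 0) stop("require L > d > 0")
  p <- L / d
  delta_r <- -0.662 + 0.917 / p - 0.050 / p^2
  L_m <- L * 1e-6
  D_r <- 3 * .kB * temperature * (log(p) + delta_r) / (pi * mu * L_m^3)
  structure(list(
    D_r = D_r, order_of_magnitude = floor(log10(D_r)),
    snr_thermal = if (is.null(kappa)) NA_real_ else pi * kappa * V_P / D_r,
    L = L, d = d, mu = mu, temperature = temperature
  ), class = "thermal_bound")
}

#' @export
print.thermal_bound <- function(x, ...) {
  cat("<thermal_bound> D_r =", signif(x$D_r, 4), "1/s (order 10^",
      x$order_of_magnitude, ")\n", sep = "")
  invisible(x)
}
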
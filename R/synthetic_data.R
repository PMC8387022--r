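#' Medium presets
#'
#' Swimming conditions in the standard medium (TALP) and in the viscous
#' (4% polyvinylpyrrolidone, `PVP4`) and viscoelastic (1% polyacrylamide,
#' `PAM1`) solutions: path speed 70 +- 5 um/s in TALP and PAM1 and
#' 45 +- 5 um/s in PVP4; rolling active only in TALP, with intervals of
#' mean 0.11 s and sd 0.02 s; frame intervals 0.08 s (TALP, PAM1) and
#' 0.16 s (PVP4).
#'
#' @param name one of `"TALP"`, `"PVP4"`, `"PAM1"`.
#' @return object of class `medium_preset`.
#' @export
medium_preset <- function(name = c("TALP", "PVP4", "PAM1")) {
  name <- match.arg(name)
  p <- switch(name,
    TALP = list(speed = 70, rolling = TRUE, interval_mean = 0.11,
                interval_sd = 0.02, dt = 0.08,
                kappa_range = c(0.003, 0.02), snr_range = c(10, 1000)),
    PVP4 = list(speed = 45, rolling = FALSE, interval_mean = NA,
                interval_sd = NA, dt = 0.16,
                kappa_range = c(0.003, 0.03), snr_range = c(10, 1000)),
    PAM1 = list(speed = 70, rolling = FALSE, interval_mean = NA,
                interval_sd = NA, dt = 0.08,
                kappa_range = c(0.003, 0.05), snr_range = c(10, 1000)))
  structure(c(list(name = name), p), class = "medium_preset")
}

#' Generate a synthetic sperm track
#'
#' Emulates the microscopy track phenomenology consumed by the analysis
#' stack. Modes:
#' \describe{
#'   \item{progressive}{rolling trajectory: heading integrated with the
#'     switching function of a sampled rolling process (frequent rolling
#'     converts the intrinsic rotation `Omega` into progressive motion).}
#'   \item{circular}{non-rolling diffusive circle: per-frame multiplicative
#'     curvature noise `kappa(t) = kappa (1 + eta)` with
#'     `sd(eta) = 1/sqrt(snr)`.}
#'   \item{intermittent}{circular motion interrupted at rolling events by
#'     ballistic relocations (speed `V_r`, duration `relocation_time`) with
#'     a CW/CCW flip of the circling direction.}
#'   \item{medium_switch}{concatenation of a progressive phase in
#'     `preset` and a circular phase in `preset2` with an instantaneous
#'     behavioural switch at the boundary (suppression of rolling on
#'     entering the viscous/viscoelastic medium).}
#' }
#' An HLI channel with one pulse per rolling event is attached, and the
#' ground truth (curvature, events, mode parameters) is stored in the
#' `"truth"` attribute.
#'
#' @param preset a [medium_preset()] or preset name.
#' @param mode one of `"progressive"`, `"circular"`, `"intermittent"`,
#'   `"medium_switch"`.
#' @param duration track duration (s).
#' @param seed integer seed.
#' @param kappa path curvature (1/um); default the preset mid-range.
#' @param snr curvature signal-to-noise ratio for circular modes.
#' @param Omega intrinsic angular velocity for the progressive mode
#'   (rad/s).
#' @param dt frame interval override (s).
#' @param preset2 second preset for `medium_switch`.
#' @param interval_mean,interval_sd rolling-interval overrides (s); for
#'   intermittent mode they default to sparse rolling (mean 5 s, sd 1 s).
#' @param relocation_time ballistic relocation duration (s).
#' @param hli_pulse_width HLI pulse width (s); default one frame.
#' @return a [track()] with `hli` channel and a `"truth"` attribute.
#' @export
make_track <- function(preset = "TALP",
                       mode = c("progressive", "circular", "intermittent",
                                "medium_switch"),
                       duration = 40, seed = 1, kappa = NULL, snr = 100,
                       Omega = 3, dt = NULL, preset2 = "PVP4",
                       interval_mean = NULL, interval_sd = NULL,
                       relocation_time = 0.3, hli_pulse_width = NULL) {
  if (is.character(preset)) preset <- medium_preset(preset)
  stopifnot(inherits(preset, "medium_preset"))
  mode <- match.arg(mode)
  if (is.null(dt)) dt <- preset$dt
  if (is.null(kappa)) kappa <- mean(preset$kappa_range)
  set.seed(seed)

  if (mode == "medium_switch") {
    if (is.character(preset2)) preset2 <- medium_preset(preset2)
    t1 <- make_track(preset, "progressive", duration / 2, seed = seed,
                     Omega = Omega, dt = dt)
    t2 <- make_track(preset2, "circular", duration / 2, seed = seed + 1,
                     kappa = kappa, snr = snr, dt = dt)
    th0 <- t1$heading[nrow(t1)]
    rot <- th0 - t2$heading[1]
    cs <- cos(rot); sn <- sin(rot)
    x2 <- t1$x[nrow(t1)] + cs * t2$x - sn * t2$y
    y2 <- t1$y[nrow(t1)] + sn * t2$x + cs * t2$y
    trk <- track(c(t1$time, t2$time[-1] + t1$time[nrow(t1)]),
                 c(t1$x, x2[-1]), c(t1$y, y2[-1]),
                 heading = c(t1$heading, t2$heading[-1] + rot),
                 hli = c(t1$hli, t2$hli[-1]))
    attr(trk, "truth") <- list(
      mode = mode, switch_time = t1$time[nrow(t1)],
      phase1 = attr(t1, "truth"), phase2 = attr(t2, "truth"))
    return(trk)
  }

  tt <- seq(0, duration, by = dt)
  n <- length(tt)
  if (is.null(hli_pulse_width)) hli_pulse_width <- dt
  V <- preset$speed

  if (mode == "progressive") {
    im <- if (!is.null(interval_mean)) interval_mean else preset$interval_mean
    is_ <- if (!is.null(interval_sd)) interval_sd else preset$interval_sd
    if (!preset$rolling || is.na(im))
      stop("progressive mode requires a rolling preset or interval overrides")
    roll <- sample_rolling_intervals(im, is_, duration,
                                     seed = seed + 1000L)
    dti <- min(0.002, dt)
    sub <- max(1L, round(dt / dti)); dti <- dt / sub
    kin <- list(V_P = V, Omega = Omega)
    fine <- integrate_trajectory(kin, rolling = roll, D0 = 1e-3, dt = dti,
                                 duration = duration, seed = seed)
    idx <- seq(1, nrow(fine), by = sub)[seq_len(n)]
    trk <- track(tt, fine$x[idx], fine$y[idx],
                 heading = fine$heading[idx],
                 hli = hli_pulses(tt, roll$events, hli_pulse_width))
    attr(trk, "truth") <- list(mode = mode, V_P = V, Omega = Omega,
                               events = roll$events,
                               interval_mean = im, interval_sd = is_)
    return(trk)
  }

  # circular / intermittent (per-frame integration)
  eta_sd <- 1 / sqrt(snr)
  ev <- if (mode == "intermittent") {
    im <- if (!is.null(interval_mean)) interval_mean else 5
    is_ <- if (!is.null(interval_sd)) interval_sd else 1
    sample_rolling_intervals(im, is_, duration, seed = seed + 1000L)$events
  } else numeric(0)
  x <- y <- th <- numeric(n)
  kap <- numeric(n - 1)
  sgn <- 1
  reloc_until <- -1
  ei <- 1
  for (i in seq_len(n - 1)) {
    if (ei <= length(ev) && ev[ei] <= tt[i]) {
      sgn <- -sgn
      reloc_until <- tt[i] + relocation_time
      th[i] <- runif(1, 0, 2 * pi)       # random relocation direction
      ei <- ei + 1
    }
    relocating <- tt[i] < reloc_until
    ki <- if (relocating) 0 else sgn * kappa * (1 + rnorm(1, 0, eta_sd))
    vi <- if (relocating) max(V, 70) else V
    kap[i] <- ki
    x[i + 1] <- x[i] + vi * cos(th[i]) * dt
    y[i + 1] <- y[i] + vi * sin(th[i]) * dt
    th[i + 1] <- th[i] + ki * vi * dt
  }
  trk <- track(tt, x, y, heading = th,
               hli = hli_pulses(tt, ev, hli_pulse_width))
  attr(trk, "truth") <- list(mode = mode, V_P = V, kappa = kappa,
                             snr = snr, events = ev,
                             kappa_series = kap)
  trk
}

hli_pulses <- function(times, events, width, baseline = 0.1, amp = 1) {
  h <- rep(baseline, length(times))
  for (e in events)
    h[times >= e & times < e + width + 1e-12] <- baseline + amp
  h
}

#' Generate a synthetic midpiece waveform series
#'
#' Wraps [synthesize_deflection()] for a [beat_spec()] or an opening angle
#' `phi0`, sampled at the video frame rate, with the ground truth attached.
#'
#' @param spec a [beat_spec()] or a numeric `phi0` in `(pi, 2*pi]` passed
#'   to [build_asymmetric_beat()].
#' @param duration series duration (s).
#' @param dt frame interval (s), at most 0.04 (25 frames/s).
#' @param seed integer seed.
#' @param x position along the flagellum (um).
#' @param ... passed to [build_asymmetric_beat()] when `spec` is `phi0`.
#' @return data.frame with `time_s`, `deflection_um` and a `"truth"`
#'   attribute (`a0`, `spec`).
#' @export
make_waveform <- function(spec, duration = 2, dt = 0.01, seed = 1, x = 0,
                          ...) {
  if (dt > 0.04) stop("dt must be <= 0.04 s (video frame rate)")
  if (is.numeric(spec)) spec <- build_asymmetric_beat(spec, ...)
  tt <- seq(0, duration, by = dt)
  y <- synthesize_deflection(spec, tt, x = x, seed = seed)
  out <- data.frame(time_s = tt, deflection_um = y)
  attr(out, "truth") <- list(a0 = spec$amplitudes[1], spec = spec)
  out
}

#' Brownian center series
#'
#' Pure 2-D Brownian motion, the ground-truth model of a diffusing
#' circular-path center, for parameter-recovery tests of the MSD pipeline.
#'
#' @param D diffusion coefficient (um^2/s).
#' @param dt step (s).
#' @param n number of samples.
#' @param seed integer seed.
#' @return data.frame with `cx`, `cy` (um).
#' @export
make_brownian_centers <- function(D, dt, n, seed = 1) {
  set.seed(seed)
  data.frame(cx = cumsum(rnorm(n, 0, sqrt(2 * D * dt))),
             cy = cumsum(rnorm(n, 0, sqrt(2 * D * dt))))
}
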
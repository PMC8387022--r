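#' Flagellar beat specification
#'
#' Describes a planar flagellar beating pattern as a truncated Fourier series
#' \deqn{y(x,t) = \sum_{n=0}^{N} a_n \cos(n\omega t - kx),}
#' where the zeroth harmonic \eqn{a_0} is the DC (asymmetry) component of the
#' beat: a non-zero \eqn{a_0} means the flagellum bends more to one side and
#' produces a net torque, hence circular swimming. Amplitude and frequency
#' noise are delta-correlated Gaussian processes with intensities `D_amp`
#' (per harmonic) and `D_omega`.
#'
#' @param amplitudes numeric vector `a_0 .. a_N` of harmonic amplitudes (um).
#'   `a_0` may carry a sign (the direction of asymmetry); higher harmonics
#'   must be non-negative.
#' @param omega main angular beat frequency (rad/s).
#' @param L flagellum length (um).
#' @param lambda wavelength of the travelling wave (um); defaults to `L`.
#' @param D_amp amplitude-noise intensities (1/s), recycled over harmonics.
#' @param D_omega frequency-noise intensity (1/s).
#'
#' @return An object of class `beat_spec` with fields `amplitudes`, `omega`,
#'   `k`, `lambda`, `L`, `D_amp`, `D_omega` and the asymmetry index
#'   `sigma = (a_1 - a_0)/a_1`.
#'
#' @details The small-amplitude regime `|a_n| << L` is assumed by the
#'   resistive-force-theory mapping; a warning is issued when any
#'   `|a_n|/L >= 0.2`.
#' @seealso [build_asymmetric_beat()], [synthesize_deflection()]
#' @export
beat_spec <- function(amplitudes, omega, L, lambda = L, D_amp = 0, D_omega = 0) {
  stopifnot(is.numeric(amplitudes), length(amplitudes) >= 1)
  if (any(!is.finite(amplitudes))) stop("amplitudes must be finite")
  if (length(amplitudes) > 1 && any(amplitudes[-1] < 0))
    stop("harmonic amplitudes a_1..a_N must be non-negative")
  if (omega <= 0) stop("omega must be positive")
  if (L <= 0 || lambda <= 0) stop("L and lambda must be positive")
  if (any(D_amp < 0) || D_omega < 0) stop("noise intensities must be non-negative")
  if (any(abs(amplitudes) / L >= 0.2))
    warning("some |a_n|/L >= 0.2: outside the small-amplitude regime")
  D_amp <- rep_len(D_amp, length(amplitudes))
  a0 <- amplitudes[1]
  a1 <- if (length(amplitudes) >= 2) amplitudes[2] else NA_real_
  sigma <- if (!is.na(a1) && a1 > 0) (a1 - a0) / a1 else NA_real_
  structure(list(
    amplitudes = amplitudes, omega = omega, k = 2 * pi / lambda,
    lambda = lambda, L = L, D_amp = D_amp, D_omega = D_omega, sigma = sigma
  ), class = "beat_spec")
}

#' @export
print.beat_spec <- function(x, ...) {
  cat("<beat_spec>", length(x$amplitudes) - 1, "harmonics, omega =", x$omega,
      "rad/s, L =", x$L, "um\n")
  cat("  a_n (um):", signif(x$amplitudes, 4), "\n")
  cat("  sigma =", signif(x$sigma, 4), "\n")
  invisible(x)
}

#' Synthesize a midpiece deflection time series
#'
#' Evaluates the (noisy) beat
#' \deqn{y(x,t) = \sum_n \Pi(t)\, a_n(t) \cos(n\omega(t) t - kx)}
#' on a time grid, where \eqn{\Pi(t) \in \{-1, +1\}} is the rolling switching
#' function. Delta-correlated noise is realised per time step as independent
#' Gaussian perturbations with standard deviation \eqn{\sqrt{D/\Delta t}}
#' (Euler-Maruyama convention), so results are dt-convergent in distribution.
#'
#' @param spec a [beat_spec()].
#' @param times strictly increasing time grid (s).
#' @param x position along the flagellum (um), in `[0, L]`.
#' @param pi_series switching function: `NULL` (identically +1), a numeric
#'   vector of the same length as `times`, or a [rolling_process()] from
#'   which \eqn{\Pi(t)} is built.
#' @param seed optional integer; fixing it makes the noise reproducible.
#' @return numeric vector of deflections (um), same length as `times`.
#' @export
synthesize_deflection <- function(spec, times, x = 0, pi_series = NULL,
                                  seed = NULL) {
  stopifnot(inherits(spec, "beat_spec"))
  if (length(times) == 0) stop("empty time grid")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (x < 0 || x > spec$L) stop("x must lie in [0, L]")
  if (inherits(pi_series, "rolling_process"))
    pi_series <- build_pi(pi_series$events, times)$pi
  if (is.null(pi_series)) pi_series <- rep(1, length(times))
  if (length(pi_series) != length(times))
    stop("pi_series must match the time grid")
  if (!is.null(seed)) set.seed(seed)

  nt <- length(times)
  dt <- if (nt > 1) c(diff(times)[1], diff(times)) else 1
  a <- spec$amplitudes
  nh <- length(a)
  # per-step multiplicative perturbations
  amp <- matrix(rep(a, each = nt), nrow = nt)
  if (any(spec$D_amp > 0)) {
    for (j in seq_len(nh)) if (spec$D_amp[j] > 0)
      amp[, j] <- a[j] * (1 + rnorm(nt, 0, sqrt(spec$D_amp[j] / dt)))
  }
  omega_t <- rep(spec$omega, nt)
  if (spec$D_omega > 0)
    omega_t <- spec$omega * (1 + rnorm(nt, 0, sqrt(spec$D_omega / dt)))

  y <- numeric(nt)
  for (j in seq_len(nh)) {
    n <- j - 1
    y <- y + amp[, j] * cos(n * omega_t * times - spec$k * x)
  }
  pi_series * y
}

#' Construct an asymmetric beat from the opening angle phi0
#'
#' One half-beat is a sine arc \eqn{\sin(u)} traversed over the phase window
#' \eqn{u \in [0, \phi_0]} with \eqn{\phi_0 \in (\pi, 2\pi]}; even extension
#' about the turning point (`u = 0`) and periodic continuation give a beat of
#' period \eqn{2\phi_0} in phase. \eqn{\phi_0 = 2\pi} closes the arc on a
#' full sine cycle and yields a symmetric beat (`a_0 = 0`, `sigma = 1`);
#' smaller \eqn{\phi_0} leaves an unbalanced lobe, a positive zeroth harmonic
#' and `sigma < 1`. The leading Fourier amplitudes of that waveform (fast
#' numerical quadrature, magnitudes) populate the returned [beat_spec()].
#'
#' @param phi0 opening angle in `(pi, 2*pi]`.
#' @param n_harmonics number of AC harmonics kept (default 2: the beat is
#'   described by its zeroth, first and second harmonics).
#' @param a1_scale physical amplitude assigned to the first harmonic (um);
#'   all coefficients are scaled proportionally. Default 4 um, a typical
#'   midpiece deflection.
#' @param omega,L,lambda,D_amp,D_omega passed to [beat_spec()].
#' @return a [beat_spec()]; the raw (unit-sine) coefficients are attached as
#'   attribute `"raw_coefficients"` and `phi0` as attribute `"phi0"`.
#' @export
build_asymmetric_beat <- function(phi0, n_harmonics = 2, a1_scale = 4,
                                  omega = 70, L = 60, lambda = L,
                                  D_amp = 0, D_omega = 0) {
  if (!is.numeric(phi0) || length(phi0) != 1 || phi0 <= pi || phi0 > 2 * pi)
    stop("phi0 must lie in (pi, 2*pi]")
  raw <- beat_fourier_coefficients(phi0, n_harmonics)
  a1 <- abs(raw[2])
  if (a1 == 0) stop("degenerate beat: vanishing first harmonic")
  amps <- abs(raw) * a1_scale / a1
  amps[1] <- raw[1] * a1_scale / a1     # a0 keeps its sign (>= 0 here)
  spec <- beat_spec(amps, omega = omega, L = L, lambda = lambda,
                    D_amp = D_amp, D_omega = D_omega)
  attr(spec, "raw_coefficients") <- raw
  attr(spec, "phi0") <- phi0
  spec
}

#' Fourier coefficients of the sine-arc beat
#'
#' Cosine-series coefficients of the even, `2*phi0`-periodic extension of
#' `sin(u)` on `[0, phi0]`:
#' \deqn{a_0 = \frac{1}{\phi_0}\int_0^{\phi_0}\!\sin u\,du,\qquad
#'       a_n = \frac{2}{\phi_0}\int_0^{\phi_0}\!\sin u \cos(n\pi u/\phi_0)\,du.}
#'
#' @param phi0 opening angle in `(pi, 2*pi]`.
#' @param n_harmonics highest harmonic index returned.
#' @return numeric vector `a_0 .. a_N` (signed).
#' @export
beat_fourier_coefficients <- function(phi0, n_harmonics = 2) {
  vapply(0:n_harmonics, function(n) {
    if (n == 0) return((1 - cos(phi0)) / phi0)
    (2 / phi0) * integrate(function(u) sin(u) * cos(n * pi * u / phi0),
                           0, phi0, rel.tol = 1e-10)$value
  }, numeric(1))
}

#' Measure the zeroth harmonic of a deflection series
#'
#' The amplitude of the zeroth (asymmetry) harmonic from the maximum
#' deflections to the two sides of the centerline:
#' \deqn{a_0 = |y_L - y_R| / 2,}
#' with \eqn{y_L = \max(y - c)} and \eqn{y_R = -\min(y - c)} for centerline
#' `c`. For a beat of the form `a_0 + a_1 cos(wt)` this midrange estimator is
#' exact; even higher harmonics of amplitude `a_2` bias it by up to `a_2`.
#'
#' @param deflection numeric deflection series (um).
#' @param times optional time stamps (s); when supplied on a uniform grid the
#'   dominant beat period is estimated and the series is required to cover at
#'   least two full periods.
#' @param centerline reference deflection of the straight flagellar axis
#'   (um). Defaults to 0, the reference in which [synthesize_deflection()]
#'   emits its series. (Subtracting the time mean instead would remove the
#'   very DC component being measured.)
#' @return estimated `a_0` (um, non-negative).
#' @export
measure_zeroth_harmonic <- function(deflection, times = NULL, centerline = 0) {
  y <- deflection - centerline
  if (length(y) < 4) stop("insufficient data: series too short")
  if (!is.null(times)) {
    if (length(times) != length(y)) stop("times must match the series")
    dts <- diff(times)
    if (diff(range(dts)) > 1e-9) stop("times must be uniformly spaced")
    sp <- beat_spectrum(y, dts[1])
    if (!is.na(sp$peak_omega) && sp$peak_omega > 0) {
      period <- 2 * pi / sp$peak_omega
      span <- times[length(times)] - times[1]
      if (span < 2 * period)
        stop("insufficient data: series covers fewer than two beat periods")
      # per-beat extremes averaged: unbiased under symmetric amplitude
      # noise, and identical to the plain midrange for noise-free beats
      n_beats <- floor(span / period)
      if (n_beats >= 3) {
        beat <- pmin(floor((times - times[1]) / period), n_beats - 1)
        yl <- tapply(y, beat, max)
        yr <- tapply(y, beat, min)
        return(abs(mean(yl) + mean(yr)) / 2)
      }
    }
  }
  abs(max(y) + min(y)) / 2
}

#' Normalized amplitude spectrum of a deflection series
#'
#' One-sided amplitude spectrum of a uniformly sampled series, normalized to
#' its largest AC line. The zeroth-harmonic line (DC) is reported separately;
#' it is non-zero exactly when the beat is asymmetric.
#'
#' @param deflection numeric series (um).
#' @param dt sampling interval (s).
#' @return list of class `beat_spectrum`: `omega` (rad/s), `amplitude` (um),
#'   `normalized` (unit peak), `dc_amplitude` (|mean|, um), `peak_omega`
#'   (rad/s, dominant AC line), `peaks` (data.frame of local spectral peaks
#'   above 5% of the maximum).
#' @export
beat_spectrum <- function(deflection, dt) {
  if (length(dt) != 1 || dt <= 0) stop("dt must be a positive scalar")
  n <- length(deflection)
  if (n < 8) stop("insufficient data for a spectrum")
  Y <- fft(deflection)
  half <- seq_len(floor(n / 2))  # excludes DC (index 1 handled apart)
  amp <- Mod(Y[half + 1]) * 2 / n
  omega <- 2 * pi * half / (n * dt)
  dc <- abs(Mod(Y[1]) / n)
  peak_i <- which.max(amp)
  peak_omega <- if (max(amp) > 0) omega[peak_i] else NA_real_
  norm <- if (max(amp) > 0) amp / max(amp) else amp
  is_peak <- norm > 0.05 &
    norm >= c(-Inf, norm[-length(norm)]) & norm >= c(norm[-1], -Inf)
  structure(list(
    omega = omega, amplitude = amp, normalized = norm, dc_amplitude = dc,
    peak_omega = peak_omega,
    peaks = data.frame(omega = omega[is_peak], amplitude = amp[is_peak])
  ), class = "beat_spectrum")
}

#' @export
print.beat_spectrum <- function(x, ...) {
  cat("<beat_spectrum> dominant line at", signif(x$peak_omega, 4),
      "rad/s; DC amplitude", signif(x$dc_amplitude, 4), "um\n")
  invisible(x)
}
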
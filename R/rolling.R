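#' Rolling process
#'
#' A record of discrete rolling events (rapid rotations of the sperm about
#' its longitudinal axis). Each event flips the sign of the edge-sensitive
#' switching function \eqn{\Pi(t)}, which starts at +1. The elapsed time
#' between consecutive events, `T_SR`, is a random variable with mean
#' `mu_SR` and standard deviation `sigma_SR`.
#'
#' @param events strictly increasing event times (s).
#' @param duration observation duration (s); defaults to the last event time.
#' @param mean_interval,sd_interval nominal interval law parameters (s), if
#'   known (e.g. from the generator); otherwise estimated from the events.
#' @return object of class `rolling_process` with fields `events`, `n_SR`,
#'   `mu_SR`, `sigma_SR`, `omega_SR = 1/mu_SR` and `duration`.
#' @export
rolling_process <- function(events, duration = NULL, mean_interval = NULL,
                            sd_interval = NULL) {
  events <- as.numeric(events)
  if (length(events) && any(diff(events) <= 0))
    stop("event times must be strictly increasing")
  if (is.null(duration))
    duration <- if (length(events)) max(events) else 0
  iv <- diff(c(0, events))
  mu <- if (!is.null(mean_interval)) mean_interval
        else if (length(iv) > 1) mean(diff(events)) else NA_real_
  s  <- if (!is.null(sd_interval)) sd_interval
        else if (length(iv) > 2) sd(diff(events)) else NA_real_
  structure(list(
    events = events, n_SR = length(events), mu_SR = mu, sigma_SR = s,
    omega_SR = if (is.na(mu) || mu <= 0) NA_real_ else 1 / mu,
    duration = duration
  ), class = "rolling_process")
}

#' @export
print.rolling_process <- function(x, ...) {
  cat("<rolling_process>", x$n_SR, "events over", signif(x$duration, 4),
      "s; interval mean", signif(x$mu_SR, 4), "s, sd",
      signif(x$sigma_SR, 4), "s\n")
  invisible(x)
}

#' Sample rolling event times
#'
#' Inter-event intervals are drawn i.i.d. from a Gaussian truncated at zero
#' (inverse-CDF sampling, so a fixed seed reproduces the events exactly);
#' their cumulative sums within `duration` form the event times. An
#' alternative gamma interval law with the same mean and sd is available.
#'
#' @param mean,sd interval mean and standard deviation (s).
#' @param duration total duration to fill with events (s).
#' @param seed integer seed.
#' @param law `"truncated_normal"` (default) or `"gamma"`.
#' @return a [rolling_process()].
#' @export
sample_rolling_intervals <- function(mean, sd, duration, seed = NULL,
                                     law = c("truncated_normal", "gamma")) {
  law <- match.arg(law)
  if (mean <= 0) stop("mean must be positive")
  if (sd < 0) stop("sd must be non-negative")
  if (sd > mean / 2)
    warning("sd > mean/2: truncation at zero biases the realized moments")
  if (!is.null(seed)) set.seed(seed)
  events <- numeric(0); t_last <- 0
  repeat {
    n <- max(16L, ceiling((duration - t_last) / mean * 1.3))
    iv <- if (sd == 0) rep(mean, n)
      else if (law == "truncated_normal") {
        u <- runif(n, pnorm(0, mean, sd), 1)
        qnorm(u, mean, sd)
      } else {
        shape <- (mean / sd)^2
        stats::rgamma(n, shape = shape, rate = shape / mean)
      }
    ev <- t_last + cumsum(iv)
    events <- c(events, ev)
    t_last <- ev[length(ev)]
    if (t_last > duration) break
  }
  rolling_process(events[events <= duration], duration = duration,
                  mean_interval = mean, sd_interval = sd)
}

#' Build the switching function Pi(t) on a time grid
#'
#' Piecewise-constant series in \{-1, +1\} starting at +1 and multiplied by
#' -1 at each event time. Events outside the grid range are ignored with a
#' warning. The duty average \eqn{\tilde\Pi} is the time average of the
#' series.
#'
#' @param events sorted rolling event times (s).
#' @param times evaluation grid (s).
#' @return list with `pi` (numeric +-1 series), `pi_tilde` (time average)
#'   and `events` (the events used).
#' @export
build_pi <- function(events, times) {
  if (is.unsorted(events, strictly = TRUE) && length(events) > 1)
    stop("events must be sorted and distinct")
  out <- events < times[1] | events > times[length(times)]
  if (any(out)) {
    warning(sum(out), " event(s) outside the time grid ignored")
    events <- events[!out]
  }
  flips <- findInterval(times, events)   # events at t flip Pi at t
  p <- 1 - 2 * (flips %% 2)
  list(pi = p, pi_tilde = mean(p), events = events)
}

#' Detect rolling events from a head-light-intensity channel
#'
#' HLI is a pulse-type signal: each rolling event produces a short intensity
#' pulse. Pulses are segmented by an Otsu two-class threshold with a
#' hysteresis band of 10% of the dynamic range; each positive (rising) edge
#' is a rolling event. The switching function is then rebuilt from the
#' detected events.
#'
#' @param track a [track()] carrying an `hli` channel.
#' @param hysteresis hysteresis width as a fraction of the dynamic range.
#' @return list with `process` (a [rolling_process()]), `pi` (reconstructed
#'   series on the track grid), `pi_tilde`, and `threshold`.
#' @export
detect_rolling_from_hli <- function(track, hysteresis = 0.1) {
  stopifnot(inherits(track, "track"))
  if (is.null(track$hli)) stop("track has no HLI channel")
  h <- track$hli; tt <- track$time
  rng <- diff(range(h))
  if (rng <= 0 || !is.finite(rng)) {
    pr <- rolling_process(numeric(0), duration = diff(range(tt)))
    return(list(process = pr, pi = rep(1, length(tt)), pi_tilde = 1,
                threshold = NA_real_))
  }
  th <- otsu_threshold(h)
  hi <- th + hysteresis * rng / 2
  lo <- th - hysteresis * rng / 2
  state <- h[1] > hi
  events <- numeric(0)
  for (i in seq_along(h)[-1]) {
    if (!state && h[i] > hi) { state <- TRUE; events <- c(events, tt[i]) }
    else if (state && h[i] < lo) state <- FALSE
  }
  pr <- rolling_process(events, duration = tt[length(tt)] - tt[1])
  bp <- build_pi(events, tt)
  list(process = pr, pi = bp$pi, pi_tilde = bp$pi_tilde, threshold = th)
}

# Otsu's two-class threshold on a numeric signal (256-bin histogram).
otsu_threshold <- function(x, bins = 256) {
  br <- seq(min(x), max(x), length.out = bins + 1)
  counts <- tabulate(findInterval(x, br, rightmost.closed = TRUE), bins)
  p <- counts / sum(counts)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_tot <- mu[bins]
  between <- (mu_tot * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  # the maximum is flat across an empty gap between classes: use its middle
  top <- which(between >= max(between) * (1 - 1e-9))
  mids[round(mean(range(top)))]
}

#' Dispersion of the progressive direction under rolling
#'
#' With `n_SR` rolling events whose intervals fluctuate with standard
#' deviation `sigma_SR`, the heading accumulates independent interval errors
#' of size `sigma_SR * |Omega|`; after `n_SR` events the direction of the
#' average path is distributed with mean 0 and standard deviation
#' \deqn{\sqrt{n_{SR}}\,\sigma_{SR}\,|\tilde\Omega|} (random-walk
#' accumulation). The linear-in-`n_SR` alternative reading is returned
#' alongside; [heading_dispersion_mc()] discriminates them by simulation.
#'
#' @param n_SR number of rolling events.
#' @param sigma_SR interval standard deviation (s).
#' @param Omega intrinsic angular velocity (rad/s).
#' @return list with `dispersion` (sqrt-law value, rad), `sqrt_law`,
#'   `linear_law`.
#' @export
heading_dispersion <- function(n_SR, sigma_SR, Omega) {
  if (n_SR < 1) stop("n_SR must be >= 1")
  s <- sqrt(n_SR) * sigma_SR * abs(Omega)
  list(dispersion = s, sqrt_law = s, linear_law = n_SR * sigma_SR * abs(Omega))
}

#' Monte-Carlo heading dispersion
#'
#' Simulates the heading after `n_SR` sign-alternating rolling intervals,
#' \eqn{\theta = \Omega \sum_i (-1)^{i-1} T_i} with
#' \eqn{T_i \sim N(\mu_{SR}, \sigma_{SR})} truncated at zero, and returns the
#' standard deviation of the final heading across replicates.
#'
#' @param n_SR events per replicate.
#' @param mean_SR,sigma_SR interval mean and sd (s).
#' @param Omega angular velocity (rad/s).
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @return list with `sd` (rad) and `se` (bootstrap-free standard error of
#'   the sd estimate, `sd/sqrt(2 n_rep)`).
#' @export
heading_dispersion_mc <- function(n_SR, mean_SR, sigma_SR, Omega,
                                  n_rep = 2000, seed = 1) {
  set.seed(seed)
  u <- matrix(runif(n_SR * n_rep, pnorm(0, mean_SR, sigma_SR), 1),
              nrow = n_SR)
  Tm <- qnorm(u, mean_SR, sigma_SR)
  signs <- rep_len(c(1, -1), n_SR)
  theta <- Omega * colSums(signs * Tm)
  list(sd = sd(theta), se = sd(theta) / sqrt(2 * n_rep))
}

# restrict events to a time grid (callers that legitimately hold a longer
# event record than the integration horizon)
events_in_grid <- function(events, times) {
  events[events >= times[1] & events <= times[length(times)]]
}
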
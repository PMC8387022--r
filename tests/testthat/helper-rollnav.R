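# shared fixtures and Monte-Carlo helpers

default_drag <- drag_coefficients()

ref_beat <- function(a0 = 0.3, a1 = 4, a2 = 0.5, omega = 70, L = 60)
  beat_spec(c(a0, a1, a2), omega = omega, L = L)

# Per-period path-speed estimator: displacement between event k and k+2
# divided by the elapsed time, averaged over periods, one value per seed.
mc_path_speed <- function(V_P, Omega, mean_SR, sd_SR, n_seeds = 100,
                          n_periods = 8, dt = NULL, D0 = 1e-3,
                          seed0 = 100) {
  if (is.null(dt)) dt <- min(0.01 / max(abs(Omega), 1 / mean_SR), 1e-3)
  duration <- (2 * n_periods + 2) * mean_SR
  kin <- list(V_P = V_P, Omega = Omega)
  speeds <- vapply(seq_len(n_seeds), function(s) {
    roll <- sample_rolling_intervals(mean_SR, sd_SR, duration,
                                     seed = seed0 + s)
    trk <- integrate_trajectory(kin, rolling = roll, D0 = D0, dt = dt,
                                duration = duration, seed = seed0 + s)
    ev <- roll$events
    ev <- ev[ev <= trk$time[nrow(trk)]]
    ks <- seq(1, length(ev) - 2, by = 2)
    sp <- vapply(ks, function(k) {
      i1 <- round(ev[k] / dt) + 1
      i2 <- round(ev[k + 2] / dt) + 1
      sqrt((trk$x[i2] - trk$x[i1])^2 + (trk$y[i2] - trk$y[i1])^2) /
        (ev[k + 2] - ev[k])
    }, numeric(1))
    mean(sp)
  }, numeric(1))
  list(mean = mean(speeds), se = sd(speeds) / sqrt(n_seeds))
}

# circular-path center series reconstructed from positions and headings
centers_from_heading <- function(trk, V_P, Omega) {
  data.frame(cx = trk$x - (V_P / Omega) * sin(trk$heading),
             cy = trk$y + (V_P / Omega) * cos(trk$heading))
}
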
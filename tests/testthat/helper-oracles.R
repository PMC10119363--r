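# Independent oracles and small fixture builders used across tests.

# Brute-force turn-count oracle: quantize the heading to 8 sectors,
# scan for maximal same-sign runs of sector steps, and credit
# floor(|cumulative rotation| / 360 deg) full turns per run (360 deg =
# 8 sector steps). Independent batch algorithm against the package's
# online counter.
oracle_turn_count <- function(heading_deg) {
  sec <- floor((heading_deg %% 360) / 45)
  d <- diff(sec)
  steps <- ((d + 4) %% 8) - 4
  steps <- steps[steps != 0]
  ccw <- 0L; cw <- 0L
  i <- 1
  while (i <= length(steps)) {
    j <- i
    while (j < length(steps) && sign(steps[j + 1]) == sign(steps[i])) j <- j + 1
    total <- sum(steps[i:j])
    if (total > 0) ccw <- ccw + total %/% 8L
    if (total < 0) cw <- cw + (-total) %/% 8L
    i <- j + 1
  }
  list(ccw = as.integer(ccw), cw = as.integer(cw))
}

# Random piecewise-monotone heading series with reversals and
# occasional multi-sector jumps per frame.
random_heading_series <- function(seed) {
  set.seed(seed)
  n_seg <- sample(3:8, 1)
  h <- numeric(0)
  cur <- runif(1, 0, 360)
  for (s in seq_len(n_seg)) {
    len <- sample(10:60, 1)
    # up to ~120 deg/frame: frequently skips sectors
    w <- sample(c(-1, 1), 1) * runif(1, 0, 120)
    h <- c(h, cur + cumsum(rep(w, len)))
    cur <- h[length(h)]
  }
  h %% 360
}

# Exhaustive grid-search oracle for the peak-model least squares:
# minimum SS over a discretized (A, B, C, D, E) box.
oracle_grid_search_ss <- function(f, y, A_grid, B_grid, C_grid, D_grid,
                                  E_grid) {
  best <- Inf
  for (A in A_grid) for (B in B_grid) for (C in C_grid)
    for (D in D_grid) for (E in E_grid) {
      ss <- sum((A * exp(-((f - B) / C)^2) + D * f + E - y)^2)
      if (ss < best) best <- ss
    }
  best
}

# Circular error between an angle and a target, in (-180, 180].
wrap_err <- function(x, target) ((x - target + 180) %% 360) - 180

# Unwrapped phase (degrees) for slope checks.
unwrap_deg <- function(phi) {
  ok <- is.finite(phi)
  d <- diff(phi[ok])
  d <- ((d + 180) %% 360) - 180
  cumsum(c(phi[ok][1], d))
}

# Small two-structure session with one shared NBG source.
shared_nbg_session <- function(lag_deg, seed, duration_s = 72,
                               n_wires = 3, amplitude = 12) {
  src <- osc_source(
    osc_burst_spec("NBG", 90, 4, amplitude = amplitude),
    data.frame(structure = c("M1FL", "DLS"),
               phase_lag_deg = c(0, lag_deg)))
  generate_session(session_spec(
    duration_s = duration_s,
    structures = data.frame(name = c("M1FL", "DLS"),
                            n_wires = c(n_wires, n_wires)),
    fractal = fractal_spec(1, scale = 100), sources = list(src),
    sensor_noise_sd = 1, seed = seed))
}
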
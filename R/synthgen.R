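#' Specification of a power-law (fractal) LFP background
#'
#' The arrhythmic component of an LFP power spectrum is well described by a
#' power law, PSD(f) proportional to 1/f^chi. The generator realizes such a
#' background by spectral shaping of Gaussian white noise, giving exact
#' control of the exponent.
#'
#' @param exponent_chi Power-law exponent chi (>= 0); 0 gives white noise.
#' @param scale Variance of the generated series in signal units squared
#'   (microvolt^2 for synthetic sessions).
#' @param fmin_Hz,fmax_Hz Band over which the power law holds. Below
#'   `fmin_Hz` the amplitude profile is held flat (avoids a DC singularity);
#'   `fmax_Hz = NULL` extends the law to the Nyquist frequency.
#' @return An object of class `fractal_spec`.
#' @export
fractal_spec <- function(exponent_chi, scale = 1, fmin_Hz = 1, fmax_Hz = NULL) {
  if (!is.numeric(exponent_chi) || exponent_chi < 0)
    stop("exponent_chi must be >= 0")
  if (!is.numeric(scale) || scale < 0)
    stop("scale must be >= 0")
  if (!is.null(fmax_Hz) && fmin_Hz >= fmax_Hz)
    stop("fmin_Hz must be < fmax_Hz")
  structure(list(exponent_chi = exponent_chi, scale = scale,
                 fmin_Hz = fmin_Hz, fmax_Hz = fmax_Hz),
            class = "fractal_spec")
}

# Amplitude profile of the shaping filter on an FFT frequency grid.
fractal_amp_profile <- function(spec, freqs) {
  chi <- spec$exponent_chi
  fmin <- spec$fmin_Hz
  fmax <- spec$fmax_Hz %||% Inf
  f <- pmin(pmax(abs(freqs), fmin), fmax)
  g <- f^(-chi / 2)
  g[freqs == 0] <- 0
  g
}

#' Generate a power-law noise series
#'
#' Spectral shaping of white noise: the FFT of a Gaussian white series is
#' multiplied by f^(-chi/2) over the configured band and inverse
#' transformed. The output has zero mean and variance equal to
#' `spec$scale` in expectation, and its Welch log-log PSD slope is -chi.
#'
#' @param spec A [fractal_spec()].
#' @param n_samples Number of samples (>= 4096).
#' @param fs_Hz Sampling rate in Hz.
#' @param seed Integer RNG seed; identical inputs give identical output.
#' @return Numeric vector of length `n_samples`.
#' @export
generate_fractal_series <- function(spec, n_samples, fs_Hz, seed) {
  stopifnot(inherits(spec, "fractal_spec"))
  if (n_samples < 2^12) stop("n_samples must be >= 4096")
  if (spec$scale == 0) return(numeric(n_samples))
  set.seed(seed)
  x <- stats::rnorm(n_samples)
  freqs <- fft_freqs(n_samples, fs_Hz)
  g <- fractal_amp_profile(spec, freqs)
  c0 <- sqrt(spec$scale / mean(g^2))
  y <- Re(stats::fft(stats::fft(x) * (c0 * g), inverse = TRUE)) / n_samples
  y - mean(y)
}

# Signed FFT frequency grid (0, df, ..., -df) of length n.
fft_freqs <- function(n, fs) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' Expected one-sided PSD level of a fractal spec at a frequency
#'
#' Analytic expectation of the Welch PSD of [generate_fractal_series()]
#' at frequency `f0`, useful for placing backgrounds of different
#' exponents at a common level (e.g. to compare normalized peak heights
#' across background slopes).
#'
#' @inheritParams generate_fractal_series
#' @param f0 Frequency of interest in Hz.
#' @return Expected PSD in units^2/Hz.
#' @export
fractal_psd_level <- function(spec, f0, n_samples, fs_Hz) {
  freqs <- fft_freqs(n_samples, fs_Hz)
  g <- fractal_amp_profile(spec, freqs)
  c2 <- spec$scale / mean(g^2)
  gf <- fractal_amp_profile(spec, f0)
  2 * c2 * gf^2 / fs_Hz
}

#' Scale that places a fractal background at a target PSD level
#'
#' Returns the `scale` (variance) for which a [fractal_spec()] with the
#' given exponent has expected one-sided PSD `psd0` at `f0`.
#'
#' @inheritParams fractal_psd_level
#' @param exponent_chi Power-law exponent.
#' @param psd0 Target PSD in units^2/Hz at `f0`.
#' @param fmin_Hz,fmax_Hz Passed to [fractal_spec()].
#' @export
fractal_scale_for_psd <- function(exponent_chi, f0, psd0, n_samples, fs_Hz,
                                  fmin_Hz = 1, fmax_Hz = NULL) {
  sp1 <- fractal_spec(exponent_chi, scale = 1, fmin_Hz = fmin_Hz,
                      fmax_Hz = fmax_Hz)
  p1 <- fractal_psd_level(sp1, f0, n_samples, fs_Hz)
  psd0 / p1
}

#' Specification of a band-limited oscillatory burst source
#'
#' A narrowband oscillation whose ensemble power spectrum is an
#' approximately Gaussian peak: a sinusoid whose instantaneous frequency
#' follows an Ornstein-Uhlenbeck process around `center_Hz` with
#' stationary standard deviation `width_Hz`. Presence over time is gated
#' by an envelope in [0, 1] (e.g. a drug-response time course).
#'
#' @param band_name One of "theta", "beta", "NBG".
#' @param center_Hz Peak frequency; must lie in the named band
#'   (theta 5-10, beta 12-35, NBG 70-110 Hz).
#' @param width_Hz Spectral half-width (Gaussian sigma of the peak), > 0.
#' @param amplitude Peak sinusoid amplitude in signal units.
#' @param envelope `NULL` (always on), a function of time in seconds
#'   returning values in [0, 1], or a per-sample numeric vector.
#' @param phase_lag_deg Per-structure lag of the shared source (degrees);
#'   a larger lag means the structure's copy is later in phase.
#' @export
osc_burst_spec <- function(band_name, center_Hz, width_Hz, amplitude = 1,
                           envelope = NULL, phase_lag_deg = 0) {
  ranges <- band_ranges()
  if (!band_name %in% names(ranges)) stop("unknown band: ", band_name)
  rg <- ranges[[band_name]]
  if (center_Hz < rg[1] || center_Hz > rg[2])
    stop(sprintf("center_Hz %.1f outside %s range [%g, %g]",
                 center_Hz, band_name, rg[1], rg[2]))
  if (width_Hz <= 0) stop("width_Hz must be > 0")
  structure(list(band_name = band_name, center_Hz = center_Hz,
                 width_Hz = width_Hz, amplitude = amplitude,
                 envelope = envelope, phase_lag_deg = phase_lag_deg),
            class = "osc_burst_spec")
}

#' Frequency ranges of the analysed LFP bands (Hz)
#' @return Named list of c(lo, hi) vectors.
#' @export
band_ranges <- function() {
  list(theta = c(5, 10), beta = c(12, 35), NBG = c(70, 110))
}

resolve_envelope <- function(envelope, n, fs) {
  if (is.null(envelope)) return(rep(1, n))
  if (is.function(envelope)) {
    t <- (seq_len(n) - 1) / fs
    e <- envelope(t)
  } else {
    e <- rep_len(as.numeric(envelope), n)
  }
  if (any(e < -1e-9 | e > 1 + 1e-9)) stop("envelope values must be in [0, 1]")
  pmin(pmax(e, 0), 1)
}

#' Piecewise-trapezoid burst envelope
#'
#' Convenience envelope mimicking a drug-response time course: 0 before
#' `on_s`, linear ramp to 1 over `ramp_s`, sustained, ramp down to 0 at
#' `off_s`.
#'
#' @param on_s,off_s Start and end of the response (seconds).
#' @param ramp_s Ramp duration (seconds).
#' @return A function of time usable as an `envelope`.
#' @export
trapezoid_envelope <- function(on_s, off_s, ramp_s = 10) {
  force(on_s); force(off_s); force(ramp_s)
  function(t) {
    up <- pmin(pmax((t - on_s) / ramp_s, 0), 1)
    down <- pmin(pmax((off_s - t) / ramp_s, 0), 1)
    pmin(up, down)
  }
}

# Phase track of an OU-jittered oscillator. Returns radians.
ou_oscillator_phase <- function(center_Hz, width_Hz, n, fs, seed,
                                tau_s = 0.15) {
  set.seed(seed)
  dt <- 1 / fs
  a <- exp(-dt / tau_s)
  b <- width_Hz * sqrt(1 - a^2)
  eps <- stats::rnorm(n)
  x1 <- stats::rnorm(1, 0, width_Hz)
  x <- as.numeric(stats::filter(c(x1, b * eps[-1]), a,
                                method = "recursive"))
  f_inst <- pmin(pmax(center_Hz + x, 0.1), fs / 2 - 1)
  2 * pi * cumsum(f_inst) * dt + stats::runif(1, 0, 2 * pi)
}

#' Generate a narrowband oscillatory series
#'
#' @inheritParams generate_fractal_series
#' @param spec An [osc_burst_spec()].
#' @return Numeric vector: `amplitude * envelope * cos(phase - lag)`.
#' @export
generate_oscillation <- function(spec, n_samples, fs_Hz, seed) {
  stopifnot(inherits(spec, "osc_burst_spec"))
  if (fs_Hz <= 2 * spec$center_Hz)
    stop("fs_Hz must exceed twice the center frequency")
  env <- resolve_envelope(spec$envelope, n_samples, fs_Hz)
  if (all(env == 0)) return(numeric(n_samples))
  phi <- ou_oscillator_phase(spec$center_Hz, spec$width_Hz, n_samples,
                             fs_Hz, seed)
  spec$amplitude * env * cos(phi - spec$phase_lag_deg * pi / 180)
}

#' Define an oscillatory source shared between structures
#'
#' One physical source can be picked up by several structures with
#' per-structure phase lags and amplitude scalings; the induced
#' ground-truth phase difference between structures a and b is
#' `lag_b - lag_a` degrees (a leads b when b's lag is larger).
#'
#' @param spec An [osc_burst_spec()] (its own `phase_lag_deg` is ignored;
#'   lags are per target).
#' @param targets `data.frame(structure, phase_lag_deg, amp_scale)`;
#'   `amp_scale` defaults to 1.
#' @export
osc_source <- function(spec, targets) {
  stopifnot(inherits(spec, "osc_burst_spec"), is.data.frame(targets))
  if (is.null(targets$phase_lag_deg)) targets$phase_lag_deg <- 0
  if (is.null(targets$amp_scale)) targets$amp_scale <- 1
  structure(list(spec = spec, targets = targets), class = "osc_source")
}

#' Specification of a synthetic multi-structure LFP session
#'
#' @param duration_s Session duration in seconds.
#' @param structures `data.frame(name, hemisphere, n_wires)`; each
#'   structure needs at least 2 wires so bipolar pairs exist.
#' @param fractal A [fractal_spec()] applied to every structure, or a
#'   named list keyed by structure name. Each wire receives an
#'   independent realization of its structure's spec.
#' @param sources List of [osc_source()] objects.
#' @param fs_Hz Sampling rate (default 2000 Hz, the LFP rate).
#' @param common_mode_amp Standard deviation of a broadband artifact
#'   shared identically by all wires of a bundle (cancels in bipolar
#'   derivations).
#' @param line_noise_amp Amplitude of 50 Hz mains contamination.
#' @param sensor_noise_sd Standard deviation of independent white sensor
#'   noise per wire.
#' @param wire_gain_sd Per-wire gain jitter (sd around 1) applied to
#'   oscillatory sources and line noise, reflecting heterogeneous pickup
#'   of local sources across wires of a bundle; this is what lets local
#'   sources survive bipolar subtraction. Default 0.5 (order-unity
#'   heterogeneity, as expected from steep distance falloff over the
#'   250-micron wire spacing).
#' @param seed Master seed; per-component substreams are derived from it.
#' @export
session_spec <- function(duration_s, structures, fractal, sources = list(),
                         fs_Hz = 2000, common_mode_amp = 0,
                         line_noise_amp = 0, sensor_noise_sd = 0.5,
                         wire_gain_sd = 0.5, seed = 1) {
  stopifnot(is.data.frame(structures),
            all(c("name", "n_wires") %in% names(structures)))
  if (is.null(structures$hemisphere)) structures$hemisphere <- "lesioned"
  if (any(structures$n_wires < 2))
    stop("every structure needs n_wires >= 2 for bipolar pairs")
  fmax_osc <- 0
  for (src in sources) {
    stopifnot(inherits(src, "osc_source"))
    fmax_osc <- max(fmax_osc, src$spec$center_Hz)
    if (!all(src$targets$structure %in% structures$name))
      stop("source targets an unknown structure")
  }
  if (fs_Hz < 2 * fmax_osc)
    stop("fs_Hz must be at least twice the highest oscillation frequency")
  if (inherits(fractal, "fractal_spec")) {
    fractal <- stats::setNames(rep(list(fractal), nrow(structures)),
                               structures$name)
  }
  if (!all(structures$name %in% names(fractal)))
    stop("fractal must cover every structure")
  structure(list(duration_s = duration_s, structures = structures,
                 fractal = fractal, sources = sources, fs_Hz = fs_Hz,
                 common_mode_amp = common_mode_amp,
                 line_noise_amp = line_noise_amp,
                 sensor_noise_sd = sensor_noise_sd,
                 wire_gain_sd = wire_gain_sd, seed = seed),
            class = "session_spec")
}

#' Generate a synthetic LFP session with ground truth
#'
#' Each wire is the sum of an independent fractal background (its
#' structure's spec), the shared oscillatory sources delayed by the
#' structure's phase lag and scaled by a per-wire gain, a bundle
#' common-mode artifact (identical on all wires of a bundle), 50 Hz line
#' noise, and independent white sensor noise.
#'
#' @param spec A [session_spec()].
#' @return An object of class `lfp_session`: list with `signals`
#'   (wires x samples matrix, microvolts), `fs_Hz`, `channel_map`
#'   (wire_id, structure, hemisphere, bundle), `excluded_wires`, and
#'   `ground_truth` (detection-grid presence per source and structure,
#'   true peak parameters, true pairwise phase lags).
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  fs <- spec$fs_Hz
  n <- round(spec$duration_s * fs)
  st <- spec$structures
  n_wires_tot <- sum(st$n_wires)
  cmap <- data.frame(
    wire_id = seq_len(n_wires_tot),
    structure = rep(st$name, st$n_wires),
    hemisphere = rep(st$hemisphere, st$n_wires),
    stringsAsFactors = FALSE)
  cmap$bundle <- paste(cmap$structure, cmap$hemisphere, sep = "/")

  sig <- matrix(0, nrow = n_wires_tot, ncol = n)

  # fractal background: independent realization per wire
  for (w in seq_len(n_wires_tot)) {
    fsp <- spec$fractal[[cmap$structure[w]]]
    if (fsp$scale > 0)
      sig[w, ] <- generate_fractal_series(fsp, n, fs,
                                          substream_seed(spec$seed, w))
  }

  # per-wire gains for local pickup heterogeneity: stratified quantiles
  # of N(1, sd) within each bundle (randomly permuted), so every bundle
  # is guaranteed a representative spread even with few wires
  set.seed(substream_seed(spec$seed, 9001))
  osc_gain <- numeric(n_wires_tot)
  for (b in unique(cmap$bundle)) {
    wsel <- which(cmap$bundle == b)
    k <- length(wsel)
    q <- stats::qnorm((seq_len(k) - 0.5) / k)
    osc_gain[wsel] <- 1 + spec$wire_gain_sd * sample(q)
  }
  line_gain <- 1 + stats::rnorm(n_wires_tot, 0, 0.05)

  # shared oscillatory sources
  src_truth <- list()
  tvec <- (seq_len(n) - 1) / fs
  for (si in seq_along(spec$sources)) {
    src <- spec$sources[[si]]
    osp <- src$spec
    env <- resolve_envelope(osp$envelope, n, fs)
    phi <- ou_oscillator_phase(osp$center_Hz, osp$width_Hz, n, fs,
                               substream_seed(spec$seed, 5000 + si))
    for (ti in seq_len(nrow(src$targets))) {
      tg <- src$targets[ti, ]
      lag_rad <- tg$phase_lag_deg * pi / 180
      comp <- osp$amplitude * tg$amp_scale * env * cos(phi - lag_rad)
      wsel <- which(cmap$structure == tg$structure)
      for (w in wsel) sig[w, ] <- sig[w, ] + osc_gain[w] * comp
    }
    src_truth[[si]] <- list(band = osp$band_name, center_Hz = osp$center_Hz,
                            width_Hz = osp$width_Hz,
                            amplitude = osp$amplitude,
                            targets = src$targets, envelope = env)
  }

  # bundle common-mode artifact (identical within bundle)
  if (spec$common_mode_amp > 0) {
    bundles <- unique(cmap$bundle)
    for (bi in seq_along(bundles)) {
      cm <- generate_fractal_series(
        fractal_spec(1, scale = spec$common_mode_amp^2), n, fs,
        substream_seed(spec$seed, 7000 + bi))
      wsel <- which(cmap$bundle == bundles[bi])
      for (w in wsel) sig[w, ] <- sig[w, ] + cm
    }
  }

  # 50 Hz line contamination
  if (spec$line_noise_amp > 0) {
    line <- spec$line_noise_amp * sin(2 * pi * 50 * tvec)
    for (w in seq_len(n_wires_tot)) sig[w, ] <- sig[w, ] + line_gain[w] * line
  }

  # independent sensor noise
  if (spec$sensor_noise_sd > 0) {
    for (w in seq_len(n_wires_tot)) {
      set.seed(substream_seed(spec$seed, 3000 + w))
      sig[w, ] <- sig[w, ] + stats::rnorm(n, 0, spec$sensor_noise_sd)
    }
  }

  gt <- session_ground_truth(spec, src_truth)
  structure(list(signals = sig, fs_Hz = fs, channel_map = cmap,
                 excluded_wires = integer(0), duration_s = spec$duration_s,
                 ground_truth = gt),
            class = "lfp_session")
}

# Presence labels on the 4-s detection grid, plus true pairwise lags.
session_ground_truth <- function(spec, src_truth) {
  fs <- spec$fs_Hz
  n <- round(spec$duration_s * fs)
  grid <- detection_grid(spec$duration_s)
  sources <- lapply(src_truth, function(s) {
    pres <- vapply(grid$times_s, function(tc) {
      i0 <- max(1, round((tc - grid$window_s / 2) * fs) + 1)
      i1 <- min(n, round((tc + grid$window_s / 2) * fs))
      mean(s$envelope[i0:i1])
    }, numeric(1))
    lags <- stats::setNames(s$targets$phase_lag_deg, s$targets$structure)
    pairs <- NULL
    if (length(lags) > 1) {
      cb <- utils::combn(names(lags), 2)
      pairs <- data.frame(structure_a = cb[1, ], structure_b = cb[2, ],
                          delta_phi_deg = wrap180(lags[cb[2, ]] - lags[cb[1, ]]),
                          stringsAsFactors = FALSE)
    }
    list(band = s$band, center_Hz = s$center_Hz, width_Hz = s$width_Hz,
         amplitude = s$amplitude, structures = s$targets$structure,
         bin_envelope = pres, present = pres > 0.5, lag_pairs = pairs)
  })
  list(times_s = grid$times_s, window_s = grid$window_s, sources = sources)
}

#' AIM monitoring schedule
#'
#' Monitoring periods of 1 min every 5 min for the first 20 min post
#' injection, then every 10 min for the rest of the session.
#'
#' @param session_min Total session length in minutes (default 180).
#' @return Vector of period times in minutes.
#' @export
aim_schedule <- function(session_min = 180) {
  c(seq(5, 20, by = 5), seq(30, session_min, by = 10))
}

#' Generate an AIM score sheet on the monitoring schedule
#'
#' @param schedule Period times in minutes (see [aim_schedule()]).
#' @param severity_profile,amplitude_profile Named list (axial, limb,
#'   orolingual) of either a single integer score 0-4, a vector of scores
#'   per period, or a function of time in minutes returning scores 0-4.
#' @param seed Optional seed; when `jitter_prob > 0`, scores are
#'   perturbed by +/-1 (clamped to 0-4) with that probability.
#' @param jitter_prob Probability of rater jitter per score (default 0).
#' @return Tidy `data.frame(period_min, subtype, severity, amplitude)`.
#' @export
generate_aim_series <- function(schedule, severity_profile, amplitude_profile,
                                seed = NULL, jitter_prob = 0) {
  subtypes <- c("axial", "limb", "orolingual")
  resolve <- function(profile, subtype) {
    p <- profile[[subtype]]
    if (is.null(p)) p <- 0
    v <- if (is.function(p)) p(schedule) else rep_len(p, length(schedule))
    if (any(v != round(v) | v < 0 | v > 4))
      stop("scores must be integers in 0-4")
    as.integer(v)
  }
  out <- do.call(rbind, lapply(subtypes, function(s) {
    data.frame(period_min = schedule, subtype = s,
               severity = resolve(severity_profile, s),
               amplitude = resolve(amplitude_profile, s),
               stringsAsFactors = FALSE)
  }))
  if (jitter_prob > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (col in c("severity", "amplitude")) {
      hit <- stats::runif(nrow(out)) < jitter_prob
      out[[col]][hit] <- pmin(pmax(out[[col]][hit] +
        sample(c(-1L, 1L), sum(hit), replace = TRUE), 0L), 4L)
    }
  }
  rownames(out) <- NULL
  out
}

#' Specification of a synthetic open-field trajectory
#'
#' A rat in a circular arena whose body center orbits at `speed_cm_s`
#' on a circle of `path_radius_cm` while its heading rotates according to
#' `angular_velocity_fn` (positive = counter-clockwise = contralateral by
#' default convention).
#'
#' @param angular_velocity_fn Function of time (s) returning signed
#'   angular velocity in deg/s, or a single number.
#' @param duration_s Duration in seconds.
#' @param arena_diameter_cm Arena diameter (default 55).
#' @param fps Frames per second (default 25).
#' @param path_radius_cm Radius of the locomotor circle (0 = in place).
#' @param speed_cm_s Tangential speed of the body center.
#' @param keypoint_jitter_cm Gaussian jitter sd added to each keypoint.
#' @param dropout_prob Probability that a keypoint-frame has likelihood
#'   below the 0.9 acceptance threshold.
#' @param seed RNG seed.
#' @export
trajectory_spec <- function(angular_velocity_fn, duration_s,
                            arena_diameter_cm = 55, fps = 25,
                            path_radius_cm = 0, speed_cm_s = 0,
                            keypoint_jitter_cm = 0.1, dropout_prob = 0,
                            seed = 1) {
  if (fps <= 0) stop("fps must be > 0")
  if (is.numeric(angular_velocity_fn)) {
    w0 <- angular_velocity_fn
    angular_velocity_fn <- function(t) rep(w0, length(t))
  }
  structure(list(angular_velocity_fn = angular_velocity_fn,
                 duration_s = duration_s,
                 arena_diameter_cm = arena_diameter_cm, fps = fps,
                 path_radius_cm = path_radius_cm, speed_cm_s = speed_cm_s,
                 keypoint_jitter_cm = keypoint_jitter_cm,
                 dropout_prob = dropout_prob, seed = seed),
            class = "trajectory_spec")
}

# Rigid body template (cm), origin at body center, facing +x.
rat_template <- function() {
  data.frame(
    part = c("nose", "left_ear", "right_ear", "head_top", "body_center",
             "tail_base", "tail_tip"),
    x = c(8, 6, 6, 5.5, 0, -6, -13),
    y = c(0, 1.5, -1.5, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic keypoint trajectory with ground truth
#'
#' @param spec A [trajectory_spec()].
#' @return List with `keypoints` (data.frame, one row per frame with
#'   `<part>_x`, `<part>_y`, `<part>_likelihood` columns in cm), `fps`,
#'   `arena_diameter_cm`, and `ground_truth` (true heading series, turn
#'   counts per direction, net rotation).
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  set.seed(spec$seed)
  fps <- spec$fps
  # include the endpoint frame so duration_s of rotation is realized
  n <- round(spec$duration_s * fps) + 1
  t <- (seq_len(n) - 1) / fps
  omega <- spec$angular_velocity_fn(t)
  heading <- (c(0, cumsum(omega[-n]) / fps)) %% 360

  R <- spec$arena_diameter_cm / 2
  cx <- R; cy <- R  # arena center in cm coordinates
  if (spec$path_radius_cm > 0 && spec$speed_cm_s > 0) {
    psi <- spec$speed_cm_s / spec$path_radius_cm * t
    bx <- cx + spec$path_radius_cm * cos(psi)
    by <- cy + spec$path_radius_cm * sin(psi)
  } else {
    bx <- rep(cx, n); by <- rep(cy, n)
  }

  tmpl <- rat_template()
  kp <- data.frame(frame = seq_len(n) - 1)
  th <- heading * pi / 180
  for (i in seq_len(nrow(tmpl))) {
    px <- tmpl$x[i]; py <- tmpl$y[i]
    x <- bx + px * cos(th) - py * sin(th) +
      stats::rnorm(n, 0, spec$keypoint_jitter_cm)
    y <- by + px * sin(th) + py * cos(th) +
      stats::rnorm(n, 0, spec$keypoint_jitter_cm)
    # keep inside the arena circle
    rr <- sqrt((x - cx)^2 + (y - cy)^2)
    over <- rr > R - 0.1
    if (any(over)) {
      f <- (R - 0.1) / rr[over]
      x[over] <- cx + (x[over] - cx) * f
      y[over] <- cy + (y[over] - cy) * f
    }
    lik <- stats::runif(n, 0.95, 1)
    drop <- stats::runif(n) < spec$dropout_prob
    lik[drop] <- stats::runif(sum(drop), 0.1, 0.9)
    kp[[paste0(tmpl$part[i], "_x")]] <- x
    kp[[paste0(tmpl$part[i], "_y")]] <- y
    kp[[paste0(tmpl$part[i], "_likelihood")]] <- lik
  }

  turns <- true_turn_counts(heading)
  list(keypoints = kp, fps = fps,
       arena_diameter_cm = spec$arena_diameter_cm,
       ground_truth = list(heading_deg = heading,
                           net_rotation_deg = sum(omega[-n]) / fps,
                           contralateral_turns = turns$ccw,
                           ipsilateral_turns = turns$cw))
}

# Ground-truth turn counts: maximal same-sign rotation runs of the true
# heading, each contributing floor(|rotation| / 360).
true_turn_counts <- function(heading_deg) {
  d <- diff(heading_deg)
  d <- wrap180(d)
  ccw <- 0L; cw <- 0L
  run <- 0
  for (k in seq_along(d)) {
    if (d[k] == 0) next
    if (sign(d[k]) == sign(run) || run == 0) {
      run <- run + d[k]
    } else {
      if (run >= 360) ccw <- ccw + floor(run / 360)
      if (run <= -360) cw <- cw + floor(-run / 360)
      run <- d[k]
    }
  }
  if (run >= 360) ccw <- ccw + floor(run / 360)
  if (run <= -360) cw <- cw + floor(-run / 360)
  list(ccw = as.integer(ccw), cw = as.integer(cw))
}
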
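#' Circular mean and resultant vector length
#'
#' Standard first-trigonometric-moment statistics of angles in degrees:
#' the circular mean is `atan2(mean sin, mean cos)` and the mean
#' resultant length r is the magnitude of the mean unit phasor (1 =
#' perfect concentration, 0 = uniform).
#'
#' @param angles_deg Angles in degrees.
#' @return `circ_mean_deg`: mean angle in [-180, 180). `circ_r`: r in
#'   [0, 1].
#' @export
circ_mean_deg <- function(angles_deg) {
  a <- angles_deg * pi / 180
  wrap180(atan2(mean(sin(a)), mean(cos(a))) * 180 / pi)
}

#' @rdname circ_mean_deg
#' @export
circ_r <- function(angles_deg) {
  a <- angles_deg * pi / 180
  sqrt(mean(sin(a))^2 + mean(cos(a))^2)
}

#' Median NBG frequency across detections
#'
#' The common passband center: the median of the fitted peak frequencies
#' (B) over all positive detections in the analysis window, pooled
#' across the structures involved.
#'
#' @param detections_list List of [detect_oscillations()] outputs.
#' @param window Optional `c(t0, t1)` seconds restriction.
#' @export
nbg_median_frequency <- function(detections_list, window = NULL) {
  bs <- unlist(lapply(detections_list, function(d) {
    sel <- d$detected
    if (!is.null(window))
      sel <- sel & d$bin_time_s >= window[1] & d$bin_time_s <= window[2]
    d$B[sel]
  }))
  if (!length(bs))
    stop("no detections available to define the median frequency")
  stats::median(bs)
}

#' Zero-phase bandpass about a center frequency
#'
#' 4th-order Butterworth bandpass at `center +/- half_width` Hz applied
#' forward-backward (zero phase distortion, essential for downstream
#' phase differences).
#'
#' @param x Numeric series or wires x samples matrix.
#' @param fs Sampling rate (Hz).
#' @param center_Hz Passband center, e.g. the median detected NBG
#'   frequency (see [nbg_median_frequency()]).
#' @param half_width Half passband width (default 5 Hz).
#' @export
bandpass_about_median <- function(x, fs, center_Hz, half_width = 5) {
  lo <- center_Hz - half_width; hi <- center_Hz + half_width
  if (lo <= 0 || hi >= fs / 2) stop("passband outside (0, Nyquist)")
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    t(apply(x, 1, function(r) signal::filtfilt(bf, r)))
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Instantaneous phase of a narrowband signal
#'
#' Phase angle of the analytic signal (Hilbert transform), in degrees
#' wrapped to [-180, 180). The first and last `trim_s` seconds are set
#' to NA to discard filter/Hilbert edge transients.
#'
#' @param x Narrowband series.
#' @param fs Sampling rate (Hz).
#' @param trim_s Edge trim in seconds (default 0.5).
#' @export
instantaneous_phase <- function(x, fs, trim_s = 0.5) {
  z <- analytic_signal(x)
  phi <- Arg(z) * 180 / pi
  phi <- wrap180(phi)
  nt <- round(trim_s * fs)
  if (nt > 0 && 2 * nt < length(phi)) {
    phi[seq_len(nt)] <- NA_real_
    phi[(length(phi) - nt + 1):length(phi)] <- NA_real_
  }
  phi
}

# Analytic signal via FFT half-spectrum doubling.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase-difference statistics for one wire pair
#'
#' Circular mean `delta_phi = <phi_i(t) - phi_j(t)>` and mean resultant
#' vector length r of the instantaneous phase difference. NA samples
#' (edge trims, gaps) are dropped pairwise.
#'
#' @param phi_i,phi_j Equal-length phase series in degrees.
#' @return List with `delta_phi_deg` in [-180, 180), `r`, `n`.
#' @export
pair_phase_stats <- function(phi_i, phi_j) {
  if (length(phi_i) != length(phi_j)) stop("phase series length mismatch")
  d <- phi_i - phi_j
  d <- d[is.finite(d)]
  if (!length(d)) stop("no overlapping finite phase samples")
  list(delta_phi_deg = circ_mean_deg(d), r = circ_r(d), n = length(d))
}

#' Structure-level phase coupling from wire-pair statistics
#'
#' Functional connectivity between two structures is the mean resultant
#' length r over all wire pairs spanning them; the structure-level phase
#' difference is the circular mean of delta_phi over pairs passing the
#' quality filter r > `r_min` (pairs below it carry unreliable phase
#' estimates and are logged but excluded). When no pair passes, the
#' phase difference is reported missing.
#'
#' @param pairs data.frame with columns `structure_a`, `structure_b`,
#'   `delta_phi_deg`, `r` (one row per wire pair).
#' @param r_min Quality threshold on r (default 0.5).
#' @return data.frame per structure pair: `structure_a`, `structure_b`,
#'   `mean_r`, `mean_dphi_deg` (NA if no pair passes), `n_pairs`,
#'   `n_pass_filter`.
#' @export
structure_coupling <- function(pairs, r_min = 0.5) {
  req <- c("structure_a", "structure_b", "delta_phi_deg", "r")
  stopifnot(all(req %in% names(pairs)))
  key <- paste(pairs$structure_a, pairs$structure_b, sep = "|")
  out <- lapply(unique(key), function(k) {
    p <- pairs[key == k, ]
    pass <- p$r > r_min
    data.frame(structure_a = p$structure_a[1],
               structure_b = p$structure_b[1],
               mean_r = mean(p$r),
               mean_dphi_deg = if (any(pass))
                 circ_mean_deg(p$delta_phi_deg[pass]) else NA_real_,
               n_pairs = nrow(p), n_pass_filter = sum(pass),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' One-sample test for the mean angle
#'
#' Confidence-interval test of H0: mean angle = `mu0`. The (1 - alpha)
#' confidence interval for the population mean direction is computed
#' from the mean resultant length (Zar's formulas, the circ_mtest
#' approach); H0 is rejected when `mu0` falls outside it. With too
#' little concentration the interval is undefined and the test is
#' flagged inconclusive.
#'
#' @param angles_deg Phase-difference samples in degrees (n >= 8).
#' @param mu0 Hypothesised mean angle in degrees (default 0).
#' @param alpha Significance level; divide by the number of structure
#'   pairs for a Bonferroni-corrected family.
#' @return List: `reject` (TRUE/FALSE/NA), `conclusive`, `mean_deg`,
#'   `ci_halfwidth_deg`, `r`, `n`.
#' @export
mean_angle_test <- function(angles_deg, mu0 = 0, alpha = 0.05) {
  angles_deg <- angles_deg[is.finite(angles_deg)]
  n <- length(angles_deg)
  if (n < 8) stop("need at least 8 samples")
  r <- circ_r(angles_deg)
  mu <- circ_mean_deg(angles_deg)
  R <- n * r
  chi2 <- stats::qchisq(1 - alpha, df = 1)
  d <- NA_real_
  if (r < 0.9) {
    num <- 2 * n * (2 * R^2 - n * chi2)
    if (num > 0) {
      arg <- sqrt(num / (R^2 * (4 * n - chi2)))
      if (is.finite(arg) && arg <= 1) d <- acos(arg)
    }
  } else {
    inner <- n^2 - (n^2 - R^2) * exp(chi2 / n)
    if (inner > 0) {
      arg <- sqrt(inner) / R
      if (is.finite(arg) && arg <= 1) d <- acos(arg)
    }
  }
  if (!is.finite(d))
    return(list(reject = NA, conclusive = FALSE, mean_deg = mu,
                ci_halfwidth_deg = NA_real_, r = r, n = n))
  dd <- d * 180 / pi
  reject <- abs(wrap180(mu - mu0)) > dd
  list(reject = reject, conclusive = TRUE, mean_deg = mu,
       ci_halfwidth_deg = dd, r = r, n = n)
}

#' Convert a phase difference to a time delay
#'
#' `delay_ms = (delta_phi / 360) / f * 1000`. Positive values mean the
#' first (column) structure leads the second (row) structure.
#'
#' @param delta_phi_deg Phase difference in degrees.
#' @param f_Hz Oscillation frequency (> 0).
#' @export
phase_to_delay <- function(delta_phi_deg, f_Hz) {
  if (any(f_Hz <= 0)) stop("f_Hz must be > 0")
  (delta_phi_deg / 360) / f_Hz * 1000
}

#' NBG phase synchrony and functional connectivity for a session
#'
#' End-to-end phase stage: pools detected NBG peak frequencies to define
#' the common `median +/- 5 Hz` passband, bandpasses the per-wire
#' (monopolar) signals of every structure with eligible detections,
#' extracts instantaneous phases, restricts samples to analysis bins
#' where both structures have a positive detection (`codetect_only`),
#' computes wire-pair circular statistics for all cross-structure pairs,
#' and aggregates to structure level.
#'
#' @param session An `lfp_session`.
#' @param detections Named list (structure/hemisphere key) of
#'   [detect_oscillations()] outputs for the NBG band.
#' @param window Optional `c(t0, t1)` seconds analysis window.
#' @param half_width Passband half-width (default 5 Hz).
#' @param r_min Quality filter threshold (default 0.5).
#' @param codetect_only Restrict to co-detected bins (default TRUE).
#' @param mode "monopolar" (default) uses per-wire signals; "bipolar"
#'   uses within-structure bipolar derivations instead.
#' @return List: `median_freq_Hz`, `wire_pairs` (per-pair data.frame),
#'   `coupling` (from [structure_coupling()]).
#' @export
nbg_phase_coupling <- function(session, detections, window = NULL,
                               half_width = 5, r_min = 0.5,
                               codetect_only = TRUE,
                               mode = c("monopolar", "bipolar")) {
  mode <- match.arg(mode)
  stopifnot(inherits(session, "lfp_session"))
  fs <- session$fs_Hz
  m <- nbg_median_frequency(detections, window)

  eligible <- names(detections)[vapply(detections, function(d) {
    sel <- if (is.null(window)) rep(TRUE, nrow(d)) else
      d$bin_time_s >= window[1] & d$bin_time_s <= window[2]
    mean(d$detected[sel]) > 0.05
  }, logical(1))]
  if (length(eligible) < 2)
    stop("need NBG detections in at least two structures")

  cm <- session$channel_map
  key_of <- paste(cm$structure, cm$hemisphere, sep = "/")
  if (mode == "monopolar") {
    wire_rows <- which(key_of %in% eligible &
                       !(cm$wire_id %in% session$excluded_wires))
    sigs <- session$signals[wire_rows, , drop = FALSE]
    wire_key <- key_of[wire_rows]
    wire_lab <- cm$wire_id[wire_rows]
  } else {
    bip <- make_bipolar_pairs(session)
    bkey <- paste(bip$pairs$structure, bip$pairs$hemisphere, sep = "/")
    sel <- which(bkey %in% eligible)
    sigs <- bip$signals[sel, , drop = FALSE]
    wire_key <- bkey[sel]
    wire_lab <- paste0(bip$pairs$wire_i[sel], "-", bip$pairs$wire_j[sel])
  }

  nb <- bandpass_about_median(sigs, fs, m, half_width)
  ph <- t(apply(nb, 1, instantaneous_phase, fs = fs))

  # sample-level mask: analysis window plus per-structure detected bins
  n <- ncol(ph)
  tvec <- (seq_len(n) - 1) / fs
  base_keep <- if (is.null(window)) rep(TRUE, n) else
    tvec >= window[1] & tvec <= window[2]
  bin_keep <- list()
  for (key in eligible) {
    d <- detections[[key]]
    keep <- rep(FALSE, n)
    half <- 2  # detection bins tile the grid at 4-s hop
    for (k in which(d$detected)) {
      i0 <- max(1, floor((d$bin_time_s[k] - half) * fs) + 1)
      i1 <- min(n, ceiling((d$bin_time_s[k] + half) * fs))
      keep[i0:i1] <- TRUE
    }
    bin_keep[[key]] <- keep
  }

  out <- list()
  for (a in seq_len(nrow(ph) - 1)) {
    for (b in (a + 1):nrow(ph)) {
      if (wire_key[a] == wire_key[b]) next
      keep <- base_keep
      if (codetect_only)
        keep <- keep & bin_keep[[wire_key[a]]] & bin_keep[[wire_key[b]]]
      pa <- ph[a, ]; pb <- ph[b, ]
      pa[!keep] <- NA_real_
      st <- tryCatch(pair_phase_stats(pa, pb), error = function(e) NULL)
      if (is.null(st)) next
      out[[length(out) + 1]] <- data.frame(
        structure_a = wire_key[a], structure_b = wire_key[b],
        wire_i = wire_lab[a], wire_j = wire_lab[b],
        delta_phi_deg = st$delta_phi_deg, r = st$r, n = st$n,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no cross-structure wire pairs with usable samples")
  wp <- do.call(rbind, out)
  list(median_freq_Hz = m, wire_pairs = wp,
       coupling = structure_coupling(wp, r_min))
}
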
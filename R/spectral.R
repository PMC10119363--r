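#' Detection/spectrogram time grid
#'
#' With 8-s analysis windows at 50% overlap the spectrogram has one
#' column — and the detector one opportunity — every 4 s. Window centers
#' run from `window_s/2` to `duration_s - window_s/2`.
#'
#' @param duration_s Recording duration in seconds.
#' @param window_s Analysis window length (default 8 s).
#' @param overlap Fractional overlap (default 0.5).
#' @return List with `times_s` (window centers), `hop_s`, `window_s`,
#'   `n_bins`.
#' @export
detection_grid <- function(duration_s, window_s = 8, overlap = 0.5) {
  hop <- window_s * (1 - overlap)
  if (duration_s < window_s) stop("duration shorter than one window")
  n_bins <- floor((duration_s - window_s) / hop) + 1
  times <- window_s / 2 + hop * (seq_len(n_bins) - 1)
  list(times_s = times, hop_s = hop, window_s = window_s, n_bins = n_bins)
}

#' Welch spectrogram of an LFP series
#'
#' Time series of power spectral densities over 0-`fmax` Hz: one Hann
#' taper per window position (8 s, 50% overlap by default), giving a
#' frequency resolution of `1/window_s` and one column per hop. Optional
#' sub-window averaging (`n_sub` > 1) averages `n_sub` 50%-overlapped
#' Hann periodograms inside each window at coarser resolution.
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param window_s,overlap Window length (s) and fractional overlap.
#' @param fmax Upper frequency limit of the grid (default 250 Hz).
#' @param n_sub Number of sub-windows per column (default 1).
#' @return Object of class `spectrogram_grid`: list with `times_s`,
#'   `freqs_Hz`, `psd` (freq x time matrix, V^2/Hz), `mask` (logical,
#'   TRUE = excised), `fs`, `window_s`.
#' @export
welch_spectrogram <- function(x, fs, window_s = 8, overlap = 0.5,
                              fmax = 250, n_sub = 1) {
  nwin <- round(window_s * fs)
  if (length(x) < nwin) stop("series shorter than one window")
  grid <- detection_grid(length(x) / fs, window_s, overlap)
  hop <- round(grid$hop_s * fs)
  psd <- NULL
  for (k in seq_len(grid$n_bins)) {
    i0 <- (k - 1) * hop + 1
    seg <- x[i0:(i0 + nwin - 1)]
    p <- segment_psd(seg, fs, n_sub, fmax)
    if (is.null(psd)) {
      freqs <- p$freqs
      psd <- matrix(0, length(freqs), grid$n_bins)
    }
    psd[, k] <- p$psd
  }
  structure(list(times_s = grid$times_s, freqs_Hz = freqs, psd = psd,
                 mask = matrix(FALSE, length(freqs), grid$n_bins),
                 fs = fs, window_s = window_s),
            class = "spectrogram_grid")
}

segment_psd <- function(seg, fs, n_sub = 1, fmax = NULL) {
  if (n_sub <= 1) return(periodogram_psd(seg, fs, fmax))
  nsegl <- floor(2 * length(seg) / (n_sub + 1))
  hop <- floor(nsegl / 2)
  w <- hann_window(nsegl)
  M <- vapply(seq_len(n_sub), function(j) {
    s <- seg[((j - 1) * hop + 1):((j - 1) * hop + nsegl)]
    (s - mean(s)) * w
  }, numeric(nsegl))
  X <- stats::mvfft(M)
  nh <- floor(nsegl / 2)
  psd <- rowMeans(Mod(X[seq_len(nh + 1), , drop = FALSE])^2) /
    (fs * sum(w^2))
  dbl <- rep(2, nh + 1)
  dbl[1] <- 1
  if (nsegl %% 2 == 0) dbl[nh + 1] <- 1
  psd <- psd * dbl
  freqs <- seq(0, nh) * fs / nsegl
  if (!is.null(fmax)) {
    keep <- freqs <= fmax + 1e-9
    freqs <- freqs[keep]
    psd <- psd[keep]
  }
  list(freqs = freqs, psd = psd)
}

#' Default IRASA resampling factors
#'
#' The published default set 1.1, 1.15, ..., 1.9.
#' @export
irasa_hset <- function() seq(1.1, 1.9, by = 0.05)

#' IRASA fractal/oscillatory decomposition of one analysis window
#'
#' Irregular-resampling auto-spectral analysis: for each factor h in
#' `hset` the segment is resampled by h and by 1/h; the geometric mean of
#' each pair of PSDs leaves a power-law (fractal) spectrum invariant
#' while displacing rhythmic peaks, and the median across factors yields
#' the fractal estimate `S_fractal`. The normalized spectrum is
#' `S_dB_fractal(f) = 10 log10(S(f) / S_fractal(f))`, zero for purely
#' fractal input and positive at oscillatory peaks.
#'
#' Resampling uses the Fourier method (spectrum truncation/zero-padding),
#' which applies an ideal anti-aliasing filter implicitly. Frequencies
#' whose fractal estimate would require content beyond the resampled
#' Nyquist (`f > nyquist / max(hset)`) are flagged invalid.
#'
#' All PSD estimates (the mixed spectrum and every resampled spectrum)
#' use the same Welch sub-averaging inside the window (`n_sub`
#' half-overlapped Hann sub-windows, default 7, i.e. 2-s sub-windows for
#' an 8-s window). Raw single-taper periodograms carry multiplicative
#' chi-squared(2) noise whose logarithm is biased by -2.5 dB, which
#' would contaminate the normalized spectrum; sub-averaging makes the
#' numerator and the fractal estimate consistent so `S_dB_fractal`
#' averages to zero on purely fractal input. `n_sub = 1` recovers the
#' literal single-taper estimate.
#'
#' @param segment One analysis window of samples.
#' @param fs Sampling rate (Hz).
#' @param hset Resampling factors, all > 1 (default [irasa_hset()]).
#' @param fmax Upper frequency limit (default 250 Hz).
#' @param n_sub Number of half-overlapped Hann sub-windows per PSD
#'   estimate (default 7).
#' @return List with `freqs`, `psd` (mixed S(f)), `psd_fractal`,
#'   `db_fractal`, `valid` (logical per frequency).
#' @export
irasa_fractal <- function(segment, fs, hset = irasa_hset(), fmax = 250,
                          n_sub = 7) {
  if (any(hset <= 1)) stop("all hset factors must be > 1")
  n <- length(segment)
  mixed <- segment_psd(segment, fs, n_sub, fmax)
  freqs <- mixed$freqs
  X <- stats::fft(segment)
  gm <- matrix(NA_real_, length(freqs), length(hset))
  for (j in seq_along(hset)) {
    h <- hset[j]
    # snap resampled lengths to 5-smooth values for fast FFTs; the
    # effective factor n/m differs negligibly from the nominal h
    up <- fft_resample_spec(X, n, smooth_length(round(n * h)))
    dn <- fft_resample_spec(X, n, smooth_length(round(n / h)))
    pu <- resampled_psd_on_grid(up, fs, freqs, n_sub)
    pd <- resampled_psd_on_grid(dn, fs, freqs, n_sub)
    gm[, j] <- sqrt(pu * pd)
  }
  frac <- apply(gm, 1, stats::median)
  frac[frac <= 0] <- NA_real_
  valid <- freqs <= (fs / 2) / max(hset) & is.finite(frac)
  db <- 10 * log10(mixed$psd / frac)
  list(freqs = freqs, psd = mixed$psd, psd_fractal = frac,
       db_fractal = db, valid = valid)
}

# PSD of a resampled segment interpreted at the original rate, linearly
# interpolated (in log power) onto the target frequency grid.
resampled_psd_on_grid <- function(y, fs, freqs, n_sub = 1) {
  p <- segment_psd(y, fs, n_sub)
  lp <- log(pmax(p$psd, 1e-300))
  out <- stats::approx(p$freqs, lp, xout = freqs, rule = 2)$y
  exp(out)
}

#' Fractal-normalized spectrogram of one series
#'
#' Runs [irasa_fractal()] per 8-s window position to produce a time x
#' frequency grid of `S_dB_fractal`, on the same grid as
#' [welch_spectrogram()].
#'
#' @inheritParams welch_spectrogram
#' @param hset IRASA resampling factors.
#' @param n_sub Sub-windows per PSD estimate (see [irasa_fractal()]).
#' @return A `spectrogram_grid` whose `psd` field holds dB_fractal values
#'   (field also aliased as `db_fractal`); frequencies beyond the valid
#'   IRASA range are masked.
#' @export
fractal_spectrogram <- function(x, fs, window_s = 8, overlap = 0.5,
                                fmax = 250, hset = irasa_hset(),
                                n_sub = 7) {
  nwin <- round(window_s * fs)
  if (length(x) < nwin) stop("series shorter than one window")
  grid <- detection_grid(length(x) / fs, window_s, overlap)
  hop <- round(grid$hop_s * fs)
  db <- NULL
  for (k in seq_len(grid$n_bins)) {
    i0 <- (k - 1) * hop + 1
    res <- irasa_fractal(x[i0:(i0 + nwin - 1)], fs, hset, fmax, n_sub)
    if (is.null(db)) {
      freqs <- res$freqs
      db <- matrix(NA_real_, length(freqs), grid$n_bins)
      mask <- matrix(FALSE, length(freqs), grid$n_bins)
    }
    db[, k] <- res$db_fractal
    mask[!res$valid, k] <- TRUE
  }
  g <- structure(list(times_s = grid$times_s, freqs_Hz = freqs, psd = db,
                      mask = mask, fs = fs, window_s = window_s),
                 class = "spectrogram_grid")
  g$db_fractal <- g$psd
  g
}

#' Default line-noise excision bands
#'
#' 50 +/- 2 Hz mains plus harmonics at 100 +/- 1, 150 +/- 1 and
#' 200 +/- 1 Hz.
#' @export
line_noise_bands <- function() {
  list(c(48, 52), c(99, 101), c(149, 151), c(199, 201))
}

#' Mask power-line-noise frequency bins
#'
#' Marks bins inside the mains bands as excised. Masked bins are flagged,
#' not zeroed, and are excluded from later peak fitting and averaging.
#'
#' @param grid A `spectrogram_grid`.
#' @param bands List of c(lo, hi) frequency intervals
#'   (default [line_noise_bands()]).
#' @export
excise_line_noise <- function(grid, bands = line_noise_bands()) {
  stopifnot(inherits(grid, "spectrogram_grid"))
  for (b in bands) {
    sel <- grid$freqs_Hz >= b[1] - 1e-9 & grid$freqs_Hz <= b[2] + 1e-9
    grid$mask[sel, ] <- TRUE
  }
  grid
}

#' Average per-pair spectrograms into one structure spectrogram
#'
#' Arithmetic mean of dB_fractal across a structure's bipolar pairs per
#' time-frequency bin, skipping masked bins; a bin masked in every pair
#' stays masked.
#'
#' @param grids List of `spectrogram_grid` objects sharing axes.
#' @return A `spectrogram_grid` with an added `n_pairs` matrix.
#' @export
average_structure <- function(grids) {
  if (!length(grids)) stop("no contributing pair spectrograms")
  f0 <- grids[[1]]$freqs_Hz; t0 <- grids[[1]]$times_s
  for (g in grids)
    if (!isTRUE(all.equal(g$freqs_Hz, f0)) ||
        !isTRUE(all.equal(g$times_s, t0)))
      stop("pair grids must share time/frequency axes")
  acc <- matrix(0, length(f0), length(t0))
  cnt <- matrix(0L, length(f0), length(t0))
  for (g in grids) {
    use <- !g$mask & is.finite(g$psd)
    acc[use] <- acc[use] + g$psd[use]
    cnt[use] <- cnt[use] + 1L
  }
  avg <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  out <- grids[[1]]
  out$psd <- avg
  out$db_fractal <- avg
  out$mask <- cnt == 0L
  out$n_pairs <- cnt
  out
}

#' Structure-level fractal-normalized spectrograms for a session
#'
#' Full spectral stage: bipolar derivation, per-pair IRASA-normalized
#' spectrogram, line-noise excision, and within-structure averaging.
#'
#' @param session An `lfp_session`.
#' @param window_s,overlap,fmax,hset Passed to [fractal_spectrogram()].
#' @param excise Apply [excise_line_noise()] per pair (default TRUE).
#' @return Named list (structure/hemisphere key) of averaged
#'   `spectrogram_grid` objects.
#' @export
structure_spectrograms <- function(session, window_s = 8, overlap = 0.5,
                                   fmax = 250, hset = irasa_hset(),
                                   excise = TRUE, n_sub = 7) {
  bip <- make_bipolar_pairs(session)
  if (!nrow(bip$pairs)) stop("no usable bipolar pairs in session")
  keys <- unique(paste(bip$pairs$structure, bip$pairs$hemisphere, sep = "/"))
  out <- list()
  for (key in keys) {
    sel <- which(paste(bip$pairs$structure, bip$pairs$hemisphere,
                       sep = "/") == key)
    grids <- lapply(sel, function(i) {
      g <- fractal_spectrogram(bip$signals[i, ], bip$fs_Hz, window_s,
                               overlap, fmax, hset, n_sub)
      if (excise) g <- excise_line_noise(g)
      g
    })
    out[[key]] <- average_structure(grids)
  }
  out
}
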
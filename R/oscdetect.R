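#' Band configuration for parametric peak detection
#'
#' Each band pairs the spectral segment used for fitting with the
#' frequency range in which a genuine peak must lie, plus limit values
#' for the fitted parameters and goodness of fit: theta fits [1, 15] Hz
#' and detects 5-10 Hz, beta fits [8, 48] Hz and detects 12-35 Hz, NBG
#' fits [40, 120] Hz and detects 70-110 Hz.
#'
#' Default limits (configurable): peak height A >= 1.5 dB_fractal, peak
#' frequency B within the band range, peak width C in [0.5, 15] Hz
#' ([0.3, 4] for theta), background slope |D| <= 0.2 dB/Hz, R^2 >= 0.7.
#'
#' @param name "theta", "beta" or "NBG".
#' @param limits Optional named list overriding any of `A_min`,
#'   `C_range`, `D_absmax`, `R2_min`.
#' @export
band_config <- function(name = c("theta", "beta", "NBG"), limits = list()) {
  name <- match.arg(name)
  fit_windows <- list(theta = c(1, 15), beta = c(8, 48), NBG = c(40, 120))
  def <- list(A_min = 1.5,
              C_range = if (name == "theta") c(0.3, 4) else c(0.5, 15),
              D_absmax = 0.2, R2_min = 0.7)
  def[names(limits)] <- limits
  structure(list(name = name, fit_window_Hz = fit_windows[[name]],
                 band_range_Hz = band_ranges()[[name]], limits = def),
            class = "band_config")
}

# Gaussian peak on a linear background: the detector's spectral model.
peak_model <- function(f, A, B, C, D, E) {
  A * exp(-((f - B) / C)^2) + D * f + E
}

#' Fit the 5-parameter spectral peak model to one spectrum column
#'
#' Least-squares fit of `y(f) = A exp(-((f - B)/C)^2) + D f + E` to the
#' dB_fractal values inside the band's fit window, with masked (excised)
#' bins dropped from the residual. A (peak height, dB_fractal),
#' B (peak frequency, Hz), C (peak width, Hz), D (background slope,
#' dB/Hz) and E (background offset, dB) are estimated by
#' Levenberg-Marquardt from multiple starts of B across the band range;
#' the fit with the smallest residual sum of squares is kept. R^2 is
#' reported as 1 - SS_res/SS_tot.
#'
#' @param freqs Frequency grid (Hz).
#' @param values dB_fractal values; `NA` entries are dropped.
#' @param band A [band_config()].
#' @param n_starts Number of B starting points (default 5).
#' @return List with `params` (named A, B, C, D, E), `R2`, `ss`,
#'   `converged`, `n_points`.
#' @export
fit_peak_model <- function(freqs, values, band, n_starts = 5) {
  stopifnot(inherits(band, "band_config"))
  fw <- band$fit_window_Hz
  use <- freqs >= fw[1] & freqs <= fw[2] & is.finite(values)
  f <- freqs[use]; y <- values[use]
  if (length(f) < 10)
    return(list(params = c(A = NA, B = NA, C = NA, D = NA, E = NA),
                R2 = NA_real_, ss = NA_real_, converged = FALSE,
                n_points = length(f)))
  # robust line estimate for background starting values
  lf <- stats::lm.fit(cbind(1, f), y)
  E0 <- unname(lf$coefficients[1]); D0 <- unname(lf$coefficients[2])
  resid0 <- y - (D0 * f + E0)
  A0 <- max(resid0)
  rg <- band$band_range_Hz
  B_starts <- seq(rg[1], rg[2], length.out = n_starts)
  C0 <- diff(rg) / 6
  best <- NULL
  for (B0 in B_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-((f - B) / C)^2) + D * f + E,
        start = list(A = max(A0, 0.1), B = B0, C = C0, D = D0, E = E0),
        lower = c(A = 0, B = fw[1], C = 1e-3, D = -5, E = -50),
        upper = c(A = 50, B = fw[2], C = diff(fw), D = 5, E = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || ss < best$ss)
      best <- list(ss = ss, coef = stats::coef(fit))
  }
  if (is.null(best))
    return(list(params = c(A = NA, B = NA, C = NA, D = NA, E = NA),
                R2 = NA_real_, ss = NA_real_, converged = FALSE,
                n_points = length(f)))
  ss_tot <- sum((y - mean(y))^2)
  R2 <- if (ss_tot > 0) 1 - best$ss / ss_tot else NA_real_
  list(params = best$coef[c("A", "B", "C", "D", "E")], R2 = R2,
       ss = best$ss, converged = TRUE, n_points = length(f))
}

#' Classify a fitted peak as a positive detection
#'
#' TRUE iff the fit converged, A, C, D fall within the band's limit
#' values, B lies inside the band range, and R^2 meets the minimum.
#'
#' @param fit Result of [fit_peak_model()].
#' @param band A [band_config()].
#' @export
classify_detection <- function(fit, band) {
  stopifnot(inherits(band, "band_config"))
  if (!isTRUE(fit$converged)) return(FALSE)
  p <- fit$params; lim <- band$limits; rg <- band$band_range_Hz
  isTRUE(p[["A"]] >= lim$A_min &&
         p[["B"]] >= rg[1] && p[["B"]] <= rg[2] &&
         p[["C"]] >= lim$C_range[1] && p[["C"]] <= lim$C_range[2] &&
         abs(p[["D"]]) <= lim$D_absmax &&
         is.finite(fit$R2) && fit$R2 >= lim$R2_min)
}

#' Band-specific oscillation detection on a structure spectrogram
#'
#' Fits the peak model to each 4-s column of a fractal-normalized
#' structure spectrogram and applies the limit gating, yielding one
#' possible detection per 4 s.
#'
#' @param grid A `spectrogram_grid` of dB_fractal values (e.g. from
#'   [structure_spectrograms()]).
#' @param band A [band_config()].
#' @return data.frame with one row per bin: `bin_time_s`, `detected`,
#'   `A`, `B`, `C`, `D`, `E`, `R2`.
#' @export
detect_oscillations <- function(grid, band) {
  stopifnot(inherits(grid, "spectrogram_grid"))
  vals <- grid$psd
  vals[grid$mask] <- NA_real_
  rows <- lapply(seq_along(grid$times_s), function(k) {
    fit <- fit_peak_model(grid$freqs_Hz, vals[, k], band)
    data.frame(bin_time_s = grid$times_s[k],
               detected = classify_detection(fit, band),
               A = unname(fit$params["A"]), B = unname(fit$params["B"]),
               C = unname(fit$params["C"]), D = unname(fit$params["D"]),
               E = unname(fit$params["E"]), R2 = fit$R2)
  })
  out <- do.call(rbind, rows)
  attr(out, "band") <- band$name
  out
}

#' Detection-rate summary over an analysis window
#'
#' Detection rate is the mean of the binary detection outcome over the
#' bins inside the window. When the rate exceeds 5%, summaries of
#' oscillation intensity (mean peak height) and frequency (mean and SD
#' of peak frequency) over the positive bins are reported; below that
#' threshold they are withheld as unreliable.
#'
#' @param detections Output of [detect_oscillations()].
#' @param window `c(t0, t1)` in seconds, or NULL for all bins.
#' @return List: `rate`, `n_bins`, `n_detected`, `eligible`
#'   (rate > 0.05), `mean_height`, `mean_freq`, `sd_freq`.
#' @export
detection_rate <- function(detections, window = NULL) {
  sel <- rep(TRUE, nrow(detections))
  if (!is.null(window))
    sel <- detections$bin_time_s >= window[1] &
           detections$bin_time_s <= window[2]
  if (!any(sel)) stop("empty analysis window")
  d <- detections[sel, ]
  rate <- mean(d$detected)
  eligible <- rate > 0.05
  pos <- d[d$detected, ]
  list(rate = rate, n_bins = nrow(d), n_detected = nrow(pos),
       eligible = eligible,
       mean_height = if (eligible) mean(pos$A) else NA_real_,
       mean_freq = if (eligible) mean(pos$B) else NA_real_,
       sd_freq = if (eligible) stats::sd(pos$B) else NA_real_)
}

#' Peak-dyskinesia analysis window for a treatment
#'
#' 20-60 min post injection for SKF82958; 40-80 min for L-DOPA,
#' sumanirole, and vehicle.
#'
#' @param treatment One of "SKF82958", "L-DOPA", "sumanirole", "vehicle".
#' @return `c(t0, t1)` in minutes.
#' @export
peak_window <- function(treatment = c("L-DOPA", "SKF82958", "sumanirole",
                                      "vehicle")) {
  treatment <- match.arg(treatment)
  if (treatment == "SKF82958") c(20, 60) else c(40, 80)
}

#' Rank correlation between oscillation power and AIM scores
#'
#' Spearman's rho (tie-corrected ranks, two-sided p) between per-period
#' peak heights and global AIM scores aligned to the same monitoring
#' periods.
#'
#' @param peak_heights Numeric vector per monitoring period.
#' @param aim_global Global AIM score per the same periods.
#' @return List with `rho`, `p_value`, `n`.
#' @export
correlate_power_aims <- function(peak_heights, aim_global) {
  if (length(peak_heights) != length(aim_global))
    stop("inputs must be paired per monitoring period")
  ok <- is.finite(peak_heights) & is.finite(aim_global)
  if (sum(ok) < 5) stop("need at least 5 paired observations")
  x <- peak_heights[ok]; y <- aim_global[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
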
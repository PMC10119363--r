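# Internal numerical helpers shared across modules.

#' @keywords internal
hann_window <- function(n) {
  if (n == 1) return(1)
  key <- as.character(n)
  hit <- .hann_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  .hann_cache[[key]] <- w
  w
}

.hann_cache <- new.env(parent = emptyenv())

#' One-sided Hann-tapered periodogram PSD.
#'
#' Single-taper power spectral density in V^2/Hz, normalized so that
#' sum(psd) * df equals the variance of the (demeaned, untapered) series
#' in expectation. DC and Nyquist bins are not doubled.
#'
#' @keywords internal
periodogram_psd <- function(x, fs, fmax = NULL) {
  n <- length(x)
  w <- hann_window(n)
  xw <- (x - mean(x)) * w
  X <- stats::fft(xw)
  nh <- floor(n / 2)
  scale <- 1 / (fs * sum(w^2))
  psd <- (Mod(X[seq_len(nh + 1)])^2) * scale
  # one-sided: double everything except DC (and Nyquist when n is even)
  dbl <- rep(2, nh + 1)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nh + 1] <- 1
  psd <- psd * dbl
  freqs <- seq(0, nh) * fs / n
  if (!is.null(fmax)) {
    keep <- freqs <= fmax + 1e-9
    freqs <- freqs[keep]
    psd <- psd[keep]
  }
  list(freqs = freqs, psd = psd)
}

#' Fourier-domain resampling to m samples.
#'
#' Band-limited resampling by spectrum truncation/zero-padding (the
#' scipy.signal.resample algorithm). Implicitly applies an ideal
#' anti-aliasing filter when m < n.
#'
#' @keywords internal
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  fft_resample_spec(stats::fft(x), n, m)
}

# As fft_resample but from a precomputed forward FFT (avoids repeating
# the forward transform across many target lengths).
#' @keywords internal
fft_resample_spec <- function(X, n, m) {
  if (m == n) return(Re(stats::fft(X, inverse = TRUE)) / n)
  Y <- complex(m)
  nyq <- min(n, m)
  nh <- floor(nyq / 2)
  Y[seq_len(nh + 1)] <- X[seq_len(nh + 1)]
  if (nh >= 1) Y[m - seq_len(nh) + 1] <- X[n - seq_len(nh) + 1]
  if (nyq %% 2 == 0) {
    # split/merge the shared Nyquist bin to keep the result real
    if (m < n) {
      Y[nh + 1] <- X[nh + 1] + X[n - nh + 1]
    } else {
      Y[nh + 1] <- X[nh + 1] / 2
      Y[m - nh + 1] <- X[nh + 1] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) * (1 / n)
}

#' Nearest 5-smooth (2^a 3^b 5^c) integer >= 16, for fast FFT sizes.
#' @keywords internal
smooth_length <- function(n) {
  n <- max(n, 16)
  key <- as.character(n)
  hit <- .smooth_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- stats::nextn(n, c(2, 3, 5))
  # also consider the largest 5-smooth number below n
  lo <- n
  while (lo > 16) {
    k <- lo
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) break
    lo <- lo - 1
  }
  res <- if (abs(lo - n) <= abs(m - n)) lo else m
  .smooth_cache[[key]] <- res
  res
}

.smooth_cache <- new.env(parent = emptyenv())

#' Deterministic per-component substream seed from a master seed.
#' @keywords internal
substream_seed <- function(master, k) {
  s <- (as.double(master) %% 65521) * 31607 + as.double(k) * 7919 + 17
  as.integer(s %% 2147483629) + 1L
}

#' Wrap angles in degrees to [-180, 180).
#' @keywords internal
wrap180 <- function(deg) {
  ((deg + 180) %% 360) - 180
}

`%||%` <- function(a, b) if (is.null(a)) b else a
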
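#' Build a channel map
#'
#' Maps each wire to an anatomical structure, hemisphere, and electrode
#' bundle. Structure names are free-form; the implant targeted in this
#' workflow uses RFA, M1FL, M1Tr, DMS, DLS, GPe, SNr.
#'
#' @param wire_id Integer wire identifiers.
#' @param structure Structure name per wire.
#' @param hemisphere "lesioned" or "intact" per wire.
#' @param bundle Bundle identifier; defaults to structure/hemisphere.
#' @export
channel_map <- function(wire_id, structure, hemisphere = "lesioned",
                        bundle = NULL) {
  cm <- data.frame(wire_id = as.integer(wire_id), structure = structure,
                   hemisphere = hemisphere, stringsAsFactors = FALSE)
  cm$bundle <- bundle %||% paste(cm$structure, cm$hemisphere, sep = "/")
  if (anyDuplicated(cm$wire_id)) stop("duplicate wire ids")
  cm
}

#' Assemble an LFP session from signals and a channel map
#'
#' @param signals Wires x samples numeric matrix in microvolts.
#' @param fs_Hz Sampling rate in Hz.
#' @param channel_map A [channel_map()] with one row per signal row.
#' @param excluded_wires Wire ids excluded from analysis.
#' @export
lfp_session <- function(signals, fs_Hz, channel_map,
                        excluded_wires = integer(0)) {
  signals <- as.matrix(signals)
  if (nrow(channel_map) != nrow(signals))
    stop("channel_map must have one row per wire")
  if (fs_Hz <= 0) stop("fs_Hz must be > 0")
  structure(list(signals = signals, fs_Hz = fs_Hz,
                 channel_map = channel_map,
                 excluded_wires = as.integer(excluded_wires),
                 duration_s = ncol(signals) / fs_Hz,
                 ground_truth = NULL),
            class = "lfp_session")
}

#' Low-pass filter and downsample a wideband series to the LFP rate
#'
#' Applies a zero-phase (forward-backward) 8th-order Butterworth low-pass
#' at 500 Hz, then downsamples. For integer rate ratios the filtered
#' series is subsampled directly; otherwise polyphase resampling is used
#' and a warning is issued.
#'
#' @param x Numeric series (one wire).
#' @param fs_in Input sampling rate (Hz).
#' @param fs_out Output rate (default 2000 Hz); must exceed 1000 Hz so
#'   the 500 Hz corner stays below the output Nyquist.
#' @param corner_Hz Low-pass corner (default 500 Hz).
#' @return Series of length `ceiling(length(x) * fs_out / fs_in)`.
#' @export
decimate_lfp <- function(x, fs_in, fs_out = 2000, corner_Hz = 500) {
  if (fs_in < fs_out) stop("fs_in must be >= fs_out")
  if (fs_out <= 2 * corner_Hz)
    stop("fs_out must exceed twice the filter corner ",
         "(corner below output Nyquist)")
  bf <- signal::butter(8, corner_Hz / (fs_in / 2), type = "low")
  y <- signal::filtfilt(bf, x)
  if (fs_in == fs_out) return(y)
  fac <- fs_in / fs_out
  if (abs(fac - round(fac)) < 1e-9) {
    y[seq(1, length(y), by = round(fac))]
  } else {
    warning("non-integer decimation factor; using polyphase resampling")
    r <- rational_approx(fs_out / fs_in)
    out <- signal::resample(y, r$p, r$q)
    out[seq_len(ceiling(length(x) * fs_out / fs_in))]
  }
}

rational_approx <- function(x, max_den = 1000) {
  best <- c(1, 1); err <- Inf
  for (q in 1:max_den) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (err < 1e-12) break
  }
  list(p = best[1], q = best[2])
}

#' Bipolar derivations from all unique wire pairs within structures
#'
#' Computes difference series `wire_i - wire_j` (lower id minus higher
#' id) for every unordered pair of included wires within each
#' structure/hemisphere, suppressing signals common to both wires and
#' emphasising local sources. Structures with fewer than two included
#' wires are flagged unusable and contribute no pairs.
#'
#' @param session An `lfp_session`.
#' @return Object of class `bipolar_set`: list with `pairs`
#'   (data.frame: structure, hemisphere, wire_i, wire_j), `signals`
#'   (pairs x samples matrix), `fs_Hz`, and `unusable` (structure keys
#'   with < 2 included wires).
#' @export
make_bipolar_pairs <- function(session) {
  stopifnot(inherits(session, "lfp_session"))
  cm <- session$channel_map
  included <- !(cm$wire_id %in% session$excluded_wires)
  keys <- unique(cm[, c("structure", "hemisphere")])
  meta <- list(); rows <- list(); unusable <- character(0)
  for (i in seq_len(nrow(keys))) {
    sel <- which(cm$structure == keys$structure[i] &
                 cm$hemisphere == keys$hemisphere[i] & included)
    if (length(sel) < 2) {
      unusable <- c(unusable,
                    paste(keys$structure[i], keys$hemisphere[i], sep = "/"))
      next
    }
    ids <- sort(cm$wire_id[sel])
    cb <- utils::combn(ids, 2)
    for (j in seq_len(ncol(cb))) {
      ri <- which(cm$wire_id == cb[1, j])
      rj <- which(cm$wire_id == cb[2, j])
      meta[[length(meta) + 1]] <- data.frame(
        structure = keys$structure[i], hemisphere = keys$hemisphere[i],
        wire_i = cb[1, j], wire_j = cb[2, j], stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- session$signals[ri, ] - session$signals[rj, ]
    }
  }
  pairs <- if (length(meta)) do.call(rbind, meta) else
    data.frame(structure = character(0), hemisphere = character(0),
               wire_i = integer(0), wire_j = integer(0))
  signals <- if (length(rows)) do.call(rbind, rows) else
    matrix(0, 0, ncol(session$signals))
  structure(list(pairs = pairs, signals = signals, fs_Hz = session$fs_Hz,
                 unusable = unusable),
            class = "bipolar_set")
}

#' Automated exclusion of noisy or dead channels
#'
#' Reproducible surrogate for visual-inspection channel rejection:
#' flat-line wires (standard deviation below `flat_eps` microvolts) and
#' broadband-RMS outliers (RMS above `outlier_k` times the median RMS of
#' the same structure/hemisphere) are excluded.
#'
#' @param session An `lfp_session`.
#' @param flat_eps Flat-line threshold in microvolts (default 0.1).
#' @param outlier_k RMS outlier multiplier (default 5).
#' @return The session with `excluded_wires` extended and an
#'   `exclusion_log` data.frame (wire_id, reason) attached.
#' @export
exclude_noisy_channels <- function(session, flat_eps = 0.1, outlier_k = 5) {
  stopifnot(inherits(session, "lfp_session"))
  cm <- session$channel_map
  sds <- apply(session$signals, 1, stats::sd)
  rms <- sqrt(rowMeans(session$signals^2))
  log <- list()
  excl <- session$excluded_wires
  flat <- which(sds < flat_eps)
  for (w in flat)
    log[[length(log) + 1]] <- data.frame(wire_id = cm$wire_id[w],
                                         reason = "flat_line")
  excl <- union(excl, cm$wire_id[flat])
  keys <- unique(cm[, c("structure", "hemisphere")])
  for (i in seq_len(nrow(keys))) {
    sel <- which(cm$structure == keys$structure[i] &
                 cm$hemisphere == keys$hemisphere[i])
    ok <- sel[!(cm$wire_id[sel] %in% excl)]
    if (!length(ok)) next
    med <- stats::median(rms[ok])
    out <- ok[rms[ok] > outlier_k * med]
    for (w in out)
      log[[length(log) + 1]] <- data.frame(wire_id = cm$wire_id[w],
                                           reason = "rms_outlier")
    excl <- union(excl, cm$wire_id[out])
  }
  session$excluded_wires <- sort(excl)
  session$exclusion_log <- if (length(log)) do.call(rbind, log) else
    data.frame(wire_id = integer(0), reason = character(0))
  # flag structures left without usable wires
  usable <- !(cm$wire_id %in% session$excluded_wires)
  bad <- c()
  for (i in seq_len(nrow(keys))) {
    k <- sum(usable & cm$structure == keys$structure[i] &
             cm$hemisphere == keys$hemisphere[i])
    if (k < 2)
      bad <- c(bad, paste(keys$structure[i], keys$hemisphere[i], sep = "/"))
  }
  session$unusable_structures <- bad
  session
}
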
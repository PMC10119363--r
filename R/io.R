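# File-format entry points: pose-estimation keypoint CSV (3-row header
# dialect), AIM score CSV, and flat-binary wideband recordings with a
# YAML channel map.

#' Read a pose-estimation keypoint CSV
#'
#' Reads the common 3-row-header dialect (scorer / bodyparts /
#' coords{x,y,likelihood}) into the wide `<part>_x`, `<part>_y`,
#' `<part>_likelihood` layout used by [derive_pose()].
#'
#' @param path CSV file path.
#' @param calibration_cm_per_px Multiplies coordinates to convert pixel
#'   units to cm (default 1: file already in cm).
#' @return data.frame with a `frame` column plus per-part columns.
#' @export
read_keypoints <- function(path, calibration_cm_per_px = 1) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         stringsAsFactors = FALSE)
  body <- utils::read.csv(path, header = FALSE, skip = 3,
                          stringsAsFactors = FALSE)
  parts <- as.character(unlist(hdr[2, -1]))
  coords <- as.character(unlist(hdr[3, -1]))
  out <- data.frame(frame = as.integer(body[[1]]))
  for (j in seq_along(parts)) {
    col <- paste0(parts[j], "_", coords[j])
    v <- as.numeric(body[[j + 1]])
    if (coords[j] %in% c("x", "y")) v <- v * calibration_cm_per_px
    out[[col]] <- v
  }
  out
}

#' Write a keypoint table in the 3-row-header CSV dialect
#'
#' @param keypoints Wide keypoint table (see [generate_trajectory()]).
#' @param path Output CSV path.
#' @param scorer Scorer label for the first header row.
#' @export
write_keypoints <- function(keypoints, path, scorer = "synthetic") {
  cols <- setdiff(names(keypoints), "frame")
  parts <- sub("_(x|y|likelihood)$", "", cols)
  coords <- sub("^.*_(x|y|likelihood)$", "\\1", cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("scorer", rep(scorer, length(cols))), collapse = ","),
             con)
  writeLines(paste(c("bodyparts", parts), collapse = ","), con)
  writeLines(paste(c("coords", coords), collapse = ","), con)
  utils::write.table(keypoints[, c("frame", cols)], con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
}

#' Read / write AIM score sheets
#'
#' Tidy CSV with columns period_min, subtype, severity, amplitude.
#'
#' @param path CSV file path.
#' @export
read_aim_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("period_min", "subtype", "severity", "amplitude")
  if (!all(req %in% names(df)))
    stop("AIM CSV must have columns: ", paste(req, collapse = ", "))
  df
}

#' @rdname read_aim_csv
#' @param sheet AIM data.frame to write.
#' @export
write_aim_csv <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE)
}

#' Read a flat-binary multi-wire recording
#'
#' Interleaved int16 samples (wire-major within each frame, the common
#' acquisition layout) scaled by a gain in microvolts per bit, with the
#' channel map supplied either as a data.frame or as a YAML file with
#' fields `fs_Hz`, `gain_uV_per_bit`, and a `wires` list of
#' {wire_id, structure, hemisphere, bundle}.
#'
#' @param path Binary file path.
#' @param channel_map A [channel_map()] data.frame, or the path of a
#'   YAML config describing it (requires the yaml package).
#' @param fs_Hz Sampling rate; taken from the YAML config when omitted.
#' @param gain_uV_per_bit Microvolts per integer unit; from YAML when
#'   omitted.
#' @return An `lfp_session`.
#' @export
read_lfp_binary <- function(path, channel_map, fs_Hz = NULL,
                            gain_uV_per_bit = NULL) {
  if (is.character(channel_map)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML channel map requires the yaml package")
    cfg <- yaml::read_yaml(channel_map)
    fs_Hz <- fs_Hz %||% cfg$fs_Hz
    gain_uV_per_bit <- gain_uV_per_bit %||% cfg$gain_uV_per_bit
    wires <- do.call(rbind, lapply(cfg$wires, as.data.frame))
    channel_map <- channel_map(wires$wire_id, wires$structure,
                               wires$hemisphere %||% "lesioned",
                               wires$bundle)
  }
  if (is.null(fs_Hz) || is.null(gain_uV_per_bit))
    stop("fs_Hz and gain_uV_per_bit must be given (directly or via YAML)")
  nw <- nrow(channel_map)
  raw <- readBin(path, "integer", n = file.size(path) / 2, size = 2,
                 signed = TRUE, endian = "little")
  ns <- floor(length(raw) / nw)
  sig <- matrix(raw[seq_len(nw * ns)], nrow = nw) * gain_uV_per_bit
  lfp_session(sig, fs_Hz, channel_map)
}
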
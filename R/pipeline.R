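#' Run the spectral + detection stages on a session
#'
#' Convenience wrapper: bipolar derivation, fractal-normalized structure
#' spectrograms, and band-specific oscillation detection, giving one
#' detection table per structure/hemisphere.
#'
#' @param session An `lfp_session`.
#' @param band A [band_config()] or band name.
#' @param ... Passed to [structure_spectrograms()].
#' @return List with `spectrograms` (named list of grids) and
#'   `detections` (named list of [detect_oscillations()] tables).
#' @export
detect_session <- function(session, band = "NBG", ...) {
  if (is.character(band)) band <- band_config(band)
  specs <- structure_spectrograms(session, ...)
  dets <- lapply(specs, detect_oscillations, band = band)
  list(spectrograms = specs, detections = dets)
}
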
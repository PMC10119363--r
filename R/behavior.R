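#' Body parts expected in a keypoint table
#' @export
keypoint_parts <- function() {
  c("nose", "left_ear", "right_ear", "head_top", "body_center",
    "tail_base", "tail_tip")
}

#' Derive centroid, front and heading from a keypoint table
#'
#' Frames in which any body part has likelihood at or below
#' `likelihood_min` are excluded. For retained frames, the centroid is
#' the mean of all 7 body parts, the front is the mean of nose, both
#' ears and head top, and the heading is the direction of the line from
#' tail base towards the front, in degrees in [0, 360)
#' (counter-clockwise, 0 = +x).
#'
#' @param keypoints data.frame with `<part>_x`, `<part>_y`,
#'   `<part>_likelihood` columns (cm) for the parts in
#'   [keypoint_parts()].
#' @param likelihood_min Acceptance threshold (default 0.9, exclusive).
#' @param fps Frames per second (default 25).
#' @return Object of class `trajectory_record`: list with `frames`
#'   (retained frame indices, 1-based), `centroid_x`, `centroid_y`,
#'   `front_x`, `front_y`, `heading_deg` (NA at excluded frames; all
#'   vectors are full length), `n_excluded`, `fps`.
#' @export
derive_pose <- function(keypoints, likelihood_min = 0.9, fps = 25) {
  parts <- keypoint_parts()
  need <- c(paste0(parts, "_x"), paste0(parts, "_y"),
            paste0(parts, "_likelihood"))
  if (!all(need %in% names(keypoints)))
    stop("keypoint table must contain x/y/likelihood for all 7 body parts")
  n <- nrow(keypoints)
  lik <- sapply(parts, function(p) keypoints[[paste0(p, "_likelihood")]])
  ok <- rowSums(lik > likelihood_min) == length(parts)
  if (!any(ok)) stop("all frames excluded by the likelihood filter")
  if (mean(!ok) > 0.5)
    warning("more than 50% of frames excluded by the likelihood filter")
  xs <- sapply(parts, function(p) keypoints[[paste0(p, "_x")]])
  ys <- sapply(parts, function(p) keypoints[[paste0(p, "_y")]])
  centroid_x <- rowMeans(xs); centroid_y <- rowMeans(ys)
  fr <- c("nose", "left_ear", "right_ear", "head_top")
  front_x <- rowMeans(xs[, fr, drop = FALSE])
  front_y <- rowMeans(ys[, fr, drop = FALSE])
  heading <- atan2(front_y - ys[, "tail_base"],
                   front_x - xs[, "tail_base"]) * 180 / pi
  heading <- heading %% 360
  centroid_x[!ok] <- NA; centroid_y[!ok] <- NA
  front_x[!ok] <- NA; front_y[!ok] <- NA
  heading[!ok] <- NA
  structure(list(frames = which(ok), centroid_x = centroid_x,
                 centroid_y = centroid_y, front_x = front_x,
                 front_y = front_y, heading_deg = heading,
                 n_excluded = sum(!ok), fps = fps),
            class = "trajectory_record")
}

# Signed sector steps between consecutive sector indices (8 sectors of
# 45 deg); jumps of more than one sector count each skipped sector.
sector_steps <- function(sectors) {
  d <- diff(sectors)
  ((d + 4) %% 8) - 4
}

#' Count full 360-degree turns from a heading series
#'
#' The heading is binned into 8 absolute sectors of 45 degrees. A full
#' turn is a traversal of all 8 sectors in a consistent rotational
#' sense: an online counter accumulates same-direction sector
#' transitions (multi-sector jumps within one frame count each crossed
#' sector) and declares a turn at 8 accumulated transitions. A reversal
#' resets the count, with the current sector starting the next count.
#' Counter-clockwise turns are contralateral by default convention,
#' clockwise ipsilateral (swap via `contralateral`). Gaps (NA headings)
#' longer than `gap_reset_s` reset the running count; shorter gaps are
#' bridged.
#'
#' @param heading_deg Heading series in degrees (NA = excluded frame).
#' @param fps Frames per second.
#' @param contralateral "ccw" (default) or "cw": which image-coordinate
#'   rotation sense is contralateral to the lesion.
#' @param gap_reset_s Gap duration that resets the sector count
#'   (default 1 s).
#' @return data.frame of turn events: `direction` ("contralateral" /
#'   "ipsilateral"), `start_frame`, `end_frame` (1-based indices).
#' @export
count_full_turns <- function(heading_deg, fps = 25, contralateral = "ccw",
                             gap_reset_s = 1) {
  idx <- which(is.finite(heading_deg))
  events <- list()
  if (length(idx) >= 2) {
    sec <- floor((heading_deg[idx] %% 360) / 45)
    run <- 0L            # signed accumulated steps in the current sense
    run_start <- idx[1]  # frame where the current candidate turn began
    max_gap <- round(gap_reset_s * fps)
    for (k in 2:length(idx)) {
      if (idx[k] - idx[k - 1] > max_gap) {
        run <- 0L; run_start <- idx[k]
        next
      }
      s <- sector_steps(sec[(k - 1):k])
      if (s == 0) next
      if (run == 0L || sign(s) == sign(run)) {
        run <- run + s
      } else {
        # reversal: discard the incomplete rotation; the last angle of
        # the discarded rotation starts the next count
        run <- s
        run_start <- idx[k - 1]
      }
      while (abs(run) >= 8L) {
        dir <- if (run > 0) "ccw" else "cw"
        events[[length(events) + 1]] <- data.frame(
          sense = dir, start_frame = run_start, end_frame = idx[k],
          stringsAsFactors = FALSE)
        run <- run - sign(run) * 8L
        run_start <- idx[k]
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(sense = character(0), start_frame = integer(0),
               end_frame = integer(0))
  contra <- match.arg(contralateral, c("ccw", "cw"))
  ev$direction <- ifelse(ev$sense == contra, "contralateral", "ipsilateral")
  ev[, c("direction", "start_frame", "end_frame")]
}

#' Distance and duration of each full turn
#'
#' Distance is the summed frame-to-frame centroid displacement inside
#' the turn's frame range (missing frames contribute the available
#' segments and are flagged); duration is the frame span over fps.
#'
#' @param turns Output of [count_full_turns()].
#' @param centroid_x,centroid_y Centroid series in cm (NA allowed).
#' @param fps Frames per second.
#' @return `turns` with added `distance_cm`, `duration_s`,
#'   `has_gaps` columns.
#' @export
turn_metrics <- function(turns, centroid_x, centroid_y, fps = 25) {
  n <- nrow(turns)
  turns$distance_cm <- NA_real_
  turns$duration_s <- NA_real_
  turns$has_gaps <- FALSE
  for (i in seq_len(n)) {
    rng <- turns$start_frame[i]:turns$end_frame[i]
    x <- centroid_x[rng]; y <- centroid_y[rng]
    ok <- is.finite(x) & is.finite(y)
    turns$has_gaps[i] <- any(!ok)
    xs <- x[ok]; ys <- y[ok]
    turns$distance_cm[i] <- if (length(xs) >= 2)
      sum(sqrt(diff(xs)^2 + diff(ys)^2)) else 0
    turns$duration_s[i] <- (turns$end_frame[i] - turns$start_frame[i]) / fps
  }
  turns
}

#' Fraction of arena area visited per minute
#'
#' The arena circle is divided into 1 x 1 cm squares (those whose center
#' lies inside the circle); per 1-min bin, the fraction is the number of
#' distinct squares visited by the centroid over the total.
#'
#' @param centroid_x,centroid_y Centroid series in cm, origin at the
#'   arena bounding-box corner (arena center at diameter/2).
#' @param fps Frames per second.
#' @param arena_diameter_cm Arena diameter (default 55).
#' @param bin_s Bin length in seconds (default 60).
#' @return data.frame: `bin_start_s`, `n_squares`, `fraction`.
#' @export
occupancy_fraction <- function(centroid_x, centroid_y, fps = 25,
                               arena_diameter_cm = 55, bin_s = 60) {
  R <- arena_diameter_cm / 2
  ncell <- ceiling(arena_diameter_cm)
  centers <- seq_len(ncell) - 0.5
  inside <- outer(centers - R, centers - R,
                  function(a, b) a^2 + b^2 < R^2)
  total <- sum(inside)
  n <- length(centroid_x)
  nbin <- max(1, floor(n / (bin_s * fps)))
  out <- lapply(seq_len(nbin), function(k) {
    i0 <- (k - 1) * bin_s * fps + 1
    i1 <- min(n, k * bin_s * fps)
    x <- centroid_x[i0:i1]; y <- centroid_y[i0:i1]
    ok <- is.finite(x) & is.finite(y)
    cellx <- pmin(pmax(floor(x[ok]) + 1, 1), ncell)
    celly <- pmin(pmax(floor(y[ok]) + 1, 1), ncell)
    visited <- unique(cellx + (celly - 1) * ncell)
    data.frame(bin_start_s = (k - 1) * bin_s, n_squares = length(visited),
               fraction = length(visited) / total)
  })
  res <- do.call(rbind, out)
  attr(res, "total_squares") <- total
  res
}

#' Number of 1 x 1 cm squares inside the arena circle
#' @param arena_diameter_cm Arena diameter (default 55).
#' @export
arena_total_squares <- function(arena_diameter_cm = 55) {
  attr(occupancy_fraction(numeric(0), numeric(0), fps = 25,
                          arena_diameter_cm = arena_diameter_cm),
       "total_squares")
}

#' Centroid speed over a sliding 1-s window
#'
#' Per frame, the displacement of the body centroid between the window
#' endpoints `window_s` apart, divided by the window length. Frames
#' whose window spans a gap are NA.
#'
#' @param centroid_x,centroid_y Centroid series in cm.
#' @param fps Frames per second.
#' @param window_s Window length in seconds (default 1).
#' @return Speed series in cm/s, length `n - window_s*fps` + trailing
#'   NAs to keep full length.
#' @export
compute_speed <- function(centroid_x, centroid_y, fps = 25, window_s = 1) {
  n <- length(centroid_x)
  w <- round(window_s * fps)
  if (n <= w) stop("need more than one window of data")
  sp <- rep(NA_real_, n)
  i <- seq_len(n - w)
  dx <- centroid_x[i + w] - centroid_x[i]
  dy <- centroid_y[i + w] - centroid_y[i]
  sp[i] <- sqrt(dx^2 + dy^2) / window_s
  sp
}

#' Composite, global, total and peak AIM scores
#'
#' Per monitoring period and AIM subtype (axial, limb, orolingual), the
#' composite score is severity x amplitude (each 0-4, so composite
#' 0-16); the global score per period is the sum over subtypes (0-48);
#' the session total sums globals over all periods; the peak score sums
#' globals over the treatment's peak-dyskinesia window.
#'
#' @param sheet Tidy data.frame (period_min, subtype, severity,
#'   amplitude), as from [generate_aim_series()] or [read_aim_csv()].
#' @param treatment Optional treatment name selecting the peak window
#'   (see [peak_window()]).
#' @return List: `periods` (data.frame period_min, axial, limb,
#'   orolingual composites, global), `session_total`, `peak_score`
#'   (NA without `treatment`), `peak_window_min`.
#' @export
score_aims <- function(sheet, treatment = NULL) {
  req <- c("period_min", "subtype", "severity", "amplitude")
  stopifnot(all(req %in% names(sheet)))
  if (any(sheet$severity != round(sheet$severity) |
          sheet$severity < 0 | sheet$severity > 4 |
          sheet$amplitude != round(sheet$amplitude) |
          sheet$amplitude < 0 | sheet$amplitude > 4))
    stop("severity and amplitude must be integers in 0-4")
  sheet$composite <- sheet$severity * sheet$amplitude
  periods <- sort(unique(sheet$period_min))
  wide <- data.frame(period_min = periods)
  for (s in unique(sheet$subtype)) {
    sub <- sheet[sheet$subtype == s, ]
    wide[[s]] <- sub$composite[match(periods, sub$period_min)]
  }
  comp_cols <- setdiff(names(wide), "period_min")
  wide$global <- rowSums(wide[, comp_cols, drop = FALSE])
  pw <- NULL; peak <- NA_real_
  if (!is.null(treatment)) {
    pw <- peak_window(treatment)
    inw <- wide$period_min >= pw[1] & wide$period_min <= pw[2]
    peak <- sum(wide$global[inw])
  }
  list(periods = wide, session_total = sum(wide$global),
       peak_score = peak, peak_window_min = pw)
}
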
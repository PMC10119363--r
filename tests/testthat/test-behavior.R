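# Pose derivation, turn counting, locomotion metrics, AIM scoring.

template_keypoints <- function(heading_deg = 0, n = 10, cx = 27.5,
                               cy = 27.5, likelihood = 0.99) {
  tmpl <- lfposc:::rat_template()
  th <- heading_deg * pi / 180
  kp <- data.frame(frame = seq_len(n) - 1)
  for (i in seq_len(nrow(tmpl))) {
    kp[[paste0(tmpl$part[i], "_x")]] <-
      rep(cx + tmpl$x[i] * cos(th) - tmpl$y[i] * sin(th), n)
    kp[[paste0(tmpl$part[i], "_y")]] <-
      rep(cy + tmpl$x[i] * sin(th) + tmpl$y[i] * cos(th), n)
    kp[[paste0(tmpl$part[i], "_likelihood")]] <- rep(likelihood, n)
  }
  kp
}

test_that("pose derivation recovers heading from the rigid template", {
  pose0 <- derive_pose(template_keypoints(0))
  expect_equal(unique(round(pose0$heading_deg, 6)) %% 360, 0)
  pose90 <- derive_pose(template_keypoints(90))
  expect_equal(unique(round(pose90$heading_deg, 6)), 90)
  # rigid rotation by theta shifts heading by theta (mod 360)
  for (th in c(37, 185, 290)) {
    p <- derive_pose(template_keypoints(th))
    expect_equal(unique(round(p$heading_deg, 6)) %% 360, th)
  }
  # likelihood filter: all at 0.5 -> error
  expect_error(derive_pose(template_keypoints(likelihood = 0.5)),
               "all frames excluded|excluded")
})

test_that("full-turn counting follows the 8-sector rule", {
  # monotone 0 -> 720: two turns one way, none the other
  h <- seq(0, 720, by = 5) %% 360
  tu <- count_full_turns(h, 25)
  expect_equal(sum(tu$direction == "contralateral"), 2)
  expect_equal(sum(tu$direction == "ipsilateral"), 0)
  # reversal before the 8th sector: no turns
  hr <- c(seq(0, 315, by = 5), seq(315, 0, by = -5))
  expect_equal(nrow(count_full_turns(hr, 25)), 0)
  # oscillation within +/- 90 degrees: never passes all 8 sectors
  t <- seq(0, 60, by = 1 / 25)
  hw <- (180 + 90 * sin(2 * pi * 0.2 * t)) %% 360
  expect_equal(nrow(count_full_turns(hw, 25)), 0)
  # sector skipping: 90 deg per frame still counts the crossed sectors
  hj <- seq(0, 1440, by = 90) %% 360
  tj <- count_full_turns(hj, 25)
  expect_equal(sum(tj$direction == "contralateral"), 4)
})

test_that("reversing the heading sign swaps rotational senses", {
  for (seed in 1:20) {
    h <- random_heading_series(seed)
    a <- count_full_turns(h, 25)
    b <- count_full_turns((-h) %% 360, 25)
    expect_equal(sum(a$direction == "contralateral"),
                 sum(b$direction == "ipsilateral"))
    expect_equal(sum(a$direction == "ipsilateral"),
                 sum(b$direction == "contralateral"))
  }
})

test_that("online counter matches the batch monotone-run oracle", {
  for (seed in 1:50) {
    h <- random_heading_series(seed)
    tu <- count_full_turns(h, 25, gap_reset_s = Inf)
    orc <- oracle_turn_count(h)
    expect_equal(sum(tu$direction == "contralateral"), orc$ccw,
                 info = paste("seed", seed))
    expect_equal(sum(tu$direction == "ipsilateral"), orc$cw,
                 info = paste("seed", seed))
  }
})

test_that("gaps longer than one second reset the turn count", {
  h <- seq(0, 355, by = 5)            # almost one full turn...
  h2 <- c(h, rep(NA, 30), seq(0, 40, by = 5))  # ...interrupted by 1.2 s gap
  expect_equal(nrow(count_full_turns(h2, 25)), 0)
  # a short gap is bridged
  h3 <- c(h, rep(NA, 5), seq(0, 40, by = 5))
  expect_equal(nrow(count_full_turns(h3, 25)), 1)
})

test_that("turn metrics measure path length and duration", {
  # centroid on a 10 cm circle, heading completing one turn in 10 s
  fps <- 25
  t <- seq(0, 10, by = 1 / fps)
  cx <- 27.5 + 10 * cos(2 * pi * t / 10)
  cy <- 27.5 + 10 * sin(2 * pi * t / 10)
  h <- (360 * t / 10) %% 360
  tu <- count_full_turns(h, fps)
  expect_equal(nrow(tu), 1)
  tm <- turn_metrics(tu, cx, cy, fps)
  expect_equal(tm$distance_cm, 2 * pi * 10, tolerance = 0.02)
  expect_equal(tm$duration_s, 10, tolerance = 0.05)
  # stationary centroid, rotating heading: distance ~ 0
  tm0 <- turn_metrics(tu, rep(10, length(t)), rep(10, length(t)), fps)
  expect_equal(tm0$distance_cm, 0)
})

test_that("occupancy fraction counts distinct squares inside the circle", {
  # enumeration oracle for the 55-cm arena denominator
  centers <- seq_len(55) - 0.5
  oracle_total <- sum(outer((centers - 27.5)^2, (centers - 27.5)^2,
                            "+") < 27.5^2)
  expect_equal(arena_total_squares(55), oracle_total)
  # stationary animal: exactly one square per bin
  occ <- occupancy_fraction(rep(10.5, 25 * 120), rep(10.5, 25 * 120), 25)
  expect_equal(nrow(occ), 2)
  expect_true(all(occ$n_squares == 1))
  expect_equal(occ$fraction, rep(1 / oracle_total, 2))
  # superset path visits at least as many squares
  set.seed(3)
  x <- 27.5 + cumsum(rnorm(25 * 60, 0, 0.5))
  y <- 27.5 + cumsum(rnorm(25 * 60, 0, 0.5))
  half <- occupancy_fraction(c(x[1:750], rep(x[750], 750)),
                             c(y[1:750], rep(y[750], 750)), 25)
  full <- occupancy_fraction(x, y, 25)
  expect_gte(full$fraction, half$fraction)
})

test_that("speed is displacement over a sliding 1-s window", {
  fps <- 25
  # uniform linear motion at 5 cm/s
  x <- 5 * seq(0, 20, by = 1 / fps)
  sp <- compute_speed(x, rep(0, length(x)), fps)
  expect_true(all(abs(sp[is.finite(sp)] - 5) < 1e-9))
  # stationary
  sp0 <- compute_speed(rep(3, 100), rep(4, 100), fps)
  expect_true(all(sp0[is.finite(sp0)] == 0))
  # circular motion: chord formula 2 r sin(pi / T)
  r <- 10; T <- 8
  t <- seq(0, 40, by = 1 / fps)
  spc <- compute_speed(r * cos(2 * pi * t / T), r * sin(2 * pi * t / T),
                       fps)
  expect_equal(mean(spc, na.rm = TRUE), 2 * r * sin(pi / T),
               tolerance = 0.01)
})

test_that("AIM scoring composes severity x amplitude into global scores", {
  sched <- c(5, 10)
  sheet <- generate_aim_series(
    sched,
    list(axial = 2, limb = 3, orolingual = 1),
    list(axial = 2, limb = 2, orolingual = 1))
  sc <- score_aims(sheet)
  expect_equal(sc$periods$axial, c(4, 4))
  expect_equal(sc$periods$limb, c(6, 6))
  expect_equal(sc$periods$orolingual, c(1, 1))
  expect_equal(sc$periods$global, c(11, 11))
  expect_equal(sc$session_total, 22)
  # peak window selection
  full <- generate_aim_series(aim_schedule(180),
                              list(axial = 4, limb = 4, orolingual = 4),
                              list(axial = 4, limb = 4, orolingual = 4))
  skf <- score_aims(full, "SKF82958")
  expect_equal(skf$peak_window_min, c(20, 60))
  # periods at 20, 30, 40, 50, 60 -> 5 periods x 48
  expect_equal(skf$peak_score, 5 * 48)
  bad <- sheet; bad$severity[1] <- 7
  expect_error(score_aims(bad), "0-4")
})

test_that("keypoint and AIM CSV round trips preserve the tables", {
  dir <- withr::local_tempdir()
  tr <- generate_trajectory(trajectory_spec(20, 4, seed = 5))
  f <- file.path(dir, "kp.csv")
  write_keypoints(tr$keypoints, f)
  back <- read_keypoints(f)
  expect_equal(names(back), names(tr$keypoints))
  expect_equal(back$nose_x, tr$keypoints$nose_x, tolerance = 1e-6)
  # pose pipeline runs identically on the round-tripped table
  expect_equal(derive_pose(back)$heading_deg,
               derive_pose(tr$keypoints)$heading_deg, tolerance = 1e-6)
  sheet <- generate_aim_series(c(5, 10), list(axial = 2), list(axial = 3))
  fa <- file.path(dir, "aims.csv")
  write_aim_csv(sheet, fa)
  expect_equal(read_aim_csv(fa), sheet)
})
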
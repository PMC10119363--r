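# Synthetic-data generator: spectral fidelity, ground truth, determinism.

test_that("fractal generator realizes the requested power-law slope", {
  fit_slope <- function(chi, seed) {
    x <- generate_fractal_series(fractal_spec(chi), 2^16, 2000, seed)
    p <- lfposc:::periodogram_psd(x, 2000)
    sel <- p$freqs >= 2 & p$freqs <= 200
    unname(coef(lm(log10(p$psd[sel]) ~ log10(p$freqs[sel])))[2])
  }
  expect_lt(abs(fit_slope(1, 11) - (-1)), 0.1)
  expect_lt(abs(fit_slope(2, 12) - (-2)), 0.1)
  expect_lt(abs(fit_slope(0, 13) - 0), 0.1)
  # variance control and degenerate scale
  x <- generate_fractal_series(fractal_spec(1, scale = 25), 2^16, 2000, 14)
  expect_lt(abs(var(x) - 25) / 25, 0.25)
  expect_identical(generate_fractal_series(fractal_spec(1, scale = 0),
                                           2^13, 2000, 1),
                   numeric(2^13))
  expect_error(fractal_spec(-1), "exponent_chi")
  expect_error(fractal_spec(1, fmin_Hz = 10, fmax_Hz = 5), "fmin")
})

test_that("generators are deterministic given a seed", {
  a <- generate_fractal_series(fractal_spec(1), 2^13, 2000, 42)
  b <- generate_fractal_series(fractal_spec(1), 2^13, 2000, 42)
  expect_identical(a, b)
  o1 <- generate_oscillation(osc_burst_spec("NBG", 90, 5), 2^13, 2000, 7)
  o2 <- generate_oscillation(osc_burst_spec("NBG", 90, 5), 2^13, 2000, 7)
  expect_identical(o1, o2)
  sp <- session_spec(10, data.frame(name = "M1FL", n_wires = 2),
                     fractal_spec(1, 100), seed = 5)
  expect_identical(generate_session(sp)$signals,
                   generate_session(sp)$signals)
})

test_that("oscillation generator puts its spectral peak at the center", {
  argmax_welch <- function(center, width, seed) {
    x <- generate_oscillation(osc_burst_spec(
      if (center > 50) "NBG" else "theta", center, width, amplitude = 2),
      2000 * 64, 2000, seed)
    g <- welch_spectrogram(x, 2000)
    g$freqs_Hz[which.max(rowMeans(g$psd))]
  }
  expect_lt(abs(argmax_welch(90, 5, 3) - 90), 2)
  # theta at its typical dyskinesia-session mean frequency
  expect_lt(abs(argmax_welch(6.8, 1.2, 4) - 6.8), 1)
  # envelope identically zero -> silence
  z <- generate_oscillation(osc_burst_spec("NBG", 90, 5,
                                           envelope = function(t) t * 0),
                            2^13, 2000, 1)
  expect_identical(z, numeric(2^13))
  expect_error(generate_oscillation(osc_burst_spec("NBG", 90, 5),
                                    2^13, 150, 1), "Nyquist|twice")
  expect_error(osc_burst_spec("NBG", 50, 5), "outside")
})

test_that("bundle common-mode cancels exactly in bipolar derivations", {
  sp <- session_spec(12, data.frame(name = "M1FL", n_wires = 3),
                     fractal = fractal_spec(1, scale = 0),
                     common_mode_amp = 10, sensor_noise_sd = 0, seed = 3)
  ses <- generate_session(sp)
  # wires carry only the shared artifact
  expect_gt(sd(ses$signals[1, ]), 1)
  bip <- make_bipolar_pairs(ses)
  rel <- max(abs(bip$signals)) / max(abs(ses$signals))
  expect_lt(rel, 1e-6)
})

test_that("session ground truth tracks envelope and phase lags", {
  env <- function(t) as.numeric(t < 32)  # first half of a 64-s session
  src <- osc_source(osc_burst_spec("NBG", 90, 4, amplitude = 10,
                                   envelope = env),
                    data.frame(structure = c("M1FL", "DLS"),
                               phase_lag_deg = c(0, 30)))
  sp <- session_spec(64, data.frame(name = c("M1FL", "DLS"),
                                    n_wires = c(2, 2)),
                     fractal_spec(1, 100), sources = list(src), seed = 8)
  gt <- generate_session(sp)$ground_truth
  expect_equal(gt$times_s, seq(4, 60, by = 4))
  s1 <- gt$sources[[1]]
  # presence: on-half bins TRUE, off-half FALSE, boundary bin (mean 0.5)
  # not counted present
  expect_equal(s1$present, gt$times_s < 32)
  expect_equal(mean(s1$present), 0.5, tolerance = 0.07)
  expect_equal(s1$lag_pairs$delta_phi_deg, 30)
  expect_setequal(s1$structures, c("M1FL", "DLS"))
})

test_that("session spec validation enforces wires and Nyquist", {
  expect_error(session_spec(10, data.frame(name = "A", n_wires = 1),
                            fractal_spec(1)), "n_wires")
  src <- osc_source(osc_burst_spec("NBG", 110, 4),
                    data.frame(structure = "A"))
  expect_error(session_spec(10, data.frame(name = "A", n_wires = 2),
                            fractal_spec(1), sources = list(src),
                            fs_Hz = 200), "twice")
})

test_that("AIM sheets follow the monitoring schedule and score bounds", {
  expect_equal(aim_schedule(180),
               c(5, 10, 15, 20, seq(30, 180, by = 10)))
  sched <- aim_schedule(180)
  zero <- generate_aim_series(sched, list(), list())
  expect_true(all(score_aims(zero)$periods$global == 0))
  full <- generate_aim_series(sched,
                              list(axial = 4, limb = 4, orolingual = 4),
                              list(axial = 4, limb = 4, orolingual = 4))
  sc <- score_aims(full)
  expect_true(all(sc$periods$axial == 16))
  expect_true(all(sc$periods$global == 48))
  expect_error(generate_aim_series(sched, list(axial = 5), list()), "0-4")
})

test_that("trajectory ground truth counts full revolutions", {
  tr <- generate_trajectory(trajectory_spec(36, 60, seed = 2))
  expect_equal(tr$ground_truth$contralateral_turns, 6L)
  expect_equal(tr$ground_truth$ipsilateral_turns, 0L)
  expect_equal(tr$ground_truth$net_rotation_deg, 2160)
  # zero angular velocity
  tr0 <- generate_trajectory(trajectory_spec(0, 20, seed = 3))
  expect_equal(tr0$ground_truth$contralateral_turns, 0L)
  expect_true(all(abs(diff(tr0$ground_truth$heading_deg)) < 1e-9))
  # oscillating heading never completes a turn
  trw <- generate_trajectory(trajectory_spec(
    function(t) 90 * pi / 2 * cos(pi / 2 * t), 60, seed = 4))
  expect_equal(trw$ground_truth$contralateral_turns, 0L)
  expect_equal(trw$ground_truth$ipsilateral_turns, 0L)
  # positions stay inside the arena
  kp <- tr$keypoints
  for (p in keypoint_parts()) {
    r <- sqrt((kp[[paste0(p, "_x")]] - 27.5)^2 +
              (kp[[paste0(p, "_y")]] - 27.5)^2)
    expect_true(all(r <= 27.5))
  }
})
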
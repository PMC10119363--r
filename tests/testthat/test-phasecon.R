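# Hilbert phase, circular statistics, structure coupling, delays.

test_that("instantaneous phase advances at the oscillation frequency", {
  fs <- 2000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  phi <- instantaneous_phase(cos(2 * pi * 90 * t), fs)
  uw <- unwrap_deg(phi)
  slope <- (uw[length(uw)] - uw[1]) / (sum(is.finite(phi)) / fs)
  expect_equal(slope, 360 * 90, tolerance = 1e-3)
  # quarter-period shift -> constant 90 degree difference
  shift <- round(fs / 90 / 4)
  x <- cos(2 * pi * 90 * t)
  st <- pair_phase_stats(instantaneous_phase(x[-(1:shift)], fs),
                         instantaneous_phase(x[1:(length(x) - shift)], fs))
  expect_equal(st$delta_phi_deg, 90, tolerance = 1)
  expect_gt(st$r, 0.999)
})

test_that("amplitude modulation leaves the phase slope unchanged", {
  fs <- 2000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  am <- (1 + 0.5 * sin(2 * pi * 1 * t)) * cos(2 * pi * 90 * t)
  phi <- instantaneous_phase(am, fs)
  uw <- unwrap_deg(phi)
  slope <- (uw[length(uw)] - uw[1]) / (sum(is.finite(phi)) / fs)
  expect_lt(abs(slope - 360 * 90) / 360, 1)  # within 1 deg per second
})

test_that("circular statistics behave at the reference points", {
  expect_equal(circ_mean_deg(c(179, -179)), 180 - 360, tolerance = 1e-9)
  expect_equal(abs(circ_mean_deg(c(179, -179))), 180)
  expect_equal(circ_r(rep(42, 10)), 1)
  set.seed(12)
  u <- runif(1e4, -180, 180)
  expect_lt(circ_r(u), 0.03)   # E[r] ~ sqrt(pi / (4 N))
  # identical phases
  st <- pair_phase_stats(rep(30, 100), rep(30, 100))
  expect_equal(st$delta_phi_deg, 0)
  expect_equal(st$r, 1)
  expect_error(pair_phase_stats(1:5, 1:6), "mismatch")
})

test_that("an imposed 1 ms delay at 90 Hz appears as 32.4 degrees", {
  fs <- 2000
  n <- fs * 20
  x <- generate_oscillation(osc_burst_spec("NBG", 90, 2), n + 10, fs, 3)
  lagged <- x[1:n]          # earlier copy
  lead <- x[3:(n + 2)]      # 2 samples = 1 ms later
  nb_a <- bandpass_about_median(lead, fs, 90)
  nb_b <- bandpass_about_median(lagged, fs, 90)
  st <- pair_phase_stats(instantaneous_phase(nb_a, fs),
                         instantaneous_phase(nb_b, fs))
  expect_equal(st$delta_phi_deg, 360 * 90 * 0.001, tolerance = 1.5)
  expect_gt(st$r, 0.9)
})

test_that("pair statistics are antisymmetric in the pair order", {
  set.seed(13)
  phi_i <- runif(500, -180, 180)
  phi_j <- wrap180(phi_i + 40 + rnorm(500, 0, 20))
  ab <- pair_phase_stats(phi_i, phi_j)
  ba <- pair_phase_stats(phi_j, phi_i)
  expect_equal(ab$r, ba$r)
  expect_equal(wrap180(ab$delta_phi_deg + ba$delta_phi_deg), 0,
               tolerance = 1e-9)
})

test_that("structure coupling averages r and filters phase by quality", {
  pairs <- data.frame(structure_a = "M1FL", structure_b = "DLS",
                      delta_phi_deg = c(30, 120), r = c(0.9, 0.2))
  cp <- structure_coupling(pairs)
  expect_equal(cp$mean_r, 0.55)
  expect_equal(cp$mean_dphi_deg, 30)   # only the r = 0.9 pair passes
  expect_equal(cp$n_pass_filter, 1L)
  # all pairs passing
  all_in <- structure_coupling(data.frame(
    structure_a = "A", structure_b = "B",
    delta_phi_deg = c(30, 30, 30), r = c(1, 1, 1)))
  expect_equal(all_in$mean_r, 1)
  expect_equal(all_in$mean_dphi_deg, 30)
  # none passing: phase reported missing
  none <- structure_coupling(data.frame(
    structure_a = "A", structure_b = "B",
    delta_phi_deg = c(10, 20), r = c(0.3, 0.4)))
  expect_true(is.na(none$mean_dphi_deg))
})

test_that("one-sample mean-angle test rejects, retains, and abstains", {
  set.seed(14)
  tight30 <- wrap180(30 + rnorm(50, 0, 10))
  expect_true(mean_angle_test(tight30, mu0 = 0)$reject)
  tight0 <- wrap180(rnorm(50, 0, 10))
  expect_false(mean_angle_test(tight0, mu0 = 0)$reject)
  unif <- runif(50, -180, 180)
  out <- mean_angle_test(unif, mu0 = 0)
  expect_false(out$conclusive)
  expect_error(mean_angle_test(1:5), "at least 8")
})

test_that("phase-to-delay conversion", {
  expect_equal(phase_to_delay(30, 94.9), (30 / 360) / 94.9 * 1000)
  expect_equal(phase_to_delay(0, 50), 0)
  expect_equal(phase_to_delay(360, 100), 10)
  expect_error(phase_to_delay(30, 0), "f_Hz")
})

test_that("median frequency defines the passband and filtering is selective", {
  mk <- function(Bs) data.frame(bin_time_s = seq_along(Bs) * 4,
                                detected = TRUE, A = 5, B = Bs, C = 4,
                                D = 0, E = 0, R2 = 0.9)
  m <- nbg_median_frequency(list(mk(c(85, 90)), mk(95)))
  expect_equal(m, 90)
  # a 70 Hz tone through the [85, 95] band is suppressed below 5%
  fs <- 2000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x70 <- sin(2 * pi * 70 * t)
  y <- bandpass_about_median(x70, fs, 90)
  expect_lt(sd(y) / sd(x70), 0.05)
  # in-band tone passes
  x90 <- sin(2 * pi * 90 * t)
  expect_gt(sd(bandpass_about_median(x90, fs, 90)) / sd(x90), 0.95)
  none <- data.frame(bin_time_s = 4, detected = FALSE, A = NA, B = NA,
                     C = NA, D = NA, E = NA, R2 = NA)
  expect_error(nbg_median_frequency(list(none)), "no detections")
})
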
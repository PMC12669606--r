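# Level estimation and half-amplitude idealization.

test_that("noiseless square wave gives exact levels and exact events", {
  tr <- square_trace(closed = 0, open = 1, half_n = 100, n_cycles = 10)
  lev <- estimate_levels(tr)
  expect_equal(lev$closed_pA, 0)
  expect_equal(lev$open_pA, 1)
  ev <- idealize_half_amplitude(tr, lev, dead_time_s = 10 * tr$dt)
  expect_equal(sum(ev$state == "open"), 10)
  expect_true(all(ev$duration_s[ev$state == "open"] == 100 * tr$dt))
  expect_equal(ev$amplitude_pA[ev$state == "open"], rep(1, 10))
  # events tile the trace and strictly alternate
  expect_equal(sum(ev$duration_s), length(tr$current_pA) * tr$dt)
  expect_true(all(ev$state[-1] != ev$state[-nrow(ev)]))
})

test_that("channel-free traces are flagged", {
  set.seed(21)
  tr <- recording_trace(rnorm(50000, sd = 0.1), 1e-5, list(voltage_mV = 80))
  expect_error(estimate_levels(tr), class = "ionpore_no_channel")
})

test_that("levels recovered within 0.05 pA on a realistic synthetic trace", {
  m <- channel_model(conductance_pS = 18.4, e_rev_mV = 0, noise_sd_pA = 0.15)
  tr <- simulate_recording(m, 80, fast_acq(10), seed = 5)
  lev <- estimate_levels(tr)
  expect_lt(abs(lev$closed_pA - 0), 0.05)
  expect_lt(abs(lev$open_pA - 1.472), 0.05)
})

test_that("all-closed trace yields one closed event; spikes are censored", {
  lev <- list(closed_pA = 0, open_pA = 1)
  x <- rep(0, 2000)
  tr <- recording_trace(x, 1e-4, list(voltage_mV = 80))
  ev <- idealize_half_amplitude(tr, lev, dead_time_s = 10e-4)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$state, "closed")
  expect_equal(ev$duration_s, 0.2)
  # inserting sub-dead-time spikes does not change the event count
  x2 <- x; x2[c(500, 1200)] <- 1
  tr2 <- recording_trace(x2, 1e-4, list(voltage_mV = 80))
  ev2 <- idealize_half_amplitude(tr2, lev, dead_time_s = 10e-4)
  expect_equal(nrow(ev2), 1L)
  # same for a clean square wave with spikes added
  tr3 <- square_trace()
  ev3 <- idealize_half_amplitude(tr3, estimate_levels(tr3),
                                 dead_time_s = 10 * tr3$dt)
  x4 <- tr3$current_pA; x4[c(50, 1450)] <- 1 - x4[c(50, 1450)]
  tr4 <- recording_trace(x4, tr3$dt, tr3$meta)
  ev4 <- idealize_half_amplitude(tr4, estimate_levels(tr3),
                                 dead_time_s = 10 * tr3$dt)
  expect_equal(nrow(ev4), nrow(ev3))
})

test_that("dead-time configuration is validated", {
  tr <- square_trace()
  lev <- list(closed_pA = 0, open_pA = 1)
  expect_error(idealize_half_amplitude(tr, lev, dead_time_s = 1e3),
               class = "ionpore_config_error")
  expect_error(idealize_half_amplitude(tr, lev, dead_time_s = tr$dt / 2),
               class = "ionpore_config_error")
})

test_that("amplitude: duration-weighted, translation-invariant, antisymmetric", {
  tr <- square_trace(closed = 0, open = 1.47)
  lev <- estimate_levels(tr)
  ev <- idealize_half_amplitude(tr, lev, dead_time_s = 10 * tr$dt)
  expect_equal(single_channel_amplitude(ev), 1.47)
  # translation invariance
  tr_off <- recording_trace(tr$current_pA + 3.5, tr$dt, tr$meta)
  lev_off <- estimate_levels(tr_off)
  ev_off <- idealize_half_amplitude(tr_off, lev_off, dead_time_s = 10 * tr$dt)
  expect_equal(single_channel_amplitude(ev_off), 1.47, tolerance = 1e-12)
  # antisymmetry under negation
  tr_neg <- recording_trace(-tr$current_pA, tr$dt, tr$meta)
  lev_neg <- estimate_levels(tr_neg)
  ev_neg <- idealize_half_amplitude(tr_neg, lev_neg, dead_time_s = 10 * tr$dt)
  expect_equal(single_channel_amplitude(ev_neg), -1.47, tolerance = 1e-12)
  # no open events -> dedicated signal
  allc <- idealize_half_amplitude(
    recording_trace(rep(0, 1000), 1e-4, list(voltage_mV = 0)),
    list(closed_pA = 0, open_pA = 1), dead_time_s = 1e-3
  )
  expect_error(single_channel_amplitude(allc),
               class = "ionpore_no_amplitude")
})

test_that("open probability: trivial cases and Markov stationarity", {
  tr <- square_trace()
  ev <- idealize_half_amplitude(tr, estimate_levels(tr),
                                dead_time_s = 10 * tr$dt)
  expect_equal(open_probability(ev), 0.5)
  allc <- idealize_half_amplitude(
    recording_trace(rep(0, 1000), 1e-4, list(voltage_mV = 0)),
    list(closed_pA = 0, open_pA = 1), dead_time_s = 1e-3
  )
  expect_equal(open_probability(allc), 0)
  m <- channel_model(k_open_s = 50, k_close_s = 50, noise_sd_pA = 0.1)
  tr2 <- simulate_recording(m, 80, fast_acq(10), seed = 31)
  ev2 <- idealize_half_amplitude(tr2, estimate_levels(tr2))
  n_cyc <- sum(ev2$state == "open")
  expect_lt(abs(open_probability(ev2) - 0.5), 3 * sqrt(0.25 / n_cyc) + 0.02)
})

test_that("round trip recovers event count (dead-time censoring accounted) and amplitude", {
  m <- channel_model(conductance_pS = 18.4, e_rev_mV = 0, noise_sd_pA = 0.147,
                     k_open_s = 50, k_close_s = 50)
  acq <- fast_acq(10)
  dw <- simulate_gating(m, acq$duration_s, seed = 55)
  tr <- apply_lowpass(render_trace(dw, m, 80, acq, seed = 56), 800)
  ev <- idealize_half_amplitude(tr, estimate_levels(tr))
  n_true <- sum(dw$state == "open")
  # an open event survives if its dwell exceeds the dead time and is not
  # merged away; to first order the detected count is n_true * P(open dwell
  # >= tau) * P(neighbouring closed dwell >= tau)
  tau <- default_dead_time(800)
  expected <- n_true * exp(-m$k_close_s * tau) * exp(-m$k_open_s * tau)
  n_det <- sum(ev$state == "open")
  expect_lt(abs(n_det - expected) / expected, 0.1)
  expect_lt(abs(single_channel_amplitude(ev) - 1.472) / 1.472, 0.03)
  # idealization tiles the full analyzed duration
  expect_equal(sum(ev$duration_s), acq$duration_s, tolerance = 1e-9)
})
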
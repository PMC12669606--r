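# MD-style permeation accounting: crossing detection, conductance from
# charge flux, species partitioning, Poisson generator, hydration profile.

e_charge <- 1.602177e-19

test_that("hysteresis crossing detection on constructed paths", {
  up <- seq(-3, 3, length.out = 60)
  cc <- detect_crossings(ion_trajectory(up, z_low = -2, z_high = 2))
  expect_equal(nrow(cc$events), 1L)
  expect_equal(cc$events$direction, 1L)
  # oscillation inside the slab: zero events
  wob <- c(-3, rep(c(-1.5, 1.5), 20), -3)
  cc2 <- detect_crossings(ion_trajectory(wob, z_low = -2, z_high = 2))
  expect_equal(nrow(cc2$events), 0L)
  # full traversal and return: two events of opposite direction, net 0
  there_back <- c(seq(-3, 3, length.out = 40), seq(3, -3, length.out = 40))
  cc3 <- detect_crossings(ion_trajectory(there_back, z_low = -2, z_high = 2))
  expect_equal(nrow(cc3$events), 2L)
  expect_equal(sum(cc3$events$direction), 0L)
  expect_equal(sort(cc3$events$direction), c(-1L, 1L))
  # slab bounds outside the explored range
  expect_error(
    detect_crossings(ion_trajectory(seq(0, 1, 0.1), z_low = 5, z_high = 6)),
    class = "ionpore_config_error"
  )
})

test_that("detection is invariant to periodic-image shifts of a suffix", {
  set.seed(8)
  box <- 10
  z <- cumsum(rnorm(800, mean = 0.02, sd = 0.3))
  base <- detect_crossings(ion_trajectory(z, z_low = -2, z_high = 2,
                                          box_z_nm = box))
  for (k in c(1L, -2L)) {
    z2 <- z
    cut <- 400
    z2[cut:length(z2)] <- z2[cut:length(z2)] + k * box
    shifted <- detect_crossings(ion_trajectory(z2, z_low = -2, z_high = 2,
                                               box_z_nm = box))
    expect_equal(shifted$events, base$events)
  }
})

test_that("conductance from crossings: arithmetic, linearity, valence", {
  mk <- function(n_k, dir = 1L, valence = 1L, v = 100, t_ns = 1000) {
    crossing_events(
      data.frame(time_ns = seq_len(n_k), species = "K",
                 valence = valence, direction = dir),
      voltage_mV = v, duration_ns = t_ns
    )
  }
  # 9 forward K+ in 1 us at 100 mV -> 9 e / (0.1 V * 1e-6 s) = 14.4 pS
  expect_equal(conductance_from_crossings(mk(9)),
               1e12 * 9 * e_charge / (0.1 * 1e-6), tolerance = 1e-12)
  expect_equal(conductance_from_crossings(mk(9)), 14.4, tolerance = 0.02)
  # empty set -> 0
  empty <- crossing_events(
    data.frame(time_ns = numeric(0), species = character(0),
               valence = integer(0), direction = integer(0)),
    voltage_mV = 100, duration_ns = 1000
  )
  expect_equal(conductance_from_crossings(empty), 0)
  # one Ca2+ counts exactly twice one K+
  expect_equal(conductance_from_crossings(mk(1, valence = 2L)),
               2 * conductance_from_crossings(mk(1)))
  # net = forward - reverse
  mixed <- crossing_events(
    data.frame(time_ns = 1:5, species = "K", valence = 1L,
               direction = c(1L, 1L, 1L, -1L, -1L)),
    voltage_mV = 100, duration_ns = 1000
  )
  expect_equal(conductance_from_crossings(mixed),
               conductance_from_crossings(mk(1)))
  expect_error(conductance_from_crossings(
    crossing_events(mk(1)$events, voltage_mV = 0, duration_ns = 1)
  ), class = "ionpore_domain_error")
})

test_that("species fractions: charge-flux normalization", {
  # 22 K+ forward and 3 Cl- current-additive: Cl fraction = 3/25 = 12%
  ev <- crossing_events(
    data.frame(
      time_ns = 1:25,
      species = c(rep("K", 22), rep("Cl", 3)),
      valence = c(rep(1L, 22), rep(-1L, 3)),
      direction = c(rep(1L, 22), rep(-1L, 3))
    ),
    voltage_mV = 100, duration_ns = 1000
  )
  fr <- species_current_fraction(ev)
  expect_equal(fr$charge_fraction[fr$species == "Cl"], 0.12)
  expect_equal(sum(fr$charge_fraction), 1)
  one <- species_current_fraction(crossing_events(
    data.frame(time_ns = 1, species = "K", valence = 1L, direction = 1L),
    100, 1000
  ))
  expect_equal(one$charge_fraction, 1)
  empty <- crossing_events(
    data.frame(time_ns = numeric(0), species = character(0),
               valence = integer(0), direction = integer(0)), 100, 1000
  )
  expect_error(species_current_fraction(empty),
               class = "ionpore_not_assessable")
})

test_that("Poisson generator: determinism, rate, degenerate cases", {
  a <- simulate_crossing_events(15, 100, 1000, seed = 12)
  b <- simulate_crossing_events(15, 100, 1000, seed = 12)
  expect_identical(a$events, b$events)
  z <- simulate_crossing_events(0, 100, 1000, seed = 12)
  expect_equal(nrow(z$events), 0L)
  expect_error(simulate_crossing_events(-1, 100, 1000),
               class = "ionpore_domain_error")
  # expected rate: G V / e = 9.36 events per us at 15 pS, 100 mV
  lam <- 15e-12 * 0.1 / e_charge * 1e-6
  counts <- vapply(1:100, function(s) {
    nrow(simulate_crossing_events(15, 100, 1000, seed = s)$events)
  }, numeric(1))
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / 100))
  expect_equal(round(lam, 2), 9.36)
})

test_that("conductance estimator is consistent over many windows", {
  for (g in c(4, 15)) {
    for (v in c(100, 350)) {
      est <- vapply(1:200, function(s) {
        conductance_from_crossings(
          simulate_crossing_events(g, v, 1000, seed = 1000 + s)
        )
      }, numeric(1))
      se <- sd(est) / sqrt(length(est))
      expect_lt(abs(mean(est) - g), 2 * se + 1e-9)
    }
  }
})

test_that("hydration profile: uniform column, dewetting, conservation", {
  set.seed(4)
  frames <- replicate(30, runif(200, -2, 2), simplify = FALSE)
  hp <- hydration_profile(frames, -2, 2, bin_nm = 0.2)
  expect_true(hp$continuous)
  expect_equal(nrow(hp$profile), 20L)
  expect_equal(sum(hp$profile$mean_count), 200, tolerance = 1e-9)
  # a dewetted band spanning one whole bin
  frames_dw <- lapply(frames, function(z) z[z < 0 | z > 0.5])
  hp_dw <- hydration_profile(frames_dw, -2, 2, bin_nm = 0.5)
  expect_false(hp_dw$continuous)
  # doubling bin width halves bin count, conserves occupancy
  hp2 <- hydration_profile(frames, -2, 2, bin_nm = 0.4)
  expect_equal(nrow(hp2$profile), 10L)
  expect_equal(sum(hp2$profile$mean_count), sum(hp$profile$mean_count))
  expect_error(hydration_profile(list(), -2, 2),
               class = "ionpore_input_error")
  expect_error(hydration_profile(frames, -2, 2, bin_nm = 0),
               class = "ionpore_domain_error")
})
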
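# Visit segmentation, event detection and conductance arithmetic.

test_that("a monotone crossing yields one permeating efflux visit", {
  fs <- make_ion_fs(list(c(-25, -10, 0, 10, 25)))
  v <- segment_visits(fs)
  expect_equal(nrow(v), 1L)
  expect_equal(v$classification, "permeating")
  expect_equal(v$direction, "efflux")
  expect_equal(v$entry_side, "intracellular")
  expect_equal(v$exit_side, "extracellular")
  expect_equal(v$completion_time, 400)     # first frame beyond +20 A
})

test_that("a turnback yields one blocked visit on the entry side", {
  fs <- make_ion_fs(list(c(-25, -10, -5, -12, -25)))
  v <- segment_visits(fs)
  expect_equal(nrow(v), 1L)
  expect_equal(v$classification, "blocked")
  expect_equal(v$entry_side, "intracellular")
  expect_equal(v$exit_side, "intracellular")
  expect_true(is.na(v$direction))
})

test_that("truncated and laterally exiting visits are handled separately", {
  # starts inside the pore: truncated
  fs1 <- make_ion_fs(list(c(0, 5, 25, 26, 27)))
  v1 <- segment_visits(fs1)
  expect_equal(v1$classification, "blocked_incomplete")
  # leaves the ROI laterally mid-visit: blocked, flagged
  nf <- 5
  fs2 <- make_ion_fs(list(c(-25, -10, 0, 0, 0)))
  fs2$x[4:5, 2] <- -15      # outside the lateral ROI
  v2 <- segment_visits(fs2)
  v2 <- v2[v2$classification != "blocked_incomplete", ]
  expect_equal(v2$classification, "blocked")
  expect_true(v2$lateral_exit)
})

test_that("detection planes must lie inside the ROI", {
  fs <- make_ion_fs(list(c(-25, 0, 25)))
  expect_error(segment_visits(fs, plane_z = 40), "inside the ROI")
})

test_that("segmentation matches a brute-force frame scan on synthetic data", {
  for (seed in 1:8) {
    rates <- default_crossing_rates(runif(1, 0, 30), runif(1, 0, 30),
                                    runif(1, 0, 30), runif(1, 0, 30))
    cfg <- ions_only_config(seed = seed, n_frames = 3000,
                            voltage = sample(c(-300, 300), 1),
                            crossing_rate = rates)
    fs <- generate_protomer(cfg)$frames
    got <- segment_visits(fs)
    got <- got[order(got$particle_id, got$entry_frame), ]
    want <- brute_force_visits(fs)
    expect_equal(got$particle_id, want$particle_id)
    expect_equal(got$entry_frame, want$entry_frame)
    expect_equal(got$exit_frame, want$exit_frame)
    expect_equal(got$classification, want$classification)
    expect_equal(got$completion_time, want$completion_time)
  }
})

test_that("mean conductance follows N_p e / (|V| (t - t1))", {
  ev <- make_events(c(1e5, 2e5, 3e5, 4e5, 5e5, 6e5, 7e5, 8e5, 9e5, 9.5e5))
  g <- mean_conductance(ev, voltage = 500, t = 1e6)
  expect_equal(g, 10 * 1.602176634e-19 / (0.5 * 900e-9) * 1e12,
               tolerance = 1e-9)
  expect_equal(round(g, 3), 3.560)
  # doubling the window halves G_m
  g2 <- mean_conductance(ev, voltage = 500, t = 2e6 - 1e5)
  expect_equal(g2, g / 2, tolerance = 1e-12)
  # sign of V is metadata only
  expect_equal(mean_conductance(ev, voltage = -500, t = 1e6), g)
  expect_true(is.na(mean_conductance(ev[0, ], voltage = 500, t = 1e6)))
  expect_error(mean_conductance(ev, voltage = 0, t = 1e6), "non-zero")
  expect_error(mean_conductance(ev, voltage = 500, t = 5e4), "exceed")
})

test_that("instantaneous conductances reproduce the worked stream", {
  ev <- make_events(c(100, 110, 130, 160) * 1e3)   # ns -> ps
  gi <- instantaneous_conductances(ev, voltage = 500)
  expect_equal(round(gi$G_i, 2), c(32.04, 16.02, 10.68))
  expect_equal(round(gi$median, 2), 16.02)
  # uniform spacing: median equals e / (|V| dt) exactly
  ev_u <- make_events(seq(1e5, 1e6, by = 1e4))
  gi_u <- instantaneous_conductances(ev_u, voltage = 500)
  expect_equal(gi_u$median, 1.602176634e-19 / (0.5 * 1e4 * 1e-12) * 1e12,
               tolerance = 1e-9)
  expect_true(is.na(instantaneous_conductances(ev[1, ], 500)$median))
  expect_error(instantaneous_conductances(make_events(c(1e5, 1e5)), 500),
               "duplicate")
})

test_that("median instantaneous conductance matches the exponential law", {
  # Poisson stream rate lambda: median waiting time ln 2 / lambda, so
  # median G_i = e lambda / (|V| ln 2)
  set.seed(77)
  lambda <- 2e-5                     # events per ps (20 per us)
  tt <- cumsum(rexp(10000, lambda))
  gi <- instantaneous_conductances(make_events(tt), voltage = 500)
  expected <- 1.602176634e-19 * (lambda * 1e12) / (0.5 * log(2)) * 1e12
  expect_lt(abs(gi$median - expected) / expected, 0.1)
})

test_that("time to first event and conductive fraction behave", {
  ev <- make_events(c(1e5, 1.1e5))
  expect_equal(time_to_first_event(ev), 1e5)
  expect_true(is.na(time_to_first_event(ev[0, ])))
  gm <- c(0.5, 5, 50)
  expect_equal(unname(conductive_fraction(gm, 1)), 2 / 3)
  expect_equal(unname(conductive_fraction(gm, 0)), 1)
  expect_equal(unname(conductive_fraction(c(gm, NA), 0)), 3 / 4)
  # monotone non-increasing over a sweep, with NA (no permeation) records
  set.seed(5)
  gm2 <- c(rexp(50, 0.1), rep(NA, 5))
  sweep <- conductive_fraction(gm2, seq(0, 50, by = 0.5))
  expect_true(all(diff(sweep) <= 1e-12))
})

test_that("detected events are in bijection with permeating visits", {
  cfg <- ions_only_config(seed = 31, n_frames = 4000)
  fs <- generate_protomer(cfg)$frames
  v <- segment_visits(fs)
  ev <- permeation_events(v)
  expect_equal(nrow(ev), sum(v$classification == "permeating"))
  expect_false(anyDuplicated(ev[, c("particle_id", "completion_time")]) > 0)
})
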
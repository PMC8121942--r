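# Coordinate conventions, ROI geometry and the canonical track format.

test_that("ROI membership uses the periphery-shifted box with closed bounds", {
  roi <- roi_box()
  expect_true(in_roi(7.5, 0, 0, roi))
  expect_false(in_roi(7.5, 0, 41, roi))
  expect_false(in_roi(7.5, 0, -40.5, roi))
  # x interval is [-5, 20] with the default +7.5 A shift
  expect_true(in_roi(-5.0, 0, 0, roi))
  expect_false(in_roi(-5.1, 0, 0, roi))
  expect_true(in_roi(20.0, 0, 0, roi))
  expect_false(in_roi(20.1, 0, 0, roi))
  expect_true(in_roi(7.5, -20, 40, roi))
})

test_that("ROI volume fraction matches Monte Carlo sampling", {
  set.seed(401)
  n <- 20000
  x <- runif(n, -25, 25); y <- runif(n, -40, 40); z <- runif(n, -80, 80)
  # centre the sampling box on the ROI x centre so the box encloses it
  frac <- mean(in_roi(x + 7.5, y, z))
  expected <- (25 * 40 * 80) / (50 * 80 * 160)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("protomer frame transform centres, flips and preserves distances", {
  particles <- data.frame(
    particle_id = c("ref", "ion"), species = c("PORE_REF", "NA"),
    lipid_id = NA_character_, residue_id = NA_integer_)
  xs <- cbind(c(1, 2), c(4, 5)); ys <- cbind(c(0, 1), c(2, 2))
  zs <- cbind(c(30, 31), c(35, 30))
  fs <- protomer_frame_set("p", 300, c(0, 100), particles, xs, ys, zs,
                           analysis_start = 0)
  loc <- to_protomer_frame(fs)
  expect_equal(unname(loc$z[, 2]), c(5, -1))      # relative to PORE_REF
  expect_equal(unname(loc$x[, 1]), c(0, 0))
  flipped <- to_protomer_frame(fs, flip = TRUE)
  expect_equal(unname(flipped$z[, 2]), c(-5, 1))
  # isometry: pairwise distance preserved by the flip
  d_lab <- sqrt(sum((c(xs[1, 2], ys[1, 2], zs[1, 2]) -
                       c(xs[1, 1], ys[1, 1], zs[1, 1]))^2))
  d_flip <- sqrt(flipped$x[1, 2]^2 + flipped$y[1, 2]^2 + flipped$z[1, 2]^2)
  expect_equal(d_flip, d_lab, tolerance = 1e-6)
})

test_that("periodic z wraps are flagged and excluded from pore motion", {
  # box_z = 80: a +39 -> -39 step is a wrap (minimum image +2), not a
  # -78 A sweep through the pore
  fs <- make_ion_fs(list(c(39, 39, -39, -39)), box_z = 80)
  expect_true(fs$wrap[2, 2])
  expect_equal(minimum_image_dz(-78, 80), 2)
  expect_equal(minimum_image_dz(10, 80), 10)
  # the wrapped ion never creates a permeation event
  v <- segment_visits(fs)
  expect_equal(nrow(permeation_events(v)), 0L)
})

test_that("canonical track files round-trip byte-identically", {
  fs <- generate_protomer(synthetic_config(seed = 5, n_frames = 40))$frames
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(fs, f1)
  fs2 <- read_tracks(f1)
  write_tracks(fs2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(fs2$voltage, fs$voltage)
  expect_lt(max(abs(fs2$z - fs$z)), 5.001e-4)   # 0.001-A printed precision
  # gzip-transparent
  fgz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_tracks(fs, fgz)
  expect_equal(read_tracks(fgz)$x, fs2$x)
})

test_that("malformed inputs are rejected", {
  particles <- data.frame(particle_id = "a", species = "NA",
                          lipid_id = NA_character_, residue_id = NA_integer_)
  m <- matrix(0, 3, 1)
  expect_error(
    protomer_frame_set("p", 300, c(0, 100, 250), particles, m, m, m),
    "non-uniform")
  expect_error(
    protomer_frame_set("p", 300, c(0, 100, 200),
                       transform(particles, species = "XX"), m, m, m),
    "unknown species")
  fs <- make_ion_fs(list(c(-30, -30)))
  fs$particles$species[1] <- "NA"    # remove the PORE_REF track
  expect_error(to_protomer_frame(fs), "PORE_REF")
  expect_error(read_tracks("/nonexistent/file.tsv"), "no such file")
})

test_that("single-frame sets load but are rejected by time-series analyses", {
  particles <- data.frame(particle_id = c("r", "a"),
                          species = c("PORE_REF", "NA"),
                          lipid_id = NA_character_, residue_id = NA_integer_)
  m <- matrix(0, 1, 2)
  fs <- protomer_frame_set("p", 300, 0, particles, m, m, m,
                           analysis_start = 0)
  expect_s3_class(fs, "ProtomerFrameSet")
  expect_error(segment_visits(fs), "at least 2 frames")
})

test_that("built-in site tables reproduce the published z ranges", {
  s <- default_sites("nhTMEM16")
  expect_equal(c(s$p_c$z_lo, s$p_c$z_hi), c(-3, 7))
  expect_equal(c(s$n_c$z_lo, s$n_c$z_hi), c(-5, 0))
  expect_equal(c(s$p_e$z_lo, s$p_e$z_hi), c(7, 17))
  expect_equal(c(s$n_e$z_lo, s$n_e$z_hi), c(5, 10))
  expect_equal(c(s$Cl_v$z_lo, s$Cl_v$z_hi), c(-16, -1))
  expect_equal(c(s$Na_i$z_lo, s$Na_i$z_hi), c(-25, -15))
  k <- default_sites("TMEM16K")
  expect_equal(c(k$p1$z_lo, k$p1$z_hi), c(-15, -10))
  expect_equal(c(k$n5$z_lo, k$n5$z_hi), c(13, 18))
  expect_equal(c(k$Na_c$z_lo, k$Na_c$z_hi), c(-10, 0))
})

test_that("pipeline configuration files override defaults", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "protein: nhTMEM16",
    "roi:",
    "  dx: 30",
    "voltages:",
    "  protomer1: 300",
    "  protomer2: -300"), cfg_file)
  cfg <- read_pipeline_config(cfg_file)
  expect_equal(cfg$roi$dx, 30)
  expect_equal(cfg$roi$dy, 40)            # untouched default
  expect_equal(cfg$voltages[["protomer2"]], -300)
  expect_named(cfg$sites, names(default_sites("nhTMEM16")))
})
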
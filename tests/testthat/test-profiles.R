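# Pore-axis distributions: headgroup densities, angles, ion densities,
# hydration, neck inference, dilation exclusion, dwell times.

make_lipid_fs <- function(p_z, n_offset = c(0, 0, 4.5), p_x = 0, p_y = 0,
                          nf = 3) {
  n <- length(p_z)
  p_x <- rep_len(p_x, n); p_y <- rep_len(p_y, n)
  particles <- data.frame(
    particle_id = c("pore_ref",
                    sprintf("l%d_P", seq_len(n)), sprintf("l%d_N", seq_len(n))),
    species = c("PORE_REF", rep("LIPID_P", n), rep("LIPID_N", n)),
    lipid_id = c(NA, sprintf("l%d", seq_len(n)), sprintf("l%d", seq_len(n))),
    residue_id = NA_integer_, stringsAsFactors = FALSE)
  row_x <- c(0, p_x, p_x + n_offset[1])
  row_y <- c(0, p_y, p_y + n_offset[2])
  row_z <- c(0, p_z, p_z + n_offset[3])
  mk <- function(v) matrix(rep(v, each = nf), nf)
  fs <- protomer_frame_set("lfix", 300, (seq_len(nf) - 1) * 100, particles,
                           mk(row_x), mk(row_y), mk(row_z),
                           analysis_start = 0)
  to_protomer_frame(fs)
}

test_that("headgroup density uses only the k atoms nearest the pore centre", {
  fs <- make_lipid_fs(c(-12, -3, 2, 8, 30))
  d <- local_headgroup_density(list(fs), "LIPID_P", k = 4)
  hit_bins <- d$bin_edges[-length(d$bin_edges)][d$mean > 0]
  expect_setequal(hit_bins, c(-12, -3, 2, 8))   # never the z = 30 atom
  expect_equal(sum(d$mean * diff(d$bin_edges)), 1, tolerance = 1e-9)
  # adding decoys beyond the k-th nearest leaves the profile unchanged
  fs_decoy <- make_lipid_fs(c(-12, -3, 2, 8, 30, 35, -35))
  d2 <- local_headgroup_density(list(fs_decoy), "LIPID_P", k = 4)
  expect_equal(d2$mean, d$mean)
  expect_error(local_headgroup_density(list(fs), "LIPID_P", k = 9), "need k")
})

test_that("a point mass gives density 1/binwidth in its bin", {
  fs <- make_lipid_fs(0.5)
  d <- local_headgroup_density(list(fs), "LIPID_P", k = 1)
  expect_equal(max(d$mean), 1)               # 1 / (1 A bin)
  expect_equal(sum(d$mean > 0), 1L)
})

test_that("planted site modes are recovered within one bin", {
  sites <- data.frame(name = c("s1", "s2"), mean_z = c(2, 12),
                      sd = c(1, 1), occupancy = c(1, 1))
  coh <- generate_cohort(25, seed = 808, n_frames = 400,
                         headgroup_sites = sites,
                         water_profile = list(edges = numeric(0),
                                              mean = numeric(0)))
  fsl <- lapply(coh, `[[`, "frames")
  d <- local_headgroup_density(fsl, "LIPID_P", k = 2)
  mids <- d$bin_edges[-length(d$bin_edges)] + 0.5
  # the two planted modes dominate
  top2 <- mids[order(d$mean, decreasing = TRUE)[1:2]]
  expect_lte(min(abs(top2 - 2)), 1)
  expect_lte(min(abs(top2 - 12)), 1)
  # per-protomer normalisation before averaging
  expect_equal(sum(d$mean * diff(d$bin_edges)), 1, tolerance = 1e-9)
  expect_equal(d$n_protomers, 25L)
  expect_true(all(d$sem >= 0))
})

test_that("headgroup angles measure the P-to-N tilt from the membrane normal", {
  up <- make_lipid_fs(2, n_offset = c(0, 0, 4.5))
  a_up <- headgroup_angle_distribution(list(up))
  expect_equal(a_up$bin_edges[which(a_up$mean > 0)], 0)      # 0-5 deg bin
  side <- make_lipid_fs(2, n_offset = c(0, 4.5, 0))
  a_side <- headgroup_angle_distribution(list(side))
  expect_equal(a_side$bin_edges[which(a_side$mean > 0)], 90)
  expect_equal(sum(a_side$mean), 1)
  bad <- make_lipid_fs(2)
  bad$particles$lipid_id[3] <- "other"
  expect_error(headgroup_angle_distribution(list(bad)), "unpaired")
})

test_that("planted orientation flip with voltage polarity is recovered", {
  mk <- function(v, seed) {
    generate_cohort(6, seed = seed, n_frames = 300, voltage = v,
      orientation_mode = list(mean_pos = 0, mean_neg = 180, sd = 15),
      water_profile = list(edges = numeric(0), mean = numeric(0)))
  }
  fs_pos <- lapply(mk(300, 11), `[[`, "frames")
  fs_neg <- lapply(mk(-300, 12), `[[`, "frames")
  mean_angle <- function(a) {
    mids <- a$bin_edges[-length(a$bin_edges)] + 2.5
    sum(mids * a$mean)
  }
  m_pos <- mean_angle(headgroup_angle_distribution(fs_pos))
  m_neg <- mean_angle(headgroup_angle_distribution(fs_neg))
  expect_gt(abs(m_neg - m_pos), 150)
})

test_that("ion densities by class have the expected support and integral", {
  cfg <- ions_only_config(seed = 55, n_frames = 4000)
  fs <- generate_protomer(cfg)$frames
  v <- segment_visits(fs)
  dp <- ion_z_density(list(fs), list(v), "permeating")
  db <- ion_z_density(list(fs), list(v), "blocked")
  mids <- dp$bin_edges[-length(dp$bin_edges)] + 0.5
  expect_gt(sum(dp$mean[mids < 0]), 0)
  expect_gt(sum(dp$mean[mids > 0]), 0)
  expect_equal(sum(dp$mean), 1, tolerance = 1e-9)   # 1-A bins
  expect_equal(sum(db$mean), 1, tolerance = 1e-9)
  # blocked ions never sample the planted neck (0, 7)
  expect_equal(sum(db$mean[mids > 0 & mids < 7]), 0)
  # a blocked visit confined to z < 0 puts no mass above the centre
  fsb <- make_ion_fs(list(c(-25, -18, -8, -12, -18, -25)))
  vb <- segment_visits(fsb)
  d1 <- ion_z_density(list(fsb), list(vb), "blocked")
  expect_equal(sum(d1$mean[mids > 0]), 0)
  expect_null(ion_z_density(list(fsb), list(vb), "permeating"))
})

test_that("hydration counts the 10-A extracellular section and adds up", {
  coords <- list(cbind(7.5, 0, c(1, 5, 9, 11)),
                 cbind(7.5, 0, c(0.5, 3, 9.5, -2)))
  fs <- make_water_fs(coords)
  h <- hydration_extracellular(fs)
  expect_equal(h$per_frame, c(3, 3))
  hp <- hydration_profile(list(fs))
  lo <- hp$bin_edges[-length(hp$bin_edges)]
  expect_equal(sum(hp$mean[lo >= 0 & lo < 10]), h$mean)
  expect_true(all(hp$mean[lo > 20] == 0))
  # generator oracle: planted Poisson water counts recovered within 3 SE
  out <- generate_protomer(synthetic_config(seed = 14, n_frames = 1500))
  h2 <- hydration_extracellular(out$frames)
  mids <- out$truth$water_bin_edges[-1] - 0.5
  planted_mean <- sum(out$truth$config$water_profile$mean[mids > 0 & mids < 10])
  se <- sqrt(planted_mean / 1500)
  expect_lt(abs(h2$mean - planted_mean), 3 * se)
})

test_that("the neck is inferred from the blocked-ion density gap", {
  mids <- seq(-39.5, 39.5, by = 1)
  d <- rep(0.02, length(mids))
  d[mids > 0 & mids < 7] <- 0                      # exact gap on [0, 7)
  prof <- list(bin_edges = seq(-40, 40, 1), mean = d)
  neck <- find_neck(prof)
  expect_equal(c(neck$z_lo, neck$z_hi), c(0, 7))
  # everywhere-positive density: no neck
  expect_null(find_neck(list(bin_edges = seq(-40, 40, 1),
                             mean = rep(0.0125, 80))))
  # planted depletion recovered within +-1 A across a cohort
  coh <- generate_cohort(12, seed = 31, n_frames = 2500,
                         headgroup_sites = default_headgroup_sites()[0, ],
                         n_decoy_lipids = 0)
  fsl <- lapply(coh, `[[`, "frames")
  vl <- lapply(fsl, segment_visits)
  db <- ion_z_density(fsl, vl, "blocked")
  neck2 <- find_neck(db)
  expect_lte(abs(neck2$z_lo - 0), 1)
  expect_lte(abs(neck2$z_hi - 7), 1)
})

test_that("dilated-pore exclusion uses the strict > 45 rule", {
  # construct frame sets with a controlled mean neck water count
  mk_neck_fs <- function(count) {
    coords <- replicate(4, cbind(7.5, 0, runif(count, 0.5, 6.5)),
                        simplify = FALSE)
    make_water_fs(coords)
  }
  set.seed(9)
  neck <- list(z_lo = 0, z_hi = 7)
  expect_false(filter_dilated(mk_neck_fs(46), neck)$keep)
  expect_true(filter_dilated(mk_neck_fs(45), neck)$keep)    # exactly 45 kept
  # planted dilation labels are recovered exactly
  lab <- c(TRUE, FALSE, TRUE, FALSE)
  keep <- vapply(seq_along(lab), function(i) {
    fs <- generate_protomer(synthetic_config(seed = 40 + i, n_frames = 200,
                                             dilated = lab[i]))$frames
    filter_dilated(fs, neck)$keep
  }, logical(1))
  expect_equal(keep, !lab)
})

test_that("dwell times are contiguous-run lengths times the sampling interval", {
  z <- rep(-30, 30)
  z[10:15] <- 1          # 6 frames inside Na_v [-8, 2)
  fs <- make_ion_fs(list(z))
  site <- default_sites("nhTMEM16")$Na_v
  d <- dwell_times(fs, site)
  expect_equal(d$durations, 600)
  expect_equal(d$max, 600)
  # never occupied
  fs2 <- make_ion_fs(list(rep(-30, 10)))
  d2 <- dwell_times(fs2, site)
  expect_length(d2$durations, 0)
  expect_true(is.na(d2$max))
  # two separated residences
  z3 <- rep(-30, 40); z3[5:6] <- 0; z3[20:24] <- -1
  d3 <- dwell_times(make_ion_fs(list(z3)), site)
  expect_setequal(d3$durations, c(200, 500))
})
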
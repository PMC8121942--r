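# Blockage geometry, contacts, RDF hydration shells, pore RMSD.

test_that("the mean pathway point averages in-site visit coordinates", {
  site <- default_sites("nhTMEM16")$Na_v
  # one crossing dwelling in the site at alternating lateral offsets
  z <- c(-25, -4, -4, -4, -4, 25)
  fs <- make_ion_fs(list(z))
  fs$x[2:5, 2] <- 7.5 + c(1, -1, 0, 0)
  fs$y[2:5, 2] <- c(0, 0, 2, -2)
  v <- segment_visits(fs)
  mp <- mean_pathway_point(list(fs), list(v), site)
  expect_equal(mp$x, 7.5)
  expect_equal(mp$y, 0)
  # constant-offset visits return that offset
  fs2 <- make_ion_fs(list(z), x = 9.5, y = 3)
  v2 <- segment_visits(fs2)
  mp2 <- mean_pathway_point(list(fs2), list(v2), site)
  expect_equal(c(mp2$x, mp2$y), c(9.5, 3))
  expect_null(mean_pathway_point(list(fs), list(v),
                                 default_sites("nhTMEM16")$Na_e))
})

test_that("blockage distances recover a 3-4-5 triangle and are translation-invariant", {
  site <- default_sites("nhTMEM16")$Na_v
  b <- generate_blockage_protomer(1, site, "open", distance = 5,
                                  noise_sd = 0)
  fs <- b$frames
  # pin the moiety exactly (3, 4) away from the pathway during visits
  mcol <- which(fs$particles$particle_id == "moiety1_P")
  in_site <- fs$z[, mcol] >= site$z_lo & fs$z[, mcol] < site$z_hi
  fs$x[in_site, mcol] <- 7.5 + 3
  fs$y[in_site, mcol] <- 4
  v <- segment_visits(fs)
  d <- blockage_distances(list(fs), list(v), site, "LIPID_P", "efflux",
                          "permeating",
                          pathway = list(x = 7.5, y = 0))
  expect_equal(d$mean_distance, 5, tolerance = 1e-9)
  # translate everything: distances unchanged (frame is pore-centred, so
  # translation acts on the lab frame before centring)
  expect_equal(nrow(d), 1L)
})

test_that("the planted open-vs-closed distance effect is detected", {
  site <- default_sites("nhTMEM16")$Na_v
  open <- lapply(1:15, function(i)
    generate_blockage_protomer(i, site, "open", distance = 6,
                               noise_sd = 0.5))
  closed <- lapply(16:30, function(i)
    generate_blockage_protomer(i, site, "closed", distance = 4,
                               noise_sd = 0.5))
  fso <- lapply(open, `[[`, "frames")
  fsc <- lapply(closed, `[[`, "frames")
  for (i in seq_along(fso)) fso[[i]]$protomer_id <- sprintf("o%02d", i)
  for (i in seq_along(fsc)) fsc[[i]]$protomer_id <- sprintf("c%02d", i)
  vo <- lapply(fso, segment_visits)
  vc <- lapply(fsc, segment_visits)
  mp <- mean_pathway_point(fso, vo, site)
  do <- blockage_distances(fso, vo, site, "LIPID_P", "efflux", "permeating",
                           pathway = mp)
  dc <- blockage_distances(fsc, vc, site, "LIPID_P", "efflux", "blocked",
                           pathway = mp)
  expect_equal(nrow(do), 15L)
  expect_equal(nrow(dc), 15L)
  # per-protomer means track the planted protomer-level distances
  planted_o <- vapply(open, `[[`, 0, "planted_distance")
  expect_equal(do$mean_distance, planted_o, tolerance = 0.05)
  mw <- mann_whitney_one_sided(do$mean_distance, dc$mean_distance, "greater")
  expect_lt(mw$p_value, 0.05)
})

test_that("contact probabilities are occupancy-frame fractions, monotone in cutoff", {
  nf <- 100
  # moiety in the site every frame; residue 301 within 4 A in 20 frames
  particles <- data.frame(
    particle_id = c("pore_ref", "p1", "ca301", "ca302"),
    species = c("PORE_REF", "LIPID_P", "PROTEIN_CA", "PROTEIN_CA"),
    lipid_id = c(NA, "l1", NA, NA),
    residue_id = c(NA, NA, 301L, 302L), stringsAsFactors = FALSE)
  xs <- cbind(rep(0, nf), rep(7.5, nf), rep(7.5, nf), rep(7.5, nf))
  ys <- matrix(0, nf, 4)
  zs <- cbind(rep(0, nf), rep(2, nf), c(rep(4, 20), rep(12, 80)),
              rep(-15, nf))
  fs <- to_protomer_frame(protomer_frame_set("c", 300, (1:nf - 1) * 100,
                                             particles, xs, ys, zs,
                                             analysis_start = 0))
  site <- default_sites("nhTMEM16")$p_c
  cp <- contact_probability(fs, site, cutoff = 4)
  expect_equal(cp$probability[cp$residue_id == 301], 0.20)
  expect_equal(cp$probability[cp$residue_id == 302], 0)
  expect_equal(attr(cp, "n_occupancy_frames"), nf)
  # monotone non-decreasing in the cutoff
  cuts <- c(2, 3, 4, 6, 10, 20)
  probs <- vapply(cuts, function(cc)
    contact_probability(fs, site, cutoff = cc)$probability[1], numeric(1))
  expect_true(all(diff(probs) >= 0))
  expect_error(contact_probability(fs, site, cutoff = 0), "positive")
})

test_that("RDF of a two-shell fixture gives a first-shell radius near 4 A", {
  set.seed(71)
  nf <- 30; n1 <- 80; n2 <- 160
  np <- 2 + n1 + n2
  xs <- ys <- zs <- matrix(0, nf, np)
  for (f in seq_len(nf)) {
    w <- rbind(shell_points(n1, 2.5, 3.5), shell_points(n2, 4.5, 6.0))
    xs[f, 3:np] <- w[, 1]; ys[f, 3:np] <- w[, 2]; zs[f, 3:np] <- w[, 3]
  }
  particles <- data.frame(
    particle_id = c("ref", "ion", sprintf("w%d", seq_len(n1 + n2))),
    species = c("PORE_REF", "NA", rep("WATER_O", n1 + n2)),
    lipid_id = NA_character_, residue_id = NA_integer_)
  fs <- protomer_frame_set("rdf", 300, (seq_len(nf) - 1) * 100, particles,
                           xs, ys, zs, analysis_start = 0)
  r <- rdf_first_shell(fs, "NA")
  expect_lt(abs(r$first_shell_radius - 4.0), 0.15)
  expect_true(all(r$g >= 0))
  # featureless uniform gas: no shell structure
  set.seed(72)
  xs2 <- ys2 <- zs2 <- matrix(0, nf, np)
  for (f in seq_len(nf)) {
    w <- shell_points(n1 + n2, 0.5, 7.9)
    xs2[f, 3:np] <- w[, 1]; ys2[f, 3:np] <- w[, 2]; zs2[f, 3:np] <- w[, 3]
  }
  fs2 <- protomer_frame_set("gas", 300, (seq_len(nf) - 1) * 100, particles,
                            xs2, ys2, zs2, analysis_start = 0)
  r2 <- rdf_first_shell(fs2, "NA")
  expect_true(is.na(r2$first_shell_radius))
})

test_that("permeating ions keep a constant planted coordination shell", {
  # six waters glued within 3 A of the ion through a crossing
  z_ion <- c(-25, -15, -5, 3, 12, 25)
  nf <- length(z_ion)
  offsets <- rbind(c(1.5, 0, 0), c(-1.5, 0, 0), c(0, 1.5, 0),
                   c(0, -1.5, 0), c(0, 0, 2.5), c(0, 0, -2.5))
  particles <- data.frame(
    particle_id = c("ref", "ion", sprintf("w%d", 1:6)),
    species = c("PORE_REF", "NA", rep("WATER_O", 6)),
    lipid_id = NA_character_, residue_id = NA_integer_)
  xs <- cbind(0, 7.5, matrix(rep(7.5 + offsets[, 1], each = nf), nf))
  ys <- cbind(0, 0, matrix(rep(offsets[, 2], each = nf), nf))
  zs <- cbind(0, z_ion, matrix(rep(offsets[, 3], each = nf), nf) + z_ion)
  fs <- protomer_frame_set("sh", 300, (seq_len(nf) - 1) * 100, particles,
                           xs, ys, zs, analysis_start = 0)
  v <- segment_visits(fs)
  ret <- shell_retention(fs, v, neck = list(z_lo = 0, z_hi = 7),
                         shell_radius = 3.0, species = "NA")
  expect_equal(ret$neck, 6)
  expect_equal(ret$bulk, 6)
})

test_that("pore RMSD matches identity, rigid-shift and brute-force cases", {
  set.seed(91)
  rng <- pore_residue_ranges("nhTMEM16")
  resid <- unlist(mapply(seq, rng$lo, rng$hi, SIMPLIFY = FALSE))
  nres <- length(resid)
  expect_equal(nres, sum(rng$hi - rng$lo + 1))
  ref <- matrix(rnorm(nres * 3, sd = 10), ncol = 3)
  particles <- data.frame(
    particle_id = c(sprintf("ca%d", seq_len(nres)), "ref"),
    species = c(rep("PROTEIN_CA", nres), "PORE_REF"),
    lipid_id = NA_character_, residue_id = c(resid, NA))
  rand <- ref + matrix(rnorm(nres * 3), ncol = 3)
  xs <- cbind(rbind(ref[, 1], ref[, 1] + 1, rand[, 1]), 0)
  ys <- cbind(rbind(ref[, 2], ref[, 2], rand[, 2]), 0)
  zs <- cbind(rbind(ref[, 3], ref[, 3], rand[, 3]), 0)
  fs <- protomer_frame_set("r", 300, c(0, 100, 200), particles,
                           xs, ys, zs, analysis_start = 0)
  out <- pore_rmsd(fs, ref, rng, fit = FALSE)
  expect_equal(out$rmsd[1], 0)
  expect_equal(out$rmsd[2], 1)               # uniform +1 A x shift
  # brute-force formula on the random frame
  expect_equal(out$rmsd[3], sqrt(mean(rowSums((rand - ref)^2))),
               tolerance = 1e-12)
  fit <- pore_rmsd(fs, ref, rng, fit = TRUE)
  expect_equal(fit$rmsd[2], 0, tolerance = 1e-9)  # shift removed by fit
  expect_true(all(fit$rmsd <= out$rmsd + 1e-9))
  # missing residues are an error
  expect_error(pore_rmsd(fs, ref[-1, , drop = FALSE],
                         data.frame(lo = 200, hi = 210)), "missing residues")
})

test_that("TMEM16K residue ranges are available", {
  rng <- pore_residue_ranges("TMEM16K")
  expect_equal(rng$lo, c(320, 355, 404, 426, 496, 518))
  expect_equal(rng$hi, c(349, 377, 420, 449, 511, 538))
})
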
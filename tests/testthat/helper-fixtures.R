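# Fixture builders used across the suite.  Everything is generated in
# code; no data files.

# Frame set with explicit ion z paths (list of numeric vectors, one per
# ion), all ions at pore-lateral position (x = 7.5, y = 0) unless
# overridden.  A PORE_REF track at the origin is added automatically.
make_ion_fs <- function(z_paths, species = "NA", x = 7.5, y = 0,
                        voltage = 300, dt = 100, box_z = 160) {
  nf <- length(z_paths[[1]])
  stopifnot(all(vapply(z_paths, length, 0L) == nf))
  n <- length(z_paths)
  species <- rep_len(species, n)
  x <- rep_len(x, n); y <- rep_len(y, n)
  particles <- data.frame(
    particle_id = c("pore_ref", sprintf("ion%d", seq_len(n))),
    species = c("PORE_REF", species),
    lipid_id = NA_character_, residue_id = NA_integer_,
    stringsAsFactors = FALSE)
  zs <- cbind(0, do.call(cbind, z_paths))
  xs <- cbind(0, matrix(rep(x, each = nf), nf))
  ys <- cbind(0, matrix(rep(y, each = nf), nf))
  fs <- protomer_frame_set("fixture", voltage, (seq_len(nf) - 1) * dt,
                           particles, xs, ys, zs,
                           analysis_start = 0, box_z = box_z)
  to_protomer_frame(fs)
}

# Independent brute-force visit scanner: a frame-by-frame loop with no
# shared code with segment_visits().  Returns the same columns used in
# comparisons.
brute_force_visits <- function(fs, roi = roi_box(), plane_z = 20,
                               species = c("NA", "CL")) {
  fs <- analysis_window(fs)
  nf <- length(fs$frame_times)
  res <- list()
  for (j in which(fs$particles$species %in% species)) {
    zj <- fs$z[, j]; xj <- fs$x[, j]; yj <- fs$y[, j]
    lateral <- xj >= roi$x_shift - roi$dx / 2 & xj <= roi$x_shift + roi$dx / 2 &
      yj >= -roi$dy / 2 & yj <= roi$dy / 2
    inside <- abs(zj) < plane_z & lateral
    f <- 1L
    while (f <= nf) {
      if (!inside[f]) { f <- f + 1L; next }
      s <- f
      while (f < nf && inside[f + 1L]) f <- f + 1L
      e <- f
      f <- f + 1L
      if (s == 1L || e == nf) {
        cls <- "blocked_incomplete"; dir <- NA_character_; ct <- NA_real_
      } else {
        wrap_in <- !is.null(fs$wrap) && fs$wrap[s - 1L, j]
        wrap_out <- !is.null(fs$wrap) && fs$wrap[e, j]
        from_below <- !wrap_in && zj[s - 1L] <= -plane_z
        from_above <- !wrap_in && zj[s - 1L] >= plane_z
        to_below <- !wrap_out && zj[e + 1L] <= -plane_z
        to_above <- !wrap_out && zj[e + 1L] >= plane_z
        if (from_below && to_above) {
          cls <- "permeating"; dir <- "efflux"; ct <- fs$frame_times[e + 1L]
        } else if (from_above && to_below) {
          cls <- "permeating"; dir <- "influx"; ct <- fs$frame_times[e + 1L]
        } else {
          cls <- "blocked"; dir <- NA_character_; ct <- NA_real_
        }
      }
      res[[length(res) + 1L]] <- data.frame(
        particle_id = fs$particles$particle_id[j],
        species = fs$particles$species[j],
        entry_frame = s, exit_frame = e, classification = cls,
        direction = dir, completion_time = ct, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(particle_id = character(), species = character(),
                      entry_frame = integer(), exit_frame = integer(),
                      classification = character(), direction = character(),
                      completion_time = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$particle_id, out$entry_frame), ]
}

# Synthetic event stream -> data.frame shaped like permeation_events()
make_events <- function(times_ps, species = "NA", direction = "efflux") {
  data.frame(particle_id = sprintf("e%d", seq_along(times_ps)),
             species = rep_len(species, length(times_ps)),
             completion_time = times_ps,
             direction = rep_len(direction, length(times_ps)),
             stringsAsFactors = FALSE)
}

# Frame set with waters at fixed positions per frame.  `coords` is a list
# of n x 3 matrices, one per frame (same n across frames); extra species
# columns can be prepended via `extra`.
make_water_fs <- function(coords, extra_particles = NULL, extra_xyz = NULL,
                          voltage = 300, dt = 100) {
  nf <- length(coords)
  n <- nrow(coords[[1]])
  particles <- data.frame(
    particle_id = c("pore_ref", sprintf("w%d", seq_len(n))),
    species = c("PORE_REF", rep("WATER_O", n)),
    lipid_id = NA_character_, residue_id = NA_integer_,
    stringsAsFactors = FALSE)
  xs <- cbind(0, t(vapply(coords, function(m) m[, 1], numeric(n))))
  ys <- cbind(0, t(vapply(coords, function(m) m[, 2], numeric(n))))
  zs <- cbind(0, t(vapply(coords, function(m) m[, 3], numeric(n))))
  if (!is.null(extra_particles)) {
    particles <- rbind(particles, extra_particles)
    xs <- cbind(xs, extra_xyz$x); ys <- cbind(ys, extra_xyz$y)
    zs <- cbind(zs, extra_xyz$z)
  }
  fs <- protomer_frame_set("wfixture", voltage, (seq_len(nf) - 1) * dt,
                           particles, xs, ys, zs, analysis_start = 0)
  to_protomer_frame(fs)
}

# Uniform points in a spherical shell
shell_points <- function(n, rlo, rhi) {
  r <- (stats::runif(n, rlo^3, rhi^3))^(1 / 3)
  u <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  cbind(r * sqrt(1 - u^2) * cos(phi), r * sqrt(1 - u^2) * sin(phi), r * u)
}

# Ions-only synthetic config (no lipids, no waters) for fast event tests
ions_only_config <- function(seed, n_frames, ...) {
  synthetic_config(seed = seed, n_frames = n_frames,
                   headgroup_sites = default_headgroup_sites()[0, ],
                   water_profile = list(edges = numeric(0), mean = numeric(0)),
                   n_decoy_lipids = 0, ...)
}
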
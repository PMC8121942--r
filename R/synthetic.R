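# Synthetic trajectory generator with planted ground truth.
#
# The generator emulates the statistical structure that the analysis
# pipeline assumes about voltage-driven scramblase trajectories, not the
# physics: ion crossings arrive with exponential waiting times per
# species and direction; blocked ions penetrate to the neck boundary and
# turn back through their entry plane; lipid headgroups occupy discrete
# z-localisation sites and orient with the voltage polarity; water
# counts follow a pore-axis profile with a neck depletion.  Every planted
# quantity is returned as ground truth so downstream detectors can be
# tested oracle-style.

#' Configuration of the synthetic trajectory generator
#'
#' @param seed master RNG seed (all randomness derives from it; the same
#'   seed reproduces byte-identical tracks).
#' @param n_frames number of frames.
#' @param sampling_interval ps between frames (default 100).
#' @param voltage signed transmembrane voltage, mV.
#' @param crossing_rate 2 x 2 matrix of permeation rates, events per
#'   microsecond; rows `"NA"`, `"CL"`, columns `"influx"`, `"efflux"`.
#' @param blocked_visit_rate 2 x 2 matrix of blocked-visit rates per
#'   microsecond; columns `"intracellular"`, `"extracellular"` (entry
#'   side).
#' @param headgroup_sites data.frame `name`, `mean_z`, `sd`, `occupancy`
#'   -- one pore-engaged lipid per site, its phosphorus jittering about
#'   `mean_z`.
#' @param orientation_mode list `mean_pos`, `mean_neg` (mean P-to-N angle
#'   in degrees at positive / negative voltage) and `sd` (degrees).
#' @param water_profile list `edges` (z bin edges, Angstrom) and `mean`
#'   (mean water count per bin); counts are drawn Poisson per frame.
#' @param neck_interval c(z_lo, z_hi), Angstrom: the depleted section
#'   blocked ions never enter.
#' @param dilated when `TRUE`, neck water means are inflated so the mean
#'   neck count exceeds the dilation threshold of 45.
#' @param n_bulk_ions named vector: ion tracks per species.
#' @param n_decoy_lipids far-away headgroup pairs that must never enter
#'   k-nearest densities.
#' @param plane_z detection-plane half distance used when planting
#'   completion times, Angstrom.
#' @param analysis_start ps (default 0: synthetic data carries no
#'   equilibration transient).
#' @return list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(seed = 1,
                             n_frames = 2000,
                             sampling_interval = 100,
                             voltage = 300,
                             crossing_rate = default_crossing_rates(),
                             blocked_visit_rate = default_blocked_rates(),
                             headgroup_sites = default_headgroup_sites(),
                             orientation_mode = list(mean_pos = 40,
                                                     mean_neg = 140,
                                                     sd = 25),
                             water_profile = default_water_profile(),
                             neck_interval = c(0, 7),
                             dilated = FALSE,
                             n_bulk_ions = c("NA" = 8, "CL" = 8),
                             n_decoy_lipids = 4,
                             plane_z = 20,
                             analysis_start = 0) {
  stopifnot(all(crossing_rate >= 0), all(blocked_visit_rate >= 0),
            n_frames >= 20, sampling_interval > 0,
            neck_interval[1] < neck_interval[2])
  if (nrow(headgroup_sites) > 0)
    stopifnot(all(headgroup_sites$occupancy >= 0),
              all(headgroup_sites$occupancy <= 1),
              all(headgroup_sites$sd > 0))
  structure(as.list(environment()), class = "SyntheticConfig")
}

#' Default permeation rates (events per microsecond)
#' @export
default_crossing_rates <- function(na_influx = 2, na_efflux = 10,
                                   cl_influx = 1, cl_efflux = 4) {
  matrix(c(na_influx, na_efflux, cl_influx, cl_efflux), nrow = 2,
         byrow = TRUE, dimnames = list(c("NA", "CL"),
                                       c("influx", "efflux")))
}

#' Default blocked-visit rates (visits per microsecond)
#' @export
default_blocked_rates <- function(na_intra = 4, na_extra = 4,
                                  cl_intra = 4, cl_extra = 4) {
  matrix(c(na_intra, na_extra, cl_intra, cl_extra), nrow = 2,
         byrow = TRUE, dimnames = list(c("NA", "CL"),
                                       c("intracellular", "extracellular")))
}

#' Default headgroup localisation sites (nhTMEM16-like)
#' @export
default_headgroup_sites <- function() {
  data.frame(name = c("p_c", "p_e", "p_i", "p_o"),
             mean_z = c(2, 12, -12, 17),
             sd = c(1.5, 1.5, 1.5, 1.5),
             occupancy = c(0.9, 0.9, 0.9, 0.9),
             stringsAsFactors = FALSE)
}

#' Default pore-axis water profile: flat with a neck depletion
#'
#' Mean counts per 1-Angstrom bin over [-20, 20]: 8 waters per section
#' in the hydrated cavity, 1 in the neck [0, 7).
#' @param neck c(z_lo, z_hi).
#' @param bulk_mean,neck_mean mean counts per bin.
#' @export
default_water_profile <- function(neck = c(0, 7), bulk_mean = 8,
                                  neck_mean = 1) {
  edges <- seq(-20, 20, by = 1)
  mids <- edges[-1] - 0.5
  m <- rep(bulk_mean, length(mids))
  m[mids > neck[1] & mids < neck[2]] <- neck_mean
  list(edges = edges, mean = m)
}

P_N_DISTANCE <- 4.5   # phosphocholine P-N distance, Angstrom

# reflect values into [lo, hi] (triangle-wave folding)
fold_into <- function(v, lo, hi) {
  period <- 2 * (hi - lo)
  w <- (v - lo) %% period
  lo + pmin(w, period - w)
}

smoothstep <- function(u) 3 * u^2 - 2 * u^3

#' Generate one synthetic protomer with ground truth
#'
#' @param cfg a [synthetic_config()].
#' @return list `frames` (a `ProtomerFrameSet` in the protomer-local
#'   frame) and `truth` (list `planted_events`,
#'   `planted_blocked_visits`, `planted_orientations`,
#'   `planted_water_counts`, `config`).
#' @export
generate_protomer <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed)
  nf <- cfg$n_frames
  dt <- cfg$sampling_interval
  times <- (seq_len(nf) - 1) * dt
  plane <- cfg$plane_z
  z_out <- plane + 8          # flank depth beyond the detection plane

  schedules <- plan_activities(cfg, nf)
  ion_tracks <- realize_ion_tracks(cfg, schedules, nf, z_out)
  lipid <- realize_headgroups(cfg, nf)
  water <- realize_waters(cfg, nf)

  particles <- rbind(
    data.frame(particle_id = "pore_ref", species = "PORE_REF",
               lipid_id = NA_character_, residue_id = NA_integer_,
               stringsAsFactors = FALSE),
    ion_tracks$particles, lipid$particles, water$particles)
  bind_xyz <- function(w) cbind(matrix(0, nf, 1),
                                ion_tracks[[w]], lipid[[w]], water[[w]])
  fs <- protomer_frame_set(
    protomer_id = sprintf("synthetic_seed%d", cfg$seed),
    voltage = cfg$voltage, frame_times = times, particles = particles,
    x = bind_xyz("x"), y = bind_xyz("y"), z = bind_xyz("z"),
    analysis_start = cfg$analysis_start, box_z = 160)
  fs <- to_protomer_frame(fs)   # origin already centred; computes wrap flags

  truth <- list(planted_events = ion_tracks$events,
                planted_blocked_visits = ion_tracks$blocked,
                planted_orientations = lipid$orientations,
                planted_water_counts = water$counts,
                water_bin_edges = cfg$water_profile$edges,
                config = cfg)
  list(frames = fs, truth = truth)
}

# ---------------------------------------------------------------------------
# Activity scheduling: exponential arrivals, assignment to ion tracks
# ---------------------------------------------------------------------------

# An activity occupies a frame window on one ion: a 5-frame crossing ramp
# for permeation events, a 7-frame excursion for blocked visits (plus one
# flank frame each side).
plan_activities <- function(cfg, nf) {
  dt <- cfg$sampling_interval
  total_ps <- (nf - 1) * dt
  draw_times <- function(rate_per_us) {
    rate_ps <- rate_per_us * 1e-6
    if (rate_ps <= 0) return(numeric())
    n_max <- max(20, stats::qpois(1 - 1e-12, rate_ps * total_ps))
    tt <- cumsum(stats::rexp(n_max, rate_ps))
    tt[tt < total_ps]
  }
  acts <- list()
  for (sp in c("NA", "CL")) {
    for (dir in c("influx", "efflux")) {
      for (tc in draw_times(cfg$crossing_rate[sp, dir])) {
        fr <- as.integer(round(tc / dt)) + 1L   # completion frame (1-based)
        acts[[length(acts) + 1L]] <- list(species = sp, kind = "event",
                                          direction = dir, anchor = fr,
                                          span = 5L)
      }
    }
    for (side in c("intracellular", "extracellular")) {
      for (tc in draw_times(cfg$blocked_visit_rate[sp, side])) {
        fr <- as.integer(round(tc / dt)) + 1L   # apex frame
        acts[[length(acts) + 1L]] <- list(species = sp, kind = "blocked",
                                          side = side, anchor = fr,
                                          span = 7L)
      }
    }
  }
  assign_activities(cfg, acts, nf)
}

# Assign activities to ion tracks without overlap; resample an activity's
# anchor frame a bounded number of times when no ion is free.
assign_activities <- function(cfg, acts, nf) {
  events <- blocked <- list()
  per_species <- split(acts, vapply(acts, `[[`, "", "species"))
  assigned <- list()
  for (sp in names(per_species)) {
    sa <- per_species[[sp]]
    n_ions <- cfg$n_bulk_ions[sp]
    if (length(sa) && n_ions < 1L)
      stop("activities planted for species ", sp, " but no ion tracks")
    busy_until <- rep(0L, n_ions)
    ord <- order(vapply(sa, `[[`, 0L, "anchor"))
    for (a in sa[ord]) {
      placed <- FALSE
      for (try in seq_len(50L)) {
        win <- activity_window(a, nf)
        if (!is.null(win)) {
          free <- which(busy_until < win[1])
          if (length(free)) {
            ion <- free[which.min(busy_until[free])]
            busy_until[ion] <- win[2] + 1L
            a$ion <- ion
            a$window <- win
            assigned[[length(assigned) + 1L]] <- a
            placed <- TRUE
            break
          }
        }
        # resample the anchor uniformly inside the feasible range
        a$anchor <- sample(seq(a$span + 2L, nf - a$span - 2L), 1L)
      }
      if (!placed)
        stop("activity rates too high: could not place all planted ",
             "events/visits on ", cfg$n_bulk_ions[sp], " ", sp, " tracks")
    }
  }
  assigned
}

# Frame window [first flank, last flank] of an activity, or NULL when it
# does not fit inside the trajectory with one bulk frame to spare.
activity_window <- function(a, nf) {
  if (a$kind == "event") {
    f0 <- a$anchor - 4L; f1 <- a$anchor
  } else {
    f0 <- a$anchor - 3L; f1 <- a$anchor + 3L
  }
  if (f0 < 2L || f1 > nf - 1L) return(NULL)
  c(f0, f1)
}

# ---------------------------------------------------------------------------
# Track realisation
# ---------------------------------------------------------------------------

realize_ion_tracks <- function(cfg, acts, nf, z_out) {
  dt <- cfg$sampling_interval
  plane <- cfg$plane_z
  neck <- cfg$neck_interval
  ids <- character(); spec <- character()
  xs <- ys <- zs <- list()
  events <- blocked <- list()
  for (sp in c("NA", "CL")) {
    n_ions <- cfg$n_bulk_ions[sp]
    if (is.na(n_ions) || n_ions < 1L) next
    sp_acts <- Filter(function(a) a$species == sp, acts)
    by_ion <- split(sp_acts, vapply(sp_acts, `[[`, 0L, "ion"))
    for (ion in seq_len(n_ions)) {
      ia <- by_ion[[as.character(ion)]]
      if (!is.null(ia))
        ia <- ia[order(vapply(ia, function(a) a$window[1], 0L))]
      tr <- realize_one_ion(cfg, ia, nf, z_out)
      pid <- sprintf("%s_%d", tolower(sp), ion)
      ids <- c(ids, pid); spec <- c(spec, sp)
      xs[[pid]] <- tr$x; ys[[pid]] <- tr$y; zs[[pid]] <- tr$z
      for (a in ia %||% list()) {
        if (a$kind == "event") {
          events[[length(events) + 1L]] <- data.frame(
            particle_id = pid, species = sp,
            completion_frame = a$window[2],
            completion_time = (a$window[2] - 1L) * dt,
            direction = a$direction, stringsAsFactors = FALSE)
        } else {
          blocked[[length(blocked) + 1L]] <- data.frame(
            particle_id = pid, species = sp,
            entry_frame = a$window[1] + 1L, exit_frame = a$window[2] - 1L,
            side = a$side, stringsAsFactors = FALSE)
        }
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(particle_id = character(), species = character(),
               completion_frame = integer(), completion_time = numeric(),
               direction = character(), stringsAsFactors = FALSE)
  ev <- ev[order(ev$completion_time), , drop = FALSE]
  rownames(ev) <- NULL
  bl <- if (length(blocked)) do.call(rbind, blocked) else
    data.frame(particle_id = character(), species = character(),
               entry_frame = integer(), exit_frame = integer(),
               side = character(), stringsAsFactors = FALSE)
  list(particles = data.frame(particle_id = ids, species = spec,
                              lipid_id = NA_character_,
                              residue_id = NA_integer_,
                              stringsAsFactors = FALSE),
       x = do.call(cbind, xs) %||% matrix(0, nf, 0),
       y = do.call(cbind, ys) %||% matrix(0, nf, 0),
       z = do.call(cbind, zs) %||% matrix(0, nf, 0),
       events = ev, blocked = bl)
}

# z path of one activity, first to last flank
activity_z_path <- function(a, cfg, z_out) {
  plane <- cfg$plane_z
  neck <- cfg$neck_interval
  if (a$kind == "event") {
    u <- seq(0, 1, length.out = 5L)
    ramp <- -z_out + 2 * z_out * smoothstep(u)
    ramp[2:4] <- ramp[2:4] + stats::runif(3, -0.3, 0.3)
    if (a$direction == "efflux") ramp else -ramp
  } else {
    jit <- stats::runif(1, 0, 0.5)
    if (a$side == "intracellular") {
      apex <- neck[1] - 0.75 - jit
      c(-z_out, -16, -8, apex, -8, -16, -z_out) +
        c(0, stats::runif(2, -0.4, 0.4), 0, stats::runif(2, -0.4, 0.4), 0)
    } else {
      apex <- min(neck[2] + 0.75 + jit, plane - 2)
      c(z_out, 16, 10, apex, 10, 16, z_out) +
        c(0, stats::runif(2, -0.4, 0.4), 0, stats::runif(2, -0.4, 0.4), 0)
    }
  }
}

realize_one_ion <- function(cfg, ia, nf, z_out) {
  plane <- cfg$plane_z
  bands <- list(intracellular = c(-35, -(plane + 2)),
                extracellular = c(plane + 2, 35))
  x <- rep(-20, nf); y <- rep(0, nf); z <- numeric(nf)
  # entry side of the first activity (or a random side when idle)
  side <- if (!is.null(ia) && length(ia)) {
    a <- ia[[1L]]
    if (a$kind == "event") {
      if (a$direction == "efflux") "intracellular" else "extracellular"
    } else a$side
  } else sample(names(bands), 1L)
  cursor <- 1L
  z_prev <- stats::runif(1, bands[[side]][1], bands[[side]][2])
  fill_bulk <- function(from, to, side, z_start) {
    if (to < from) return(invisible(NULL))
    n <- to - from + 1L
    steps <- stats::rnorm(n, 0, 2)
    z[from:to] <<- fold_into(z_start + cumsum(steps),
                             bands[[side]][1], bands[[side]][2])
  }
  for (a in ia %||% list()) {
    w <- a$window
    entry_side <- if (a$kind == "event") {
      if (a$direction == "efflux") "intracellular" else "extracellular"
    } else a$side
    fill_bulk(cursor, w[1] - 1L, entry_side, z_prev)
    path <- activity_z_path(a, cfg, z_out)
    z[w[1]:w[2]] <- path
    x[w[1]:w[2]] <- 7.5 + stats::runif(1, -2, 2)
    y[w[1]:w[2]] <- stats::runif(1, -2, 2)
    side <- if (a$kind == "event") {
      if (a$direction == "efflux") "extracellular" else "intracellular"
    } else a$side
    z_prev <- path[length(path)]
    cursor <- w[2] + 1L
  }
  fill_bulk(cursor, nf, side, z_prev)
  list(x = x, y = y, z = z)
}

realize_headgroups <- function(cfg, nf) {
  sites <- cfg$headgroup_sites
  n_sites <- if (is.null(sites)) 0L else nrow(sites)
  n_decoy <- cfg$n_decoy_lipids
  n_lip <- n_sites + n_decoy
  if (n_lip == 0L)
    return(list(particles = data.frame(particle_id = character(),
                                       species = character(),
                                       lipid_id = character(),
                                       residue_id = integer(),
                                       stringsAsFactors = FALSE),
                x = matrix(0, nf, 0), y = matrix(0, nf, 0),
                z = matrix(0, nf, 0), orientations = NULL))
  mean_angle <- if (cfg$voltage >= 0) cfg$orientation_mode$mean_pos
                else cfg$orientation_mode$mean_neg
  sd_angle <- cfg$orientation_mode$sd
  ids <- spec <- lip <- character()
  xs <- ys <- zs <- list()
  ori <- list()
  for (i in seq_len(n_lip)) {
    lid <- sprintf("lip%d", i)
    is_decoy <- i > n_sites
    if (is_decoy) {
      # parked far from the pore centre, outside every site
      base <- c(x = 17, y = 18 * sign(stats::runif(1, -1, 1)),
                z = sample(c(-33, 33), 1L))
      px <- rep(base["x"], nf) + stats::rnorm(nf, 0, 0.5)
      py <- rep(base["y"], nf) + stats::rnorm(nf, 0, 0.5)
      pz <- rep(base["z"], nf) + stats::rnorm(nf, 0, 0.5)
      occupied <- rep(FALSE, nf)
    } else {
      s <- sites[i, ]
      occupied <- stats::runif(nf) < s$occupancy
      pz <- ifelse(occupied, stats::rnorm(nf, s$mean_z, s$sd), 34)
      px <- ifelse(occupied, 7.5 + stats::runif(nf, -2, 2), -20)
      py <- ifelse(occupied, stats::runif(nf, -2, 2), 15)
    }
    theta <- pmin(pmax(stats::rnorm(nf, mean_angle, sd_angle), 0.1), 179.9)
    phi <- stats::runif(nf, 0, 2 * pi)
    nx <- px + P_N_DISTANCE * sin(theta * pi / 180) * cos(phi)
    ny <- py + P_N_DISTANCE * sin(theta * pi / 180) * sin(phi)
    nz <- pz + P_N_DISTANCE * cos(theta * pi / 180)
    pid_p <- paste0(lid, "_P"); pid_n <- paste0(lid, "_N")
    ids <- c(ids, pid_p, pid_n)
    spec <- c(spec, "LIPID_P", "LIPID_N")
    lip <- c(lip, lid, lid)
    xs[[pid_p]] <- px; xs[[pid_n]] <- nx
    ys[[pid_p]] <- py; ys[[pid_n]] <- ny
    zs[[pid_p]] <- pz; zs[[pid_n]] <- nz
    ori[[lid]] <- data.frame(lipid_id = lid, frame = seq_len(nf),
                             angle = theta, occupied = occupied,
                             site = if (is_decoy) NA_character_
                                    else sites$name[i],
                             stringsAsFactors = FALSE)
  }
  list(particles = data.frame(particle_id = ids, species = spec,
                              lipid_id = lip, residue_id = NA_integer_,
                              stringsAsFactors = FALSE),
       x = do.call(cbind, xs), y = do.call(cbind, ys),
       z = do.call(cbind, zs),
       orientations = do.call(rbind, ori))
}

realize_waters <- function(cfg, nf) {
  prof <- cfg$water_profile
  means <- prof$mean
  if (cfg$dilated) {
    mids <- prof$edges[-1] - diff(prof$edges) / 2
    in_neck <- mids > cfg$neck_interval[1] & mids < cfg$neck_interval[2]
    n_neck_bins <- max(sum(in_neck), 1L)
    means[in_neck] <- 60 / n_neck_bins    # mean neck count 60 > 45
  }
  nb <- length(means)
  if (nb == 0L || sum(means) == 0)
    return(list(particles = data.frame(particle_id = character(),
                                       species = character(),
                                       lipid_id = character(),
                                       residue_id = integer(),
                                       stringsAsFactors = FALSE),
                x = matrix(0, nf, 0), y = matrix(0, nf, 0),
                z = matrix(0, nf, 0), counts = NULL))
  counts <- matrix(stats::rpois(nf * nb, rep(means, each = nf)), nf, nb)
  totals <- rowSums(counts)
  n_water <- max(totals)
  x <- matrix(-20, nf, n_water)
  y <- matrix(-15, nf, n_water)
  z <- matrix(55, nf, n_water)            # parked outside the ROI
  for (f in seq_len(nf)) {
    tot <- totals[f]
    if (tot == 0L) next
    zb <- rep(seq_len(nb), counts[f, ])
    z[f, seq_len(tot)] <- stats::runif(tot, prof$edges[zb],
                                       prof$edges[zb + 1L])
    x[f, seq_len(tot)] <- stats::runif(tot, 2.5, 12.5)
    y[f, seq_len(tot)] <- stats::runif(tot, -10, 10)
  }
  ids <- sprintf("w%d", seq_len(n_water))
  list(particles = data.frame(particle_id = ids, species = "WATER_O",
                              lipid_id = NA_character_,
                              residue_id = NA_integer_,
                              stringsAsFactors = FALSE),
       x = x, y = y, z = z, counts = counts)
}

#' Self-test a generated frame set against its ground truth
#'
#' Checks that every planted permeation event's track crosses both
#' detection planes around its completion frame and that every planted
#' blocked visit stays on its entry side of the far plane.
#'
#' @param frames `ProtomerFrameSet` from [generate_protomer()].
#' @param truth matching ground-truth list.
#' @param plane_z detection-plane half distance, Angstrom.
#' @return `TRUE` when consistent, otherwise `FALSE`.
#' @export
validate_ground_truth <- function(frames, truth, plane_z = 20) {
  ev <- truth$planted_events
  for (k in seq_len(nrow(ev))) {
    j <- match(ev$particle_id[k], frames$particles$particle_id)
    if (is.na(j)) stop("ground-truth particle not in frame set: ",
                       ev$particle_id[k])
    fr <- ev$completion_frame[k]
    zwin <- frames$z[max(1, fr - 4L):min(length(frames$frame_times), fr), j]
    ok <- if (ev$direction[k] == "efflux")
      min(zwin) <= -plane_z && max(zwin) >= plane_z
    else
      max(zwin) >= plane_z && min(zwin) <= -plane_z
    if (!ok) return(FALSE)
  }
  bl <- truth$planted_blocked_visits
  for (k in seq_len(nrow(bl))) {
    j <- match(bl$particle_id[k], frames$particles$particle_id)
    if (is.na(j)) stop("ground-truth particle not in frame set: ",
                       bl$particle_id[k])
    fr <- bl$entry_frame[k]:bl$exit_frame[k]
    zv <- frames$z[fr, j]
    crossed <- if (bl$side[k] == "intracellular") any(zv >= plane_z)
               else any(zv <= -plane_z)
    if (crossed) return(FALSE)
  }
  TRUE
}

#' Generate a cohort of independent synthetic protomers
#'
#' Child seeds are derived deterministically from the master seed.
#'
#' @param n number of protomers.
#' @param seed master seed.
#' @param ... overrides passed to [synthetic_config()] (applied to every
#'   protomer).
#' @return list of `list(frames, truth)` pairs.
#' @export
generate_cohort <- function(n, seed = 1, ...) {
  lapply(seq_len(n), function(i) {
    child <- (seed + 104729 * i) %% 2147483647L
    cfg <- synthetic_config(seed = as.integer(child), ...)
    out <- generate_protomer(cfg)
    out$frames$protomer_id <- sprintf("protomer%03d", i)
    out
  })
}

# ---------------------------------------------------------------------------
# Blockage-geometry scenario
# ---------------------------------------------------------------------------

#' Generate a protomer for the headgroup-blockage measurement
#'
#' Builds a minimal frame set in which one ion repeatedly visits a
#' localisation site -- permeating through the pore in the open state,
#' turning back in the closed state -- while a headgroup moiety sits in
#' the same site at a planted in-plane distance from the permeation
#' pathway.  The planted distance receives one protomer-level Gaussian
#' offset (`noise_sd`), so a cohort of such protomers has per-protomer
#' mean distances distributed N(distance, noise_sd).
#'
#' @param seed RNG seed.
#' @param site ion [site_definition()] whose sub-slab the visits dwell
#'   in.
#' @param state `"open"` (permeating visits) or `"closed"` (blocked).
#' @param distance planted in-plane moiety-to-pathway distance, Angstrom.
#' @param noise_sd protomer-level distance noise, Angstrom.
#' @param moiety `"LIPID_P"` or `"LIPID_N"`.
#' @param direction `"efflux"` (visits dwell below the site centre) or
#'   `"influx"` (above).
#' @param n_visits visits planted in the trajectory.
#' @param species ion species of the visiting ion.
#' @return list `frames` (a `ProtomerFrameSet`) and
#'   `planted_distance` (the noise-offset distance realised for this
#'   protomer).
#' @export
generate_blockage_protomer <- function(seed, site, state = c("open", "closed"),
                                       distance = 5, noise_sd = 0.5,
                                       moiety = "LIPID_P",
                                       direction = c("efflux", "influx"),
                                       n_visits = 4, species = "NA") {
  state <- match.arg(state)
  direction <- match.arg(direction)
  set.seed(seed)
  zc <- (site$z_lo + site$z_hi) / 2
  dwell <- if (direction == "efflux") zc - 1.25 else zc + 1.25
  d_protomer <- max(distance + stats::rnorm(1, 0, noise_sd), 0.05)
  phi <- stats::runif(1, 0, 2 * pi)
  # pathway anchor: the ion dwells at the pore axis position (7.5, 0)
  ion_xy <- c(7.5, 0)
  visit_len <- 11L
  gap <- 6L
  nf <- n_visits * (visit_len + gap) + gap
  x <- rep(-20, nf); y <- rep(0, nf); z <- rep(-28, nf)
  if (state == "open") {
    path <- c(-28, -15, rep(dwell, 5), c(5, 12, 19.2, 28))
  } else {
    path <- c(-28, -15, rep(dwell, 5), c(-10, -15, -19.2, -28))
  }
  if (direction == "influx") path <- -path
  mx <- rep(-20, nf); my <- rep(15, nf); mz <- rep(34, nf)
  for (v in seq_len(n_visits)) {
    f0 <- gap + (v - 1L) * (visit_len + gap) + 1L
    fr <- f0:(f0 + visit_len - 1L)
    z[fr] <- path
    x[fr] <- ion_xy[1]; y[fr] <- ion_xy[2]
    # moiety present in the site during the whole visit, at the planted
    # in-plane distance (small per-frame jitter averages out within the
    # visit)
    d_f <- d_protomer + stats::rnorm(visit_len, 0, 0.05)
    mx[fr] <- ion_xy[1] + d_f * cos(phi)
    my[fr] <- ion_xy[2] + d_f * sin(phi)
    mz[fr] <- stats::runif(visit_len, site$z_lo, site$z_hi - 0.01)
  }
  particles <- data.frame(
    particle_id = c("pore_ref", "ion1", "moiety1_P", "moiety1_N"),
    species = c("PORE_REF", species, "LIPID_P", "LIPID_N"),
    lipid_id = c(NA, NA, "lip1", "lip1"),
    residue_id = NA_integer_, stringsAsFactors = FALSE)
  keep_moiety <- moiety == "LIPID_P"
  xs <- cbind(0, x, if (keep_moiety) mx else rep(-20, nf),
              if (keep_moiety) rep(-20, nf) else mx)
  ys <- cbind(0, y, if (keep_moiety) my else rep(15, nf),
              if (keep_moiety) rep(15, nf) else my)
  zs <- cbind(0, z, if (keep_moiety) mz else rep(34, nf),
              if (keep_moiety) rep(34, nf) else mz)
  fs <- protomer_frame_set(sprintf("blockage_seed%d", seed), 300,
                           (seq_len(nf) - 1) * 100, particles,
                           xs, ys, zs, analysis_start = 0)
  list(frames = to_protomer_frame(fs), planted_distance = d_protomer)
}
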
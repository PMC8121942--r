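# Ion visit segmentation, permeation-event detection, and single-channel
# conductance statistics.
#
# A pore visit is a maximal run of frames in which an ion lies between the
# two detection planes (|z| < plane_z) and inside the lateral extent of
# the region of interest.  A visit is permeating when the ion came from
# beyond one plane and left beyond the other; otherwise it is blocked.
# Influx is extracellular -> intracellular (+z to -z), efflux the reverse.

#' Segment ion excursions through the pore region into visits
#'
#' Frames before `analysis_start` are discarded first.  Visits truncated
#' by either end of the (windowed) trajectory are classified
#' `blocked_incomplete` and excluded from both permeating and blocked
#' statistics; visits that end because the ion left the ROI laterally are
#' classified blocked and flagged `lateral_exit`.  Displacements flagged
#' as periodic wraps by [to_protomer_frame()] never count as motion
#' through a detection plane.
#'
#' @param fs a `ProtomerFrameSet` in the protomer-local frame.
#' @param roi the analysis [roi_box()].
#' @param plane_z detection-plane half-distance, Angstrom (default 20,
#'   half the membrane thickness); must satisfy `plane_z < roi$dz / 2`.
#' @param species ion species to segment.
#' @return data.frame of visits: `particle_id`, `species`, `entry_frame`,
#'   `exit_frame` (indices into the analysis window), `entry_time`,
#'   `exit_time` (ps), `entry_side`, `exit_side`, `classification`
#'   (`permeating` / `blocked` / `blocked_incomplete`), `direction`
#'   (`influx` / `efflux` / `NA`), `completion_time` (ps, permeating
#'   only), `lateral_exit`.
#' @export
segment_visits <- function(fs, roi = roi_box(), plane_z = 20,
                           species = c("NA", "CL")) {
  if (plane_z <= 0) stop("plane_z must be positive")
  if (plane_z >= roi$dz / 2)
    stop("detection planes (plane_z) must lie inside the ROI (dz/2)")
  fs <- analysis_window(fs)
  nf <- length(fs$frame_times)
  if (nf < 2L) stop("need at least 2 frames after analysis_start")
  cols <- species_cols(fs, species)
  out <- list()
  for (j in cols) {
    zj <- fs$z[, j]
    inside <- abs(zj) < plane_z & in_roi_lateral(fs$x[, j], fs$y[, j], roi)
    runs <- logical_runs(inside)
    if (!nrow(runs)) next
    wrapj <- if (!is.null(fs$wrap)) fs$wrap[, j] else rep(FALSE, nf - 1L)
    for (k in seq_len(nrow(runs))) {
      s <- runs$start[k]; e <- runs$end[k]
      if (s == 1L || e == nf) {
        out[[length(out) + 1L]] <- visit_row(fs, j, s, e,
          entry_side = NA_character_, exit_side = NA_character_,
          classification = "blocked_incomplete", direction = NA_character_,
          completion_time = NA_real_, lateral_exit = FALSE)
        next
      }
      z_prev <- zj[s - 1L]; z_next <- zj[e + 1L]
      wrap_in <- wrapj[s - 1L]; wrap_out <- wrapj[e]
      entry_cross <- !wrap_in && abs(z_prev) >= plane_z
      exit_cross <- !wrap_out && abs(z_next) >= plane_z
      entry_side <- side_of(if (entry_cross) z_prev else zj[s])
      exit_side <- side_of(if (exit_cross) z_next else zj[e])
      lateral_exit <- !exit_cross
      permeating <- entry_cross && exit_cross && entry_side != exit_side
      if (permeating) {
        direction <- if (exit_side == "extracellular") "efflux" else "influx"
        out[[length(out) + 1L]] <- visit_row(fs, j, s, e,
          entry_side = entry_side, exit_side = exit_side,
          classification = "permeating", direction = direction,
          completion_time = fs$frame_times[e + 1L], lateral_exit = FALSE)
      } else {
        out[[length(out) + 1L]] <- visit_row(fs, j, s, e,
          entry_side = entry_side, exit_side = exit_side,
          classification = "blocked", direction = NA_character_,
          completion_time = NA_real_, lateral_exit = lateral_exit)
      }
    }
  }
  if (!length(out)) return(empty_visits())
  do.call(rbind, out)
}

side_of <- function(z) if (z < 0) "intracellular" else "extracellular"

visit_row <- function(fs, j, s, e, ...) {
  data.frame(particle_id = fs$particles$particle_id[j],
             species = fs$particles$species[j],
             entry_frame = s, exit_frame = e,
             entry_time = fs$frame_times[s], exit_time = fs$frame_times[e],
             ..., stringsAsFactors = FALSE)
}

empty_visits <- function() {
  data.frame(particle_id = character(), species = character(),
             entry_frame = integer(), exit_frame = integer(),
             entry_time = numeric(), exit_time = numeric(),
             entry_side = character(), exit_side = character(),
             classification = character(), direction = character(),
             completion_time = numeric(), lateral_exit = logical(),
             stringsAsFactors = FALSE)
}

# start/end indices of runs of TRUE
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Extract completed permeation events from segmented visits
#'
#' @param visits output of [segment_visits()].
#' @return data.frame `particle_id`, `species`, `completion_time` (ps),
#'   `direction`, sorted by completion time.
#' @export
permeation_events <- function(visits) {
  ev <- visits[visits$classification == "permeating",
               c("particle_id", "species", "completion_time", "direction")]
  ev <- ev[order(ev$completion_time), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Mean conductance from a permeation-event stream
#'
#' G_m = N_p * e / (|V| * (t - t1)), where N_p counts events of both ion
#' species, t is the total trajectory time and t1 the time of the first
#' event (the pre-conductive phase is excluded).  Returns `NA` for a
#' protomer with no permeations.
#'
#' @param events data.frame from [permeation_events()].
#' @param voltage transmembrane voltage, mV (sign ignored; must be
#'   non-zero).
#' @param t total trajectory time, ps.
#' @return conductance in pS, or `NA_real_` when no events.
#' @export
mean_conductance <- function(events, voltage, t) {
  if (voltage == 0) stop("voltage must be non-zero")
  n <- nrow(events)
  if (n == 0L) return(NA_real_)
  t1 <- min(events$completion_time)
  if (t <= t1) stop("total time must exceed the first event time")
  # e [C] / (V [V] * t [s]) = S; report pS
  ELEMENTARY_CHARGE * n / (abs(voltage) * 1e-3 * (t - t1) * 1e-12) * 1e12
}

#' Instantaneous conductances and their median
#'
#' G_i = e / (|V| * dt) for every waiting time dt between consecutive
#' permeation events, pooling both ion species.  The median G_i
#' characterises the dominant conductive microstate of the pore and is the
#' quantity compared with experimental single-channel conductances.
#'
#' @inheritParams mean_conductance
#' @param drop_subresolution two events completing within the same
#'   sampling frame have a waiting time of zero at the trajectory's time
#'   resolution; by default this is an error, with
#'   `drop_subresolution = TRUE` such unmeasurable waiting times are
#'   excluded from the G_i list instead.
#' @return list with `G_i` (pS, one per consecutive event pair) and
#'   `median` (pS); both `NA` when fewer than 2 events.
#' @export
instantaneous_conductances <- function(events, voltage,
                                       drop_subresolution = FALSE) {
  if (voltage == 0) stop("voltage must be non-zero")
  if (nrow(events) < 2L) return(list(G_i = numeric(), median = NA_real_))
  tt <- sort(events$completion_time)
  dt <- diff(tt)
  if (any(dt == 0)) {
    if (!drop_subresolution) stop("duplicate event completion times")
    dt <- dt[dt > 0]
    if (!length(dt)) return(list(G_i = numeric(), median = NA_real_))
  }
  g <- ELEMENTARY_CHARGE / (abs(voltage) * 1e-3 * dt * 1e-12) * 1e12
  list(G_i = g, median = stats::median(g))
}

#' Time of the first permeation event
#' @param events data.frame from [permeation_events()].
#' @return ps, or `NA_real_` when no events.
#' @export
time_to_first_event <- function(events) {
  if (nrow(events) == 0L) return(NA_real_)
  min(events$completion_time)
}

#' Assemble the per-protomer conductance record
#'
#' @param fs a `ProtomerFrameSet` (used for id, voltage and total time).
#' @param events data.frame from [permeation_events()].
#' @return list with `protomer_id`, `voltage`, `N_p` (named count per
#'   species), `N_p_total`, `t1`, `G_m`, `G_i`, `G_i_median`.
#' @export
conductance_record <- function(fs, events) {
  w <- analysis_window(fs)
  t_end <- w$frame_times[length(w$frame_times)]
  gi <- instantaneous_conductances(events, fs$voltage,
                                   drop_subresolution = TRUE)
  np <- table(factor(events$species, levels = c("NA", "CL")))
  list(protomer_id = fs$protomer_id,
       voltage = fs$voltage,
       N_p = c(np),
       N_p_total = nrow(events),
       t1 = time_to_first_event(events),
       G_m = mean_conductance(events, fs$voltage, t_end),
       G_i = gi$G_i,
       G_i_median = gi$median)
}

#' Fraction of conductive protomers over a threshold sweep
#'
#' A protomer is conductive at threshold g when its mean conductance is at
#' least g; protomers without any permeation count as nonconductive at
#' every threshold.
#'
#' @param G_m numeric vector of per-protomer mean conductances, pS, with
#'   `NA` for protomers without permeations.
#' @param thresholds numeric vector of thresholds, pS.
#' @return named numeric vector, fraction conductive per threshold.
#' @export
conductive_fraction <- function(G_m, thresholds) {
  if (!length(G_m)) stop("no conductance records")
  if (!length(thresholds)) stop("empty threshold list")
  vapply(thresholds, function(th)
    mean(!is.na(G_m) & G_m >= th), numeric(1)) |>
    stats::setNames(format(thresholds))
}
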
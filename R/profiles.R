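# Distributions along the pore axis: lipid-headgroup densities and
# orientation angles, ion densities by visit class, hydration, neck-region
# inference, dilated-pore exclusion, and site dwell times.
#
# All z profiles use 1-Angstrom bins over [-40, 40] by default; every
# per-protomer density is normalised to unit integral before averaging,
# and the spread across protomers is reported as the standard error of
# the mean.

#' Default 1-Angstrom bin edges over the ROI z extent
#' @param roi a [roi_box()].
#' @param width bin width, Angstrom.
#' @export
z_bins <- function(roi = roi_box(), width = 1) {
  seq(-roi$dz / 2, roi$dz / 2, by = width)
}

# Histogram of values on closed-open bins [e_i, e_{i+1}); returns counts.
bin_counts <- function(values, edges) {
  values <- values[values >= edges[1L] & values < edges[length(edges)]]
  if (!length(values)) return(numeric(length(edges) - 1L))
  idx <- findInterval(values, edges, rightmost.closed = FALSE)
  tabulate(idx, nbins = length(edges) - 1L)
}

# Normalise counts to a probability density (unit integral).
to_density <- function(counts, edges) {
  widths <- diff(edges)
  tot <- sum(counts)
  if (tot == 0) return(rep(NA_real_, length(counts)))
  counts / tot / widths
}

#' Average per-protomer profiles with SEM
#'
#' @param profiles list of equal-length numeric vectors (one per
#'   protomer); `NA` vectors (empty protomers) are dropped.
#' @param edges shared bin edges.
#' @return list `bin_edges`, `mean`, `sem`, `n_protomers`.
#' @export
average_profiles <- function(profiles, edges) {
  keep <- !vapply(profiles, function(p) all(is.na(p)), logical(1))
  profiles <- profiles[keep]
  n <- length(profiles)
  if (n == 0L) stop("no non-empty profiles to average")
  m <- do.call(rbind, profiles)
  mean_p <- colMeans(m)
  sem_p <- if (n > 1L) apply(m, 2L, stats::sd) / sqrt(n) else rep(0, ncol(m))
  list(bin_edges = edges, mean = mean_p, sem = sem_p, n_protomers = n)
}

#' Local probability density of lipid-headgroup atoms along the pore axis
#'
#' Locality follows the published criterion: in every frame only the k
#' atoms of the requested species closest (3D Euclidean distance) to the
#' pore centre contribute (k = 4 for nhTMEM16, 5 for TMEM16K).  Each
#' protomer's histogram is normalised to unit integral, then profiles are
#' averaged with SEM across protomers.
#'
#' @param fs_list list of `ProtomerFrameSet` objects (protomer-local
#'   frame).
#' @param species `"LIPID_P"` or `"LIPID_N"`.
#' @param k number of nearest atoms per frame.
#' @param roi a [roi_box()]; used for the z extent of the histogram.
#' @param width bin width, Angstrom.
#' @return list `bin_edges`, `mean` (density per Angstrom), `sem`,
#'   `n_protomers`.
#' @export
local_headgroup_density <- function(fs_list, species = "LIPID_P", k = 4,
                                    roi = roi_box(), width = 1) {
  stopifnot(k >= 1)
  edges <- z_bins(roi, width)
  profiles <- lapply(fs_list, function(fs) {
    fs <- analysis_window(fs)
    cols <- species_cols(fs, species)
    if (length(cols) < k)
      stop(sprintf("protomer %s has %d %s atoms, need k = %d",
                   fs$protomer_id, length(cols), species, k))
    d2 <- fs$x[, cols, drop = FALSE]^2 + fs$y[, cols, drop = FALSE]^2 +
      fs$z[, cols, drop = FALSE]^2
    zsel <- t(vapply(seq_len(nrow(d2)), function(i) {
      fs$z[i, cols[order(d2[i, ])[seq_len(k)]]]
    }, numeric(k)))
    to_density(bin_counts(as.vector(zsel), edges), edges)
  })
  average_profiles(profiles, edges)
}

#' Lipid headgroup orientation distribution
#'
#' The headgroup orientation is the angle between the phosphorus-to-
#' nitrogen vector and the outward membrane normal (+z): 0 degrees is
#' upright (choline pointing extracellularly), 180 degrees downright.  A
#' headgroup contributes in frames where its P atom lies inside the filter
#' region.  Distributions are normalised per protomer, then averaged.
#'
#' @param fs_list list of `ProtomerFrameSet` objects.
#' @param site optional [site_definition()]; when given, the filter is
#'   P-atom z in `[z_lo, z_hi)` and laterally inside `roi`; otherwise the
#'   whole ROI box.
#' @param roi a [roi_box()].
#' @param width angular bin width, degrees.
#' @return list `bin_edges` (degrees over [0, 180]), `mean` (probability
#'   per bin), `sem`, `n_protomers`.
#' @export
headgroup_angle_distribution <- function(fs_list, site = NULL,
                                         roi = roi_box(), width = 5) {
  edges <- seq(0, 180, by = width)
  profiles <- lapply(fs_list, function(fs) {
    fs <- analysis_window(fs)
    ang <- headgroup_angles(fs, site, roi)
    cnt <- bin_counts(pmin(ang, 180 - 1e-9), edges)
    if (sum(cnt) == 0) return(rep(NA_real_, length(cnt)))
    cnt / sum(cnt)                       # probability per bin
  })
  average_profiles(profiles, edges)
}

# Angles (degrees) of all in-filter headgroup observations of one frame set.
headgroup_angles <- function(fs, site = NULL, roi = roi_box()) {
  p_cols <- species_cols(fs, "LIPID_P")
  n_cols <- species_cols(fs, "LIPID_N")
  p_lip <- fs$particles$lipid_id[p_cols]
  n_lip <- fs$particles$lipid_id[n_cols]
  if (anyNA(p_lip) || anyNA(n_lip))
    stop("headgroup atoms must carry lipid_id to be paired")
  match_n <- match(p_lip, n_lip)
  if (anyNA(match_n)) stop("unpaired LIPID_P atom(s)")
  angles <- c()
  for (i in seq_along(p_cols)) {
    jp <- p_cols[i]; jn <- n_cols[match_n[i]]
    px <- fs$x[, jp]; py <- fs$y[, jp]; pz <- fs$z[, jp]
    keep <- if (is.null(site)) in_roi(px, py, pz, roi)
            else pz >= site$z_lo & pz < site$z_hi & in_roi_lateral(px, py, roi)
    if (!any(keep)) next
    dx <- fs$x[keep, jn] - px[keep]
    dy <- fs$y[keep, jn] - py[keep]
    dz <- fs$z[keep, jn] - pz[keep]
    cosang <- dz / sqrt(dx^2 + dy^2 + dz^2)
    angles <- c(angles, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
  }
  angles
}

#' Ion probability density along the pore axis, by visit class
#'
#' Histograms the z positions sampled by ions during visits of the
#' requested class (permeating or blocked), per protomer, normalised to
#' unit integral and averaged with SEM.
#'
#' @param fs_list list of `ProtomerFrameSet` objects.
#' @param visits_list matching list of [segment_visits()] outputs.
#' @param class `"permeating"` or `"blocked"`.
#' @param species ion species to include.
#' @param voltage_sign `"+"`, `"-"` or `"both"` (default: pool
#'   polarities).
#' @param roi,width histogram geometry.
#' @return list `bin_edges`, `mean`, `sem`, `n_protomers`; `NULL` when no
#'   protomer has a qualifying visit.
#' @export
ion_z_density <- function(fs_list, visits_list,
                          class = c("permeating", "blocked"),
                          species = c("NA", "CL"), voltage_sign = "both",
                          roi = roi_box(), width = 1) {
  class <- match.arg(class)
  stopifnot(length(fs_list) == length(visits_list))
  edges <- z_bins(roi, width)
  profiles <- mapply(function(fs, visits) {
    if (voltage_sign != "both" &&
        (if (fs$voltage >= 0) "+" else "-") != voltage_sign)
      return(rep(NA_real_, length(edges) - 1L))
    fs <- analysis_window(fs)
    v <- visits[visits$classification == class & visits$species %in% species, ,
                drop = FALSE]
    if (!nrow(v)) return(rep(NA_real_, length(edges) - 1L))
    zs <- unlist(lapply(seq_len(nrow(v)), function(i) {
      j <- match(v$particle_id[i], fs$particles$particle_id)
      fs$z[v$entry_frame[i]:v$exit_frame[i], j]
    }))
    to_density(bin_counts(zs, edges), edges)
  }, fs_list, visits_list, SIMPLIFY = FALSE)
  if (all(vapply(profiles, function(p) all(is.na(p)), logical(1))))
    return(NULL)
  average_profiles(profiles, edges)
}

#' Hydration of the extracellular pore section
#'
#' Counts water oxygens with z in [0, 10) Angstrom (the 10-A region
#' starting at the pore centre) and laterally inside the ROI, per frame.
#'
#' @param fs a `ProtomerFrameSet`.
#' @param roi a [roi_box()].
#' @return list `per_frame` (counts) and `mean` over the analysis window.
#' @export
hydration_extracellular <- function(fs, roi = roi_box()) {
  fs <- analysis_window(fs)
  cols <- species_cols(fs, "WATER_O")
  counts <- water_bin_counts(fs, cols, roi, lo = 0, hi = 10)
  list(per_frame = counts, mean = mean(counts))
}

water_bin_counts <- function(fs, cols, roi, lo, hi) {
  if (!length(cols)) return(rep(0L, length(fs$frame_times)))
  inside <- in_roi_lateral(fs$x[, cols, drop = FALSE],
                           fs$y[, cols, drop = FALSE], roi) &
    fs$z[, cols, drop = FALSE] >= lo & fs$z[, cols, drop = FALSE] < hi
  rowSums(inside)
}

#' Pore hydration profile in 1-Angstrom sections
#'
#' Mean number of water molecules per 1-A z section of the pore, averaged
#' per protomer and then across protomers with SEM.
#'
#' @param fs_list list of `ProtomerFrameSet` objects.
#' @param roi a [roi_box()].
#' @param width section width, Angstrom.
#' @return list `bin_edges`, `mean` (water count per section), `sem`,
#'   `n_protomers`.
#' @export
hydration_profile <- function(fs_list, roi = roi_box(), width = 1) {
  edges <- z_bins(roi, width)
  nb <- length(edges) - 1L
  profiles <- lapply(fs_list, function(fs) {
    fs <- analysis_window(fs)
    cols <- species_cols(fs, "WATER_O")
    if (!length(cols)) return(numeric(nb))
    nf <- length(fs$frame_times)
    xin <- in_roi_lateral(fs$x[, cols, drop = FALSE],
                          fs$y[, cols, drop = FALSE], roi)
    zz <- fs$z[, cols, drop = FALSE]
    sel <- xin & zz >= edges[1L] & zz < edges[nb + 1L]
    bin <- findInterval(zz[sel], edges, rightmost.closed = FALSE)
    frame <- row(zz)[sel]
    tabulate((frame - 1L) * nb + bin, nbins = nf * nb) |>
      matrix(nrow = nb) |> rowMeans()
  })
  average_profiles(profiles, edges)
}

#' Infer the neck region from the blocked-ion density
#'
#' The neck is the pore section that blocked ions essentially never
#' sample: the contiguous run of bins with density below
#' `epsilon_frac * max(density)` that contains z = 0 or abuts it on the
#' extracellular side.
#'
#' @param blocked_density result of [ion_z_density()] for blocked ions.
#' @param epsilon_frac "negligible" threshold as a fraction of the peak
#'   density (default 0.01).
#' @return list `z_lo`, `z_hi` (Angstrom), or `NULL` when no qualifying
#'   gap exists.
#' @export
find_neck <- function(blocked_density, epsilon_frac = 0.01) {
  if (is.null(blocked_density)) stop("empty blocked-ion density")
  d <- blocked_density$mean
  edges <- blocked_density$bin_edges
  low <- d < epsilon_frac * max(d, na.rm = TRUE)
  low[is.na(low)] <- TRUE
  runs <- logical_runs(low)
  if (!nrow(runs)) return(NULL)
  centre_bin <- findInterval(0, edges, rightmost.closed = FALSE)
  for (k in seq_len(nrow(runs))) {
    if (runs$start[k] <= centre_bin + 1L && runs$end[k] >= centre_bin)
      return(list(z_lo = edges[runs$start[k]], z_hi = edges[runs$end[k] + 1L]))
  }
  NULL
}

#' Dilated-pore exclusion
#'
#' Protomers whose mean water count in the neck region exceeds `limit`
#' (strictly more than 45 by default) represent an artificially dilated,
#' leaky pore and are excluded from all distributions.
#'
#' @param fs a `ProtomerFrameSet`.
#' @param neck list `z_lo`, `z_hi` from [find_neck()] (or fixed bounds).
#' @param limit water-count threshold (exclude when mean > limit).
#' @param roi a [roi_box()].
#' @return list `keep` (logical), `mean_neck_waters`.
#' @export
filter_dilated <- function(fs, neck, limit = 45, roi = roi_box()) {
  if (is.null(neck)) stop("neck region undefined")
  fsw <- analysis_window(fs)
  cols <- species_cols(fsw, "WATER_O")
  counts <- water_bin_counts(fsw, cols, roi, lo = neck$z_lo, hi = neck$z_hi)
  m <- mean(counts)
  list(keep = !(m > limit), mean_neck_waters = m)
}

#' Dwell times of a moiety at a localisation site
#'
#' A dwell is a maximal run of frames with the particle inside the site's
#' z interval and laterally inside the ROI; its duration is the run
#' length times the sampling interval.
#'
#' @param fs a `ProtomerFrameSet`.
#' @param site a [site_definition()].
#' @param roi a [roi_box()].
#' @return list `durations` (ps, one per dwell over all particles of the
#'   site's moiety) and `max` (ps; `NA` when never occupied).
#' @export
dwell_times <- function(fs, site, roi = roi_box()) {
  fs <- analysis_window(fs)
  cols <- species_cols(fs, site$moiety)
  durations <- numeric()
  for (j in cols) {
    occ <- fs$z[, j] >= site$z_lo & fs$z[, j] < site$z_hi &
      in_roi_lateral(fs$x[, j], fs$y[, j], roi)
    runs <- logical_runs(occ)
    if (nrow(runs))
      durations <- c(durations,
                     (runs$end - runs$start + 1L) * fs$sampling_interval)
  }
  list(durations = durations,
       max = if (length(durations)) max(durations) else NA_real_)
}
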
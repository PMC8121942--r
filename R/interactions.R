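# Headgroup-blockage geometry, contact probabilities, hydration-shell
# radii from radial distribution functions, and pore RMSD.

#' Mean in-plane position of the permeation pathway at a site
#'
#' Averages the x and y coordinates of permeating ions over every frame
#' they spend inside the site's z interval, pooled over all visits in all
#' supplied protomers.  This point anchors all in-plane blockage
#' distances.
#'
#' @param fs_list list of `ProtomerFrameSet` objects.
#' @param visits_list matching list of [segment_visits()] outputs.
#' @param site a [site_definition()] (an ion site).
#' @param species ion species to pool.
#' @return list `x`, `y` (Angstrom), `n_points`; `NULL` when no
#'   permeating visit intersects the site.
#' @export
mean_pathway_point <- function(fs_list, visits_list, site,
                               species = c("NA", "CL")) {
  xs <- ys <- numeric()
  for (i in seq_along(fs_list)) {
    fs <- analysis_window(fs_list[[i]])
    v <- visits_list[[i]]
    v <- v[v$classification == "permeating" & v$species %in% species, ,
           drop = FALSE]
    for (k in seq_len(nrow(v))) {
      j <- match(v$particle_id[k], fs$particles$particle_id)
      fr <- v$entry_frame[k]:v$exit_frame[k]
      zz <- fs$z[fr, j]
      sel <- zz >= site$z_lo & zz < site$z_hi
      xs <- c(xs, fs$x[fr, j][sel])
      ys <- c(ys, fs$y[fr, j][sel])
    }
  }
  if (!length(xs)) return(NULL)
  list(x = mean(xs), y = mean(ys), n_points = length(xs))
}

#' In-plane headgroup-to-pathway distances during ion visits
#'
#' Implements the blockage-geometry measurement: for every ion visit of
#' the requested class that reaches the 2.5-Angstrom sub-slab above
#' (influx) or below (efflux) the site's z centre, and during which at
#' least one atom of the moiety is present in the site, the minimum
#' in-plane (xy) distance from the moiety to the mean permeation pathway
#' point is recorded per frame and averaged over the visit.  Visit values
#' are then averaged per protomer, yielding one data point per protomer.
#'
#' @param fs_list list of `ProtomerFrameSet` objects.
#' @param visits_list matching list of [segment_visits()] outputs.
#' @param site an ion [site_definition()].
#' @param moiety `"LIPID_P"` or `"LIPID_N"`.
#' @param direction `"influx"` (sub-slab above the site centre) or
#'   `"efflux"` (below).
#' @param class `"permeating"` (open pore state) or `"blocked"` (closed).
#' @param pathway optional precomputed [mean_pathway_point()]; defaults
#'   to computing it from the permeating visits of `fs_list`.
#' @param species ion species considered.
#' @param roi a [roi_box()].
#' @return data.frame `protomer_id`, `mean_distance` (Angstrom),
#'   `n_visits`; protomers without qualifying visits are omitted.
#' @export
blockage_distances <- function(fs_list, visits_list, site,
                               moiety = c("LIPID_P", "LIPID_N"),
                               direction = c("influx", "efflux"),
                               class = c("permeating", "blocked"),
                               pathway = NULL, species = c("NA", "CL"),
                               roi = roi_box()) {
  moiety <- match.arg(moiety)
  direction <- match.arg(direction)
  class <- match.arg(class)
  if (is.null(pathway))
    pathway <- mean_pathway_point(fs_list, visits_list, site, species)
  if (is.null(pathway)) stop("permeation pathway undefined for this site")
  zc <- (site$z_lo + site$z_hi) / 2
  slab <- if (direction == "influx") c(zc, zc + 2.5) else c(zc - 2.5, zc)
  rows <- list()
  for (i in seq_along(fs_list)) {
    fs <- analysis_window(fs_list[[i]])
    mcols <- species_cols(fs, moiety)
    v <- visits_list[[i]]
    v <- v[v$classification == class & v$species %in% species, , drop = FALSE]
    visit_vals <- numeric()
    for (k in seq_len(nrow(v))) {
      j <- match(v$particle_id[k], fs$particles$particle_id)
      fr <- v$entry_frame[k]:v$exit_frame[k]
      zz <- fs$z[fr, j]
      if (!any(zz >= slab[1] & zz <= slab[2])) next
      # per visit frame: minimum in-plane moiety distance to the pathway,
      # over moiety atoms present in the site
      dists <- vapply(fr, function(f) {
        mz <- fs$z[f, mcols]
        present <- mz >= site$z_lo & mz < site$z_hi &
          in_roi_lateral(fs$x[f, mcols], fs$y[f, mcols], roi)
        if (!any(present)) return(NA_real_)
        min(sqrt((fs$x[f, mcols][present] - pathway$x)^2 +
                   (fs$y[f, mcols][present] - pathway$y)^2))
      }, numeric(1))
      if (all(is.na(dists))) next
      visit_vals <- c(visit_vals, mean(dists, na.rm = TRUE))
    }
    if (length(visit_vals))
      rows[[length(rows) + 1L]] <- data.frame(
        protomer_id = fs$protomer_id,
        mean_distance = mean(visit_vals),
        n_visits = length(visit_vals), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(protomer_id = character(), mean_distance = numeric(),
                      n_visits = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Contact probability between a site moiety and protein residues
#'
#' For each residue, the fraction of site-occupancy frames (frames in
#' which at least one moiety atom lies in the site and laterally in the
#' ROI) in which the minimum distance between any in-site moiety atom and
#' any atom of the residue is at most `cutoff`.
#'
#' @param fs a `ProtomerFrameSet` containing moiety tracks and protein
#'   tracks carrying `residue_id`.
#' @param site a [site_definition()].
#' @param cutoff direct-contact distance, Angstrom (default 4.0).
#' @param roi a [roi_box()].
#' @return data.frame `residue_id`, `probability`, plus attribute
#'   `n_occupancy_frames`.
#' @export
contact_probability <- function(fs, site, cutoff = 4.0, roi = roi_box()) {
  if (cutoff <= 0) stop("cutoff must be positive")
  fs <- analysis_window(fs)
  mcols <- species_cols(fs, site$moiety)
  pcols <- which(!is.na(fs$particles$residue_id))
  if (!length(pcols)) stop("no residue-labelled tracks present")
  resids <- sort(unique(fs$particles$residue_id[pcols]))
  present <- fs$z[, mcols, drop = FALSE] >= site$z_lo &
    fs$z[, mcols, drop = FALSE] < site$z_hi &
    in_roi_lateral(fs$x[, mcols, drop = FALSE],
                   fs$y[, mcols, drop = FALSE], roi)
  occ_frames <- which(rowSums(present) > 0)
  if (!length(occ_frames)) stop("site never occupied by its moiety")
  prob <- vapply(resids, function(rid) {
    rcols <- pcols[fs$particles$residue_id[pcols] == rid]
    hit <- vapply(occ_frames, function(f) {
      mc <- mcols[present[f, ]]
      dmin <- min(outer_dist2(fs, f, mc, rcols))
      sqrt(dmin) <= cutoff
    }, logical(1))
    mean(hit)
  }, numeric(1))
  out <- data.frame(residue_id = resids, probability = prob)
  attr(out, "n_occupancy_frames") <- length(occ_frames)
  out
}

# squared distances between two particle-column sets in one frame
outer_dist2 <- function(fs, f, cols_a, cols_b) {
  outer(fs$x[f, cols_a], fs$x[f, cols_b], "-")^2 +
    outer(fs$y[f, cols_a], fs$y[f, cols_b], "-")^2 +
    outer(fs$z[f, cols_a], fs$z[f, cols_b], "-")^2
}

#' Ion-water radial distribution function and first-shell radius
#'
#' Shell-volume-normalised pair histogram of ion to water-oxygen
#' distances, normalised so that a uniform ideal gas gives g(r) = 1
#' within `r_max`.  The first-shell radius is the first local minimum
#' after the first maximum of the 3-bin moving-average-smoothed g(r).
#'
#' @param fs a `ProtomerFrameSet`.
#' @param ion_species `"NA"` or `"CL"`.
#' @param bin histogram bin width, Angstrom (default 0.05).
#' @param r_max maximum distance, Angstrom (default 8).
#' @return list `r` (bin centres), `g` (raw), `g_smooth`,
#'   `first_shell_radius` (Angstrom, `NA` when g(r) is featureless).
#' @export
rdf_first_shell <- function(fs, ion_species = "NA", bin = 0.05, r_max = 8) {
  fs <- analysis_window(fs)
  icols <- species_cols(fs, ion_species)
  wcols <- species_cols(fs, "WATER_O")
  if (!length(icols) || !length(wcols))
    stop("need at least one ion and one water track")
  edges <- seq(0, r_max, by = bin)
  counts <- numeric(length(edges) - 1L)
  for (f in seq_along(fs$frame_times)) {
    d <- sqrt(outer_dist2(fs, f, icols, wcols))
    counts <- counts + bin_counts(d[d < r_max], edges)
  }
  if (sum(counts) == 0) stop("no ion-water pairs within r_max")
  centres <- edges[-1L] - bin / 2
  shell_vol <- 4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  dens <- counts / shell_vol
  rho <- sum(counts) / (4 / 3 * pi * r_max^3)
  g <- dens / rho
  g_smooth <- stats::filter(g, rep(1 / 3, 3), sides = 2)
  g_smooth[is.na(g_smooth)] <- g[is.na(g_smooth)]
  g_smooth <- as.numeric(g_smooth)
  list(r = centres, g = g, g_smooth = g_smooth,
       first_shell_radius = first_minimum_after_peak(centres, g_smooth,
                                                     counts))
}

# First-shell boundary: the first local minimum after the first genuine
# peak of the smoothed g(r).  Hydration-shell peaks of ion-water RDFs
# stand far above the bulk level and their first minimum is much deeper
# than the peak, so we require g_peak >= 1.5 with adequate pair
# statistics (>= 20 sampled pairs in the peak bin) and g_min below 30%
# of the peak with a later recovery; noise ripples on a featureless g(r)
# then never qualify.  A flat minimum (an empty gap between shells)
# returns the centre of the plateau.
first_minimum_after_peak <- function(r, g, counts = NULL) {
  n <- length(g)
  if (n < 5L) return(NA_real_)
  maxima <- which(vapply(2:(n - 1L), function(i)
    g[i] >= g[i - 1L] && g[i] >= g[i + 1L], logical(1))) + 1L
  maxima <- maxima[g[maxima] >= 1.5]
  if (!is.null(counts)) maxima <- maxima[counts[maxima] >= 20]
  if (!length(maxima)) return(NA_real_)
  p1 <- maxima[1L]
  for (i in (p1 + 1L):(n - 1L)) {
    is_min <- g[i] <= g[i - 1L] && g[i] <= g[i + 1L]
    deep <- g[i] < 0.3 * g[p1]
    if (is_min && deep && any(g[(i + 1L):n] >= g[i] + 0.25 * g[p1])) {
      # centre of the plateau of near-minimal bins around i
      tol <- g[i] + 0.02 * g[p1]
      lo <- i; while (lo > p1 + 1L && g[lo - 1L] <= tol) lo <- lo - 1L
      hi <- i; while (hi < n && g[hi + 1L] <= tol) hi <- hi + 1L
      return(mean(r[c(lo, hi)]))
    }
  }
  NA_real_
}

#' Hydration-shell retention across the neck
#'
#' Mean water-oxygen coordination (count within `shell_radius` of the
#' ion) of permeating ions, separately over neck-resident frames and over
#' bulk frames (|z| > neck extent), per species.
#'
#' @param fs a `ProtomerFrameSet`.
#' @param visits [segment_visits()] output for `fs`.
#' @param neck list `z_lo`, `z_hi`.
#' @param shell_radius first-shell radius, Angstrom (3.0 for Na+, 3.8 for
#'   Cl-).
#' @param species ion species.
#' @return list `neck` (mean coordination over neck frames), `bulk`,
#'   `n_neck_frames`, `n_bulk_frames`.
#' @export
shell_retention <- function(fs, visits, neck, shell_radius,
                            species = "NA") {
  stopifnot(shell_radius > 0)
  if (is.null(neck)) stop("neck region undefined")
  fs <- analysis_window(fs)
  wcols <- species_cols(fs, "WATER_O")
  v <- visits[visits$classification == "permeating" &
                visits$species == species, , drop = FALSE]
  coord_neck <- coord_bulk <- numeric()
  for (k in seq_len(nrow(v))) {
    j <- match(v$particle_id[k], fs$particles$particle_id)
    fr <- v$entry_frame[k]:v$exit_frame[k]
    for (f in fr) {
      d2 <- (fs$x[f, wcols] - fs$x[f, j])^2 +
        (fs$y[f, wcols] - fs$y[f, j])^2 +
        (fs$z[f, wcols] - fs$z[f, j])^2
      cnt <- sum(d2 <= shell_radius^2)
      if (fs$z[f, j] >= neck$z_lo && fs$z[f, j] < neck$z_hi)
        coord_neck <- c(coord_neck, cnt)
      else
        coord_bulk <- c(coord_bulk, cnt)
    }
  }
  if (!length(coord_neck)) stop("no neck-resident frames among permeating visits")
  list(neck = mean(coord_neck),
       bulk = if (length(coord_bulk)) mean(coord_bulk) else NA_real_,
       n_neck_frames = length(coord_neck),
       n_bulk_frames = length(coord_bulk))
}

#' Pore-region RMSD time series
#'
#' Root-mean-square deviation of the pore-lining C-alpha atoms (residues
#' in `ranges`) from a reference structure, per frame.  With
#' `fit = TRUE` each frame is least-squares superposed onto the reference
#' (Kabsch) before measuring; the default relies on the upstream global
#' transmembrane fit.
#'
#' @param fs a `ProtomerFrameSet` with `PROTEIN_CA` tracks carrying
#'   `residue_id`.
#' @param reference matrix `n_atoms x 3` of reference coordinates for the
#'   selected residues, ordered by residue_id.
#' @param ranges data.frame `lo`, `hi` of residue intervals (see
#'   [pore_residue_ranges()]).
#' @param fit superpose each frame onto the reference first.
#' @return list `frame_times`, `rmsd` (Angstrom per frame), `residues`.
#' @export
pore_rmsd <- function(fs, reference, ranges, fit = FALSE) {
  cols <- species_cols(fs, "PROTEIN_CA")
  rid <- fs$particles$residue_id[cols]
  wanted <- sort(unique(unlist(mapply(seq, ranges$lo, ranges$hi,
                                      SIMPLIFY = FALSE))))
  missing <- setdiff(wanted, rid)
  if (length(missing))
    stop("missing residues: ", paste(utils::head(missing, 5), collapse = ", "))
  sel <- cols[match(wanted, rid)]
  if (nrow(reference) != length(sel))
    stop("reference has ", nrow(reference), " atoms, selection has ",
         length(sel))
  rmsd <- vapply(seq_along(fs$frame_times), function(f) {
    m <- cbind(fs$x[f, sel], fs$y[f, sel], fs$z[f, sel])
    if (fit) m <- kabsch_superpose(m, reference)
    sqrt(mean(rowSums((m - reference)^2)))
  }, numeric(1))
  list(frame_times = fs$frame_times, rmsd = rmsd, residues = wanted)
}

# Least-squares superposition of m onto ref (both n x 3), returning the
# transformed copy of m.
kabsch_superpose <- function(m, ref) {
  cm <- colMeans(m); cr <- colMeans(ref)
  a <- sweep(m, 2, cm); b <- sweep(ref, 2, cr)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(a %*% t(rot), 2, cr, "+")
}
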
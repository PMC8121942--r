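# Particle-track containers and the canonical tab-separated track format.

#' Elementary charge in coulomb
#'
#' Used by all conductance conversions.
#' @export
ELEMENTARY_CHARGE <- 1.602176634e-19

#' Species labels understood by the pipeline
#' @export
TRACK_SPECIES <- c("NA", "CL", "CA", "WATER_O", "LIPID_P", "LIPID_N",
                   "PROTEIN_CA", "PORE_REF")

#' Construct a per-protomer frame set
#'
#' A `ProtomerFrameSet` holds every particle track of one protomer at one
#' signed voltage, sampled on a common, uniformly spaced time grid.
#' Positions are stored as `n_frames x n_particles` matrices so that all
#' downstream operations are vectorised over frames.
#'
#' The coordinate convention is protomer-local: the pore-centre reference
#' atom sits at the origin of every frame (see [to_protomer_frame()]), the
#' outward membrane normal is +z, and +x points toward the protein
#' periphery.  The transmembrane voltage is signed,
#' V = phi_intracellular - phi_extracellular, so positive voltage drives
#' cation efflux (intracellular -> extracellular, i.e. -z -> +z).
#'
#' @param protomer_id character scalar.
#' @param voltage signed transmembrane voltage in mV (non-zero for any
#'   conduction analysis).
#' @param frame_times numeric vector of frame times in ps, strictly
#'   increasing with uniform spacing.
#' @param particles data.frame with columns `particle_id`, `species`,
#'   `lipid_id`, `residue_id` (the last two may be `NA`).
#' @param x,y,z numeric matrices, `length(frame_times)` rows and
#'   `nrow(particles)` columns, coordinates in Angstrom.
#' @param analysis_start ps; frames before this time are excluded from all
#'   statistical analyses (default 1e5 ps = 100 ns, the equilibration
#'   window discarded for production trajectories; synthetic data
#'   generated by [generate_protomer()] sets it to 0).
#' @param box_z periodic box extent along z in Angstrom (used only to flag
#'   periodic wraps).
#' @return object of class `ProtomerFrameSet`.
#' @export
protomer_frame_set <- function(protomer_id, voltage, frame_times,
                               particles, x, y, z,
                               analysis_start = 1e5, box_z = 160) {
  stopifnot(is.character(protomer_id), length(protomer_id) == 1L)
  frame_times <- as.numeric(frame_times)
  n_frames <- length(frame_times)
  if (n_frames < 1L) stop("frame_times is empty")
  if (n_frames > 1L) {
    dts <- diff(frame_times)
    if (any(dts <= 0)) stop("frame times must be strictly increasing")
    if (max(abs(dts - dts[1L])) > 1e-6 * dts[1L])
      stop("non-uniform frame spacing: ",
           paste(utils::head(unique(round(dts, 6)), 3L), collapse = ", "))
  }
  req <- c("particle_id", "species", "lipid_id", "residue_id")
  missing_cols <- setdiff(req, names(particles))
  if (length(missing_cols))
    stop("particles is missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(particles$species), TRACK_SPECIES)
  if (length(bad)) stop("unknown species label: ", paste(bad, collapse = ", "))
  if (anyDuplicated(particles$particle_id))
    stop("duplicate particle_id")
  np <- nrow(particles)
  for (m in list(x, y, z))
    if (!is.matrix(m) || nrow(m) != n_frames || ncol(m) != np)
      stop("coordinate matrices must be n_frames x n_particles")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("non-finite coordinates")
  structure(list(
    protomer_id = protomer_id,
    voltage = as.numeric(voltage),
    frame_times = frame_times,
    sampling_interval = if (n_frames > 1L) frame_times[2L] - frame_times[1L] else NA_real_,
    analysis_start = analysis_start,
    box_z = box_z,
    particles = particles,
    x = x, y = y, z = z,
    wrap = NULL       # set by to_protomer_frame()
  ), class = "ProtomerFrameSet")
}

#' @export
print.ProtomerFrameSet <- function(x, ...) {
  cat(sprintf("ProtomerFrameSet '%s': %d particles x %d frames (%g ps spacing), V = %g mV\n",
              x$protomer_id, nrow(x$particles), length(x$frame_times),
              x$sampling_interval, x$voltage))
  tab <- table(x$particles$species)
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Total trajectory time of a frame set, in ps
#' @param fs a `ProtomerFrameSet`
#' @export
total_time <- function(fs) {
  ft <- fs$frame_times
  ft[length(ft)] - ft[1L]
}

#' Column indices of particles of one or more species
#' @param fs a `ProtomerFrameSet`
#' @param species character vector of species labels.
#' @export
species_cols <- function(fs, species) {
  which(fs$particles$species %in% species)
}

#' Restrict a frame set to its analysis window
#'
#' Drops all frames with time < `analysis_start`.  Operations computing
#' distributions or event statistics call this first.
#' @param fs a `ProtomerFrameSet`
#' @export
analysis_window <- function(fs) {
  keep <- fs$frame_times >= fs$analysis_start
  if (all(keep)) return(fs)
  if (!any(keep)) stop("analysis_start is beyond the last frame")
  sub_frames(fs, which(keep))
}

sub_frames <- function(fs, idx) {
  fs$frame_times <- fs$frame_times[idx]
  fs$x <- fs$x[idx, , drop = FALSE]
  fs$y <- fs$y[idx, , drop = FALSE]
  fs$z <- fs$z[idx, , drop = FALSE]
  if (!is.null(fs$wrap)) {
    # wrap[i, ] flags the displacement frame i -> i+1; keep flags internal
    # to the retained (contiguous) index range
    if (length(idx) > 1L) {
      fs$wrap <- fs$wrap[idx[-length(idx)], , drop = FALSE]
    } else {
      fs$wrap <- NULL
    }
  }
  fs
}

# ---------------------------------------------------------------------------
# Canonical track TSV
#
# One row per (frame, particle); columns frame_time_ps, particle_id,
# species, lipid_id, residue_id, x, y, z.  Coordinates serialised at
# 0.001 A precision.  First line carries the format version.  Reading and
# writing are gzip-transparent (a ".gz" suffix triggers compression).
# ---------------------------------------------------------------------------

TRACK_FORMAT_HEADER <- "#ionpore-tracks\tv1"

track_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a frame set to the canonical track TSV
#'
#' The canonical format is long: one row per (frame, particle) with columns
#' `frame_time_ps`, `particle_id`, `species`, `lipid_id`, `residue_id`,
#' `x`, `y`, `z`.  Coordinates are printed at 0.001 Angstrom precision, so
#' a write/read/write cycle is byte-identical.
#'
#' @param fs a `ProtomerFrameSet`.
#' @param path output file; a `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(fs, path) {
  np <- nrow(fs$particles)
  nf <- length(fs$frame_times)
  df <- data.frame(
    frame_time_ps = rep(fs$frame_times, each = np),
    particle_id = rep(fs$particles$particle_id, nf),
    species = rep(fs$particles$species, nf),
    lipid_id = rep(as.character(fs$particles$lipid_id), nf),
    residue_id = rep(fs$particles$residue_id, nf),
    x = sprintf("%.3f", as.vector(t(fs$x))),
    y = sprintf("%.3f", as.vector(t(fs$y))),
    z = sprintf("%.3f", as.vector(t(fs$z))),
    stringsAsFactors = FALSE)
  con <- track_connection(path, "wb")
  on.exit(close(con))
  meta <- sprintf("#meta\tprotomer_id=%s\tvoltage_mV=%s\tanalysis_start_ps=%s\tbox_z_A=%s",
                  fs$protomer_id, format(fs$voltage), format(fs$analysis_start),
                  format(fs$box_z))
  writeLines(c(TRACK_FORMAT_HEADER, meta,
               paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a frame set from the canonical track TSV
#'
#' @param path canonical track file (optionally gzip).
#' @param voltage override the stored voltage (mV); required if the file
#'   carries none.
#' @return a `ProtomerFrameSet`.
#' @export
read_tracks <- function(path, voltage = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- track_connection(path, "rt")
  on.exit(close(con))
  head1 <- readLines(con, n = 1L)
  if (!identical(head1, TRACK_FORMAT_HEADER))
    stop("not a canonical track file (bad version line): ", path)
  meta_line <- readLines(con, n = 1L)
  meta <- parse_track_meta(meta_line)
  df <- utils::read.table(con, sep = "\t", header = TRUE,
                          colClasses = c("numeric", "character", "character",
                                         "character", "integer",
                                         "numeric", "numeric", "numeric"),
                          na.strings = ".")
  frame_times <- unique(df$frame_time_ps)
  pid <- unique(df$particle_id)
  nf <- length(frame_times); np <- length(pid)
  if (nrow(df) != nf * np)
    stop("track file is ragged: not every particle present in every frame")
  first <- df[seq_len(np), ]
  particles <- data.frame(particle_id = first$particle_id,
                          species = first$species,
                          lipid_id = first$lipid_id,
                          residue_id = first$residue_id,
                          stringsAsFactors = FALSE)
  shape <- function(v) matrix(v, nrow = nf, ncol = np, byrow = TRUE)
  v <- if (!is.null(voltage)) voltage else meta$voltage
  protomer_frame_set(meta$protomer_id, v, frame_times, particles,
                     shape(df$x), shape(df$y), shape(df$z),
                     analysis_start = meta$analysis_start,
                     box_z = meta$box_z)
}

parse_track_meta <- function(line) {
  if (!startsWith(line, "#meta"))
    stop("canonical track file lacks the #meta line")
  kv <- strsplit(strsplit(line, "\t")[[1]][-1], "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  list(protomer_id = unname(vals[["protomer_id"]]),
       voltage = as.numeric(vals[["voltage_mV"]]),
       analysis_start = as.numeric(vals[["analysis_start_ps"]]),
       box_z = as.numeric(vals[["box_z_A"]]))
}

# ---------------------------------------------------------------------------
# Adapter for standard MD formats (PDB topology + DCD trajectory via bio3d)
# ---------------------------------------------------------------------------

#' Load tracks from a PDB topology plus DCD trajectory
#'
#' Thin adapter over `bio3d` for converting standard MD output into a
#' `ProtomerFrameSet`.  Selections map atom ranges of the topology onto
#' pipeline species; each selection is a list with elements `species` and
#' either `indices` (atom serial indices) or `elety`/`resid` filters as
#' understood by [bio3d::atom.select()].  A `PORE_REF` selection resolving
#' to exactly one atom is mandatory.  The trajectory is assumed to be
#' already least-squares fitted on the transmembrane region upstream;
#' [to_protomer_frame()] then applies the translation to the pore centre
#' and the optional flip.
#'
#' @param topology path to a PDB file.
#' @param trajectory path to a DCD file.
#' @param selections named list of selection specs (see above).
#' @param voltage signed transmembrane voltage, mV.
#' @param protomer_id identifier for the resulting frame set.
#' @param sampling_interval ps between trajectory frames.
#' @param ... passed to [protomer_frame_set()] (`analysis_start`, `box_z`).
#' @return a `ProtomerFrameSet` in the laboratory frame.
#' @export
load_tracks_md <- function(topology, trajectory, selections, voltage,
                           protomer_id = "protomer1",
                           sampling_interval = 100, ...) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("the MD-format adapter requires the 'bio3d' package")
  if (!("PORE_REF" %in% names(selections)))
    stop("selections must include PORE_REF")
  pdb <- bio3d::read.pdb(topology)
  xyz <- bio3d::read.dcd(trajectory, verbose = FALSE)
  cols <- list(); ids <- character(); spec <- character()
  lip <- character(); res <- integer()
  for (nm in names(selections)) {
    sel <- selections[[nm]]
    species <- if (!is.null(sel$species)) sel$species else nm
    if (!is.null(sel$indices)) {
      idx <- sel$indices
    } else {
      args <- sel[setdiff(names(sel), c("species", "indices"))]
      idx <- do.call(bio3d::atom.select, c(list(pdb), args))$atom
    }
    if (!length(idx)) stop("empty selection: ", nm)
    if (species == "PORE_REF" && length(idx) != 1L)
      stop("PORE_REF selection must resolve to exactly one atom")
    cols <- c(cols, as.list(idx))
    ids <- c(ids, paste0(nm, "_", seq_along(idx)))
    spec <- c(spec, rep(species, length(idx)))
    lip <- c(lip, rep(if (is.null(sel$lipid_id)) NA_character_ else sel$lipid_id,
                      length(idx)))
    res <- c(res, if (species == "PROTEIN_CA") pdb$atom$resno[idx]
             else rep(NA_integer_, length(idx)))
  }
  idx <- unlist(cols)
  nf <- nrow(xyz)
  particles <- data.frame(particle_id = ids, species = spec,
                          lipid_id = lip, residue_id = res,
                          stringsAsFactors = FALSE)
  pick <- function(k) xyz[, 3 * (idx - 1) + k, drop = FALSE]
  protomer_frame_set(protomer_id, voltage,
                     frame_times = (seq_len(nf) - 1) * sampling_interval,
                     particles = particles,
                     x = pick(1), y = pick(2), z = pick(3), ...)
}
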
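# Region-of-interest geometry, the protomer-local frame, and the built-in
# site tables.

#' Region-of-interest box around the pore centre
#'
#' The analysis region is a box of extents `dx x dy x dz` built around the
#' pore-centre reference atom, symmetric in y and z but shifted along +x
#' toward the protein periphery to exclude the dimer interface.  With the
#' defaults (25 x 40 x 80 A, shift +7.5 A) the box covers
#' x in [-5, 20], y in [-20, 20], z in [-40, 40] A.
#'
#' @param dx,dy,dz box extents in Angstrom.
#' @param x_shift shift of the box centre along the periphery direction, A.
#' @export
roi_box <- function(dx = 25, dy = 40, dz = 80, x_shift = 7.5) {
  stopifnot(dx > 0, dy > 0, dz > 0)
  structure(list(dx = dx, dy = dy, dz = dz, x_shift = x_shift),
            class = "RoiBox")
}

#' @export
print.RoiBox <- function(x, ...) {
  cat(sprintf("RoiBox %g x %g x %g A, x in [%g, %g], y in [%g, %g], z in [%g, %g]\n",
              x$dx, x$dy, x$dz,
              x$x_shift - x$dx / 2, x$x_shift + x$dx / 2,
              -x$dy / 2, x$dy / 2, -x$dz / 2, x$dz / 2))
  invisible(x)
}

#' Point-in-ROI test
#'
#' Boundaries are closed on both sides.
#' @param x,y,z coordinates (vectorised), Angstrom, pore-centre frame.
#' @param roi a [roi_box()].
#' @return logical vector.
#' @export
in_roi <- function(x, y, z, roi = roi_box()) {
  in_roi_lateral(x, y, roi) & z >= -roi$dz / 2 & z <= roi$dz / 2
}

#' Lateral (x, y) part of the ROI test
#' @inheritParams in_roi
#' @export
in_roi_lateral <- function(x, y, roi = roi_box()) {
  x >= roi$x_shift - roi$dx / 2 & x <= roi$x_shift + roi$dx / 2 &
    y >= -roi$dy / 2 & y <= roi$dy / 2
}

#' Transform a frame set into the protomer-local frame
#'
#' Translates every frame so that the pore-centre reference atom sits at
#' the origin, and (for the second membrane copy of a CompEL stack, whose
#' outward normal points along -z in the laboratory frame) rotates the
#' protomer by 180 degrees about the x axis so that +z is always the
#' outward membrane normal.  The x axis (periphery direction) is preserved
#' by this rotation; callers whose periphery direction differs must align
#' it upstream.
#'
#' After centring, z displacements between consecutive frames larger than
#' half the periodic box are flagged as periodic wraps in the `wrap`
#' element (an `(n_frames - 1) x n_particles` logical matrix); visit
#' segmentation never lets a flagged displacement count as motion through
#' the pore.
#'
#' @param fs a `ProtomerFrameSet` in the laboratory frame, containing
#'   exactly one `PORE_REF` track.
#' @param flip logical; `TRUE` for the membrane copy whose outward normal
#'   is -z in the laboratory frame.
#' @return the frame set in the protomer-local frame.
#' @export
to_protomer_frame <- function(fs, flip = FALSE) {
  ref <- species_cols(fs, "PORE_REF")
  if (length(ref) != 1L)
    stop("frame set must contain exactly one PORE_REF track")
  fs$x <- fs$x - fs$x[, ref]
  fs$y <- fs$y - fs$y[, ref]
  fs$z <- fs$z - fs$z[, ref]
  if (flip) {          # 180 deg rotation about x: proper isometry
    fs$y <- -fs$y
    fs$z <- -fs$z
  }
  if (length(fs$frame_times) > 1L) {
    dz <- diff(fs$z)
    fs$wrap <- abs(dz) > fs$box_z / 2
  }
  fs
}

#' Minimum-image displacement along the periodic z axis
#'
#' @param dz raw displacements, Angstrom.
#' @param box_z periodic extent, Angstrom.
#' @return displacement wrapped into (-box_z/2, box_z/2].
#' @export
minimum_image_dz <- function(dz, box_z) {
  dz - box_z * round(dz / box_z)
}

# ---------------------------------------------------------------------------
# Localisation sites
# ---------------------------------------------------------------------------

#' Define a localisation site along the pore axis
#'
#' A site is a named z interval `[z_lo, z_hi)` relative to the pore centre
#' occupied preferentially by one moiety (lipid phosphorus/nitrogen or an
#' ion species).
#'
#' @param name site label (e.g. `"p_c"`).
#' @param z_lo,z_hi interval bounds in Angstrom, closed-open.
#' @param moiety one of `"LIPID_P"`, `"LIPID_N"`, `"NA"`, `"CL"`.
#' @export
site_definition <- function(name, z_lo, z_hi, moiety) {
  stopifnot(z_lo < z_hi,
            moiety %in% c("LIPID_P", "LIPID_N", "NA", "CL"))
  structure(list(name = name, z_lo = z_lo, z_hi = z_hi, moiety = moiety),
            class = "SiteDefinition")
}

#' Built-in localisation-site tables
#'
#' z ranges (Angstrom, relative to the pore centre) of the lipid-headgroup
#' and ion localisation sites of the fungal (nhTMEM16) and human (TMEM16K)
#' scramblase pores.
#'
#' @param protein `"nhTMEM16"` or `"TMEM16K"`.
#' @return named list of [site_definition()] objects.
#' @export
default_sites <- function(protein = c("nhTMEM16", "TMEM16K")) {
  protein <- match.arg(protein)
  tab <- if (protein == "nhTMEM16") list(
    site_definition("p_c",  -3,   7, "LIPID_P"),
    site_definition("n_c",  -5,   0, "LIPID_N"),
    site_definition("p_e",   7,  17, "LIPID_P"),
    site_definition("n_e",   5,  10, "LIPID_N"),
    site_definition("Cl_v", -16, -1, "CL"),
    site_definition("Cl_e",   2, 17, "CL"),
    site_definition("Na_i", -25, -15, "NA"),
    site_definition("Na_v",  -8,   2, "NA"),
    site_definition("Na_e",   5,  15, "NA")
  ) else list(
    site_definition("p1", -15, -10, "LIPID_P"),
    site_definition("p2",  -8,  -2, "LIPID_P"),
    site_definition("p3",   0,   5, "LIPID_P"),
    site_definition("p4",  10,  15, "LIPID_P"),
    site_definition("n0", -18, -13, "LIPID_N"),
    site_definition("n1", -12,  -7, "LIPID_N"),
    site_definition("n2",  -4,   1, "LIPID_N"),
    site_definition("n3",   4,   9, "LIPID_N"),
    site_definition("n4",   8,  13, "LIPID_N"),
    site_definition("n5",  13,  18, "LIPID_N"),
    site_definition("Na_i", -20, -10, "NA"),
    site_definition("Na_c", -10,   0, "NA"),
    site_definition("Na_e",   4,  12, "NA")
  )
  stats::setNames(tab, vapply(tab, `[[`, "", "name"))
}

#' Pore-region residue ranges for RMSD
#'
#' C-alpha residue intervals defining the pore region of each protein.
#' @param protein `"nhTMEM16"` or `"TMEM16K"`.
#' @return data.frame with columns `lo`, `hi`.
#' @export
pore_residue_ranges <- function(protein = c("nhTMEM16", "TMEM16K")) {
  protein <- match.arg(protein)
  if (protein == "nhTMEM16")
    data.frame(lo = c(293, 327, 374, 431, 501, 524),
               hi = c(317, 348, 390, 453, 518, 543))
  else
    data.frame(lo = c(320, 355, 404, 426, 496, 518),
               hi = c(349, 377, 420, 449, 511, 538))
}

#' Read a pipeline configuration file
#'
#' YAML configuration naming ROI dimensions, site tables and per-protomer
#' voltages.  Every omitted key falls back to the built-in default (which
#' equals the published value).
#'
#' @param path YAML file.
#' @return list with elements `roi` (a [roi_box()]), `sites` (named list
#'   of [site_definition()]), `voltages` (named numeric, mV) and any
#'   further keys verbatim.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  roi_args <- cfg$roi %||% list()
  roi <- do.call(roi_box, roi_args)
  sites <- if (!is.null(cfg$sites)) {
    stats::setNames(lapply(cfg$sites, function(s)
      site_definition(s$name, s$z_lo, s$z_hi, s$moiety)),
      vapply(cfg$sites, `[[`, "", "name"))
  } else default_sites(cfg$protein %||% "nhTMEM16")
  out <- cfg
  out$roi <- roi
  out$sites <- sites
  out$voltages <- unlist(cfg$voltages)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
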
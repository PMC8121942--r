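#!/usr/bin/env Rscript
# Distributions along the pore axis: local headgroup densities (k = 4
# nearest P/N atoms), headgroup orientation angles per voltage polarity,
# permeating/blocked ion densities, the hydration profile, the inferred
# neck region, and the dilated-pore exclusion report.
#
# Writes: results/headgroup_density.tsv, results/angle_distribution.tsv,
#         results/ion_density.tsv, results/hydration_profile.tsv,
#         results/neck.tsv, results/dilation_report.tsv

source("analysis/00_cohort.R")

cohort <- build_cohort()
fsl <- lapply(cohort, `[[`, "frames")
vl <- lapply(fsl, segment_visits)

profile_rows <- function(p, what, group) {
  lo <- p$bin_edges[-length(p$bin_edges)]
  data.frame(what = what, group = group, bin_lo = lo,
             bin_hi = p$bin_edges[-1], mean = p$mean, sem = p$sem,
             n = p$n_protomers)
}

# dilation screen first: dilated protomers are excluded from averages
neck_guess <- list(z_lo = 0, z_hi = 7)
dil <- do.call(rbind, lapply(fsl, function(fs) {
  d <- filter_dilated(fs, neck_guess)
  data.frame(protomer_id = fs$protomer_id, keep = d$keep,
             mean_neck_waters = d$mean_neck_waters)
}))
write_tsv(dil, "dilation_report.tsv")
keep <- dil$keep
fsl <- fsl[keep]; vl <- vl[keep]
message(sprintf("%d of %d protomers kept after dilation screen",
                sum(keep), length(keep)))

dens <- rbind(
  profile_rows(local_headgroup_density(fsl, "LIPID_P", k = 4), "P_density",
               "all"),
  profile_rows(local_headgroup_density(fsl, "LIPID_N", k = 4), "N_density",
               "all"))
write_tsv(dens, "headgroup_density.tsv")

sign_of <- vapply(fsl, function(f) if (f$voltage >= 0) "+" else "-", "")
ang <- do.call(rbind, lapply(c("+", "-"), function(sg) {
  a <- headgroup_angle_distribution(fsl[sign_of == sg])
  profile_rows(a, "angle", sg)
}))
write_tsv(ang, "angle_distribution.tsv")

ion <- rbind(
  profile_rows(ion_z_density(fsl, vl, "permeating"), "ion_permeating",
               "all"),
  profile_rows(ion_z_density(fsl, vl, "blocked"), "ion_blocked", "all"))
write_tsv(ion, "ion_density.tsv")

hyd <- hydration_profile(fsl)
write_tsv(profile_rows(hyd, "water_count", "all"), "hydration_profile.tsv")

blocked <- ion_z_density(fsl, vl, "blocked")
neck <- find_neck(blocked)
write_tsv(data.frame(z_lo = neck$z_lo, z_hi = neck$z_hi,
                     extent_A = neck$z_hi - neck$z_lo), "neck.tsv")
message(sprintf(
  "neck region: [%g, %g) A, extending %g A from the pore centre",
  neck$z_lo, neck$z_hi, neck$z_hi - neck$z_lo))

ext <- vapply(fsl, function(fs) hydration_extracellular(fs)$mean, 0)
message(sprintf("extracellular hydration (z in [0,10)): %.1f +- %.1f waters",
                mean(ext), sem(ext)))
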
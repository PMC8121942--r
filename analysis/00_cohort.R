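# Shared study-cohort definition for the analysis scripts.
#
# The cohort emulates a CompEL production campaign on a fully open
# scramblase: 8 protomers at +300 mV and 8 at -300 mV, 1 us per
# protomer at 100-ps sampling, with the default planted conduction,
# headgroup and hydration regimes.  Scripts regenerate the cohort from
# its seeds instead of passing bulky track files around; generation is
# deterministic, so every script sees identical data.

suppressPackageStartupMessages(library(ionpore))

COHORT_SEED <- 20260922L
N_PER_SIGN <- 8L
N_FRAMES <- 10000L

build_cohort <- function() {
  pos <- generate_cohort(N_PER_SIGN, seed = COHORT_SEED,
                         n_frames = N_FRAMES, voltage = 300)
  neg <- generate_cohort(N_PER_SIGN, seed = COHORT_SEED + 1L,
                         n_frames = N_FRAMES, voltage = -300)
  for (i in seq_along(pos))
    pos[[i]]$frames$protomer_id <- sprintf("pos%02d", i)
  for (i in seq_along(neg))
    neg[[i]]$frames$protomer_id <- sprintf("neg%02d", i)
  c(pos, neg)
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}

write_tsv <- function(df, name) {
  path <- file.path(results_dir(), name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  path
}
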
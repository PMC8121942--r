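---
title: "Methods: ion permeation analysis of proteolipidic scramblase pores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ion permeation analysis of proteolipidic scramblase pores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionpore)
```

## The measurement problem

TMEM16 lipid scramblases conduct ions through a proteolipidic pore: the
membrane-exposed subunit cavity of each protomer, lined jointly by
protein residues and the headgroups of lipids that engage the cavity
while being scrambled. In computational-electrophysiology (CompEL)
simulations a sustained voltage drives Na+ and Cl− through this pore,
and the analysis task is to turn raw particle tracks into conduction
statistics: who crossed, how often, how selectively, and how the lipid
headgroups arrange around and interfere with the ion pathway.

`ionpore` implements that chain for per-protomer tracks sampled on a
uniform 100-ps grid. This vignette records the model assumptions, the
parameters that matter, and the design decisions taken where several
reasonable conventions exist.

## Coordinate conventions and the region of interest

All analyses run in a protomer-local frame: the pore-centre reference
atom (the Cα of S382 in nhTMEM16, C412 in TMEM16K) is translated to the
origin in every frame, the outward membrane normal is +z, and +x points
toward the protein periphery. For the second membrane copy of a CompEL
stack, whose outward normal points along −z in the laboratory frame,
`to_protomer_frame(flip = TRUE)` applies a 180° rotation about the x
axis — a proper isometry that preserves the periphery direction. The
transmembrane voltage is signed per protomer,
V = Φ_intracellular − Φ_extracellular, so positive voltage drives cation
efflux; how the periphery direction is identified per protomer is left
to the caller, since it depends on the upstream fit.

The region of interest (ROI) is a 25 × 40 × 80 Å box around the pore
centre, symmetric in y and z but shifted +7.5 Å along x to exclude the
dimer interface: x ∈ [−5, 20], y ∈ [−20, 20], z ∈ [−40, 40] Å. Box
boundaries are treated as closed. Displacements along z larger than half
the periodic box extent are flagged as periodic wraps and never count as
motion through the pore; no x/y periodicity handling is needed because
the ROI is interior to the box.

Tracks move through a canonical tab-separated format (one row per frame
and particle, coordinates at 0.001 Å precision, gzip-transparent) whose
write–read–write cycle is byte-identical. A thin adapter converts
PDB topology + DCD trajectory pairs via `bio3d`; trajectories are
assumed to be least-squares fitted on the transmembrane region upstream,
as is standard practice, so the adapter only translates and optionally
flips.

## Permeation events and conductance

An ion *visit* is a maximal run of frames with |z| < 20 Å (the detection
planes, half a typical membrane thickness; configurable) and laterally
inside the ROI. A visit is *permeating* when the flanking frames lie
beyond opposite planes — influx is extracellular → intracellular, efflux
the reverse — and its completion time is the first frame beyond the far
plane. A visit whose flanks lie on the same side is *blocked*. Two edge
cases are resolved conservatively: visits truncated by either end of the
trajectory are `blocked_incomplete` and excluded from both classes, and
visits that end by lateral ROI exit are blocked and flagged, since their
fate is unobservable.

Conductances follow the two standard estimators:

- mean conductance `G_m = N_p·e / (|V|·(t − t1))`, with N_p the pooled
  event count of both species, t the trajectory time and t1 the first
  event time (the pre-conductive phase is excluded);
- instantaneous conductance `G_i = e / (|V|·Δt)` per waiting time
  between consecutive events, pooling species; the median G_i reports
  the microstate that contributes most to conduction and is less
  sensitive to the open probability than G_m.

The magnitude of V is used; its sign is metadata. With events observed
on a 100-ps grid, two crossings can complete in the same frame; their
waiting time is then below the time resolution and
`conductance_record()` excludes it from the G_i list rather than
reporting an infinite conductance (the low-level
`instantaneous_conductances()` keeps the strict error as its default
contract). Protomers without events get `NA` conductances and count as
nonconductive in threshold sweeps.

## Selectivity

The permeability ratio is the count ratio `P_Na/P_Cl = G_Na/G_Cl` at the
end of a trajectory, classified into five classes with the boundaries
of the standard class definitions (≥ 10, [2, 10), (0.5, 2),
(0.1, 0.5], ≤ 0.1); a protomer with fewer than five total events is
`insufficient` and never classified. An infinite ratio (G_Cl = 0) is
Na+-selective, consistently with the ≥ 10 interval. "Weighted over the
protomers" is implemented as pooled event counts, Σ G_Na / Σ G_Cl —
equivalent to weighting per-protomer ratios by their Cl− counts — and
the unweighted mean of finite per-protomer ratios is reported alongside,
labelled, since the exact weighting convention behind published pooled
ratios is not stated.

## Distributions along the pore axis

All z profiles use 1-Å bins over the ROI ([−40, 40] Å), and all angular
distributions 5° bins — the resolution scale of the corresponding
figure panels; both are configurable. Every per-protomer histogram is
normalised to unit integral before averaging, and the spread across
protomers is the standard error of the mean; the first 100 ns of
production trajectories are excluded (`analysis_start`), while synthetic
data carry no equilibration transient and set it to 0.

Specific conventions:

- *Local headgroup density*: per frame, only the k P or N atoms closest
  to the pore centre contribute (k = 4 in nhTMEM16, 5 in TMEM16K);
  "closest" is 3D Euclidean distance, the natural reading when no metric
  is stated. The profile is invariant to adding atoms beyond the k-th
  nearest.
- *Headgroup orientation*: the angle between the P→N vector (the
  phosphocholine convention) and the outward normal, 0° upright,
  180° downright.
  A headgroup contributes when its P atom is inside the filter region.
- *Ion densities by class*: z positions sampled during permeating or
  blocked visits; polarities are pooled by default with a per-sign
  option.
- *Hydration*: water-oxygen counts per 1-Å section, and the
  extracellular hydration as the count with z ∈ [0, 10) Å inside the
  ROI.
- *Neck region*: the contiguous run of bins with blocked-ion density
  below 1% of the profile peak (the operational reading of
  "negligible"; configurable) containing or abutting the pore centre on
  the extracellular side.
- *Dilated pores*: protomers whose mean neck water count exceeds 45 —
  strictly more than 45 — represent an
  artificial, electroporation-like state and are excluded whole; the
  window mean is used rather than per-frame exclusion, which is offered
  behind a flag.
- *Dwell times*: contiguous site-residence runs times the sampling
  interval.

## Blockage geometry

The ion permeation pathway at a localisation site is the (x, y) average
of permeating-ion positions over all in-site visit frames, pooled over
all protomers of a condition before any per-protomer measurement. For
each qualifying ion visit — one that reaches the 2.5-Å sub-slab above
(influx) or below (efflux) the site centre — and each frame in which the
moiety is present in the site, the minimum in-plane distance from the
moiety atoms to the pathway point is taken, averaged over the visit, and
visit values are averaged per protomer: one data point per independent
protomer, computed separately for permeating (open state) and blocked
(closed state) visits. Open/closed state assignment is per protomer,
species and direction: open iff at least one permeating visit exists in
the window, closed iff blocked visits exist and no permeating ones.

## Structural utilities

Ion–water RDFs use 0.05-Å bins to 8 Å with a 3-bin moving average before
the minimum search. The first-shell radius is the first local minimum
after the first genuine peak; because g(r) from finite sampling is noisy
at small r, a peak must rise clearly above the bulk level (g ≥ 1.5, at
least 20 sampled pairs) and the minimum must fall below 30% of the peak
with a later recovery — criteria comfortably met by real ion hydration
shells (first minima of ion–water RDFs lie far below half peak height)
and never by a featureless gas. A flat minimum (an empty gap) returns
the centre of its plateau. Contact probabilities use a 4.0-Å
heavy-atom minimum-distance cutoff, a standard direct-contact criterion,
in the absence of a stated one; probabilities are monotone in the cutoff by
construction. Pore RMSD uses the published Cα residue ranges per
protein, by default without per-frame re-fitting (the upstream
transmembrane fit is trusted), with optional Kabsch superposition.

## The CompEL controller

The charge imbalance q = Q_A − Q_B between the two compartments is
sampled every 10 ps and averaged over a 100-ps window (10 samples); when
the full-window mean deviates from the reference dQ by more than one
elementary charge, one ion of the correcting species is swapped between
compartments, paired with a notional water. When either species could
correct the deviation, the species with the larger total count is chosen
(ties broken alphabetically), and at most one swap is emitted per check.
A monovalent swap changes q by exactly 2e and conserves per-species
totals.

One dynamical subtlety is handled explicitly: after a swap, the samples
already in the window still reflect the pre-correction imbalance, and a
controller that keeps acting on them oscillates around the reference
indefinitely (each correction triggers the next). `apply_swap()`
therefore flushes the averaging window, so the controller accumulates a
full window of post-correction samples before it can act again. Under
Poisson permeation disturbances the windowed imbalance then stays within
±2e of dQ after warm-up.

## The synthetic generator

Raw MD trajectories underlying the published analyses are archived
off-site and not deposited, so the pipeline is validated on synthetic
tracks that reproduce the *statistical* structure the analysis assumes —
never the physics (no force field, no electrostatics, no lipid tails):

- crossings arrive per species and direction with exponential waiting
  times at configurable rates (defaults 2/10/1/4 events per µs for Na+
  influx/efflux and Cl− influx/efflux — a moderately cation-selective,
  efflux-dominated regime of the order seen at a few hundred mV), each
  realised as a smooth cubic ramp in z across 5 frames inside the ROI;
- blocked visits penetrate to the neck boundary and return through the
  entry plane;
- between activities ions perform reflected Gaussian steps (sd
  2 Å/frame) in bulk bands outside the detection planes and laterally
  outside the ROI;
- one headgroup per configured localisation site jitters about the site
  mean z (default sites at z = 2, 12, −12, 17 Å, sd 1.5 Å, occupancy
  0.9), with the P→N vector at 4.5 Å (typical phosphocholine geometry)
  and the polar angle drawn from a clipped normal whose mean follows
  the voltage sign (40° at positive, 140° at negative voltage);
  far-away decoy pairs exercise the k-nearest locality;
- water counts are Poisson per 1-Å bin about a profile with 8 waters
  per section and a depleted neck ([0, 7) Å, 1 water per section);
  dilated protomers inflate the neck mean to 60 (> 45);
- all randomness derives from one master seed (child seeds for
  cohorts), so equal seeds give byte-identical track files.

Every planted quantity — events, blocked visits, per-frame orientations,
per-bin water counts — is returned as ground truth, and
`validate_ground_truth()` self-checks each generated protomer. Because
crossing ramps sample z coarsely (completion is what matters
downstream), a dedicated scenario builder
(`generate_blockage_protomer()`) plants visits that dwell in a site's
2.5-Å sub-slab together with a moiety at a planted in-plane distance
(one protomer-level Gaussian offset), which is what the blockage
pipeline needs for end-to-end validation.

What passing these tests shows — and does not. Oracle equivalence on
synthetic data demonstrates that the detectors and estimators implement
their definitions exactly and recover planted signals at realistic
sizes. It cannot certify upstream steps the generator bypasses
(trajectory fitting quality, force-field adequacy, sampling convergence
of real MD), nor regimes the generator does not emulate (correlated
multi-ion conduction, sub-frame recrossings, headgroup flips coupled to
ion passage).

## Statistics

Group comparisons use the one-sided Mann–Whitney U test, U from rank
sums with midranks for ties, exact by full enumeration when
n1 + n2 ≤ 12 without ties and by normal approximation with tie and
continuity corrections otherwise (the method used is always labelled).
Boxplot-style summaries report the median, quartile hinges and 5th/95th
percentile whiskers under the linear-interpolation quantile convention,
recorded in the output. No multiple-testing correction is applied; raw
one-sided p-values are reported.

## Problem sizes

The test suite and the acceptance script size their simulations to keep
full runs in the minutes range while leaving comfortable statistical
margins: 200 protomers of 0.2 µs for detector–oracle equivalence, one
10-µs protomer for conductance-estimator recovery, 50 protomers for
site-mode recovery, 200 replicates of the 15-vs-15 blockage comparison,
10,000 null simulations for the Mann–Whitney size, and 10^6 controller
checks. The analysis scripts use a 16-protomer, 1-µs-per-protomer
cohort, regenerated deterministically from its seeds rather than stored.

## Known limitations

- Species are hard-wired to monovalent Na+/Cl− in the conductance and
  CompEL modules; Ca2+ tracks are carried but not analysed.
- The trajectory adapter reads PDB + DCD; other MD formats should be
  converted to the canonical TSV upstream.
- The generator plants at most one activity per ion at a time and
  rejects configurations whose activity load cannot be scheduled.
- Blocked-ion densities assume the planted two-sided visit structure
  when used for neck inference; a pore blocked on one side only yields
  a one-sided gap that `find_neck()` reports as abutting the centre.
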
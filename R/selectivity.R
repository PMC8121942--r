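# Na+/Cl- permeability ratios and selectivity classification.
#
# The permeability ratio is the ratio of permeation counts,
# P_Na/P_Cl = G_Na / G_Cl, where G is the number of permeations of each
# species by the end of a trajectory.  Classes follow the published
# intervals:
#   Na+ selective            P_Na/P_Cl >= 10
#   moderately Na+ selective P_Na/P_Cl in [2, 10)
#   nonselective             P_Na/P_Cl in (0.5, 2)
#   moderately Cl- selective P_Na/P_Cl in (0.1, 0.5]
#   Cl- selective            P_Na/P_Cl <= 0.1
# Protomers with fewer than `min_events` total permeations (default 5)
# are labelled "insufficient" regardless of the ratio.

#' Permeability ratio from permeation counts
#'
#' @param g_na,g_cl permeation counts (non-negative).
#' @return `g_na / g_cl`; `Inf` when `g_cl == 0` and `g_na > 0`;
#'   `NA_real_` when both are zero.
#' @export
permeability_ratio <- function(g_na, g_cl) {
  if (g_na < 0 || g_cl < 0) stop("permeation counts must be non-negative")
  if (g_cl == 0) {
    if (g_na == 0) return(NA_real_)
    return(Inf)
  }
  g_na / g_cl
}

#' Selectivity class labels
#' @export
SELECTIVITY_CLASSES <- c("Na_selective", "moderately_Na", "nonselective",
                         "moderately_Cl", "Cl_selective", "insufficient")

#' Classify a permeability ratio into a selectivity class
#'
#' @param ratio value from [permeability_ratio()] (may be `Inf` or `NA`).
#' @param total_events total permeation count (both species).
#' @param min_events minimum event count for classification (default 5).
#' @return one of [SELECTIVITY_CLASSES].
#' @export
classify_selectivity <- function(ratio, total_events, min_events = 5) {
  if (total_events < min_events) return("insufficient")
  if (is.na(ratio)) return("insufficient")
  if (ratio >= 10) return("Na_selective")   # Inf falls here
  if (ratio >= 2) return("moderately_Na")
  if (ratio > 0.5) return("nonselective")
  if (ratio > 0.1) return("moderately_Cl")
  "Cl_selective"
}

#' Protomer-weighted permeability ratio
#'
#' Pools permeation counts over protomers before taking the ratio
#' (sum G_Na / sum G_Cl), i.e. each protomer contributes with the weight
#' of its event count.  The unweighted mean of the per-protomer finite
#' ratios is returned alongside for comparison.
#'
#' @param g_na,g_cl integer vectors of per-protomer counts.
#' @return list with `pooled` (event-count-weighted ratio) and
#'   `mean_ratio` (unweighted mean of finite per-protomer ratios, `NA`
#'   when none).
#' @export
weighted_ratio <- function(g_na, g_cl) {
  stopifnot(length(g_na) == length(g_cl), length(g_na) >= 1)
  pooled <- permeability_ratio(sum(g_na), sum(g_cl))
  per <- mapply(permeability_ratio, g_na, g_cl)
  finite <- per[is.finite(per)]
  list(pooled = pooled,
       mean_ratio = if (length(finite)) mean(finite) else NA_real_)
}

#' Build the per-protomer selectivity table
#'
#' @param records list of conductance records (see
#'   [conductance_record()]).
#' @param min_events minimum total event count for classification.
#' @return data.frame `protomer_id`, `voltage`, `voltage_sign`, `G_Na`,
#'   `G_Cl`, `ratio`, `class`.
#' @export
selectivity_table <- function(records, min_events = 5) {
  rows <- lapply(records, function(r) {
    g_na <- unname(r$N_p["NA"]); g_cl <- unname(r$N_p["CL"])
    ratio <- permeability_ratio(g_na, g_cl)
    data.frame(protomer_id = r$protomer_id,
               voltage = r$voltage,
               voltage_sign = ifelse(r$voltage >= 0, "+", "-"),
               G_Na = g_na, G_Cl = g_cl, ratio = ratio,
               class = classify_selectivity(ratio, g_na + g_cl, min_events),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
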
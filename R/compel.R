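# Computational-electrophysiology (CompEL) charge-imbalance controller.
#
# In a CompEL double-membrane system the transmembrane voltage is imposed
# by maintaining a reference charge imbalance dQ between the two aqueous
# compartments.  The imbalance is checked every 10 ps and averaged over a
# 100-ps window; an ion (paired with a notional water) is swapped between
# compartments only when the windowed average deviates from dQ by more
# than one elementary charge.  This module implements the controller over
# compartment ion inventories, decoupled from any particle dynamics.

SPECIES_CHARGE <- c("NA" = 1, "CL" = -1)

#' Initialise a CompEL controller state
#'
#' @param counts_a,counts_b named integer vectors of ion counts per
#'   species (names in `"NA"`, `"CL"`) in compartments A and B.
#' @param dq reference charge imbalance, elementary charges, defined as
#'   Q_A - Q_B.
#' @param check_interval ps between imbalance checks (default 10).
#' @param averaging_window ps over which checks are averaged (default
#'   100).
#' @return object of class `CompelState`.
#' @export
compel_state <- function(counts_a, counts_b, dq,
                         check_interval = 10, averaging_window = 100) {
  stopifnot(all(names(counts_a) %in% names(SPECIES_CHARGE)),
            identical(sort(names(counts_a)), sort(names(counts_b))),
            averaging_window %% check_interval == 0)
  structure(list(
    counts_a = counts_a[sort(names(counts_a))],
    counts_b = counts_b[sort(names(counts_b))],
    dq = dq,
    check_interval = check_interval,
    window_len = as.integer(averaging_window / check_interval),
    window = numeric(0),          # most recent q samples, oldest first
    swap_log = list()
  ), class = "CompelState")
}

#' Instantaneous charge imbalance of a controller state
#'
#' q = Q_A - Q_B in elementary charges.
#' @param state a `CompelState`.
#' @export
charge_imbalance <- function(state) {
  ch <- SPECIES_CHARGE[names(state$counts_a)]
  sum(ch * (state$counts_a - state$counts_b))
}

#' One controller check
#'
#' Appends the instantaneous imbalance sample to the averaging window;
#' once the window is full and the windowed mean deviates from the
#' reference dQ by more than one elementary charge, emits a directive
#' moving one ion of the correcting species between compartments.  When
#' either species could correct the deviation, the one with the larger
#' total count is chosen (ties broken alphabetically by species name).
#' At most one swap is emitted per check.
#'
#' @param state a `CompelState`.
#' @param t current time, ps (must be a multiple of `check_interval`).
#' @param instantaneous_q current imbalance sample, elementary charges;
#'   defaults to the imbalance implied by the inventories.
#' @return list `state` (updated) and `directive` (`NULL` or a list
#'   `species`, `from`, `to`, `time`).
#' @export
step_controller <- function(state, t, instantaneous_q = charge_imbalance(state)) {
  if (abs(t / state$check_interval - round(t / state$check_interval)) > 1e-9)
    stop("t must be aligned to the check interval")
  state$window <- c(state$window, instantaneous_q)
  if (length(state$window) > state$window_len)
    state$window <- state$window[-1L]
  directive <- NULL
  if (length(state$window) == state$window_len) {
    dev <- mean(state$window) - state$dq
    if (abs(dev) > 1) {
      # dev > 0: q too high, lower Q_A - Q_B: cation A->B or anion B->A
      # dev < 0: raise it: cation B->A or anion A->B
      cation_from <- if (dev > 0) "a" else "b"
      candidates <- list(
        list(species = "NA", from = cation_from,
             to = setdiff(c("a", "b"), cation_from)),
        list(species = "CL", from = setdiff(c("a", "b"), cation_from),
             to = cation_from))
      feasible <- Filter(function(cand) {
        pool <- if (cand$from == "a") state$counts_a else state$counts_b
        !is.na(pool[cand$species]) && pool[cand$species] >= 1
      }, candidates)
      if (length(feasible)) {
        totals <- vapply(feasible, function(cand)
          sum(state$counts_a[cand$species], state$counts_b[cand$species],
              na.rm = TRUE), numeric(1))
        best <- order(-totals, vapply(feasible, `[[`, "", "species"))[1L]
        directive <- feasible[[best]]
        directive$time <- t
      }
    }
  }
  list(state = state, directive = directive)
}

#' Apply a swap directive to the controller state
#'
#' Moves one ion of the directive's species between compartments (paired
#' with a notional water molecule moving the opposite way, which carries
#' no charge and is not tracked).  Total per-species counts are
#' conserved; the swap is appended to the log.  The averaging window is
#' flushed, so the controller must accumulate a full window of
#' post-correction samples before acting again: without this debounce
#' the stale pre-swap samples keep the windowed mean deviated and the
#' controller oscillates around the reference.
#'
#' @param state a `CompelState`.
#' @param directive list `species`, `from`, `to`, `time` as emitted by
#'   [step_controller()].
#' @return the updated `CompelState`.
#' @export
apply_swap <- function(state, directive) {
  if (is.null(directive)) return(state)
  sp <- directive$species
  src <- if (directive$from == "a") "counts_a" else "counts_b"
  dst <- if (directive$to == "a") "counts_a" else "counts_b"
  if (state[[src]][sp] < 1)
    stop("source compartment has no ", sp, " ion to swap")
  state[[src]][sp] <- state[[src]][sp] - 1L
  state[[dst]][sp] <- state[[dst]][sp] + 1L
  state$swap_log[[length(state$swap_log) + 1L]] <- directive
  state$window <- numeric(0)
  state
}

#' Run the CompEL controller under a Poisson permeation disturbance
#'
#' Simulates the maintenance loop: at every check interval each species
#' independently suffers a permeation disturbance with Poisson statistics
#' (an ion crossing from one compartment to the other, displacing the
#' imbalance by two elementary charges), then the controller samples the
#' imbalance and swaps when warranted.
#'
#' @param dq reference imbalance, elementary charges.
#' @param rate disturbance rate per species, events per microsecond.
#' @param duration ps.
#' @param seed RNG seed.
#' @param n_ions initial ions per species per compartment.
#' @param check_interval,averaging_window controller cadence, ps.
#' @return list `state` (final), `history` (data.frame `time`, `q`,
#'   `window_mean`), `swaps` (data.frame of the swap log).
#' @export
run_compel <- function(dq, rate, duration, seed = 1, n_ions = 100,
                       check_interval = 10, averaging_window = 100) {
  set.seed(seed)
  # Start at the reference imbalance: move dq/2 cations from B to A
  shift <- round(dq / 2)
  na_a <- n_ions + shift; na_b <- n_ions - shift
  cl_a <- n_ions; cl_b <- n_ions
  wl <- as.integer(averaging_window / check_interval)
  n_checks <- floor(duration / check_interval)
  p_dist <- rate * 1e-6 * check_interval   # rate [1/us] -> prob per check
  win <- numeric(wl); win_sum <- 0; win_n <- 0L; win_pos <- 0L
  times <- q_hist <- wm_hist <- numeric(n_checks)
  sw_t <- numeric(); sw_sp <- sw_from <- sw_to <- character()
  for (i in seq_len(n_checks)) {
    t <- i * check_interval
    # Poisson disturbance per species: one ion permeates in a random
    # direction (the RNG draw pattern matches the compositional
    # step_controller/apply_swap driver exactly)
    if (stats::runif(1) < p_dist) {
      if (stats::runif(1) < 0.5 && na_a > 0) {
        na_a <- na_a - 1L; na_b <- na_b + 1L
      } else if (na_b > 0) {
        na_b <- na_b - 1L; na_a <- na_a + 1L
      }
    }
    if (stats::runif(1) < p_dist) {
      if (stats::runif(1) < 0.5 && cl_a > 0) {
        cl_a <- cl_a - 1L; cl_b <- cl_b + 1L
      } else if (cl_b > 0) {
        cl_b <- cl_b - 1L; cl_a <- cl_a + 1L
      }
    }
    q <- (na_a - na_b) - (cl_a - cl_b)
    # sliding window over the last wl samples (circular buffer)
    win_pos <- if (win_pos == wl) 1L else win_pos + 1L
    if (win_n == wl) win_sum <- win_sum - win[win_pos] else win_n <- win_n + 1L
    win[win_pos] <- q
    win_sum <- win_sum + q
    if (win_n == wl && abs(win_sum / wl - dq) > 1) {
      dev_pos <- win_sum / wl > dq
      # same candidate/choice rule as step_controller: the correcting
      # species with the larger total count, ties to "CL"
      na_tot <- na_a + na_b; cl_tot <- cl_a + cl_b
      na_feas <- if (dev_pos) na_a >= 1 else na_b >= 1
      cl_feas <- if (dev_pos) cl_b >= 1 else cl_a >= 1
      pick <- if (na_feas && cl_feas) {
        if (cl_tot > na_tot) "CL" else if (na_tot > cl_tot) "NA" else "CL"
      } else if (na_feas) "NA" else if (cl_feas) "CL" else NA_character_
      if (!is.na(pick)) {
        if (pick == "NA") {
          if (dev_pos) { na_a <- na_a - 1L; na_b <- na_b + 1L }
          else { na_b <- na_b - 1L; na_a <- na_a + 1L }
          from <- if (dev_pos) "a" else "b"
        } else {
          if (dev_pos) { cl_b <- cl_b - 1L; cl_a <- cl_a + 1L }
          else { cl_a <- cl_a - 1L; cl_b <- cl_b + 1L }
          from <- if (dev_pos) "b" else "a"
        }
        sw_t <- c(sw_t, t); sw_sp <- c(sw_sp, pick)
        sw_from <- c(sw_from, from)
        sw_to <- c(sw_to, if (from == "a") "b" else "a")
        # flush the averaging window (matches apply_swap)
        win_n <- 0L; win_sum <- 0; win_pos <- 0L
      }
    }
    times[i] <- t
    q_hist[i] <- (na_a - na_b) - (cl_a - cl_b)
    wm_hist[i] <- if (win_n > 0L) win_sum / win_n else q_hist[i]
  }
  state <- compel_state(c("NA" = na_a, "CL" = cl_a),
                        c("NA" = na_b, "CL" = cl_b), dq,
                        check_interval, averaging_window)
  list(state = state,
       history = data.frame(time = times, q = q_hist, window_mean = wm_hist),
       swaps = data.frame(species = sw_sp, from = sw_from, to = sw_to,
                          time = sw_t, stringsAsFactors = FALSE))
}
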
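# Paneth-cell lifespan control: intrinsic lifespan draws, the stem-cell
# contact-starvation clock, and the death check.

#' Sample intrinsic Paneth-cell lifespans
#'
#' Lifespans are drawn once, at terminal conversion, from a normal
#' distribution with mean `tau_p_weeks * 168` hours and coefficient of
#' variation `lifespan_cv`, truncated at zero (rejection sampling). With
#' `lifespan_cv = 0` the draw is degenerate at the mean.
#'
#' @param n Number of draws.
#' @param params A [sim_params()].
#' @return Lifespans in hours.
#' @export
sample_intrinsic_lifespan <- function(n = 1, params = sim_params()) {
  tau <- params$tau_p_hours
  cv <- params$lifespan_cv
  if (cv <= 0) return(rep_len(tau, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1, tau, cv * tau)
      if (v > 0) break
    }
    out[i] <- v
  }
  out
}

#' Advance the stem-cell contact-starvation clock
#'
#' A terminal Paneth cell's clock accumulates while it has no stem-cell
#' contact and resets to zero whenever any contacting neighbour is a stem
#' cell.
#'
#' @param clock Current clock value(s), h.
#' @param has_sc_contact Logical: any contacting SC neighbour now?
#' @param dt Tick length, h.
#' @return Updated clock value(s).
#' @export
update_contact_clock <- function(clock, has_sc_contact, dt) {
  stopifnot(dt > 0)
  ifelse(has_sc_contact, 0, clock + dt)
}

#' Paneth-cell death check
#'
#' Contact-dependent programmed death fires when the starvation clock
#' exceeds the threshold (strictly; a clock exactly at the threshold is
#' still alive). Otherwise the cell dies intrinsically once its age since
#' terminal conversion exceeds its sampled lifespan. Exactly one cause is
#' reported per death.
#'
#' @param pc_clock Contact-starvation clock, h.
#' @param pc_age Age since terminal Paneth conversion, h.
#' @param lifespan Sampled intrinsic lifespan, h.
#' @param params A [sim_params()] (`contact_death`,
#'   `contact_starvation_threshold`).
#' @return Character vector: `"contact"`, `"intrinsic"` or `NA` (alive).
#' @export
pc_death_check <- function(pc_clock, pc_age, lifespan,
                           params = sim_params()) {
  contact <- isTRUE(params$contact_death) &
    pc_clock > params$contact_starvation_threshold
  intrinsic <- !contact & pc_age > lifespan
  out <- rep(NA_character_, length(pc_clock))
  out[intrinsic] <- "intrinsic"
  out[contact] <- "contact"
  out
}

#' Paneth-cell turnover time from an event log
#'
#' Operational definition: the time for the terminal Paneth cohort present
#' at analysis start to fall to `1/e` of its initial size, read off the
#' recorded death/removal events of those cells.
#'
#' @param result A [run_scenario()] result.
#' @return Turnover time in hours (`Inf` if the cohort never decayed that
#'   far before the end of the run).
#' @export
pc_turnover_time <- function(result) {
  cohort <- result$start$id[result$start$state == "PC_terminal"]
  n0 <- length(cohort)
  if (n0 == 0) return(NA_real_)
  ev <- result$events
  gone <- ev[ev$id %in% cohort &
               ev$event %in% c("death_intrinsic", "death_contact",
                               "anoikis", "exit"), ]
  need <- ceiling(n0 * (1 - exp(-1)))
  if (nrow(gone) < need) return(Inf)
  sort(gone$time)[need]
}
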
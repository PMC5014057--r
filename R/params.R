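# Simulation parameters and scenario presets.

#' Simulation parameters
#'
#' All model constants in one (flat) object. Units: cell radii (length),
#' hours (time), cubic cell radii (volume). The defaults are the package's
#' wild-type reference set: contact-controlled Paneth-cell death (intrinsic
#' mean lifespan 8 weeks plus programmed death after 12 h without stem-cell
#' contact), positional Wnt thresholds `P1 = 5` and `P2 = 12`, Notch contact
#' thresholds `C1 = 3` (Paneth contacts for stem-cell maintenance) and
#' `C2 = 1` (goblet contacts for enterocyte maintenance), and a crypt of cap
#' radius 4 with exit boundary `P > 30`.
#'
#' @param cap_radius Crypt cap/cylinder radius, cell radii.
#' @param exit_position Cells with `P > exit_position` leave the crypt.
#' @param substrate_tolerance Anoikis allowance beyond the cell radius.
#' @param k_rep Hertz-like repulsion constant (force = `k_rep * overlap^1.5`).
#' @param k_adh Constant adhesion force within `adhesion_range` of touching.
#' @param adhesion_range Gap (beyond touching) over which adhesion acts.
#' @param k_mem Membrane-attachment spring constant (restoring force per
#'   unit normal displacement). Sustained crowding can overcome it and push
#'   a cell off the membrane, triggering anoikis.
#' @param friction Overdamped friction coefficient (sets the time scale).
#' @param bias_up Active migration force (enterocytes/goblet cells, up).
#' @param bias_down Active migration force (Paneth cells, down).
#' @param dt Mechanics time step, h (must sit below the overdamped
#'   stability bound checked by [validate_params()]).
#' @param max_step Displacement clamp per mechanics step, cell radii.
#' @param contact_factor Cells i, j are in contact when their centre
#'   distance is below `contact_factor * (r_i + r_j)`.
#' @param v0 Post-division reference volume; `4*pi/3` gives newborn radius 1.
#' @param vp_frac Contact-inhibition threshold `Vp` as a fraction of `v0`.
#' @param cycle_growth_time Mean time to double volume unconstrained, h.
#' @param cycle_cv Lognormal coefficient of variation of per-cell growth
#'   times (redrawn at each division).
#' @param P1,P2 Positional Wnt thresholds: high Wnt below `P1`, terminal
#'   differentiation at `P >= P2`.
#' @param C1,C2 Notch contact-count thresholds (defaults for unmutated
#'   cells; each cell carries effective values `C1_eff`, `C2_eff`).
#' @param niche_extent Geometric extent of the stem-cell niche (`P <
#'   niche_extent`); fixed, independent of `C1`.
#' @param fate_dt Interval between fate/death updates, h.
#' @param max_pc_progenitor_wait A Paneth progenitor contact-inhibited for
#'   longer than this converts to terminal without a final division, h.
#' @param tau_p_weeks Mean intrinsic Paneth-cell lifespan, weeks.
#' @param lifespan_cv CV of the (0-truncated normal) lifespan distribution.
#' @param contact_death Enable contact-dependent Paneth-cell death.
#' @param contact_starvation_threshold Hours without stem-cell contact
#'   after which a terminal Paneth cell dies (strict inequality).
#' @param censor_weeks Analysis horizon for competition runs, weeks.
#' @param conversion_population `"SC"` (default) or `"all"`: population over
#'   which monoclonal conversion is evaluated.
#' @param burn_in_min_weeks,burn_in_max_weeks Bounds on the burn-in used by
#'   [initialize_crypt()].
#' @param drift_tol Relative population drift per week below which the
#'   burn-in is considered stationary.
#' @param init_fill_P Initial seeding fills the surface up to this position.
#' @param init_pc_frac,init_gc_frac Initial secretory fractions in the
#'   niche / transit compartment.
#' @param max_cells Hard cap on population size (guards runaway growth).
#' @param ... Overrides of any of the above by name.
#' @return A `sim_params` object (named list).
#' @export
sim_params <- function(cap_radius = 4,
                       exit_position = 30,
                       substrate_tolerance = 0.1,
                       k_rep = 5,
                       k_adh = 0.2,
                       adhesion_range = 0.2,
                       k_mem = 5,
                       friction = 1,
                       bias_up = 0.2,
                       bias_down = 0.3,
                       dt = 0.05,
                       max_step = 0.2,
                       contact_factor = 1.1,
                       v0 = 4 * pi / 3,
                       vp_frac = 0.95,
                       cycle_growth_time = 16,
                       cycle_cv = 0.1,
                       P1 = 5,
                       P2 = 12,
                       C1 = 3,
                       C2 = 1,
                       niche_extent = 5,
                       fate_dt = 4,
                       max_pc_progenitor_wait = 48,
                       tau_p_weeks = 8,
                       lifespan_cv = 0.25,
                       contact_death = TRUE,
                       contact_starvation_threshold = 12,
                       censor_weeks = 52,
                       conversion_population = "SC",
                       burn_in_min_weeks = 3,
                       burn_in_max_weeks = 12,
                       drift_tol = 0.02,
                       init_fill_P = 14,
                       init_pc_frac = 1 / 3,
                       init_gc_frac = 0.2,
                       max_cells = 4000,
                       ...) {
  p <- as.list(environment())
  p$... <- NULL
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p$tau_p_hours <- p$tau_p_weeks * 7 * 24
  class(p) <- "sim_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks invariants (positive durations, `exit_position > P2 > P1`, dt
#' below the explicit overdamped stability bound
#' `2 * friction / (9 * k_rep * sqrt(0.5) + k_mem)`, i.e. up to ~6
#' simultaneous Hertz contacts at half-radius overlap).
#'
#' @param p A `sim_params` object.
#' @return `p`, invisibly; errors on violation.
#' @export
validate_params <- function(p) {
  stopifnot(p$cap_radius > 0, p$dt > 0, p$fate_dt > 0,
            p$cycle_growth_time > 0, p$tau_p_weeks > 0,
            p$contact_starvation_threshold > 0,
            p$vp_frac > 0, p$v0 > 0, p$friction > 0)
  if (!(p$exit_position > p$P2 && p$P2 > p$P1 && p$P1 >= 0))
    stop("need exit_position > P2 > P1 >= 0")
  if (p$C1 < 0 || p$C2 < 0 || p$C1 != round(p$C1) || p$C2 != round(p$C2))
    stop("C1 and C2 must be nonnegative integers")
  # per-cell stiffness bound assuming up to ~6 simultaneous Hertz contacts
  dt_max <- 2 * p$friction / (6 * 1.5 * p$k_rep * sqrt(0.5) + p$k_mem)
  if (p$dt > dt_max)
    stop(sprintf("dt = %g exceeds the stability bound %.3g for these force constants",
                 p$dt, dt_max))
  if (abs(p$fate_dt / p$dt - round(p$fate_dt / p$dt)) > 1e-9)
    stop("fate_dt must be an integer multiple of dt")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  geometry : cap radius %g, exit P > %g\n",
              x$cap_radius, x$exit_position))
  cat(sprintf("  fate     : P1 = %g, P2 = %g, C1 = %d, C2 = %d\n",
              x$P1, x$P2, as.integer(x$C1), as.integer(x$C2)))
  cat(sprintf("  growth   : doubling %g h (CV %g), Vp = %g v0\n",
              x$cycle_growth_time, x$cycle_cv, x$vp_frac))
  cat(sprintf("  Paneth   : tau_p = %g wk, contact death %s (> %g h)\n",
              x$tau_p_weeks, if (isTRUE(x$contact_death)) "ON" else "OFF",
              x$contact_starvation_threshold))
  invisible(x)
}

#' Scenario presets
#'
#' Named parameter sets for the study scenarios:
#' \describe{
#'   \item{`wildtype`}{contact-controlled Paneth death (the default set).}
#'   \item{`tau4`}{intrinsic Paneth lifespan 4 weeks, no contact control.}
#'   \item{`tau8`}{intrinsic Paneth lifespan 8 weeks, no contact control.}
#'   \item{`autonomous_notch`}{`C1 = C2 = 0`: secretory lineages are never
#'     specified and the niche fills with stem cells.}
#'   \item{`broad_crypt`}{cap radius 6 (geometry robustness checks).}
#' }
#'
#' @param name Scenario name.
#' @param ... Further overrides passed to [sim_params()].
#' @return A `sim_params` object.
#' @export
scenario_params <- function(name = c("wildtype", "tau4", "tau8",
                                     "autonomous_notch", "broad_crypt"),
                            ...) {
  name <- match.arg(name)
  switch(name,
    wildtype = sim_params(...),
    tau4 = sim_params(tau_p_weeks = 4, contact_death = FALSE, ...),
    tau8 = {
      # separation develops over months: long burn-in unless overridden
      args <- list(tau_p_weeks = 8, contact_death = FALSE,
                   burn_in_min_weeks = 16, burn_in_max_weeks = 24)
      dots <- list(...)
      args[names(dots)] <- dots
      do.call(sim_params, args)
    },
    autonomous_notch = sim_params(C1 = 0, C2 = 0, init_pc_frac = 0,
                                  init_gc_frac = 0, ...),
    broad_crypt = sim_params(cap_radius = 6, ...))
}

# flat list handed to the C++ engine
.engine_par <- function(p, t0) {
  list(cap_radius = p$cap_radius, exit_position = p$exit_position,
       k_rep = p$k_rep, k_adh = p$k_adh, adhesion_range = p$adhesion_range,
       k_mem = p$k_mem, friction = p$friction, bias_up = p$bias_up,
       bias_down = p$bias_down, dt = p$dt, max_step = p$max_step,
       contact_factor = p$contact_factor,
       substrate_tolerance = p$substrate_tolerance, vp_frac = p$vp_frac,
       cycle_growth_time = p$cycle_growth_time, cycle_cv = p$cycle_cv,
       fate_dt = p$fate_dt, max_pc_progenitor_wait = p$max_pc_progenitor_wait,
       tau_p_hours = p$tau_p_hours, lifespan_cv = p$lifespan_cv,
       contact_death = as.integer(isTRUE(p$contact_death)),
       contact_starvation_threshold = p$contact_starvation_threshold,
       t0 = t0, P1 = p$P1, P2 = p$P2, max_cells = as.integer(p$max_cells))
}
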
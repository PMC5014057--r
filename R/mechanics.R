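# Cell mechanics: contacts, forces, overdamped motion, growth, division,
# anoikis and crypt exit. These functions expose the same compiled
# primitives the simulation engine uses internally.

#' Detect mechanical contacts
#'
#' Cells i and j are in contact when their centre distance is below
#' `contact_factor * (r_i + r_j)`. The graph is symmetric with no
#' self-edges.
#'
#' @param cells A `cell_population`.
#' @param params A [sim_params()] (supplies `contact_factor`).
#' @return A `contact_graph`: list with `edges` (two-column matrix of cell
#'   ids) and `neighbours` (list of neighbour id vectors, one per cell, in
#'   row order of `cells`).
#' @export
detect_contacts <- function(cells, params = sim_params()) {
  idx <- .cpp_detect_contacts(cells$x, cells$y, cells$z,
                              cell_radius(cells$volume),
                              params$contact_factor)
  nb <- vector("list", nrow(cells))
  if (nrow(idx) > 0) {
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      nb[[i]] <- c(nb[[i]], cells$id[j])
      nb[[j]] <- c(nb[[j]], cells$id[i])
    }
  }
  edges <- cbind(cells$id[idx[, 1]], cells$id[idx[, 2]])
  structure(list(edges = edges, neighbours = nb, ids = cells$id),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %d cells, %d contacts\n",
              length(x$ids), nrow(x$edges)))
  invisible(x)
}

#' Pairwise mechanical force between two cells
#'
#' Repulsion is Hertz-like, `k_rep * delta^1.5` for overlap depth
#' `delta = (r_i + r_j) - d > 0`; adhesion is a constant attraction of
#' magnitude `k_adh` for gaps `0 <= d - (r_i + r_j) < adhesion_range`. At
#' exact touching (`delta = 0`) repulsion is zero and adhesion acts at full
#' magnitude. The force on j is the negative of the force on i.
#'
#' @param cell_i,cell_j Single-row `cell_population` slices.
#' @param params A [sim_params()].
#' @return Length-3 force vector acting on `cell_i`.
#' @export
pairwise_force <- function(cell_i, cell_j, params = sim_params()) {
  .cpp_pair_force(c(cell_i$x, cell_i$y, cell_i$z), cell_radius(cell_i$volume),
                  c(cell_j$x, cell_j$y, cell_j$z), cell_radius(cell_j$volume),
                  params$k_rep, params$k_adh, params$adhesion_range)
}

#' Active migration bias force
#'
#' Enterocyte- and goblet-lineage cells experience a constant-magnitude
#' force along the meridian toward increasing P; Paneth-lineage cells
#' toward decreasing P (suppressed when the cell's `pc_bias` flag is off,
#' as for the hyperproliferative Wnt mutant profile); stem cells none. The
#' meridian direction is undefined at the bottom pole, so a Paneth cell at
#' P = 0 feels no bias.
#'
#' @param cells A `cell_population`.
#' @param surface A [crypt_surface()].
#' @param params A [sim_params()].
#' @return n x 3 matrix of tangential force vectors.
#' @export
migration_bias_force <- function(cells, surface = crypt_surface(),
                                 params = sim_params()) {
  tang <- .cpp_up_tangent(as.matrix(cells[, c("x", "y", "z")]),
                          surface$cap_radius)
  mag <- numeric(nrow(cells))
  up <- cells$state %in% c("EC_progenitor", "GC_progenitor",
                           "EC_terminal", "GC_terminal")
  down <- cells$state %in% c("PC_progenitor", "PC_terminal") &
    cells$pc_bias > 0
  mag[up] <- params$bias_up
  mag[down] <- -params$bias_down
  tang * mag
}

#' Advance cell positions by overdamped dynamics
#'
#' Each mechanics step sums pairwise contact forces, active migration
#' biases and the membrane-attachment spring, then moves every cell by
#' `force / friction * dt`, clamped at `max_step`. With `project = TRUE`
#' positions are additionally hard-projected back onto the surface after
#' each step (useful for idealized two-body analyses; the engine itself
#' relies on the attachment spring so that sustained crowding can detach a
#' cell and trigger anoikis).
#'
#' @param cells A `cell_population`.
#' @param params A [sim_params()]; `params$dt` is the step size.
#' @param n_steps Number of consecutive steps.
#' @param project Hard-project positions onto the surface after each step.
#' @return The updated `cell_population`.
#' @export
step_positions <- function(cells, params = sim_params(), n_steps = 1,
                           project = FALSE) {
  validate_params(params)
  par <- .engine_par(params, 0)
  for (s in seq_len(n_steps)) {
    res <- .cpp_substep(cells$x, cells$y, cells$z, cells$volume,
                        .state_code(cells$state), as.integer(cells$pc_bias),
                        par)
    pos <- res$pos
    if (project) pos <- .cpp_project(pos, params$cap_radius)
    cells$x <- pos[, 1]; cells$y <- pos[, 2]; cells$z <- pos[, 3]
  }
  cells
}

#' Available (uncompressed) volume
#'
#' The contact-inhibition proxy: a cell's own volume minus the summed
#' sphere-sphere intersection (lens) volumes with all neighbours, floored
#' at zero. Growth pauses while this falls below the threshold volume
#' `Vp = vp_frac * v0 * vp_scale`.
#'
#' @param cells A `cell_population`.
#' @return Numeric vector of available volumes.
#' @export
local_compression <- function(cells) {
  .cpp_available_volume(cells$x, cells$y, cells$z, cells$volume)
}

#' Grow proliferative cells under contact inhibition
#'
#' Proliferative (non-terminal) cells whose available volume is at least
#' their effective threshold `Vp` gain volume linearly at rate
#' `v0 / cycle_growth_time` (doubling in one unconstrained growth time);
#' compressed cells pause and are flagged `inhibited`.
#'
#' @param cells A `cell_population`.
#' @param params A [sim_params()].
#' @param dt Time increment, h.
#' @return The updated `cell_population`.
#' @export
grow_cells <- function(cells, params = sim_params(), dt = params$fate_dt) {
  avail <- local_compression(cells)
  prolif <- .is_proliferative(cells$state)
  vp_eff <- params$vp_frac * cells$v0 * cells$vp_scale
  ok <- prolif & avail >= vp_eff
  cells$volume[ok] <- cells$volume[ok] +
    cells$v0[ok] / cells$cycle_growth_time[ok] * dt
  cells$inhibited <- as.integer(prolif & !ok)
  cells
}

#' Divide a cell
#'
#' Requires volume at least `2 * v0` and a proliferative state. The two
#' daughters receive volume `v0` each, are placed symmetrically at
#' `+/- 0.5 r` along a random tangential axis (projected onto the surface),
#' and inherit lineage state, mutation profile and founder label. A Paneth
#' progenitor mother yields two terminal Paneth daughters (the last-cycle
#' rule), each with a freshly sampled intrinsic lifespan.
#'
#' @param cell Single-row `cell_population` slice.
#' @param params A [sim_params()].
#' @param next_id First id to assign to the daughters.
#' @return A two-row `cell_population` of daughters.
#' @export
divide_cell <- function(cell, params = sim_params(),
                        next_id = cell$id + c(1L, 2L)) {
  if (.is_terminal(cell$state))
    stop("divide_cell called on a terminally differentiated cell")
  if (cell$volume < 2 * cell$v0)
    stop("cell has not reached twice its reference volume")
  pos <- .cpp_division_placement(cell$x, cell$y, cell$z, cell$volume,
                                 params$cap_radius)
  d <- cell[c(1, 1), ]
  d$id <- as.integer(next_id)
  d$x <- pos[, 1]; d$y <- pos[, 2]; d$z <- pos[, 3]
  d$volume <- d$v0
  d$age <- 0
  d$pc_wait <- 0
  d$inhibited <- 0L
  d$cycle_growth_time <- .draw_growth_time(2, params, cell$cycle_delta)
  if (cell$state == "PC_progenitor") {
    d$state <- "PC_terminal"
    d$intrinsic_lifespan <- sample_intrinsic_lifespan(2, params)
    d$pc_age <- 0
    d$pc_clock <- 0
  }
  rownames(d) <- NULL
  d
}

.draw_growth_time <- function(n, params, cycle_delta = 0) {
  m <- pmax(params$cycle_growth_time + cycle_delta, 1)
  if (params$cycle_cv <= 0) return(rep_len(m, n))
  sdlog <- sqrt(log(1 + params$cycle_cv^2))
  exp(log(m) - sdlog^2 / 2 + sdlog * rnorm(n))
}

#' Remove detached and exited cells
#'
#' Cells without substrate contact undergo anoikis; cells with
#' `P > exit_position` (strict) leave the crypt. Both are removed and the
#' removals reported with their cause.
#'
#' @param cells A `cell_population`.
#' @param params A [sim_params()].
#' @return List with `cells` (survivors) and `removals` (data frame: id,
#'   founder, P, state, cause).
#' @export
apply_anoikis_and_exit <- function(cells, params = sim_params()) {
  surface <- crypt_surface(params$cap_radius, params$exit_position)
  P <- axial_position(as.matrix(cells[, c("x", "y", "z")]), surface)
  attached <- has_substrate_contact(cells, surface,
                                    params$substrate_tolerance)
  cause <- rep(NA_character_, nrow(cells))
  cause[!attached] <- "anoikis"
  cause[attached & P > params$exit_position] <- "exit"
  removed <- !is.na(cause)
  list(cells = cells[!removed, , drop = FALSE],
       removals = data.frame(id = cells$id[removed],
                             founder = cells$founder[removed],
                             P = P[removed], state = cells$state[removed],
                             cause = cause[removed],
                             stringsAsFactors = FALSE))
}
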
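# Deterministic miniature cell configurations for fast unit testing.

#' Ring fixture: evenly spaced cells on the cap equator
#'
#' `n` identical newborn cells evenly spaced on the equator circle of a
#' crypt whose cap radius is chosen (unless given) so that neighbours touch
#' exactly (chord length = 2 cell radii). Used for mechanics equilibrium
#' and contact tests.
#'
#' @param n Number of cells (>= 3).
#' @param radius Ring (= cap) radius; default makes neighbours touch.
#' @param params A [sim_params()] (supplies `v0`).
#' @return List with `cells` (a `cell_population`) and `params` (the base
#'   parameters with `cap_radius` set to the ring radius).
#' @export
make_ring_fixture <- function(n = 6, radius = NULL, params = sim_params()) {
  stopifnot(n >= 3)
  r0 <- cell_radius(params$v0)
  if (is.null(radius)) radius <- r0 / sin(pi / n)
  chord <- 2 * radius * sin(pi / n)
  if (chord < r0)
    stop("cells would overlap by more than half a diameter: increase radius")
  p <- sim_params(cap_radius = radius,
                  exit_position = max(params$exit_position,
                                      radius * pi / 2 + 1))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cells <- cell_population(radius * cos(ang), radius * sin(ang),
                           rep(radius, n), state = "SC", params = p)
  list(cells = cells, params = p)
}

#' Niche fixture: a centre cell with a ring of named neighbours
#'
#' Builds an exact neighbour structure for fate-rule unit tests: the first
#' state in `layout` sits at the bottom pole of the crypt, the remaining
#' states are placed around it at just under two cell radii so that each
#' touches the centre. `layout` is a character vector of lineage states or
#' a single string such as `"SC PC PC PC"`.
#'
#' @param layout States, centre first (see [cell_states()]).
#' @param params A [sim_params()].
#' @return A `cell_population` whose contact graph matches the layout
#'   (centre touches every ring cell).
#' @export
make_niche_fixture <- function(layout, params = sim_params()) {
  if (length(layout) == 1 && grepl("[ ,+]", layout))
    layout <- strsplit(layout, "[ ,+]+")[[1]]
  .state_code(layout) # validates symbols
  n <- length(layout)
  R <- params$cap_radius
  r0 <- cell_radius(params$v0)
  # centre at the bottom pole; ring at polar angle giving chord ~ 1.9 r0
  pts <- matrix(c(0, 0, 0), 1, 3)
  if (n > 1) {
    theta <- 2 * asin(0.95 * r0 / R)
    ang <- 2 * pi * (seq_len(n - 1) - 1) / (n - 1)
    pts <- rbind(pts, cbind(R * sin(theta) * cos(ang),
                            R * sin(theta) * sin(ang),
                            R - R * cos(theta)))
  }
  cells <- cell_population(pts[, 1], pts[, 2], pts[, 3], state = layout,
                           params = params)
  pc <- cells$state == "PC_terminal"
  if (any(pc))
    cells$intrinsic_lifespan[pc] <- params$tau_p_hours
  cells
}
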
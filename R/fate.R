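# Wnt/Notch fate regulation: positional Wnt classes, ligand-contact counts
# and the reversible fate decision table.

#' Positional Wnt class
#'
#' Wnt activity decreases with the distance from the crypt bottom: `high`
#' for `P < P1`, `low` for `P1 <= P < P2`, `terminal_zone` for `P >= P2`.
#' Threshold positions belong to the lower-Wnt class.
#'
#' @param P Axial position(s), cell radii.
#' @param params A [sim_params()] (supplies `P1`, `P2`).
#' @return Character vector in `c("high", "low", "terminal_zone")`.
#' @export
wnt_class <- function(P, params = sim_params()) {
  stopifnot(all(P >= 0))
  ifelse(P < params$P1, "high",
         ifelse(P < params$P2, "low", "terminal_zone"))
}

#' Count Notch-ligand-presenting contacts
#'
#' Secretory cells (Paneth, goblet; progenitor or terminal) present Notch
#' ligands to their mechanical neighbours. For each cell this returns the
#' number of contacting Paneth-state and goblet-state neighbours. A cell
#' never credits its own state.
#'
#' @param cells A `cell_population`.
#' @param graph A [detect_contacts()] result for `cells`.
#' @return Data frame with columns `n_PC`, `n_GC` (row order of `cells`).
#' @export
count_ligand_contacts <- function(cells, graph = detect_contacts(cells)) {
  state_of <- setNames(cells$state, cells$id)
  n_pc <- integer(nrow(cells))
  n_gc <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    st <- state_of[as.character(graph$neighbours[[i]])]
    n_pc[i] <- sum(st %in% c("PC_progenitor", "PC_terminal"))
    n_gc[i] <- sum(st %in% c("GC_progenitor", "GC_terminal"))
  }
  data.frame(n_PC = n_pc, n_GC = n_gc)
}

#' Fate decision table
#'
#' Applies the reversible Wnt/Notch fate rules to non-terminal cells given
#' their position and ligand-contact counts, using each cell's effective
#' thresholds `C1_eff`/`C2_eff`:
#' \itemize{
#'   \item SC at high Wnt keeps stemness with at least `C1_eff` Paneth
#'     contacts, otherwise specifies into a Paneth progenitor; an SC that
#'     leaves the high-Wnt region follows the enterocyte branch.
#'   \item Enterocyte progenitors terminally differentiate at `P >= P2`,
#'     revert to SC when back at high Wnt with enough Paneth contacts, and
#'     specify into goblet progenitors when goblet contacts fall below
#'     `C2_eff`.
#'   \item Goblet progenitors revert to enterocyte progenitors when they
#'     regain goblet contacts, and terminally differentiate at `P >= P2`.
#'   \item Paneth progenitors revert to SC when at high Wnt with at least
#'     `C1_eff` Paneth contacts; terminal conversion happens through the
#'     last-cycle rule (both daughters of a dividing Paneth progenitor are
#'     terminal Paneth cells).
#' }
#' Cells with `outside_niche` set behave as if Wnt were high everywhere and
#' never terminally differentiate. Calling this on a terminally
#' differentiated cell is a logic error.
#'
#' @param cells A `cell_population` (non-terminal rows).
#' @param n_PC,n_GC Contact counts (from [count_ligand_contacts()]).
#' @param P Axial positions; computed from the coordinates if missing.
#' @param params A [sim_params()].
#' @return Character vector of new lineage states.
#' @export
update_fate <- function(cells, n_PC, n_GC, P = NULL, params = sim_params()) {
  if (is.null(P)) {
    P <- axial_position(as.matrix(cells[, c("x", "y", "z")]),
                        crypt_surface(params$cap_radius,
                                      params$exit_position))
  }
  code <- .cpp_fate_decision(.state_code(cells$state), as.integer(n_PC),
                             as.integer(n_GC), as.double(P),
                             params$P1, params$P2,
                             as.integer(cells$C1_eff),
                             as.integer(cells$C2_eff),
                             as.integer(cells$outside_niche))
  .state_name(code)
}
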
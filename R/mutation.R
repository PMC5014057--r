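# Mutation engine: heritable parameter-override profiles injected into
# selected stem cells; the standard Wnt-mutant profiles; selectors.

.profile_keys <- c("C1_eff", "C2_eff", "vp_scale", "cycle_delta",
                   "pc_migration_bias", "maintain_outside_niche")

#' Define a heritable mutation profile
#'
#' A profile is a partial parameter override applied to selected stem
#' cells and inherited by every daughter. Allowed keys: effective Notch
#' thresholds `C1_eff`/`C2_eff`, the contact-inhibition rescale `vp_scale`
#' (`Vp* = vp_scale * Vp`), a cell-cycle shift `cycle_delta` (hours added
#' to the mean growth time), the Paneth migration-bias switch
#' `pc_migration_bias`, and `maintain_outside_niche` (the cell behaves as
#' if Wnt were high at every position and never terminally differentiates).
#' Later profiles win on key collision.
#'
#' @param name Profile name (bookkeeping only).
#' @param ... Named overrides among the keys above.
#' @return A `mutation_profile`.
#' @export
mutation_profile <- function(name = "custom", ...) {
  overrides <- list(...)
  bad <- setdiff(names(overrides), .profile_keys)
  if (length(bad))
    stop("unknown override key(s): ", paste(bad, collapse = ", "))
  structure(list(name = name, overrides = overrides),
            class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  ov <- if (length(x$overrides)) {
    paste(names(x$overrides), unlist(lapply(x$overrides, format)),
          sep = " = ", collapse = ", ")
  } else "neutral (label only)"
  cat(sprintf("<mutation_profile> %s: %s\n", x$name, ov))
  invisible(x)
}

#' Wnt-activating mutant profiles
#'
#' `mutant1` raises the Paneth-contact requirement for stem-cell
#' maintenance to `C1_eff > 3` (allowed values 4 or 5): mutant stem cells
#' specify into the Paneth lineage more readily, a competitive
#' disadvantage on a wild-type background. `mutant2` additionally is
#' maintained outside the stem-cell niche, is less sensitive to contact
#' inhibition of growth (`Vp* = 0.76 Vp`), and specifies into Paneth cells
#' that lack the downward migration bias.
#'
#' @param C1_value Effective `C1` of the mutant; 4 or 5.
#' @return A `mutation_profile`.
#' @export
mutant1_profile <- function(C1_value = 4) {
  if (!C1_value %in% c(4, 5))
    stop("mutant1 requires C1_value in {4, 5} (C1 > 3)")
  mutation_profile("mutant1", C1_eff = as.integer(C1_value))
}

#' @rdname mutant1_profile
#' @export
mutant2_profile <- function(C1_value = 4) {
  base <- mutant1_profile(C1_value)
  structure(list(name = "mutant2",
                 overrides = c(base$overrides,
                               list(vp_scale = 0.76,
                                    pc_migration_bias = FALSE,
                                    maintain_outside_niche = TRUE))),
            class = "mutation_profile")
}

#' Stem-cell selectors for mutation events
#'
#' Modes: `deepest_SC` (minimal P; ties broken by lowest id), `random_SC`
#' (`count` cells), `all_SCs`, `half_of_SCs` (a random half). Mutations
#' coupled to cell division (`division_associated`) are handled by
#' [run_scenario()], which labels one daughter (fair coin) of the next
#' stem-cell division after analysis start.
#'
#' @param mode Selector mode.
#' @param count Number of cells for `random_SC`.
#' @return A `mutation_selector`.
#' @export
mutation_selector <- function(mode = c("deepest_SC", "random_SC", "all_SCs",
                                       "half_of_SCs"), count = 1) {
  structure(list(mode = match.arg(mode), count = count),
            class = "mutation_selector")
}

#' Apply a mutation profile to selected stem cells
#'
#' Selected stem cells receive the profile's overrides and the clone label
#' `clone_id`; daughters inherit both. Only cells in the SC state can be
#' selected. The analysis clock of a competition experiment restarts at
#' the mutation time ([run_scenario()] freezes founder labels then).
#'
#' @param cells A `cell_population`.
#' @param selector A [mutation_selector()].
#' @param profile A [mutation_profile()].
#' @param clone_id Positive integer clone label.
#' @return The modified `cell_population`.
#' @export
apply_mutation <- function(cells, selector, profile, clone_id = 1L) {
  stopifnot(inherits(selector, "mutation_selector"),
            inherits(profile, "mutation_profile"), clone_id >= 1)
  sc <- which(cells$state == "SC")
  if (length(sc) == 0) stop("selector matches no stem cell")
  pick <- switch(selector$mode,
    deepest_SC = {
      P <- axial_position(as.matrix(cells[sc, c("x", "y", "z")]))
      cand <- sc[P == min(P)]
      cand[which.min(cells$id[cand])]
    },
    random_SC = {
      if (selector$count > length(sc)) stop("selector matches no stem cell")
      sc[sample.int(length(sc), selector$count)]
    },
    all_SCs = sc,
    half_of_SCs = sc[sample.int(length(sc), round(length(sc) / 2))])
  .apply_profile(cells, pick, profile, clone_id)
}

.apply_profile <- function(cells, rows, profile, clone_id) {
  if (any(cells$state[rows] != "SC"))
    stop("mutation profiles can only be applied to stem cells")
  ov <- profile$overrides
  if (!is.null(ov$C1_eff)) cells$C1_eff[rows] <- as.integer(ov$C1_eff)
  if (!is.null(ov$C2_eff)) cells$C2_eff[rows] <- as.integer(ov$C2_eff)
  if (!is.null(ov$vp_scale)) cells$vp_scale[rows] <- ov$vp_scale
  if (!is.null(ov$cycle_delta)) cells$cycle_delta[rows] <- ov$cycle_delta
  if (!is.null(ov$pc_migration_bias))
    cells$pc_bias[rows] <- as.integer(isTRUE(ov$pc_migration_bias))
  if (!is.null(ov$maintain_outside_niche))
    cells$outside_niche[rows] <-
      as.integer(isTRUE(ov$maintain_outside_niche))
  cells$clone[rows] <- as.integer(clone_id)
  cells
}
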
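# Cell populations: the central data frame, engine marshalling, CSV i/o.

.pop_columns <- c("id", "x", "y", "z", "volume", "v0", "state", "founder",
                  "clone", "age", "cycle_growth_time", "pc_clock", "pc_age",
                  "intrinsic_lifespan", "pc_wait", "inhibited", "C1_eff",
                  "C2_eff", "vp_scale", "cycle_delta", "pc_bias",
                  "outside_niche")

#' Construct a cell population
#'
#' A cell population is a data frame with one row per cell. Required inputs
#' are positions and lineage states; every bookkeeping column (clocks,
#' per-cell effective parameters, clone labels) is filled with defaults and
#' can be overridden by name. Per-cell effective Notch thresholds
#' (`C1_eff`, `C2_eff`), the contact-inhibition rescale `vp_scale`, the
#' cycle-time shift `cycle_delta`, the Paneth migration-bias switch
#' `pc_bias` and `outside_niche` are the heritable mutation surface (see
#' [apply_mutation()]).
#'
#' @param x,y,z Cell-centre coordinates (cell radii).
#' @param state Lineage states (see [cell_states()]).
#' @param params A [sim_params()] supplying defaults.
#' @param ... Named column overrides (recycled to length n).
#' @return A `cell_population` data frame.
#' @export
cell_population <- function(x, y, z, state = "SC", params = sim_params(),
                            ...) {
  n <- length(x)
  state <- rep_len(state, n)
  .state_code(state) # validates
  df <- data.frame(
    id = seq_len(n), x = x, y = y, z = z,
    volume = rep_len(params$v0, n), v0 = rep_len(params$v0, n),
    state = state, founder = seq_len(n), clone = 0L,
    age = 0, cycle_growth_time = rep_len(params$cycle_growth_time, n),
    pc_clock = 0, pc_age = 0, intrinsic_lifespan = NA_real_, pc_wait = 0,
    inhibited = 0L, C1_eff = as.integer(params$C1),
    C2_eff = as.integer(params$C2), vp_scale = 1, cycle_delta = 0,
    pc_bias = 1L, outside_niche = 0L,
    stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% .pop_columns) stop("unknown cell column: ", nm)
    df[[nm]] <- rep_len(dots[[nm]], n)
  }
  class(df) <- c("cell_population", "data.frame")
  df
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("<cell_population> %d cells: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$state)),
                            as.integer(table(x$state))), collapse = " ")))
  invisible(x)
}

.pop_to_engine <- function(cells) {
  list(id = as.integer(cells$id), x = as.double(cells$x),
       y = as.double(cells$y), z = as.double(cells$z),
       volume = as.double(cells$volume), v0 = as.double(cells$v0),
       state = .state_code(cells$state),
       founder = as.integer(cells$founder), clone = as.integer(cells$clone),
       age = as.double(cells$age),
       cycle_growth_time = as.double(cells$cycle_growth_time),
       pc_clock = as.double(cells$pc_clock),
       pc_age = as.double(cells$pc_age),
       intrinsic_lifespan = as.double(cells$intrinsic_lifespan),
       pc_wait = as.double(cells$pc_wait),
       inhibited = as.integer(cells$inhibited),
       C1_eff = as.integer(cells$C1_eff), C2_eff = as.integer(cells$C2_eff),
       vp_scale = as.double(cells$vp_scale),
       cycle_delta = as.double(cells$cycle_delta),
       pc_bias = as.integer(cells$pc_bias),
       outside_niche = as.integer(cells$outside_niche))
}

.engine_to_pop <- function(lst) {
  df <- as.data.frame(lst, stringsAsFactors = FALSE)
  df$state <- .state_name(df$state)
  class(df) <- c("cell_population", "data.frame")
  df
}

.event_names <- c("division", "anoikis", "exit", "death_intrinsic",
                  "death_contact", "fate_change")
.trigger_names <- c("wnt", "notch", "terminal", "last_cycle")

.events_to_df <- function(m) {
  if (nrow(m) == 0) {
    return(data.frame(time = numeric(0), event = character(0),
                      id = integer(0), founder = integer(0),
                      clone = integer(0), P = numeric(0),
                      state_old = character(0), state_new = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(time = m[, 1], event = .event_names[m[, 2]],
             id = as.integer(m[, 3]), founder = as.integer(m[, 4]),
             clone = as.integer(m[, 5]), P = m[, 6],
             state_old = .state_name(m[, 7]), state_new = .state_name(m[, 8]),
             stringsAsFactors = FALSE)
}

.divisions_to_df <- function(m) {
  if (nrow(m) == 0) {
    return(data.frame(time = numeric(0), mother = integer(0),
                      daughter1 = integer(0), daughter2 = integer(0),
                      P = numeric(0), mother_state = character(0),
                      founder = integer(0), clone = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(time = m[, 1], mother = as.integer(m[, 2]),
             daughter1 = as.integer(m[, 3]), daughter2 = as.integer(m[, 4]),
             P = m[, 5], mother_state = .state_name(m[, 6]),
             founder = as.integer(m[, 7]), clone = as.integer(m[, 8]),
             stringsAsFactors = FALSE)
}

#' Write / read a population snapshot as CSV
#'
#' Snapshots serialize losslessly through plain CSV (used by the fixtures
#' and the command-line interface).
#'
#' @param cells A `cell_population`.
#' @param file Path.
#' @return `read_snapshot()` returns the `cell_population`.
#' @export
write_snapshot <- function(cells, file) {
  df <- as.data.frame(cells)[, .pop_columns]
  for (nm in names(df)) { # full double precision so round-trips are exact
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(.pop_columns %in% names(df)))
  df <- df[, .pop_columns]
  class(df) <- c("cell_population", "data.frame")
  df
}
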
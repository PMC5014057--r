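# Simulation driver: initialization with burn-in, the main loop (compiled
# engine called in chunks), replicate management and seeding.

#' Derive a replicate seed from a master seed
#'
#' Counter-based multiplicative derivation (Lehmer step modulo 2^31 - 1),
#' so replicate sets are extensible without reseeding earlier replicates.
#'
#' @param master Master seed (integer).
#' @param i Replicate counter (1, 2, ...).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, i) {
  m <- 2147483647 # Lehmer step: exact in doubles (48271 * m < 2^53)
  s <- ((as.numeric(master) %% m) * 48271 + i) %% m
  as.integer(max(s, 1))
}

# quasi-uniform seeding of the surface up to P = init_fill_P
.place_initial_cells <- function(params) {
  R <- params$cap_radius
  cap_area <- 2 * pi * R^2
  area_of <- function(P) {
    ifelse(P <= R * pi / 2, 2 * pi * R^2 * (1 - cos(P / R)),
           cap_area + 2 * pi * R * (P - R * pi / 2))
  }
  inv_area <- function(a) {
    ifelse(a <= cap_area, R * acos(pmin(1, pmax(-1, 1 - a / (2 * pi * R^2)))),
           R * pi / 2 + (a - cap_area) / (2 * pi * R))
  }
  total <- area_of(params$init_fill_P)
  n <- round(total / 3.6) # ~one cell per 3.6 square radii: touching packing
  a <- (seq_len(n) - 0.5) / n * total
  P <- inv_area(a)
  phi <- (seq_len(n) * (1 + sqrt(5)) * pi) %% (2 * pi)
  oncap <- P <= R * pi / 2
  theta <- P / R
  x <- ifelse(oncap, R * sin(theta) * cos(phi), R * cos(phi))
  y <- ifelse(oncap, R * sin(theta) * sin(phi), R * sin(phi))
  z <- ifelse(oncap, R - R * cos(theta), R + (P - R * pi / 2))
  state <- ifelse(P < params$niche_extent,
                  ifelse(runif(n) < params$init_pc_frac, "PC_terminal", "SC"),
                  ifelse(P < params$P2,
                         ifelse(runif(n) < params$init_gc_frac,
                                "GC_progenitor", "EC_progenitor"),
                         "EC_terminal"))
  cells <- cell_population(x, y, z, state, params)
  cells$volume <- cells$v0 * runif(n, 1, 2)
  cells$cycle_growth_time <- .draw_growth_time(n, params)
  pc <- cells$state == "PC_terminal"
  if (any(pc)) {
    cells$intrinsic_lifespan[pc] <- sample_intrinsic_lifespan(sum(pc), params)
    cells$pc_age[pc] <- runif(sum(pc)) * cells$intrinsic_lifespan[pc]
  }
  cells
}

# one call into the compiled engine
.run_chunk <- function(cells, params, hours, t0, next_id,
                       stop_on_conversion = FALSE, check_clone = FALSE,
                       record_fate_events = TRUE) {
  res <- .cpp_run_crypt(.pop_to_engine(cells), .engine_par(params, t0),
                        hours, as.integer(next_id), stop_on_conversion,
                        check_clone, record_fate_events)
  list(cells = .engine_to_pop(res$pop),
       events = .events_to_df(res$events),
       divisions = .divisions_to_df(res$divisions),
       conversion_time = res$conversion_time, fix_time = res$fix_time,
       loss_time = res$loss_time, next_id = res$next_id,
       clamp_fraction = res$clamp_fraction, n_births = res$n_births,
       n_removals = res$n_removals)
}

#' Initialize a crypt at steady-state turnover
#'
#' Seeds the surface with a mixed population, then burns in until weekly
#' population counts drift by less than `drift_tol` (relative) between
#' consecutive weeks, with at least `burn_in_min_weeks` and at most
#' `burn_in_max_weeks` of burn-in. Founder labels are reset to the cell
#' ids of the returned snapshot, which defines the start of any subsequent
#' competition analysis.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed (all randomness flows from R's RNG).
#' @return A `crypt_state`: list with `cells`, `time = 0`, `next_id`,
#'   `params`, `seed`, `burn_in_hours`.
#' @export
initialize_crypt <- function(params = sim_params(), seed = 1) {
  set.seed(seed)
  cells <- .place_initial_cells(params)
  next_id <- max(cells$id) + 1L
  week_means <- numeric(0)
  weeks <- 0
  repeat {
    # one week in daily sub-chunks so the drift check uses time-averages
    daily <- numeric(7)
    for (d in 1:7) {
      ch <- .run_chunk(cells, params, 24, t0 = weeks * 168 + (d - 1) * 24,
                       next_id = next_id, record_fate_events = FALSE)
      cells <- ch$cells
      next_id <- ch$next_id
      daily[d] <- nrow(cells)
    }
    weeks <- weeks + 1
    week_means <- c(week_means, mean(daily))
    if (weeks >= max(2, params$burn_in_min_weeks) &&
        sum(cells$state == "SC") > 0) {
      drift <- abs(diff(tail(week_means, 2))) / tail(week_means, 1)
      if (drift < params$drift_tol) break
    }
    if (weeks >= params$burn_in_max_weeks) {
      # robust fallback: accept if the last four weekly means show no trend
      recent <- tail(week_means, 4)
      slope <- coef(stats::lm(recent ~ seq_along(recent)))[2]
      if (abs(slope) < params$drift_tol * mean(recent) &&
          sum(cells$state == "SC") > 0) break
      stop(sprintf(paste0("no steady state within %d weeks of burn-in ",
                          "(weekly mean populations: %s)"),
                   weeks, paste(round(week_means, 1), collapse = " ")))
    }
  }
  cells$founder <- cells$id
  structure(list(cells = cells, time = 0, next_id = next_id,
                 params = params, seed = seed,
                 burn_in_hours = weeks * 168),
            class = "crypt_state")
}

#' @export
print.crypt_state <- function(x, ...) {
  cat(sprintf("<crypt_state> t = %g h, %d cells (%d SC), burn-in %g h\n",
              x$time, nrow(x$cells), sum(x$cells$state == "SC"),
              x$burn_in_hours))
  invisible(x)
}

.snapshot_df <- function(cells, t, params) {
  data.frame(time = t, id = cells$id, founder = cells$founder,
             clone = cells$clone, state = cells$state,
             P = axial_position(as.matrix(cells[, c("x", "y", "z")]),
                                crypt_surface(params$cap_radius,
                                              params$exit_position)),
             stringsAsFactors = FALSE)
}

#' Run one simulation replicate
#'
#' Initializes (or reuses) a steady-state crypt, freezes founder labels,
#' optionally injects a mutation, then advances the model to the censoring
#' horizon or until the competition resolves. Per tick the engine updates,
#' in order: mechanics substeps, growth under contact inhibition,
#' divisions, fate rules, Paneth death checks, anoikis and crypt exit.
#'
#' @param params A [sim_params()].
#' @param seed Integer seed.
#' @param hours Analysis horizon (default `censor_weeks * 168`).
#' @param init Optional `crypt_state` to start from (its founders are
#'   re-frozen at analysis start).
#' @param mutation Optional mutation event: a list with `profile` (a
#'   [mutation_profile()]) and either `selector` (a
#'   [mutation_selector()]) or `timing = "division_associated"` (one
#'   daughter of the first stem-cell division after analysis start, fair
#'   coin). A plain function `cells -> cells` is also accepted.
#' @param stop_at_conversion Stop once monoclonal conversion (or, with a
#'   mutation, clone fixation/loss) is detected.
#' @param snapshot_every Record population snapshots at this interval, h
#'   (`NULL`: none).
#' @param record_fate_events Keep fate-change events in the log.
#' @return A `scenario_result`: list with `start`/`final` populations,
#'   `events`, `divisions`, `conversion_time`, `fix_time`, `loss_time`,
#'   `winner_founder`, `winner_start_P`, `snapshots`, `end_time`,
#'   `censored`, `params`, `seed`.
#' @export
run_scenario <- function(params = sim_params(), seed = 1, hours = NULL,
                         init = NULL, mutation = NULL,
                         stop_at_conversion = TRUE, snapshot_every = NULL,
                         record_fate_events = TRUE) {
  if (is.null(init)) {
    init <- initialize_crypt(params, seed)
  } else {
    set.seed(seed)
  }
  if (is.null(hours)) hours <- params$censor_weeks * 168
  cells <- init$cells
  cells$founder <- cells$id
  cells$clone <- 0L
  next_id <- init$next_id
  check_clone <- FALSE
  t <- 0

  if (!is.null(mutation)) {
    if (is.function(mutation)) {
      cells <- mutation(cells)
      check_clone <- any(cells$clone > 0)
    } else if (identical(mutation$timing, "division_associated")) {
      # advance hour by hour until the first stem-cell division
      repeat {
        ch <- .run_chunk(cells, params, params$fate_dt, t, next_id,
                         record_fate_events = record_fate_events)
        cells <- ch$cells; next_id <- ch$next_id; t <- t + params$fate_dt
        scdiv <- ch$divisions[ch$divisions$mother_state == "SC", ,
                              drop = FALSE]
        if (nrow(scdiv) > 0) {
          pick <- scdiv[1, ]
          daughter <- if (runif(1) < 0.5) pick$daughter1 else pick$daughter2
          row <- which(cells$id == daughter)
          if (length(row) == 1 && cells$state[row] == "SC") {
            cells <- .apply_profile(cells, row, mutation$profile, 1L)
            break
          }
        }
        if (t > hours) stop("no stem-cell division before the horizon")
      }
      # analysis restarts at the mutation time
      cells$founder <- cells$id
      t <- 0
      check_clone <- TRUE
    } else {
      # decouple the selector draw from the dynamics RNG stream so a
      # neutral (label-only) mutation leaves the trajectory bit-identical
      rng <- get(".Random.seed", envir = .GlobalEnv)
      cells <- apply_mutation(cells, mutation$selector, mutation$profile)
      assign(".Random.seed", rng, envir = .GlobalEnv)
      check_clone <- TRUE
    }
  }

  start <- cells
  surface <- crypt_surface(params$cap_radius, params$exit_position)
  events <- list(); divisions <- list()
  snapshots <- if (!is.null(snapshot_every))
    list(.snapshot_df(cells, 0, params)) else NULL
  conversion_time <- NA_real_; fix_time <- NA_real_; loss_time <- NA_real_
  chunk <- if (!is.null(snapshot_every)) snapshot_every else 168

  while (t < hours) {
    step <- min(chunk, hours - t)
    ch <- .run_chunk(cells, params, step, t, next_id,
                     stop_on_conversion = stop_at_conversion,
                     check_clone = check_clone,
                     record_fate_events = record_fate_events)
    if (ch$clamp_fraction > 0.01) {
      stop(sprintf(paste0("numerical instability: displacement clamp hit in ",
                          "%.1f%% of steps at t = %g h"),
                   100 * ch$clamp_fraction, t))
    }
    cells <- ch$cells; next_id <- ch$next_id
    events[[length(events) + 1]] <- ch$events
    divisions[[length(divisions) + 1]] <- ch$divisions
    t <- t + step
    if (!is.null(snapshot_every))
      snapshots[[length(snapshots) + 1]] <- .snapshot_df(cells, t, params)
    if (is.na(conversion_time) && ch$conversion_time >= 0)
      conversion_time <- ch$conversion_time
    if (is.na(fix_time) && ch$fix_time >= 0) fix_time <- ch$fix_time
    if (is.na(loss_time) && ch$loss_time >= 0) loss_time <- ch$loss_time
    done <- if (check_clone) !is.na(fix_time) || !is.na(loss_time)
            else !is.na(conversion_time)
    if (stop_at_conversion && done) break
  }

  winner_founder <- NA_integer_; winner_start_P <- NA_real_
  if (!is.na(conversion_time)) {
    scs <- cells$state == "SC"
    if (any(scs)) {
      winner_founder <- cells$founder[scs][1]
      row <- match(winner_founder, start$id)
      if (!is.na(row)) {
        winner_start_P <- axial_position(
          as.matrix(start[row, c("x", "y", "z")]), surface)
      }
    }
  }
  empty_ev <- .events_to_df(matrix(numeric(0), 0, 8))
  empty_dv <- .divisions_to_df(matrix(numeric(0), 0, 8))
  structure(list(
    params = params, seed = seed, start = start, final = cells,
    events = if (length(events)) do.call(rbind, events) else empty_ev,
    divisions = if (length(divisions)) do.call(rbind, divisions)
                else empty_dv,
    conversion_time = conversion_time, fix_time = fix_time,
    loss_time = loss_time, winner_founder = winner_founder,
    winner_start_P = winner_start_P,
    snapshots = if (!is.null(snapshots)) do.call(rbind, snapshots) else NULL,
    end_time = t, horizon = hours,
    censored = is.na(conversion_time) && t >= hours,
    next_id = next_id), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %g h simulated, %d cells at end\n",
              x$end_time, nrow(x$final)))
  if (!is.na(x$conversion_time))
    cat(sprintf("  monoclonal conversion at %g h (winner start P = %.2f)\n",
                x$conversion_time, x$winner_start_P))
  else cat("  no monoclonal conversion (censored)\n")
  invisible(x)
}

#' Run a replicate competition experiment
#'
#' Runs `n_reps` independent replicates (derived seeds), collects
#' conversion times and winner origins, and aggregates the positional
#' distributions f(P), w(P), p(P).
#'
#' @param params A [sim_params()].
#' @param n_reps Number of replicates.
#' @param seed Master seed; replicate i uses `derive_seed(seed, i)`.
#' @param mutation Optional mutation event passed to [run_scenario()].
#' @param hours Horizon per replicate.
#' @param keep_results Keep the full per-replicate `scenario_result`s
#'   (memory-hungry; default stores summaries only).
#' @return A `replicate_result`: list with `conversion` (data frame of
#'   per-replicate outcomes), `dist` (a [positional_distributions()]
#'   object), `outcomes` (fixation outcome per replicate, if a mutation
#'   was injected) and `n_sc` (mean stem-cell count at start).
#' @export
replicate_experiment <- function(params = sim_params(), n_reps = 10,
                                 seed = 1, mutation = NULL, hours = NULL,
                                 keep_results = FALSE) {
  stopifnot(n_reps >= 1)
  surface <- crypt_surface(params$cap_radius, params$exit_position)
  start_P <- vector("list", n_reps)
  div_P <- vector("list", n_reps)
  winner_P <- rep(NA_real_, n_reps)
  conv <- data.frame(replicate = seq_len(n_reps), seed = NA_integer_,
                     conversion_time = NA_real_, censored = NA,
                     winner_founder = NA_integer_,
                     winner_start_P = NA_real_, n_sc_start = NA_integer_)
  outcomes <- rep(NA_character_, n_reps)
  results <- if (keep_results) vector("list", n_reps) else NULL
  for (i in seq_len(n_reps)) {
    s <- derive_seed(seed, i)
    res <- run_scenario(params, seed = s, hours = hours,
                        mutation = mutation, record_fate_events = TRUE)
    sc0 <- res$start$state == "SC"
    start_P[[i]] <- axial_position(
      as.matrix(res$start[sc0, c("x", "y", "z")]), surface)
    scdiv <- res$divisions[res$divisions$mother_state == "SC", , drop = FALSE]
    div_P[[i]] <- scdiv$P
    winner_P[i] <- res$winner_start_P
    conv$seed[i] <- s
    conv$conversion_time[i] <- res$conversion_time
    conv$censored[i] <- res$censored
    conv$winner_founder[i] <- res$winner_founder
    conv$winner_start_P[i] <- res$winner_start_P
    conv$n_sc_start[i] <- sum(sc0)
    if (!is.null(mutation)) {
      outcomes[i] <- if (!is.na(res$fix_time)) "fixed"
                     else if (!is.na(res$loss_time)) "lost" else "censored"
    }
    if (keep_results) results[[i]] <- res
  }
  structure(list(conversion = conv,
                 dist = positional_distributions(start_P, winner_P, div_P),
                 outcomes = if (!is.null(mutation)) outcomes else NULL,
                 n_sc = mean(conv$n_sc_start),
                 results = results, params = params, seed = seed),
            class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  ct <- x$conversion$conversion_time
  cat(sprintf("<replicate_result> %d replicates, mean SC count %.1f\n",
              nrow(x$conversion), x$n_sc))
  if (any(!is.na(ct)))
    cat(sprintf("  conversion: %d/%d resolved, mean %.0f h (%.1f wk)\n",
                sum(!is.na(ct)), length(ct), mean(ct, na.rm = TRUE),
                mean(ct, na.rm = TRUE) / 168))
  if (!is.null(x$outcomes))
    cat(sprintf("  clone outcomes: %d fixed / %d lost / %d censored\n",
                sum(x$outcomes == "fixed"), sum(x$outcomes == "lost"),
                sum(x$outcomes == "censored")))
  invisible(x)
}

#' Split-C1 competition experiment
#'
#' From a steady-state crypt, assigns `C1_eff = c1_low` to a random half
#' of the stem cells and `C1_eff = c1_high` to the other half (fixed niche
#' size), runs each replicate to monoclonal conversion, and reports which
#' group's founder won.
#'
#' @param n_reps Replicates.
#' @param seed Master seed.
#' @param c1_low,c1_high The two Notch-contact requirements.
#' @param params Base parameters.
#' @param hours Horizon per replicate.
#' @return List with `low_wins`, `n_resolved`, `fraction_low`, and the
#'   per-replicate table.
#' @export
c1_split_experiment <- function(n_reps = 30, seed = 1, c1_low = 2,
                                c1_high = 4, params = sim_params(),
                                hours = NULL) {
  split_mutation <- function(cells) {
    sc <- which(cells$state == "SC")
    low <- sample(sc, round(length(sc) / 2))
    high <- setdiff(sc, low)
    cells$C1_eff[low] <- as.integer(c1_low)
    cells$C1_eff[high] <- as.integer(c1_high)
    cells$clone[low] <- 1L
    cells$clone[high] <- 2L
    cells
  }
  tab <- data.frame(replicate = seq_len(n_reps), winner_group = NA_character_,
                    resolution_time = NA_real_)
  for (i in seq_len(n_reps)) {
    res <- run_scenario(params, seed = derive_seed(seed, i), hours = hours,
                        mutation = split_mutation,
                        record_fate_events = FALSE)
    # clone 1 = low-C1 group: fixation of clone 1 means the low group took
    # over the stem-cell pool; loss of clone 1 means the high group did
    if (!is.na(res$fix_time)) {
      tab$winner_group[i] <- "low"
      tab$resolution_time[i] <- res$fix_time
    } else if (!is.na(res$loss_time)) {
      tab$winner_group[i] <- "high"
      tab$resolution_time[i] <- res$loss_time
    }
  }
  resolved <- !is.na(tab$winner_group)
  list(low_wins = sum(tab$winner_group[resolved] == "low"),
       n_resolved = sum(resolved),
       fraction_low = mean(tab$winner_group[resolved] == "low"),
       table = tab)
}
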
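# Lineage analysis: stem-cell division forests, monoclonal conversion,
# positional distributions f(P), w(P), p(P), advantage statistics,
# fixation probabilities, Newick export.

#' Create an (empty) stem-cell phylogeny
#'
#' The phylogeny is a forest over the stem-cell history: edges are stem
#' cells (edge length = lifetime between divisions), internal vertices are
#' mitotic events annotated with the position P of the dividing cell.
#' Roots are the stem cells present at analysis start.
#'
#' @param roots Data frame with columns `id` and optionally `birth_time`
#'   (default 0) and `P`.
#' @return A `phylogeny` object.
#' @export
new_phylogeny <- function(roots) {
  stopifnot("id" %in% names(roots))
  if (is.null(roots$birth_time)) roots$birth_time <- 0
  cells <- data.frame(id = as.integer(roots$id), parent = NA_integer_,
                      birth_time = roots$birth_time)
  structure(list(cells = cells,
                 vertices = data.frame(id = integer(0), time = numeric(0),
                                       P = numeric(0))),
            class = "phylogeny")
}

#' Record a division event in a phylogeny
#'
#' Closes the mother's edge at `time`, opens two daughter edges, and
#' annotates the new vertex with the mother's position. The mother must be
#' a live (not yet divided) edge.
#'
#' @param tree A [new_phylogeny()] object.
#' @param mother,daughter1,daughter2 Cell ids.
#' @param time Division time, h.
#' @param P Position of the dividing cell.
#' @return The updated `phylogeny`.
#' @export
record_division <- function(tree, mother, daughter1, daughter2, time, P) {
  if (!mother %in% tree$cells$id)
    stop("unknown mother cell: ", mother)
  if (mother %in% tree$vertices$id)
    stop("mother cell ", mother, " has already divided")
  tree$vertices <- rbind(tree$vertices,
                         data.frame(id = as.integer(mother), time = time,
                                    P = P))
  tree$cells <- rbind(tree$cells,
                      data.frame(id = as.integer(c(daughter1, daughter2)),
                                 parent = as.integer(mother),
                                 birth_time = time))
  tree
}

#' Build the stem-cell division forest of a simulation
#'
#' Replays the recorded stem-cell divisions of a [run_scenario()] result.
#' Roots are the stem cells at analysis start; stem cells that arose later
#' by fate reversal start additional root edges. Leaf outcomes
#' (`specified`, `anoikis`, `exit`, `alive`) and end times are annotated
#' from the event log.
#'
#' @param result A [run_scenario()] result.
#' @return A `phylogeny` with an `outcomes` annotation data frame.
#' @export
build_phylogeny <- function(result) {
  start <- result$start
  surface <- crypt_surface(result$params$cap_radius,
                           result$params$exit_position)
  sc0 <- start[start$state == "SC", , drop = FALSE]
  roots <- data.frame(id = sc0$id, birth_time = 0,
                      P = axial_position(as.matrix(sc0[, c("x", "y", "z")]),
                                         surface))
  tree <- new_phylogeny(roots)
  div <- result$divisions
  div <- div[div$mother_state == "SC", , drop = FALSE]
  div <- div[order(div$time), , drop = FALSE]
  ev <- result$events
  for (k in seq_len(nrow(div))) {
    if (!div$mother[k] %in% tree$cells$id) {
      # a progenitor reverted to SC after analysis start: new root edge
      born <- ev$time[ev$id == div$mother[k] & ev$event == "fate_change" &
                        ev$state_new == "SC"]
      tree$cells <- rbind(tree$cells,
                          data.frame(id = div$mother[k],
                                     parent = NA_integer_,
                                     birth_time = if (length(born)) min(born)
                                                  else 0))
    }
    tree <- record_division(tree, div$mother[k], div$daughter1[k],
                            div$daughter2[k], div$time[k], div$P[k])
  }
  tree$outcomes <- .leaf_outcomes(tree, ev, result$end_time)
  tree$end_time <- result$end_time
  tree
}

.leaf_outcomes <- function(tree, ev, end_time) {
  leaves <- setdiff(tree$cells$id, tree$vertices$id)
  out <- data.frame(id = leaves, outcome = "alive", time = end_time,
                    stringsAsFactors = FALSE)
  if (nrow(ev)) {
    for (k in seq_len(nrow(out))) {
      e <- ev[ev$id == out$id[k], , drop = FALSE]
      spec <- e[e$event == "fate_change" & e$state_old == "SC", , drop = FALSE]
      gone <- e[e$event %in% c("anoikis", "exit"), , drop = FALSE]
      cand <- rbind(
        if (nrow(spec)) data.frame(outcome = "specified",
                                   time = min(spec$time)),
        if (nrow(gone)) data.frame(outcome = gone$event[1],
                                   time = gone$time[1]))
      if (!is.null(cand) && nrow(cand)) {
        first <- which.min(cand$time)
        out$outcome[k] <- as.character(cand$outcome[first])
        out$time[k] <- cand$time[first]
      }
    }
  }
  out
}

#' @export
print.phylogeny <- function(x, ...) {
  cat(sprintf("<phylogeny> %d roots, %d division vertices, %d live/leaf edges\n",
              sum(is.na(x$cells$parent)), nrow(x$vertices),
              nrow(x$cells) - nrow(x$vertices)))
  invisible(x)
}

# one rooted component -> ape::phylo (NULL for a never-divided root)
.component_phylo <- function(tree, root, end_time) {
  kids <- split(tree$cells$id, tree$cells$parent)
  ids <- root
  frontier <- root
  while (length(frontier)) {
    nxt <- unlist(kids[as.character(frontier)], use.names = FALSE)
    ids <- c(ids, nxt)
    frontier <- nxt
  }
  cells <- tree$cells[match(ids, tree$cells$id), ]
  divided <- ids %in% tree$vertices$id
  tips <- ids[!divided]
  if (length(tips) < 2) return(NULL)
  internals <- c(root, setdiff(ids[divided], root))
  node_no <- c(setNames(seq_along(tips), tips),
               setNames(length(tips) + seq_along(internals), internals))
  end_of <- function(id) {
    v <- tree$vertices$time[match(id, tree$vertices$id)]
    if (!is.na(v)) return(v)
    o <- tree$outcomes$time[match(id, tree$outcomes$id)]
    if (!is.null(o) && length(o) && !is.na(o)) o else end_time
  }
  nonroot <- ids[ids != root]
  edge <- cbind(node_no[as.character(cells$parent[match(nonroot, cells$id)])],
                node_no[as.character(nonroot)])
  elen <- vapply(nonroot, function(id) {
    end_of(id) - cells$birth_time[match(id, cells$id)]
  }, numeric(1))
  phy <- list(edge = unname(edge), edge.length = unname(elen),
              tip.label = paste0("c", tips),
              node.label = paste0("c", internals),
              Nnode = length(internals))
  class(phy) <- "phylo"
  phy$root.edge <- end_of(root) - cells$birth_time[match(root, cells$id)]
  phy
}

#' Export a phylogeny as Newick
#'
#' Branch lengths are in hours. Vertex/leaf annotations (time, position P,
#' outcome) are returned as a companion table keyed by node label; the
#' strings round-trip through standard Newick parsers (e.g.
#' `ape::read.tree`).
#'
#' @param tree A `phylogeny` (from [build_phylogeny()]).
#' @param file Optional path; Newick strings are written one per line.
#' @return List with `newick` (character vector, one entry per root with at
#'   least one division) and `annotations` (data frame).
#' @export
export_newick <- function(tree, file = NULL) {
  end_time <- if (!is.null(tree$end_time)) tree$end_time else
    max(c(0, tree$vertices$time))
  roots <- tree$cells$id[is.na(tree$cells$parent)]
  phys <- lapply(roots, function(r) .component_phylo(tree, r, end_time))
  keep <- !vapply(phys, is.null, logical(1))
  nwk <- vapply(phys[keep], ape::write.tree, character(1))
  ann <- rbind(
    if (nrow(tree$vertices))
      data.frame(label = paste0("c", tree$vertices$id), type = "vertex",
                 time = tree$vertices$time, P = tree$vertices$P,
                 outcome = NA_character_, stringsAsFactors = FALSE),
    if (!is.null(tree$outcomes) && nrow(tree$outcomes))
      data.frame(label = paste0("c", tree$outcomes$id), type = "leaf",
                 time = tree$outcomes$time, P = NA_real_,
                 outcome = tree$outcomes$outcome, stringsAsFactors = FALSE))
  if (is.null(ann)) {
    ann <- data.frame(label = character(0), type = character(0),
                      time = numeric(0), P = numeric(0),
                      outcome = character(0))
  }
  if (!is.null(file)) writeLines(nwk, file)
  list(newick = nwk, annotations = ann)
}

#' Detect monoclonal conversion in a snapshot series
#'
#' Conversion is the first time at which all tracked cells share one
#' founder label. By default the tracked population is the stem cells
#' (competition among long-lived Paneth cells would otherwise dominate the
#' clock); `population = "all"` tracks every cell.
#'
#' @param snapshots Data frame with columns `time`, `founder`, `state`
#'   (multiple rows per time point).
#' @param population `"SC"` or `"all"`.
#' @return Conversion time in hours, or `NA` if it never happens within
#'   the snapshots.
#' @export
detect_monoclonal_conversion <- function(snapshots, population = "SC") {
  stopifnot(all(c("time", "founder", "state") %in% names(snapshots)))
  for (t in sort(unique(snapshots$time))) {
    s <- snapshots[snapshots$time == t, ]
    if (population == "SC") s <- s[s$state == "SC", ]
    if (nrow(s) > 0 && length(unique(s$founder)) == 1) return(t)
  }
  NA_real_
}

#' Positional distributions f(P), w(P), p(P)
#'
#' Unit-width integer position bins (`floor(P)`). `f`: fraction of stem
#' cells per bin at competition start (mean and s.d. across replicates).
#' `w`: probability that the winning clone originates per bin, estimated
#' from the winner founders' start positions pooled across replicates
#' (binomial standard errors). `p`: fraction of stem-cell division events
#' per bin. Each distribution sums to 1 where data exist.
#'
#' @param start_P List of numeric vectors: stem-cell positions at
#'   competition start, one vector per replicate.
#' @param winner_P Numeric vector of winner-origin positions (one entry
#'   per replicate that produced a winner; `NA`s are dropped).
#' @param division_P List of numeric vectors: positions of stem-cell
#'   division events per replicate.
#' @return A `positional_distribution` object.
#' @export
positional_distributions <- function(start_P, winner_P = numeric(0),
                                     division_P = list()) {
  winner_P <- winner_P[!is.na(winner_P)]
  top <- max(c(unlist(start_P), winner_P, unlist(division_P), 0))
  bins <- 0:floor(top)
  hist_norm <- function(v) {
    h <- tabulate(floor(v) + 1L, nbins = length(bins))
    if (sum(h) > 0) h / sum(h) else h
  }
  f_mat <- do.call(rbind, lapply(start_P, hist_norm))
  p_mat <- if (length(division_P))
    do.call(rbind, lapply(division_P, hist_norm)) else NULL
  w_cnt <- tabulate(floor(winner_P) + 1L, nbins = length(bins))
  nw <- length(winner_P)
  w <- if (nw > 0) w_cnt / nw else rep(NA_real_, length(bins))
  structure(list(
    bins = bins,
    f = colMeans(f_mat), f_sd = apply(f_mat, 2, sd),
    w = w, w_se = if (nw > 0) sqrt(w * (1 - w) / nw) else w,
    p = if (!is.null(p_mat)) colMeans(p_mat) else rep(NA_real_, length(bins)),
    p_sd = if (!is.null(p_mat)) apply(p_mat, 2, sd) else rep(NA_real_, length(bins)),
    n_replicates = length(start_P), n_winners = nw,
    start_P = start_P, winner_P = winner_P, division_P = division_P),
    class = "positional_distribution")
}

#' @export
print.positional_distribution <- function(x, ...) {
  cat(sprintf("<positional_distribution> %d replicates, %d winners, bins 0..%d\n",
              x$n_replicates, x$n_winners, max(x$bins)))
  df <- data.frame(P = x$bins, f = round(x$f, 3), w = round(x$w, 3),
                   p = round(x$p, 3))
  print(df[df$f > 0 | (!is.na(df$w) & df$w > 0), ], row.names = FALSE)
  invisible(x)
}

#' Positional competitive advantage w(P)/f(P)
#'
#' Ratios above one mark positions whose stem cells win clonal competition
#' more often than their share of the population predicts. Bins with
#' `f = 0` are excluded; uncertainty combines the replicate s.d. of `f`
#' and the binomial s.e. of `w`.
#'
#' @param dist A [positional_distributions()] result.
#' @return Data frame: `P`, `f`, `w`, `ratio`, `se`.
#' @export
advantage_ratio <- function(dist) {
  if (dist$n_winners == 0)
    stop("no winners across replicates: w(P) is undefined")
  keep <- dist$f > 0
  f <- dist$f[keep]; w <- dist$w[keep]
  rel <- sqrt((dist$w_se[keep] / pmax(w, .Machine$double.eps))^2 +
                (dist$f_sd[keep] / f)^2)
  data.frame(P = dist$bins[keep], f = f, w = w, ratio = w / f,
             se = (w / f) * rel)
}

#' Number of 'advantaged' stem cells
#'
#' Stem cells located, at competition start, in position bins from which
#' winning clones originate (`w(P) > 0`). Reported as the mean (and s.d.)
#' across replicates of the per-crypt count.
#'
#' @param dist A [positional_distributions()] result.
#' @return List with `mean`, `sd`, `bins` (the advantaged bins) and
#'   `per_replicate` counts.
#' @export
count_advantaged_SCs <- function(dist) {
  if (dist$n_winners == 0)
    stop("no winners across replicates: w(P) is undefined")
  adv_bins <- dist$bins[!is.na(dist$w) & dist$w > 0]
  cnt <- vapply(dist$start_P,
                function(v) sum(floor(v) %in% adv_bins), numeric(1))
  list(mean = mean(cnt), sd = sd(cnt), bins = adv_bins, per_replicate = cnt)
}

#' Fixation statistics over labelled-clone replicates
#'
#' Each replicate resolves to `fixed` (the labelled clone is the sole
#' founder lineage among stem cells), `lost` (no labelled cell remains) or
#' `censored`. The fixation probability is `fixed / (fixed + lost)`; the
#' expected number of fixations out of `n` independent mutations is
#' `n * p_fix`.
#'
#' @param outcomes Character vector (or data frame with column `outcome`)
#'   of per-replicate outcomes.
#' @param n Number of stem cells (mutations) the per-`n` statistic refers
#'   to.
#' @return List: `p_fix`, `fixations_per_n`, `n_fixed`, `n_lost`,
#'   `n_censored`.
#' @export
fixation_statistics <- function(outcomes, n = NULL) {
  if (is.data.frame(outcomes)) outcomes <- outcomes$outcome
  nf <- sum(outcomes == "fixed")
  nl <- sum(outcomes == "lost")
  nc <- sum(outcomes == "censored")
  if (nf + nl == 0) {
    warning("all replicates censored: fixation probability undefined")
    return(list(p_fix = NA_real_, fixations_per_n = NA_real_, n_fixed = nf,
                n_lost = nl, n_censored = nc))
  }
  p <- nf / (nf + nl)
  list(p_fix = p,
       fixations_per_n = if (!is.null(n)) n * p else NA_real_,
       n_fixed = nf, n_lost = nl, n_censored = nc)
}

#' Expected fixations out of n mutations for a mutation-placement rule
#'
#' For neutral labels, the chance that a clone starting in bin `P` wins is
#' `w(P) / (n f(P))`, so placing `n` independent mutations with positional
#' distribution `q` yields `sum_P q(P) w(P) / f(P)` expected fixations.
#' Random (position-independent) placement uses `q = f` and returns 1 by
#' construction; division-associated placement uses `q = p` and is
#' depressed wherever divisions are rarer than cells.
#'
#' @param dist A [positional_distributions()] result.
#' @param weighting `"random"` (q = f) or `"division"` (q = p).
#' @return Expected number of fixations out of `n` mutations.
#' @export
expected_fixations <- function(dist, weighting = c("random", "division")) {
  weighting <- match.arg(weighting)
  keep <- dist$f > 0
  q <- switch(weighting, random = dist$f, division = dist$p)
  sum(q[keep] * dist$w[keep] / dist$f[keep])
}
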
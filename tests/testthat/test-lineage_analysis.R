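# Division forests, monoclonal conversion, positional statistics,
# fixation probabilities, Newick export.

test_that("record_division keeps the forest bookkeeping straight", {
  tr <- new_phylogeny(data.frame(id = 1))
  tr <- record_division(tr, 1, 2, 3, time = 10, P = 1.5)
  expect_equal(nrow(tr$vertices), 1)
  expect_equal(sum(!tr$cells$id %in% tr$vertices$id), 2) # two leaf edges
  # chain of three divisions: 3 vertices, 4 leaves
  tr <- record_division(tr, 2, 4, 5, time = 25, P = 2.0)
  tr <- record_division(tr, 4, 6, 7, time = 41, P = 0.5)
  expect_equal(nrow(tr$vertices), 3)
  expect_equal(sum(!tr$cells$id %in% tr$vertices$id), 4)
  expect_error(record_division(tr, 99, 8, 9, 50, 1), "unknown mother")
  expect_error(record_division(tr, 1, 8, 9, 50, 1), "already divided")
})

test_that("replaying a run's divisions reproduces the stem-cell history", {
  p <- test_params()
  res <- run_scenario(p, seed = 71, hours = 336, stop_at_conversion = FALSE)
  tr <- build_phylogeny(res)
  # every stem cell alive at the end is a live (undivided) edge
  live_sc <- res$final$id[res$final$state == "SC"]
  leaves <- setdiff(tr$cells$id, tr$vertices$id)
  expect_true(all(live_sc %in% tr$cells$id))
  expect_true(all(live_sc %in% leaves))
  # vertices correspond one-to-one to recorded SC divisions
  expect_equal(nrow(tr$vertices),
               sum(res$divisions$mother_state == "SC"))
  # live SCs that never specified are open ("alive") edges; a live SC that
  # specified and later reverted had its original edge closed at the
  # specification event
  alive <- tr$outcomes$id[tr$outcomes$outcome == "alive"]
  ev <- res$events
  ever_specified <- unique(ev$id[ev$event == "fate_change" &
                                   ev$state_old == "SC"])
  expect_setequal(intersect(alive, live_sc),
                  setdiff(live_sc, ever_specified))
})

test_that("monoclonal conversion detection handles the edge cases", {
  snaps <- data.frame(time = rep(c(0, 10), each = 3),
                      founder = c(1, 1, 1, 1, 1, 1),
                      state = "SC")
  expect_equal(detect_monoclonal_conversion(snaps), 0)
  snaps$founder <- rep(c(1, 2, 1), 2)
  expect_true(is.na(detect_monoclonal_conversion(snaps)))
  # non-SC cells are ignored under the default population
  snaps$state <- c("SC", "PC_terminal", "SC", "SC", "PC_terminal", "SC")
  expect_equal(detect_monoclonal_conversion(snaps), 0)
  expect_true(is.na(detect_monoclonal_conversion(snaps,
                                                 population = "all")))
})

test_that("3-cell neutral Moran conversion matches the transition-matrix oracle", {
  # one exchange per step: a uniformly chosen cell dies and a uniformly
  # chosen survivor reproduces; states by founder multiset
  # {1,1,1} -> {2,1} with probability 1; {2,1} absorbs with probability 1/3
  Q <- rbind(c(0, 1), c(0, 2 / 3)) # transient part over ({1,1,1}, {2,1})
  expected <- (solve(diag(2) - Q) %*% c(1, 1))[1] # mean steps to absorb
  set.seed(72)
  n_sim <- 1500
  times <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    founders <- 1:3
    snaps <- data.frame(time = 0, founder = founders, state = "SC")
    t <- 0
    while (length(unique(founders)) > 1) {
      t <- t + 1
      die <- sample(3, 1)
      founders[die] <- founders[sample(setdiff(1:3, die), 1)]
      snaps <- rbind(snaps, data.frame(time = t, founder = founders,
                                       state = "SC"))
    }
    times[s] <- detect_monoclonal_conversion(snaps)
  }
  se <- sd(times) / sqrt(n_sim)
  expect_lt(abs(mean(times) - expected), 2 * se)
})

test_that("positional distributions normalize and recover known categoricals", {
  set.seed(73)
  start_P <- replicate(30, runif(12, 0, 5), simplify = FALSE)
  q <- c(0.5, 0.3, 0.15, 0.05) # winner-origin distribution over bins 0..3
  winners <- sample(0:3, 400, replace = TRUE, prob = q) + runif(400)
  div_P <- replicate(30, runif(50, 0, 5), simplify = FALSE)
  d <- positional_distributions(start_P, winners, div_P)
  expect_equal(sum(d$f), 1, tolerance = 1e-12)
  expect_equal(sum(d$w), 1, tolerance = 1e-12)
  expect_equal(sum(d$p), 1, tolerance = 1e-12)
  for (b in 1:4) # multinomial recovery within 3 s.e.
    expect_lt(abs(d$w[b] - q[b]), 3 * sqrt(q[b] * (1 - q[b]) / 400) + 1e-9)
})

test_that("advantage ratio is 1 under neutrality and excludes empty bins", {
  start_P <- replicate(10, c(rep(0.5, 5), rep(1.5, 5)), simplify = FALSE)
  winners <- c(rep(0.5, 10), rep(1.5, 10)) # w matches f exactly
  d <- positional_distributions(start_P, winners)
  ar <- advantage_ratio(d)
  expect_equal(ar$ratio, c(1, 1))
  expect_equal(ar$P, c(0, 1)) # no other bins reported
})

test_that("advantaged-SC counting equals brute force on crafted snapshots", {
  start_P <- list(c(0.2, 0.8, 1.3, 2.4, 3.7), c(0.5, 1.1, 1.9, 2.2, 4.4))
  winners <- c(0.3, 1.6) # w > 0 in bins 0 and 1 only
  d <- positional_distributions(start_P, winners)
  adv <- count_advantaged_SCs(d)
  expect_equal(adv$bins, c(0, 1))
  expect_equal(adv$per_replicate, c(3, 3)) # cells with floor(P) in {0,1}
  expect_equal(adv$mean, 3)
})

test_that("fixation statistics reproduce the neutral-drift arithmetic", {
  # 1 fixation out of 13 resolved labels: loss fraction 12/13 ~ 92%
  out <- rep(c("fixed", "lost"), c(1, 12))
  fs <- fixation_statistics(out, n = 13)
  expect_equal(fs$p_fix, 1 / 13)
  expect_equal(1 - fs$p_fix, 0.923, tolerance = 0.001)
  expect_equal(fs$fixations_per_n, 1)
  expect_warning(fs2 <- fixation_statistics(rep("censored", 5)), "censored")
  expect_true(is.na(fs2$p_fix))
  expect_equal(fixation_statistics(rep("fixed", 4))$p_fix, 1)
})

test_that("expected fixations weight clone win odds by mutation placement", {
  start_P <- replicate(20, c(rep(0.5, 4), rep(1.5, 4), rep(2.5, 4)),
                       simplify = FALSE)
  winners <- c(rep(0.5, 6), rep(1.5, 3), rep(2.5, 1))
  div_P <- replicate(20, c(rep(0.5, 1), rep(1.5, 4), rep(2.5, 5)),
                     simplify = FALSE)
  d <- positional_distributions(start_P, winners, div_P)
  expect_equal(expected_fixations(d, "random"), 1, tolerance = 1e-12)
  # hand computation: sum_b p(b) w(b) / f(b) with f = 1/3 per bin
  manual <- 0.1 * (6 / 10) / (1 / 3) + 0.4 * (3 / 10) / (1 / 3) +
    0.5 * (1 / 10) / (1 / 3)
  expect_equal(expected_fixations(d, "division"), manual)
})

test_that("Newick export round-trips through ape", {
  # single division with branch lengths 5 and 7
  tr <- new_phylogeny(data.frame(id = 1))
  tr <- record_division(tr, 1, 2, 3, time = 3, P = 1)
  tr$outcomes <- data.frame(id = c(2, 3), outcome = "alive", time = c(8, 10))
  tr$end_time <- 10
  nk <- export_newick(tr)
  phy <- ape::read.tree(text = nk$newick[1])
  expect_setequal(phy$tip.label, c("c2", "c3"))
  expect_setequal(phy$edge.length, c(5, 7))
  # random forest: leaf set and total length survive the round trip
  set.seed(74)
  tr <- new_phylogeny(data.frame(id = 1))
  t <- 0; next_id <- 2
  for (k in 1:50) {
    live <- setdiff(tr$cells$id, tr$vertices$id)
    m <- sample(live, 1)
    t <- t + runif(1, 1, 20)
    tr <- record_division(tr, m, next_id, next_id + 1, time = t,
                          P = runif(1, 0, 5))
    next_id <- next_id + 2
  }
  leaves <- setdiff(tr$cells$id, tr$vertices$id)
  tr$outcomes <- data.frame(id = leaves, outcome = "alive", time = t + 5)
  tr$end_time <- t + 5
  nk <- export_newick(tr)
  phy <- ape::read.tree(text = nk$newick[1])
  expect_setequal(phy$tip.label, paste0("c", leaves))
  manual_total <- sum(vapply(tr$cells$id, function(id) {
    end <- if (id %in% tr$vertices$id)
      tr$vertices$time[match(id, tr$vertices$id)] else t + 5
    end - tr$cells$birth_time[match(id, tr$cells$id)]
  }, numeric(1)))
  round_trip_total <- sum(phy$edge.length) +
    if (!is.null(phy$root.edge)) phy$root.edge else 0
  expect_equal(round_trip_total, manual_total, tolerance = 1e-6)
  # export -> parse -> export is idempotent
  expect_identical(ape::write.tree(phy),
                   ape::write.tree(ape::read.tree(
                     text = ape::write.tree(phy))))
})
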
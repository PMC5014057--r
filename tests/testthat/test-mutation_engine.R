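# Heritable mutation profiles, selectors and their invariants.

test_that("profiles validate their keys and preconditions", {
  expect_error(mutation_profile("x", growth_rate = 2), "unknown override")
  expect_error(mutant1_profile(3), "C1_value")
  expect_error(mutant1_profile(6), "C1_value")
  m1 <- mutant1_profile(5)
  expect_equal(m1$overrides$C1_eff, 5L)
  m2 <- mutant2_profile(4)
  expect_equal(m2$overrides$C1_eff, 4L)
  expect_equal(m2$overrides$vp_scale, 0.76)
  expect_false(m2$overrides$pc_migration_bias)
  expect_true(m2$overrides$maintain_outside_niche)
})

test_that("deepest-SC selection uses minimal P with lowest-id tie break", {
  p <- sim_params()
  # two SCs at the same height on the cylinder wall (equal P), one higher
  cells <- cell_population(
    x = c(4, 0, 4, 4), y = c(0, 4, 0, 0), z = c(6, 6, 8, 9),
    state = c("SC", "SC", "SC", "EC_progenitor"), params = p)
  cells$id <- c(7L, 3L, 5L, 1L)
  out <- apply_mutation(cells, mutation_selector("deepest_SC"),
                        mutant1_profile(4))
  expect_equal(out$clone[out$id == 3L], 1L) # lowest id among the tied pair
  expect_equal(out$C1_eff[out$id == 3L], 4L)
  expect_equal(sum(out$clone), 1L)
  # a profile can never land on a non-SC
  expect_error(apply_mutation(cells[cells$state != "SC", , drop = FALSE],
                              mutation_selector("deepest_SC"),
                              mutant1_profile(4)),
               "no stem cell")
})

test_that("half_of_SCs splits the stem-cell pool in two", {
  set.seed(51)
  p <- sim_params()
  cells <- random_surface_population(10, p, p_max = 4, state = "SC")
  out <- apply_mutation(cells, mutation_selector("half_of_SCs"),
                        mutation_profile("low", C1_eff = 2L))
  expect_equal(sum(out$clone == 1L), 5)
  expect_equal(sum(out$C1_eff == 2L), 5)
})

test_that("a neutral label leaves the trajectory bit-identical", {
  p <- test_params()
  base <- run_scenario(p, seed = 52, hours = 336,
                       stop_at_conversion = FALSE)
  lab <- run_scenario(p, seed = 52, hours = 336,
                      mutation = list(selector = mutation_selector("random_SC"),
                                      profile = mutation_profile("neutral")),
                      stop_at_conversion = FALSE)
  drop_clone <- function(df) df[, setdiff(names(df), "clone")]
  expect_identical(drop_clone(base$events), drop_clone(lab$events))
  expect_identical(drop_clone(base$divisions), drop_clone(lab$divisions))
  expect_identical(base$final$x, lab$final$x)
  expect_true(any(lab$start$clone == 1L))
})

test_that("mutant profiles are heritable and exclusive to descendants", {
  p <- test_params()
  res <- run_scenario(p, seed = 53, hours = 504,
                      mutation = list(selector = mutation_selector("deepest_SC"),
                                      profile = mutant1_profile(4)),
                      stop_at_conversion = FALSE)
  mut_founder <- res$start$founder[res$start$clone == 1L]
  expect_length(mut_founder, 1)
  fin <- res$final
  expect_true(all(fin$clone[fin$founder == mut_founder] == 1L))
  expect_true(all(fin$clone[fin$founder != mut_founder] == 0L))
  expect_true(all(fin$C1_eff[fin$clone == 1L] == 4L))
  expect_true(all(fin$C1_eff[fin$clone == 0L] == p$C1))
})

test_that("mutant1 progeny are biased toward the Paneth fate", {
  # pooled over replicates: among stem-cell specification events, the
  # share going to the Paneth lineage is higher for mutant1 (C1 = 4)
  share <- c(mut = 0, wt = 0); tot <- c(mut = 0, wt = 0)
  for (s in 1:3) {
    p <- test_params()
    res <- run_scenario(p, seed = 60 + s, hours = 504,
                        mutation = list(
                          selector = mutation_selector("random_SC"),
                          profile = mutant1_profile(4)),
                        stop_at_conversion = FALSE)
    fc <- res$events[res$events$event == "fate_change" &
                       res$events$state_old == "SC", ]
    is_mut <- fc$clone == 1L
    share["mut"] <- share["mut"] +
      sum(fc$state_new[is_mut] == "PC_progenitor")
    share["wt"] <- share["wt"] +
      sum(fc$state_new[!is_mut] == "PC_progenitor")
    tot <- tot + c(sum(is_mut), sum(!is_mut))
  }
  expect_gt(tot[["mut"]], 5)
  expect_gt(share[["mut"]] / tot[["mut"]], share[["wt"]] / tot[["wt"]])
})

test_that("division-associated mutation labels a daughter of an SC division", {
  p <- test_params()
  res <- run_scenario(p, seed = 54, hours = 336,
                      mutation = list(timing = "division_associated",
                                      profile = mutation_profile("neutral")),
                      stop_at_conversion = FALSE)
  lab <- res$start[res$start$clone == 1L, ]
  expect_equal(nrow(lab), 1)
  expect_equal(lab$state, "SC")
  expect_lte(lab$age, p$fate_dt) # newborn at analysis start
})
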
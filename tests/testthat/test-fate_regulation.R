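# Positional Wnt classes, ligand-contact counts and the fate table.

test_that("wnt class boundaries put thresholds in the lower class", {
  p <- sim_params(P1 = 5, P2 = 12)
  expect_equal(wnt_class(c(0, 4.99, 5, 11.99, 12, 20), p),
               c("high", "high", "low", "low", "terminal_zone",
                 "terminal_zone"))
  expect_error(wnt_class(-1, p))
})

test_that("ligand contacts count secretory neighbours only", {
  p <- sim_params()
  cells <- make_niche_fixture(c("SC", "PC_terminal", "PC_terminal",
                                "PC_progenitor", "EC_progenitor",
                                "EC_progenitor"), p)
  cnt <- count_ligand_contacts(cells)
  expect_equal(cnt$n_PC[1], 3) # progenitor and terminal PCs both count
  expect_equal(cnt$n_GC[1], 0)
  lone <- cell_population(4, 0, 20, params = p)
  cnt <- count_ligand_contacts(lone)
  expect_equal(unlist(cnt), c(n_PC = 0, n_GC = 0))
})

test_that("contact counts match brute-force enumeration on a 12-cell config", {
  set.seed(31)
  p <- sim_params()
  states <- c("SC", "SC", "PC_terminal", "PC_progenitor", "GC_progenitor",
              "GC_terminal", "EC_progenitor", "EC_terminal", "SC",
              "PC_terminal", "GC_progenitor", "EC_progenitor")
  cells <- random_surface_population(12, p, state = states)
  cnt <- count_ligand_contacts(cells)
  r <- cell_radius(cells$volume)
  for (i in 1:12) {
    npc <- ngc <- 0
    for (j in setdiff(1:12, i)) {
      d <- sqrt(sum((cells[i, c("x", "y", "z")] -
                       cells[j, c("x", "y", "z")])^2))
      if (d < p$contact_factor * (r[i] + r[j])) {
        if (cells$state[j] %in% c("PC_progenitor", "PC_terminal"))
          npc <- npc + 1
        if (cells$state[j] %in% c("GC_progenitor", "GC_terminal"))
          ngc <- ngc + 1
      }
    }
    expect_equal(cnt$n_PC[i], npc)
    expect_equal(cnt$n_GC[i], ngc)
  }
})

test_that("the fate table implements the Wnt/Notch rules and boundaries", {
  p <- sim_params(P1 = 5, P2 = 12, C1 = 3, C2 = 1)
  case <- function(state, n_PC, n_GC, P, C1 = 3L, C2 = 1L, outside = 0L) {
    cells <- cell_population(0, 0, 0, state = state, params = p,
                             C1_eff = C1, C2_eff = C2,
                             outside_niche = outside)
    update_fate(cells, n_PC, n_GC, P = P, params = p)
  }
  # SC: Notch loss specifies Paneth; >= C1 is sufficient (boundary)
  expect_equal(case("SC", 2, 0, P = 1), "PC_progenitor")
  expect_equal(case("SC", 3, 0, P = 1), "SC")
  # SC leaving the niche follows the enterocyte branch
  expect_equal(case("SC", 5, 1, P = 6), "EC_progenitor")
  expect_equal(case("SC", 5, 0, P = 6), "GC_progenitor")
  expect_equal(case("SC", 5, 0, P = 13), "EC_terminal")
  # EC: terminal differentiation, reversibility, goblet specification
  expect_equal(case("EC_progenitor", 0, 1, P = 12), "EC_terminal")
  expect_equal(case("EC_progenitor", 3, 0, P = 4), "SC")
  expect_equal(case("EC_progenitor", 0, 0, P = 8), "GC_progenitor")
  expect_equal(case("EC_progenitor", 0, 1, P = 8), "EC_progenitor")
  # GC: regaining contacts reverts; terminal zone fixes the fate
  expect_equal(case("GC_progenitor", 0, 1, P = 8), "EC_progenitor")
  expect_equal(case("GC_progenitor", 0, 0, P = 12), "GC_terminal")
  expect_equal(case("GC_progenitor", 0, 0, P = 8), "GC_progenitor")
  # PC progenitor reverts to SC with enough Paneth contacts at high Wnt
  expect_equal(case("PC_progenitor", 3, 0, P = 2), "SC")
  expect_equal(case("PC_progenitor", 2, 0, P = 2), "PC_progenitor")
  # autonomous Notch: thresholds zero, no secretory specification ever
  expect_equal(case("SC", 0, 0, P = 1, C1 = 0L, C2 = 0L), "SC")
  expect_equal(case("EC_progenitor", 0, 0, P = 8, C1 = 0L, C2 = 0L),
               "EC_progenitor")
  # niche-independent mutants: Wnt treated high everywhere, no terminal
  expect_equal(case("SC", 3, 0, P = 20, outside = 1L), "SC")
  expect_equal(case("SC", 0, 0, P = 20, outside = 1L), "PC_progenitor")
  # calling on a terminal cell is a logic error
  expect_error(case("EC_terminal", 0, 0, P = 8),
               "terminally differentiated")
})

test_that("the state machine is closed over random non-terminal inputs", {
  set.seed(32)
  p <- sim_params()
  for (k in 1:200) {
    s <- sample(cell_states()[1:4], 1)
    out <- update_fate(
      cell_population(0, 0, 0, state = s, params = p,
                      C1_eff = sample(0:5, 1), C2_eff = sample(0:2, 1)),
      n_PC = sample(0:6, 1), n_GC = sample(0:6, 1),
      P = runif(1, 0, 30), params = p)
    expect_true(out %in% cell_states())
  }
})

test_that("specification is reversible within one fate tick", {
  p <- sim_params()
  forced <- cell_population(0, 0, 0, state = "PC_progenitor", params = p)
  expect_equal(update_fate(forced, n_PC = 3, n_GC = 0, P = 1, params = p),
               "SC")
})

test_that("a dividing Paneth progenitor yields two terminal Paneth daughters", {
  set.seed(33)
  p <- sim_params()
  mother <- cell_population(0, 0, 0, state = "PC_progenitor", params = p)
  mother$volume <- 2 * p$v0
  d <- divide_cell(mother, p)
  expect_equal(d$state, c("PC_terminal", "PC_terminal"))
  expect_true(all(d$intrinsic_lifespan > 0))
})

test_that("a long-inhibited Paneth progenitor converts without dividing", {
  set.seed(34)
  # forces off so the compressed cluster stays compressed for a full tick
  p <- sim_params(k_rep = 0, k_adh = 0, k_mem = 0, bias_up = 0,
                  bias_down = 0)
  cells <- cell_population(x = 0.05 * (0:6), y = rep(0, 7), z = rep(0.1, 7),
                           state = c("PC_progenitor", rep("SC", 6)),
                           params = p)
  cells$pc_wait[1] <- 46 # one more inhibited tick crosses the 48 h limit
  out <- cryptdrift:::.run_chunk(cells, p, hours = p$fate_dt, t0 = 0,
                                 next_id = 100L)
  final <- out$cells
  row <- match(1L, final$id)
  expect_equal(final$state[row], "PC_terminal")
  expect_true(final$intrinsic_lifespan[row] > 0)
  expect_false(1L %in% out$divisions$mother)
})
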
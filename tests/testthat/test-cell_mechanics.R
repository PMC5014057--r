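# Contacts, forces, overdamped motion, growth, division, removal.

test_that("contact graph equals the brute-force all-pairs oracle", {
  set.seed(21)
  p <- sim_params()
  cells <- random_surface_population(20, p)
  cells$volume <- cells$v0 * runif(20, 1, 2)
  g <- detect_contacts(cells, p)
  r <- cell_radius(cells$volume)
  oracle <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    d <- sqrt(sum((cells[i, c("x", "y", "z")] - cells[j, c("x", "y", "z")])^2))
    if (d < p$contact_factor * (r[i] + r[j]))
      oracle <- rbind(oracle, c(cells$id[i], cells$id[j]))
  }
  expect_equal(nrow(g$edges), NROW(oracle))
  if (NROW(oracle) > 0)
    expect_true(all(apply(g$edges, 1, paste, collapse = "-") %in%
                      apply(oracle, 1, paste, collapse = "-")))
  # boundary conventions
  two <- cell_population(c(0, 1.8), c(0, 0), c(4, 4))
  g2 <- detect_contacts(two, p) # d = 0.9 * (r_i + r_j), factor 1.1
  expect_equal(nrow(g2$edges), 1)
  apart <- cell_population(c(0, 4), c(0, 0), c(4, 4))
  expect_equal(nrow(detect_contacts(apart, p)$edges), 0)
})

test_that("pairwise force has the Hertz/adhesion closed form", {
  p <- sim_params(k_rep = 1, k_adh = 0.2, adhesion_range = 0.2)
  mk <- function(x) cell_population(x, 0, 4, params = p) # radius 1 cells
  # overlap 0.1 -> repulsion 0.1^1.5 along the centre line
  f <- pairwise_force(mk(0), mk(1.9), p)
  expect_equal(f, c(-0.1^1.5, 0, 0))
  # exact touching: zero repulsion, adhesion at full magnitude
  f <- pairwise_force(mk(0), mk(2), p)
  expect_equal(f, c(0.2, 0, 0))
  # just beyond the adhesion range: no force
  f <- pairwise_force(mk(0), mk(2.21), p)
  expect_equal(f, c(0, 0, 0))
  # antisymmetry for a random off-axis pair
  a <- cell_population(0.3, -0.2, 4.4, params = p)
  b <- cell_population(1.1, 0.5, 3.8, params = p)
  expect_equal(pairwise_force(a, b, p), -pairwise_force(b, a, p))
})

test_that("internal forces sum to zero over a random configuration", {
  set.seed(22)
  p <- sim_params()
  cells <- random_surface_population(15, p)
  g <- detect_contacts(cells, p)
  total <- c(0, 0, 0)
  if (nrow(g$edges)) {
    for (k in seq_len(nrow(g$edges))) {
      i <- match(g$edges[k, 1], cells$id)
      j <- match(g$edges[k, 2], cells$id)
      total <- total + pairwise_force(cells[i, ], cells[j, ], p) +
        pairwise_force(cells[j, ], cells[i, ], p)
    }
  }
  expect_lt(max(abs(total)), 1e-9)
})

test_that("migration bias follows lineage and position rules", {
  p <- sim_params()
  surf <- crypt_surface(p$cap_radius, p$exit_position)
  cells <- cell_population(
    x = c(0, 4, 4, 0, 4), y = c(0, 0, 0, 0, 0), z = c(0, 4, 10, 0, 8),
    state = c("SC", "EC_progenitor", "PC_terminal", "PC_terminal",
              "PC_terminal"),
    params = p)
  cells$pc_bias[5] <- 0L # mutant-derived Paneth cell: no bias
  f <- migration_bias_force(cells, surf, p)
  expect_equal(f[1, ], c(0, 0, 0))                  # SC: none
  expect_equal(f[2, ], c(0, 0, p$bias_up))          # EC at equator: up
  expect_equal(f[3, ], c(0, 0, -p$bias_down))       # PC on cylinder: down
  expect_equal(f[4, ], c(0, 0, 0))                  # PC at the pole: none
  expect_equal(f[5, ], c(0, 0, 0))                  # biasless mutant PC
})

test_that("an isolated stem cell does not move", {
  p <- sim_params()
  cells <- cell_population(4, 0, 8, state = "SC", params = p)
  out <- step_positions(cells, p, n_steps = 50)
  expect_equal(out[, c("x", "y", "z")], cells[, c("x", "y", "z")])
})

test_that("an overlapping pair separates monotonically, matching a fine oracle", {
  p <- sim_params()
  # two cells on the cylinder wall separated along z: 1D dynamics
  cells <- cell_population(c(4, 4), c(0, 0), c(8, 9), state = "SC",
                           params = p)
  gaps <- numeric(40)
  cur <- cells
  for (k in 1:40) {
    cur <- step_positions(cur, p, n_steps = 1)
    gaps[k] <- cur$z[2] - cur$z[1]
  }
  expect_true(all(diff(gaps) >= -1e-12))
  # independent fine-timestep oracle for the relative coordinate
  sep <- 1
  dt_f <- p$dt / 50
  for (s in seq_len(40 * 50)) {
    delta <- 2 - sep
    f <- if (delta > 0) p$k_rep * delta^1.5
         else if (-delta < p$adhesion_range) -p$k_adh else 0
    sep <- sep + 2 * f / p$friction * dt_f
  }
  expect_equal(gaps[40], sep, tolerance = 0.01)
})

test_that("a lone enterocyte drifts up the cylinder at bias/friction", {
  p <- sim_params()
  cells <- cell_population(4, 0, 8, state = "EC_terminal", params = p)
  out <- step_positions(cells, p, n_steps = 100) # 100 * dt hours
  expect_equal(out$z - 8, p$bias_up / p$friction * 100 * p$dt,
               tolerance = 1e-6)
  expect_equal(out$x, 4); expect_equal(out$y, 0)
})

test_that("available volume subtracts analytic lens overlaps", {
  p <- sim_params()
  solo <- cell_population(4, 0, 8, params = p)
  expect_equal(local_compression(solo), solo$volume)
  # two identical spheres radius r at distance d = r:
  # lens volume = pi (4r + d) (2r - d)^2 / 12 = 5 pi r^3 / 12
  r <- cell_radius(p$v0)
  two <- cell_population(c(4, 4), c(0, 0), c(8, 8 + r), params = p)
  lens <- 5 * pi * r^3 / 12
  expect_equal(local_compression(two), rep(p$v0 - lens, 2))
  # full engulfment floors at the smaller sphere volume
  stack <- cell_population(rep(4, 8), rep(0, 8), rep(8, 8) + 1e-4 * (1:8),
                           params = p)
  expect_equal(local_compression(stack), rep(0, 8))
})

test_that("growth doubles volume in one unconstrained growth time", {
  p <- sim_params(cycle_cv = 0)
  cells <- cell_population(4, 0, 8, state = "SC", params = p)
  out <- grow_cells(cells, p, dt = p$cycle_growth_time)
  expect_equal(out$volume, 2 * p$v0)
  expect_equal(out$inhibited, 0L)
})

test_that("contact inhibition pauses wild-type growth but not mutant2 in the Vp window", {
  p <- sim_params()
  # choose a centre distance whose lens overlap lands the available volume
  # strictly between the mutant threshold 0.76 * Vp and the wild-type Vp
  d <- uniroot(function(d) {
    (p$v0 - pi * (4 + d) * (2 - d)^2 / 12) / p$v0 - 0.88 * p$vp_frac
  }, c(0.5, 1.99))$root
  two <- cell_population(c(4, 4), c(0, 0), c(8, 8 + d), state = "SC",
                         params = p)
  avail <- local_compression(two)
  expect_true(all(avail > 0.76 * p$vp_frac * p$v0 &
                    avail < p$vp_frac * p$v0))
  wt <- grow_cells(two, p, dt = 1)
  expect_equal(wt$volume, two$volume) # paused
  expect_equal(wt$inhibited, c(1L, 1L))
  mut <- two
  mut$vp_scale <- 0.76
  m <- grow_cells(mut, p, dt = 1)
  expect_true(all(m$volume > two$volume)) # grows despite compression
})

test_that("division conserves volume, inherits profile, errors on terminal cells", {
  set.seed(23)
  p <- sim_params()
  cell <- cell_population(4, 0, 8, state = "SC", params = p,
                          C1_eff = 5L, clone = 1L, founder = 42L)
  cell$volume <- 2 * p$v0
  d <- divide_cell(cell, p, next_id = c(100L, 101L))
  expect_equal(sum(d$volume), 2 * p$v0)
  expect_equal(d$state, c("SC", "SC"))
  expect_equal(d$C1_eff, c(5L, 5L))
  expect_equal(d$clone, c(1L, 1L))
  expect_equal(d$founder, c(42L, 42L))
  term <- cell_population(4, 0, 8, state = "EC_terminal", params = p)
  term$volume <- 2 * p$v0
  expect_error(divide_cell(term, p), "terminally differentiated")
  small <- cell_population(4, 0, 8, state = "SC", params = p)
  expect_error(divide_cell(small, p), "twice its reference volume")
})

test_that("daughter separation directions are uniform on the tangent circle", {
  set.seed(24)
  p <- sim_params()
  cell <- cell_population(4, 0, 10, state = "SC", params = p)
  cell$volume <- 2 * p$v0
  n <- 4000
  ang <- numeric(n)
  for (k in seq_len(n)) {
    d <- divide_cell(cell, p)
    # tangent plane at (4, 0, 10): spanned by y and z
    ang[k] <- atan2(d$z[1] - 10, d$y[1] - 0)
  }
  counts <- table(cut(ang, breaks = seq(-pi, pi, length.out = 9)))
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("anoikis and exit removals honour the boundary conventions", {
  p <- sim_params()
  z30 <- p$cap_radius + (30 - p$cap_radius * pi / 2)
  cells <- cell_population(
    x = c(4, 4, 2, 4), y = c(0, 0, 0, 0),
    z = c(z30, z30 + 1, 8, 8),
    state = "EC_terminal", params = p)
  # third cell is detached (2 radii inside the wall at radius 4)
  out <- apply_anoikis_and_exit(cells, p)
  expect_equal(nrow(out$cells), 2)
  expect_setequal(out$removals$cause, c("exit", "anoikis"))
  expect_equal(out$removals$cause[out$removals$id == 2], "exit")
  expect_equal(out$removals$cause[out$removals$id == 3], "anoikis")
  # P = 30 exactly is retained (strict inequality)
  expect_true(1 %in% out$cells$id)
})
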
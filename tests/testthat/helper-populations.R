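# Small deterministic populations used across test files.

# n cells scattered on the surface between P = 0 and P = p_max
random_surface_population <- function(n, params = sim_params(), p_max = 12,
                                      state = "SC") {
  surf <- crypt_surface(params$cap_radius, params$exit_position)
  pts <- matrix(rnorm(3 * n), n, 3)
  pts[, 3] <- abs(pts[, 3])
  pts <- project_to_surface(pts * 3, surf)
  # push some onto the cylinder section
  up <- runif(n) < 0.5
  pts[up, 3] <- params$cap_radius + runif(sum(up)) *
    (p_max - params$cap_radius * pi / 2)
  pts[up, 1:2] <- pts[up, 1:2] /
    sqrt(rowSums(pts[up, 1:2, drop = FALSE]^2)) * params$cap_radius
  cell_population(pts[, 1], pts[, 2], pts[, 3], state = state,
                  params = params)
}

# fast parameters for short integration runs in tests
test_params <- function(...) {
  sim_params(burn_in_min_weeks = 1, burn_in_max_weeks = 6, ...)
}
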
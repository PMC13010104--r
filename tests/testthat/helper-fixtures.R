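# shared fixtures, all generated in code

# small test-scale trunk: 3 sections, light and short
toy_config <- function(...) {
  cfg <- default_config()
  cfg$total_length <- 0.4
  cfg$total_mass <- 10
  cfg$n_sections <- 3L
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  validate_config(unclass(cfg))
}

toy_structure <- function(...) build_structure(toy_config(...))

# 1-DoF mass-spring: node 0 fixed, node 1 free along the rod axis
mass_spring <- function(k = 4 * pi^2, m = 1, damping = 0) {
  cfg <- default_config()
  cfg$damping <- damping
  cfg$damping_beta <- 0
  trunk_structure(
    nodes = data.frame(node_id = 0:1, mass = m, x = c(0, 1), y = 0, z = 0),
    rods = data.frame(node1 = 0, node2 = 1, k = k),
    fixed_nodes = 0L, config = cfg)
}

# points sampled exactly on a 3D ellipse with the package frame convention
ellipse_points <- function(center, euler_zyx, a, b, n = 8,
                           arc = c(0, 2 * pi)) {
  R <- euler_zyx_to_matrix(euler_zyx)
  th <- seq(arc[1], arc[2], length.out = n + 1)[1:n]
  t(vapply(th, function(p) {
    center + a * cos(p) * R[, 2] + b * sin(p) * R[, 3]
  }, numeric(3)))
}

rms <- function(x) sqrt(mean(x^2))

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
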
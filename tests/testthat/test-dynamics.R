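test_that("gravity load puts -m g on every Z DoF", {
  st <- mass_spring(m = 2)
  g <- gravity_load(st, g = 9.81)
  expect_equal(g[c(3, 6)], c(-19.62, -19.62))
  expect_equal(g[c(1, 2, 4, 5)], rep(0, 4))
  sys <- trunk_system(toy_structure())
  gl <- gravity_load(sys)
  expect_equal(sum(gl), -10 * 9.81, tolerance = 1e-9)
  expect_true(all(gl[-seq(3, sys$ndof, by = 3)] == 0))
})

test_that("active resultants cancel pairwise and globally", {
  sys <- trunk_system(toy_structure())
  nrods <- nrow(sys$structure$rods)
  expect_equal(nodal_active_resultants(sys, numeric(nrods)),
               numeric(sys$ndof))
  # two opposite radial rods with equal force: zero resultant at the center
  rods <- sys$structure$rods
  rP <- which(rods$type == "radial" & rods$section == 2 & rods$role == "P")
  rQ <- which(rods$type == "radial" & rods$section == 2 & rods$role == "Q")
  f <- numeric(nrods); f[c(rP, rQ)] <- 7
  res <- nodal_active_resultants(sys, f)
  centerO <- which(sys$structure$nodes$section == 2 &
                     sys$structure$nodes$role == "O")
  expect_equal(res[(centerO - 1) * 3 + 1:3], rep(0, 3), tolerance = 1e-12)
  # Newton's third law: the resultants sum to zero for random forces
  set.seed(3)
  res2 <- nodal_active_resultants(sys, rnorm(nrods, sd = 10))
  sums <- colSums(matrix(res2, ncol = 3, byrow = TRUE))
  expect_lt(max(abs(sums)), 1e-9)
})

test_that("equations of motion reduce to per-rod force balance", {
  sys <- trunk_system(toy_structure())
  rest <- system_state(numeric(sys$ndof))
  nrods <- nrow(sys$structure$rods)
  expect_equal(equations_of_motion(rest, numeric(nrods), sys,
                                   gravity_on = FALSE),
               numeric(sys$ndof))
  # Hooke: single grounded rod displaced along its axis
  ms <- mass_spring(k = 50, m = 2)
  q <- numeric(6); q[4] <- 0.01
  a <- equations_of_motion(system_state(q), 0, ms, gravity_on = FALSE)
  expect_equal(a[4], -50 / 2 * 0.01, tolerance = 1e-12)

  # random state vs an independent rod-by-rod oracle
  set.seed(14)
  q <- rnorm(sys$ndof, sd = 0.005); q[sys$fixed_dofs] <- 0
  v <- rnorm(sys$ndof, sd = 0.01); v[sys$fixed_dofs] <- 0
  f <- rnorm(nrods, sd = 5)
  a <- equations_of_motion(system_state(q, v), f, sys, gravity_on = TRUE)
  st <- sys$structure
  pos <- as.matrix(st$nodes[, c("x", "y", "z")]) +
    matrix(q, ncol = 3, byrow = TRUE)
  vel <- matrix(v, ncol = 3, byrow = TRUE)
  oracle <- matrix(0, nrow(st$nodes), 3)
  for (r in seq_len(nrow(st$rods))) {
    i1 <- match(st$rods$node1[r], st$nodes$node_id)
    i2 <- match(st$rods$node2[r], st$nodes$node_id)
    d <- pos[i2, ] - pos[i1, ]
    len <- sqrt(sum(d^2)); u <- d / len
    ldot <- sum(u * (vel[i2, ] - vel[i1, ]))
    tau <- st$rods$k[r] * (len - st$rods$L0[r]) + f[r] +
      st$config$damping_beta * st$rods$k[r] * ldot
    oracle[i1, ] <- oracle[i1, ] + tau * u
    oracle[i2, ] <- oracle[i2, ] - tau * u
  }
  for (n in seq_len(nrow(st$nodes))) {
    oracle[n, 3] <- oracle[n, 3] - st$nodes$mass[n] * 9.81
    oracle[n, ] <- (oracle[n, ] - st$config$damping * st$nodes$mass[n] *
                      vel[n, ]) / st$nodes$mass[n]
  }
  want <- as.vector(t(oracle))
  want[sys$fixed_dofs] <- 0
  expect_equal(a, want, tolerance = 1e-9)
})

test_that("mass-spring integration matches the closed-form period", {
  ms <- mass_spring(k = 4 * pi^2, m = 1)
  q0 <- numeric(6); q0[4] <- 0.01
  tr <- integrate_dynamics(ms, system_state(q0), NULL,
                           times = seq(0, 10, by = 0.01),
                           gravity_on = FALSE, rtol = 1e-9, atol = 1e-12)
  x <- tr$q[, 4]
  ups <- which(diff(sign(x)) > 0)
  period <- mean(diff(tr$times[ups]))
  expect_equal(period, 1.0, tolerance = 1e-4)
  # energy audit over 10 periods, undamped
  en <- trajectory_energy(tr, ms)
  expect_lt((max(en) - min(en)) / en[1], 0.001)
})

test_that("zero-force rest trajectories stay at rest", {
  cfg <- toy_config(gravity = 9.81)
  sys <- trunk_system(build_structure(cfg))
  tr <- integrate_dynamics(sys, NULL, NULL, times = seq(0, 0.5, by = 0.1),
                           gravity_on = FALSE)
  expect_lt(max(abs(tr$q)), 1e-12)
})

test_that("momentum is conserved without gravity or fixed nodes", {
  cfg <- default_config()
  cfg$damping <- 0
  cfg$damping_beta <- 0
  nodes <- data.frame(node_id = 0:2, mass = c(1, 2, 3),
                      x = c(0, 1, 2), y = c(0, 0.5, 0), z = 0)
  rods <- data.frame(node1 = c(0, 1, 0), node2 = c(1, 2, 2),
                     k = c(30, 20, 10))
  st <- trunk_structure(nodes, rods, fixed_nodes = integer(), config = cfg)
  q0 <- c(0.02, 0, 0, 0, -0.03, 0, 0, 0, 0.01)
  force_fn <- function(t) c(2 * sin(t), -1, 0.5)
  tr <- integrate_dynamics(st, system_state(q0), force_fn,
                           times = seq(0, 1, by = 0.05),
                           gravity_on = FALSE, rtol = 1e-10, atol = 1e-13)
  mom <- t(apply(tr$qdot, 1, function(v) {
    colSums(matrix(v, ncol = 3, byrow = TRUE) * nodes$mass)
  }))
  expect_lt(max(abs(mom)), 1e-8)
})

test_that("damped systems settle to a static equilibrium", {
  ms <- mass_spring(k = 100, m = 1, damping = 8)
  q0 <- numeric(6); q0[4] <- 0.05
  tr <- integrate_dynamics(ms, system_state(q0), c(2),
                           times = seq(0, 8, by = 0.5),
                           gravity_on = FALSE)
  final <- tr$final_state
  a <- equations_of_motion(final, c(2), ms, gravity_on = FALSE)
  expect_lt(max(abs(a)), 1e-4)
  expect_lt(max(abs(final$qdot)), 1e-4)
})

test_that("integration output converges as tolerances tighten", {
  ms <- mass_spring(k = 40, m = 1.5)
  q0 <- numeric(6); q0[4] <- 0.02
  t_out <- seq(0, 2, by = 0.1)
  a <- integrate_dynamics(ms, system_state(q0), NULL, times = t_out,
                          gravity_on = FALSE, rtol = 1e-6, atol = 1e-9)
  b <- integrate_dynamics(ms, system_state(q0), NULL, times = t_out,
                          gravity_on = FALSE, rtol = 1e-12, atol = 1e-14)
  expect_equal(a$q[, 4], b$q[, 4], tolerance = 1e-4)
})
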
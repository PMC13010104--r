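# Toy scale: 3-section trunk (0.4 m, 10 kg); all oracles generated in code.

test_that("estimation setup maps unknowns to rods consistently", {
  sys <- trunk_system(toy_structure())
  setup <- estimation_setup(sys)
  expect_equal(setup$n_segments, 2)
  expect_equal(ncol(setup$U), 6)
  rods <- sys$structure$rods
  f <- as.vector(setup$U %*% c(10, 4, 8, 0, 0, 0))
  # dorsal rod of segment 1 carries FL_dorsal, ventral FL_ventral
  expect_equal(f[rods$type == "longitudinal" & rods$segment == 1 &
                   rods$role == "P"], 10)
  expect_equal(f[rods$type == "longitudinal" & rods$segment == 1 &
                   rods$role == "Q"], 4)
  # lateral and center chains carry the mirrored mean force
  expect_equal(unique(f[rods$type == "longitudinal" & rods$segment == 1 &
                          rods$role %in% c("O", "B", "A")]), 7)
  # FR split over the four radial rods of the distal section
  expect_equal(f[rods$type == "radial" & rods$section == 2], rep(2, 4))
  expect_equal(sum(f[rods$type == "radial" & rods$section == 2]), 8)
  expect_true(all(f[rods$type == "connective"] == 0))
})

test_that("tracking objective is self-consistent and non-negative", {
  sys <- trunk_system(toy_structure())
  setup <- estimation_setup(sys)
  state <- system_state(numeric(sys$ndof))
  # target = the model's own passive step at zero active force
  passive <- integrate_dynamics(sys, state, NULL, times = c(0, 0.02),
                                gravity_on = FALSE,
                                rtol = 1e-10, atol = 1e-13)
  target <- passive$q[2, ]
  obj0 <- tracking_objective(numeric(6), sys, state, target, 0.02,
                             setup = setup, gravity_on = FALSE)
  expect_lt(obj0, 1e-12)
  set.seed(71)
  for (i in 1:5) {
    obj <- tracking_objective(rnorm(6, sd = 5), sys, state,
                              rnorm(sys$ndof, sd = 1e-3), 0.02,
                              setup = setup, gravity_on = FALSE)
    expect_gte(obj, 0)
  }
})

test_that("objective vanishes at the generating forces", {
  sys <- trunk_system(toy_structure())
  setup <- estimation_setup(sys)
  set.seed(72)
  f_star <- rnorm(6, sd = 10)
  state <- system_state(numeric(sys$ndof))
  fwd <- integrate_dynamics(sys, state, as.vector(setup$U %*% f_star),
                            times = c(0, 0.02), gravity_on = FALSE,
                            rtol = 1e-11, atol = 1e-14)
  obj <- tracking_objective(f_star, sys, state, fwd$q[2, ], 0.02,
                            setup = setup, gravity_on = FALSE)
  expect_lt(obj, 1e-10)
})

test_that("single-step estimation recovers known forces", {
  sys <- trunk_system(toy_structure())
  setup <- estimation_setup(sys)
  set.seed(73)
  f_star <- rnorm(6, sd = 15)
  state <- system_state(numeric(sys$ndof))
  fwd <- integrate_dynamics(sys, state, as.vector(setup$U %*% f_star),
                            times = c(0, 0.02), gravity_on = FALSE,
                            rtol = 1e-11, atol = 1e-14)
  est <- estimate_step_forces(sys, state, fwd$q[2, ], 0.02,
                              target_vel = fwd$qdot[2, ],
                              control = list(gravity_on = FALSE,
                                             force_penalty = 0))
  expect_lt(max(abs(est$forces - f_star)) / max(abs(f_star)), 0.02)
  # zero target displacement from equilibrium: forces stay ~0
  est0 <- estimate_step_forces(sys, state, numeric(sys$ndof), 0.02,
                               target_vel = numeric(sys$ndof),
                               control = list(gravity_on = FALSE))
  expect_lt(max(abs(est0$forces)), 1e-6 * max(abs(f_star)))
  # optimizer contract: solution no worse than the zero vector
  obj_zero <- tracking_objective(numeric(6), sys, state, fwd$q[2, ], 0.02,
                                 setup = setup, gravity_on = FALSE)
  obj_sol <- tracking_objective(est$forces, sys, state, fwd$q[2, ], 0.02,
                                setup = setup, gravity_on = FALSE)
  expect_lte(obj_sol, obj_zero + 1e-12)
})

test_that("warm starting never worsens the per-step objective", {
  sys <- trunk_system(toy_structure())
  setup <- estimation_setup(sys)
  gt <- generate_ground_truth_forces(sys, seed = 9, duration = 0.2,
                                     sample_rate = 25, amplitude = 15,
                                     gravity_on = FALSE)
  state <- system_state(gt$trajectory$q[3, ], gt$trajectory$qdot[3, ],
                        gt$trajectory$times[3])
  target <- gt$trajectory$q[4, ] - gt$trajectory$q[3, ]
  tvel <- gt$trajectory$qdot[4, ]
  ctl <- list(gravity_on = FALSE)
  warm <- estimate_step_forces(sys, state, target, 0.04,
                               warm_start = gt$unknowns[3, ] * 0.9,
                               target_vel = tvel, control = ctl)
  cold <- estimate_step_forces(sys, state, target, 0.04,
                               warm_start = numeric(6),
                               target_vel = tvel, control = ctl)
  expect_lte(warm$objective, cold$objective + 1e-12)
})

test_that("whole-trial inverse dynamics recovers a known force history", {
  sys <- trunk_system(toy_structure())
  gt <- generate_ground_truth_forces(sys, seed = 42, duration = 0.6,
                                     sample_rate = 50, amplitude = 20,
                                     gravity_on = FALSE)
  inv <- run_inverse(gt$trajectory, sys, control = list(gravity_on = FALSE))
  expect_equal(nrow(inv$history), nrow(gt$history))
  err <- rms(unlist(inv$history[, 3:5]) - unlist(gt$history[, 3:5]))
  scale <- rms(unlist(gt$history[, 3:5]))
  expect_lt(err / scale, 0.05)
  # identifiability: per-segment radial force correlation with the truth
  for (i in 1:2) {
    expect_gt(cor(inv$history$FR[inv$history$segment == i],
                  gt$history$FR[gt$history$segment == i]), 0.95)
  }
  # the replayed trajectory reproduces the observed one
  expect_lt(max(abs(inv$trajectory$positions - gt$trajectory$positions)),
            1e-3)
})

test_that("static gravity-loaded trunk is held nearly still", {
  sys <- trunk_system(toy_structure())
  nt <- 16
  times <- (0:(nt - 1)) / 50
  targets <- array(rep(sys$rest, each = nt),
                   dim = c(nt, sys$n_nodes, 3))
  attr(targets, "times") <- times
  inv <- run_inverse(targets, sys)
  tipO <- sys$n_nodes - 4L
  sag <- max(abs(inv$trajectory$positions[, tipO, ] -
                   matrix(sys$rest[tipO, ], nt, 3, byrow = TRUE)))
  expect_lt(sag, 1e-3)
})

test_that("segment force summaries follow the defining algebra", {
  h <- data.frame(time = 0, segment = 1:2, FL_dorsal = c(10, 3),
                  FL_ventral = c(4, 3), FR = c(2, 5))
  s <- segment_force_summary(h)
  expect_equal(s$dFL, c(6, 0))
  expect_equal(s$FmL, c(7, 3))
  expect_equal(s$FR, c(2, 5))
  # round trip FL_d = FmL + dFL/2
  expect_equal(s$FmL + s$dFL / 2, h$FL_dorsal)
  expect_equal(s$FmL - s$dFL / 2, h$FL_ventral)
})

test_that("mismatched trials are rejected", {
  sys <- trunk_system(toy_structure())
  sp <- generator_spec("B", peak_K = 10, duration = 0.1, sample_rate = 20,
                       seed = 1, n_sections = 4)
  trl <- generate_reaching_trial(sp)
  expect_error(run_inverse(trl, sys), "section rows")
})
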
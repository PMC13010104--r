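test_that("segment length is the Euclidean center distance", {
  expect_equal(segment_length(c(0, 0, 0), c(0.2, 0, 0)), 0.2)
  expect_equal(segment_length(c(1, 2, 2), c(2, 4, 4)), 3.0)
  expect_equal(segment_length(c(0.3, -1, 2), c(0.3, -1, 2)), 0)
  # symmetry and triangle inequality over random center triples
  set.seed(11)
  for (i in 1:20) {
    p <- matrix(rnorm(9), 3)
    expect_equal(segment_length(p[1, ], p[2, ]),
                 segment_length(p[2, ], p[1, ]))
    expect_lte(segment_length(p[1, ], p[3, ]),
               segment_length(p[1, ], p[2, ]) +
                 segment_length(p[2, ], p[3, ]) + 1e-12)
  }
})

test_that("segment curvature follows the angle/length ratios", {
  sc <- segment_curvature(4, 3, 0.2)
  expect_equal(sc$K_alpha, 20)
  expect_equal(sc$K_beta, 15)
  expect_equal(sc$K, 25)
  expect_equal(segment_curvature(0, 0, 0.5)$K, 0)
  expect_error(segment_curvature(1, 1, 0), "length")
})

test_that("relative bend angles recover constructed rotations", {
  base <- ellipse_section(c(0, 0, 0), c(0.2, -0.4, 0.1), c(0.1, 0.08))
  same <- ellipse_section(c(0, 0, 0.2), c(0.2, -0.4, 0.1), c(0.1, 0.07))
  expect_equal(unname(relative_bend_angles(base, same)), c(0, 0))

  # rotate about section 1's dorsal ("normal") axis by 4 degrees
  R1 <- base$rotation
  R2 <- R1 %*% rotation_about_axis(c(0, 0, 1), 4 * pi / 180)
  sec2 <- ellipse_section(c(0, 0, 0.2), matrix_to_euler_zyx(R2),
                          c(0.1, 0.08))
  ab <- relative_bend_angles(base, sec2)
  expect_equal(unname(ab["alpha"]), 4, tolerance = 1e-9)
  expect_equal(unname(ab["beta"]), 0, tolerance = 1e-9)

  # random small rotations: quaternion log-map oracle
  quat_log_angles <- function(R_rel) {
    tr <- sum(diag(R_rel))
    qw <- sqrt(max(0, 1 + tr)) / 2
    qv <- c(R_rel[3, 2] - R_rel[2, 3], R_rel[1, 3] - R_rel[3, 1],
            R_rel[2, 1] - R_rel[1, 2]) / 4 / qw
    ang <- 2 * atan2(sqrt(sum(qv^2)), qw)
    if (ang < 1e-15) return(c(0, 0, 0))
    axis <- qv / sqrt(sum(qv^2))
    axis * ang * 180 / pi
  }
  set.seed(21)
  for (i in 1:25) {
    e1 <- runif(3, -0.5, 0.5)
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ang <- runif(1, -0.2, 0.2)
    Ra <- euler_zyx_to_matrix(e1)
    Rb <- Ra %*% rotation_about_axis(axis, ang)
    s1 <- ellipse_section(c(0, 0, 0), e1, c(0.1, 0.08))
    s2 <- ellipse_section(c(0, 0, 0.2), matrix_to_euler_zyx(Rb),
                          c(0.1, 0.08))
    got <- relative_bend_angles(s1, s2)
    want <- quat_log_angles(crossprod(Ra, Rb))
    expect_equal(unname(got["alpha"]), want[3], tolerance = 1e-8)
    expect_equal(unname(got["beta"]), want[2], tolerance = 1e-8)
  }
})

test_that("shape time series recovers the generator's commands", {
  sp <- generator_spec("B", peak_K = 25, duration = 1, sample_rate = 20,
                       seed = 3)
  trial <- generate_reaching_trial(sp)
  shapes <- shape_timeseries(trial)
  gt <- attr(trial, "ground_truth")
  expect_equal(shapes$K, gt$K, tolerance = 1e-8)
  expect_equal(shapes$L, gt$L, tolerance = 1e-10)
  # straight rest trial: all K = 0, L = rest length
  sp0 <- generator_spec("B", peak_K = 0, duration = 0.2, sample_rate = 10,
                        seed = 3)
  sh0 <- shape_timeseries(generate_reaching_trial(sp0))
  expect_true(all(sh0$K < 1e-9))
  expect_equal(unique(round(sh0$L, 12)), 1.85 / 9)
})

test_that("curvature is invariant under a global rigid transform", {
  sp <- generator_spec("BE", peak_K = 30, elongation_fraction = 0.15,
                       duration = 0.5, sample_rate = 10, seed = 5)
  trial <- generate_reaching_trial(sp)
  ref <- shape_timeseries(trial)
  Rg <- euler_zyx_to_matrix(c(0.7, -0.3, 1.1))
  shift <- c(0.5, -1, 2)
  moved <- trial$sections
  for (i in seq_len(nrow(moved))) {
    ctr <- Rg %*% c(moved$cx[i], moved$cy[i], moved$cz[i]) + shift
    Rn <- Rg %*% euler_zyx_to_matrix(c(moved$ez[i], moved$ey[i],
                                       moved$ex[i]))
    eu <- matrix_to_euler_zyx(Rn)
    moved$cx[i] <- ctr[1]; moved$cy[i] <- ctr[2]; moved$cz[i] <- ctr[3]
    moved$ez[i] <- eu[1]; moved$ey[i] <- eu[2]; moved$ex[i] <- eu[3]
  }
  got <- shape_timeseries(movement_trial(moved))
  expect_equal(got$K, ref$K, tolerance = 1e-9)
  expect_equal(got$L, ref$L, tolerance = 1e-9)
})

test_that("movement classification applies both thresholds", {
  mk <- function(K, dL) {
    data.frame(time = rep(c(0, 1), each = 2), segment = rep(1:2, 2),
               K = c(0, 0, K, 0), K_alpha = 0, K_beta = 0, alpha = 0,
               beta = 0, L = c(0.2, 0.2, 0.2 + dL, 0.2))
  }
  expect_equal(classify_movement(mk(25, 0.005)), "B")
  expect_equal(classify_movement(mk(25, 0.03)), "BE")
  expect_equal(classify_movement(mk(10, 0.03)), "OTHER")
  expect_error(classify_movement(mk(10, 0)[0, ]), "empty")
  # monotone in the curvature threshold: raising it never promotes OTHER
  sh <- mk(25, 0.005)
  expect_equal(classify_movement(sh, k_thresh_bend = 30), "OTHER")
})

test_that("classification boundaries sit at the configured thresholds", {
  classify_peak <- function(peak_K, elong) {
    sp <- generator_spec(if (elong > 0.05) "BE" else "B", peak_K = peak_K,
                         elongation_fraction = elong, duration = 0.4,
                         sample_rate = 10, seed = 2)
    classify_movement(shape_timeseries(generate_reaching_trial(sp)))
  }
  # bisection over peak curvature at zero elongation: B <-> OTHER
  lo <- 5; hi <- 40
  for (i in 1:18) {
    mid <- (lo + hi) / 2
    if (classify_peak(mid, 0) == "B") hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, 20, tolerance = 0.01)
  # bisection over elongation at fixed bending: B <-> BE; the boundary in
  # max segment-length change is l_thresh_elong = 0.02 m
  seg_rest <- 1.85 / 9
  lo <- 0.01; hi <- 0.25
  for (i in 1:18) {
    mid <- (lo + hi) / 2
    if (classify_peak(30, mid) == "BE") hi <- mid else lo <- mid
  }
  expect_equal(((lo + hi) / 2) * seg_rest, 0.02, tolerance = 0.001)
})
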
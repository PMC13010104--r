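#' Specification for a synthetic reaching trial
#'
#' The generator emulates the structure of a mocap-derived dataset: 10
#' cross-section rows sampled at ~100 Hz, resting segment length ~0.2 m,
#' planar bending up to tens of deg/m, elongations up to 20-30% of segment
#' length, optional Gaussian noise on the section centers.
#'
#' @param movement_class `"B"` (pure bending) or `"BE"` (bending +
#'   elongation).
#' @param peak_K peak commanded curvature, deg/m, `>= 0`.
#' @param elongation_fraction peak segment elongation as a fraction of rest
#'   length, in `[0, 0.3]` (must exceed ~0.1 to cross the 0.02 m class
#'   threshold at 0.2 m segments).
#' @param duration trial duration, s.
#' @param sample_rate Hz.
#' @param noise_sd Gaussian center noise, m (default 0).
#' @param seed integer; mandatory, all generator randomness flows through
#'   it.
#' @param n_sections number of section rows (default 10).
#' @param curvature_profile `"front"` (default): per-segment curvature
#'   weights rise from near zero proximally to 1 at the tip segment,
#'   mimicking the distally concentrated curvature front of real reaching
#'   movements (holding a large uniform bend would put the whole ventral
#'   rod chain into deep compression, a configuration real trunks avoid);
#'   `"uniform"`: all segments commanded equally.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(movement_class = c("B", "BE"), peak_K = 25,
                           elongation_fraction = 0, duration = 2,
                           sample_rate = 100, noise_sd = 0, seed = 1L,
                           n_sections = 10L,
                           curvature_profile = c("front", "uniform")) {
  movement_class <- match.arg(movement_class)
  curvature_profile <- match.arg(curvature_profile)
  if (elongation_fraction < 0 || elongation_fraction > 0.3) {
    stop("elongation_fraction must be in [0, 0.3]")
  }
  stopifnot(peak_K >= 0, noise_sd >= 0, duration > 0, sample_rate > 0)
  structure(list(movement_class = movement_class, peak_K = peak_K,
                 elongation_fraction = elongation_fraction,
                 duration = duration, sample_rate = sample_rate,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 n_sections = as.integer(n_sections),
                 curvature_profile = curvature_profile),
            class = "generator_spec")
}

# minimum-jerk time profile on [0, 1]: smooth start and stop
minimum_jerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# per-segment curvature weights; the tip segment always carries weight 1
# so that max-over-segments curvature equals the commanded peak
curvature_weights <- function(profile, n_seg) {
  if (profile == "uniform" || n_seg == 1) return(rep(1, n_seg))
  tau <- seq_len(n_seg) / n_seg
  w <- 0.05 + 0.95 * tau^2.5
  w / max(w)
}

#' Generate a synthetic planar reaching trial
#'
#' Commands per-segment curvature and length trajectories that ramp from
#' rest to the spec's peak values with a minimum-jerk profile (smooth
#' start/stop, matching reaching phenomenology), reconstructs the section
#' frames by composing per-segment planar rotations along the backbone, and
#' returns ellipse sections at the sample rate. For BE movements every
#' section's radius scales as `sqrt(L_rest / L(t))` so that the
#' elliptic-frustum volume is preserved analytically. Deterministic given
#' the seed.
#'
#' @param spec a `generator_spec`.
#' @param config a `trunk_config` providing the rest geometry (segment
#'   length and radius taper).
#' @return A `movement_trial` with attribute `ground_truth`: the commanded
#'   data.frame `time, segment, K, L`.
#' @export
generate_reaching_trial <- function(spec, config = default_config()) {
  stopifnot(inherits(spec, "generator_spec"))
  cfg <- validate_config(unclass(config))
  m <- spec$n_sections
  n_seg <- m - 1L
  seg_len <- cfg$total_length / n_seg
  radii <- seq(cfg$base_radius, cfg$tip_radius, length.out = m)
  nt <- floor(spec$duration * spec$sample_rate + 1e-9) + 1L
  times <- (seq_len(nt) - 1) / spec$sample_rate
  s <- minimum_jerk(times / spec$duration)
  elong <- spec$elongation_fraction
  set.seed(spec$seed)
  noise <- if (spec$noise_sd > 0) {
    array(rnorm(nt * m * 3, sd = spec$noise_sd), dim = c(nt, m, 3))
  } else NULL

  rows <- vector("list", nt)
  gt <- vector("list", nt)
  wK <- curvature_weights(spec$curvature_profile, n_seg)
  for (ti in seq_len(nt)) {
    K <- spec$peak_K * wK * s[ti]
    L <- rep(seg_len * (1 + elong * s[ti]), n_seg)
    centers <- backbone_from_shape(K, L,
                                   base_rotation = trunk_rest_rotation())
    Rs <- attr(centers, "rotations")
    scale <- sqrt(seg_len / L[1])  # uniform elongation: common scale
    sec_rows <- lapply(seq_len(m), function(i) {
      ctr <- centers[i, ]
      if (!is.null(noise)) ctr <- ctr + noise[ti, i, ]
      eul <- matrix_to_euler_zyx(Rs[[i]])
      r <- radii[i] * scale
      data.frame(time = times[ti], row_index = i,
                 cx = ctr[1], cy = ctr[2], cz = ctr[3],
                 ez = eul[1], ey = eul[2], ex = eul[3],
                 semi_a = r, semi_b = r)
    })
    rows[[ti]] <- do.call(rbind, sec_rows)
    gt[[ti]] <- data.frame(time = times[ti], segment = seq_len(n_seg),
                           K = K, L = L)
  }
  trial <- movement_trial(do.call(rbind, rows),
                          sample_rate = spec$sample_rate,
                          label = spec$movement_class)
  attr(trial, "ground_truth") <- do.call(rbind, gt)
  trial
}

#' Forward-simulate a smooth random force history (ground-truth oracle)
#'
#' Draws a seeded, smooth (low-frequency Fourier series under a
#' minimum-jerk envelope, so forces start at zero) random history for every
#' estimation unknown, holds it piecewise constant over each sampling
#' interval, and integrates the forward model. The output pair is the
#' parameter-recovery oracle for [run_inverse()]. A draw whose trajectory
#' blows up is redrawn (up to 5 times).
#'
#' @param structure a `trunk_structure` or `trunk_system`.
#' @param seed integer seed.
#' @param duration s.
#' @param sample_rate Hz.
#' @param amplitude typical peak force per unknown, N.
#' @param gravity_on logical.
#' @return List with `trajectory` (`node_trajectory` at the sample times),
#'   `history` (data.frame `time, segment, FL_dorsal, FL_ventral, FR` over
#'   the `n_times - 1` steps) and `unknowns` (steps x unknowns matrix).
#' @export
generate_ground_truth_forces <- function(structure, seed = 1L,
                                         duration = 1, sample_rate = 50,
                                         amplitude = 20,
                                         gravity_on = FALSE) {
  sys <- as_trunk_system(structure)
  setup <- estimation_setup(sys)
  n_unknown <- ncol(setup$U)
  nt <- floor(duration * sample_rate + 1e-9) + 1L
  times <- (seq_len(nt) - 1) / sample_rate
  n_seg <- setup$n_segments
  set.seed(seed)
  for (attempt in 1:5) {
    env <- minimum_jerk(times / duration)
    F <- vapply(seq_len(n_unknown), function(j) {
      a <- rnorm(3, sd = amplitude / 2)
      ph <- runif(3, 0, 2 * pi)
      f <- a[1] * sin(2 * pi * times / duration + ph[1]) +
        a[2] * sin(4 * pi * times / duration + ph[2]) +
        a[3] * sin(pi * times / duration + ph[3])
      env * f
    }, numeric(nt))
    traj <- tryCatch({
      state <- system_state(numeric(sys$ndof))
      qs <- matrix(0, nt, sys$ndof)
      vs <- matrix(0, nt, sys$ndof)
      for (j in seq_len(nt - 1L)) {
        f_rod <- as.vector(setup$U %*% F[j, ])
        tr <- integrate_dynamics(sys, state, f_rod,
                                 times = c(times[j], times[j + 1L]),
                                 gravity_on = gravity_on,
                                 rtol = 1e-9, atol = 1e-12)
        state <- tr$final_state
        qs[j + 1L, ] <- state$q
        vs[j + 1L, ] <- state$qdot
      }
      if (max(abs(qs)) > 10) stop("unstable draw")
      positions <- array(0, dim = c(nt, sys$n_nodes, 3))
      for (s in seq_len(nt)) {
        positions[s, , ] <- sys$rest + matrix(qs[s, ], ncol = 3,
                                              byrow = TRUE)
      }
      structure(list(times = times, positions = positions, q = qs,
                     qdot = vs, final_state = state),
                class = "node_trajectory")
    }, error = function(e) NULL)
    if (!is.null(traj)) {
      hist <- do.call(rbind, lapply(seq_len(nt - 1L), function(j) {
        data.frame(time = times[j], segment = seq_len(n_seg),
                   FL_dorsal = F[j, 3 * (seq_len(n_seg) - 1L) + 1L],
                   FL_ventral = F[j, 3 * (seq_len(n_seg) - 1L) + 2L],
                   FR = F[j, 3 * (seq_len(n_seg) - 1L) + 3L])
      }))
      return(list(trajectory = traj, history = hist,
                  unknowns = F[seq_len(nt - 1L), , drop = FALSE]))
    }
  }
  stop("could not draw a stable force history after 5 attempts")
}

#' Sample dorsal marker rows from a trial
#'
#' Places `markers_per_row` markers on an arc of each section's ellipse,
#' centered on the dorsal side, and adds Gaussian position noise. Emulates
#' dorsal-only marker placement for testing [fit_section_ellipse()] under
#' partial-arc conditions.
#'
#' @param trial a `movement_trial`.
#' @param markers_per_row markers per section (>= 5 if a refit is
#'   intended).
#' @param arc_deg angular width of the marker arc (360 = full ellipse).
#' @param noise_sd m.
#' @param seed integer.
#' @return data.frame `time, row_index, marker_id, x, y, z`.
#' @export
generate_marker_rows <- function(trial, markers_per_row = 8, arc_deg = 360,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(inherits(trial, "movement_trial"))
  set.seed(seed)
  # dorsal direction is local +z, i.e. in-plane angle 90 deg
  phi <- if (arc_deg >= 360) {
    seq(0, 2 * pi, length.out = markers_per_row + 1L)[1:markers_per_row]
  } else {
    seq(pi / 2 - arc_deg * pi / 360, pi / 2 + arc_deg * pi / 360,
        length.out = markers_per_row)
  }
  out <- vector("list", length(trial$times))
  for (s in seq_along(trial$times)) {
    secs <- trial_sample_sections(trial, s)
    out[[s]] <- do.call(rbind, lapply(secs, function(sec) {
      R <- sec$rotation
      pts <- t(vapply(phi, function(p) {
        sec$center + sec$semi_axes[1] * cos(p) * R[, 2] +
          sec$semi_axes[2] * sin(p) * R[, 3]
      }, numeric(3)))
      if (noise_sd > 0) {
        pts <- pts + matrix(rnorm(length(pts), sd = noise_sd),
                            nrow = nrow(pts))
      }
      data.frame(time = sec$timestamp, row_index = sec$row_index,
                 marker_id = seq_len(markers_per_row),
                 x = pts[, 1], y = pts[, 2], z = pts[, 3])
    }))
  }
  do.call(rbind, out)
}
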
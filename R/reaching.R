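#' Define a reaching shape target
#'
#' Initial and final configuration of every segment, given by curvature and
#' length, plus the trial duration and the controller sampling frequency.
#'
#' @param K_ini,K_fin per-segment curvature, deg/m (scalars are recycled).
#' @param L_ini,L_fin per-segment length, m, positive.
#' @param duration trial duration T, s, positive.
#' @param sample_rate controller frequency fs, Hz (default 100).
#' @param n_segments number of segments (inferred from the longest vector).
#' @return Object of class `shape_target`.
#' @export
shape_target <- function(K_ini, K_fin, L_ini, L_fin, duration,
                         sample_rate = 100, n_segments = NULL) {
  if (is.null(n_segments)) {
    n_segments <- max(length(K_ini), length(K_fin), length(L_ini),
                      length(L_fin))
  }
  stopifnot(duration > 0, sample_rate > 0)
  out <- list(K_ini = rep_len(K_ini, n_segments),
              K_fin = rep_len(K_fin, n_segments),
              L_ini = rep_len(L_ini, n_segments),
              L_fin = rep_len(L_fin, n_segments),
              duration = duration, sample_rate = sample_rate,
              n_segments = n_segments)
  if (any(out$L_ini <= 0) || any(out$L_fin <= 0)) {
    stop("segment lengths must be positive")
  }
  structure(out, class = "shape_target")
}

#' Convex-combination shape interpolation
#'
#' `K(tj) = K_ini * (T - tj)/T + K_fin * tj/T` and likewise for `L`, with
#' `tj = j / fs` for `0 <= j < T*fs`; a 1 s trial at 100 Hz yields exactly
#' 100 samples, starting at the initial configuration and stopping one
#' sample short of the final one (the forward integration still runs to
#' `t = T` holding the last force value).
#'
#' @param target a `shape_target`.
#' @return data.frame `time, segment, K, L` with `floor(T * fs)` samples
#'   per segment (a warning is issued when `T * fs` is not an integer).
#' @export
interpolate_shape <- function(target) {
  stopifnot(inherits(target, "shape_target"))
  Tf <- target$duration * target$sample_rate
  if (abs(Tf - round(Tf)) > 1e-9) {
    warning("duration * sample_rate is not an integer; flooring to ",
            floor(Tf), " samples")
  }
  n <- floor(Tf + 1e-9)
  tj <- (seq_len(n) - 1) / target$sample_rate
  Tt <- target$duration
  out <- do.call(rbind, lapply(seq_len(target$n_segments), function(i) {
    data.frame(time = tj, segment = i,
               K = target$K_ini[i] * (Tt - tj) / Tt +
                 target$K_fin[i] * tj / Tt,
               L = target$L_ini[i] * (Tt - tj) / Tt +
                 target$L_fin[i] * tj / Tt)
  }))
  out[order(out$time, out$segment), ]
}

#' Distribute per-segment forces to the rods
#'
#' `FL_dorsal = FmL + dFL/2` on the segment's dorsal longitudinal rod,
#' `FL_ventral = FmL - dFL/2` on the ventral one, the mirrored mean force
#' `FmL` on the lateral and center longitudinal rods (matching
#' [estimation_setup()]'s default actuation), and `FR` split equally over
#' the four radial rods of the segment's distal section (or over the
#' dorso-ventral pair only). Connective rods carry no active force.
#'
#' @param dFL,FR,FmL per-segment forces, N (vectors of length
#'   `n_sections - 1`).
#' @param structure a `trunk_structure` or `trunk_system`.
#' @param radial_split `"four"` (default) or `"dorsoventral"`.
#' @param lateral_longitudinal `"mirrored"` (default) or `"passive"`, as in
#'   [estimation_setup()].
#' @return Per-rod force vector (length `nrow(rods)`), N.
#' @export
segment_forces_to_rod_forces <- function(dFL, FR, FmL, structure,
                                         radial_split = c("four",
                                                          "dorsoventral"),
                                         lateral_longitudinal =
                                           c("mirrored", "passive")) {
  radial_split <- match.arg(radial_split)
  lateral_longitudinal <- match.arg(lateral_longitudinal)
  sys <- as_trunk_system(structure)
  rods <- sys$structure$rods
  n_seg <- sys$structure$n_sections - 1L
  stopifnot(length(dFL) == n_seg, length(FR) == n_seg,
            length(FmL) == n_seg)
  f <- numeric(nrow(rods))
  for (i in seq_len(n_seg)) {
    rd <- rods$type == "longitudinal" & rods$segment == i & rods$role == "P"
    rv <- rods$type == "longitudinal" & rods$segment == i & rods$role == "Q"
    f[rd] <- FmL[i] + dFL[i] / 2
    f[rv] <- FmL[i] - dFL[i] / 2
    if (lateral_longitudinal == "mirrored") {
      rl <- rods$type == "longitudinal" & rods$segment == i &
        rods$role %in% c("O", "B", "A")
      f[rl] <- FmL[i]
    }
    if (radial_split == "four") {
      rr <- rods$type == "radial" & rods$section == i + 1L
      f[rr] <- FR[i] / 4
    } else {
      rr <- rods$type == "radial" & rods$section == i + 1L &
        rods$role %in% c("P", "Q")
      f[rr] <- FR[i] / 2
    }
  }
  f
}

#' Open-loop reaching driven by the stereotypical laws
#'
#' For each controller sample `tj`, solves the per-segment force system at
#' the interpolated `(K, L)` via [solve_forces_from_shape()], converts the
#' result to rod forces, and integrates the forward model over
#' `[tj, tj+1)` with the forces held constant. Open loop: the simulated
#' shape is not fed back.
#'
#' @param target a `shape_target` (segments must match the structure).
#' @param laws a `law_set` covering every segment.
#' @param structure a `trunk_structure` or `trunk_system`.
#' @param state0 initial `system_state` (default rest).
#' @param gravity_on logical (default TRUE; fit the laws under the same
#'   condition).
#' @param include_endpoint append the exact final target as an extra
#'   controller sample at `t = T` (default FALSE, matching the strict
#'   `0 <= j < T*fs` schedule).
#' @return List of class `reaching_result`: `trajectory`
#'   (`node_trajectory` sampled at the controller times plus `T`),
#'   `commanded` (the interpolated shape series), `forces` (data.frame
#'   `time, segment, dFL, FR, FmL`), `achieved_shapes` (measured from the
#'   simulation via [shapes_from_trajectory()]).
#' @export
run_reaching <- function(target, laws, structure, state0 = NULL,
                         gravity_on = TRUE, include_endpoint = FALSE) {
  sys <- as_trunk_system(structure)
  n_seg <- sys$structure$n_sections - 1L
  if (target$n_segments != n_seg) {
    stop("target has ", target$n_segments, " segments but the structure ",
         "has ", n_seg)
  }
  cmd <- interpolate_shape(target)
  times <- sort(unique(cmd$time))
  if (include_endpoint) {
    extra <- do.call(rbind, lapply(seq_len(n_seg), function(i) {
      data.frame(time = target$duration, segment = i,
                 K = target$K_fin[i], L = target$L_fin[i])
    }))
    cmd <- rbind(cmd, extra)
    times <- c(times, target$duration)
  }
  dt <- 1 / target$sample_rate
  if (is.null(state0)) state0 <- system_state(numeric(sys$ndof))
  state <- state0

  nt <- length(times)
  qs <- matrix(0, nt + 1L, sys$ndof)
  vs <- matrix(0, nt + 1L, sys$ndof)
  qs[1, ] <- state$q
  vs[1, ] <- state$qdot
  force_rows <- vector("list", nt)
  for (j in seq_len(nt)) {
    cj <- cmd[cmd$time == times[j], ]
    cj <- cj[order(cj$segment), ]
    fs3 <- t(vapply(seq_len(n_seg), function(i) {
      solve_forces_from_shape(cj$K[i], cj$L[i], laws, i)
    }, numeric(3)))
    f_rod <- segment_forces_to_rod_forces(fs3[, "dFL"], fs3[, "FR"],
                                          fs3[, "FmL"], sys)
    traj <- tryCatch(
      integrate_dynamics(sys, state, f_rod,
                         times = c(times[j], times[j] + dt),
                         gravity_on = gravity_on),
      error = function(e) stop("reaching aborted at step ", j, ": ",
                               conditionMessage(e)))
    state <- traj$final_state
    qs[j + 1L, ] <- state$q
    vs[j + 1L, ] <- state$qdot
    force_rows[[j]] <- data.frame(time = times[j],
                                  segment = seq_len(n_seg),
                                  dFL = fs3[, "dFL"], FR = fs3[, "FR"],
                                  FmL = fs3[, "FmL"])
  }
  out_times <- c(times, times[nt] + dt)
  positions <- array(0, dim = c(nt + 1L, sys$n_nodes, 3))
  for (s in seq_len(nt + 1L)) {
    positions[s, , ] <- sys$rest + matrix(qs[s, ], ncol = 3, byrow = TRUE)
  }
  trajectory <- structure(list(times = out_times, positions = positions,
                               q = qs, qdot = vs, final_state = state),
                          class = "node_trajectory")
  structure(list(
    trajectory = trajectory,
    commanded = cmd,
    forces = do.call(rbind, force_rows),
    achieved_shapes = shapes_from_trajectory(trajectory, sys$structure)
  ), class = "reaching_result")
}

#' Forward-kinematic reconstruction of section poses from a shape series
#'
#' Composes per-segment planar rotations (`theta_i = K_i * L_i`, bending
#' about the lateral axis; positive curvature bends toward the dorsal
#' side, so that bending curls the trunk in the direction of stronger
#' dorsal longitudinal force) and chord translations along the rotated
#' backbone, starting from the base frame. Used to turn commanded `(K, L)`
#' into target node/tip positions.
#'
#' @param K,L per-segment curvature (deg/m) and length (m).
#' @param base_center,base_rotation pose of section 1.
#' @return Matrix of section centers (`n_segments + 1` rows) with the
#'   rotation matrices in the `rotations` attribute.
#' @export
backbone_from_shape <- function(K, L, base_center = c(0, 0, 0),
                                base_rotation = diag(3)) {
  n_seg <- length(K)
  centers <- matrix(0, n_seg + 1L, 3)
  centers[1, ] <- base_center
  Rs <- vector("list", n_seg + 1L)
  Rs[[1]] <- base_rotation
  for (i in seq_len(n_seg)) {
    theta <- -K[i] * L[i] * pi / 180  # negative: dorsal-ward bend
    chord_dir <- Rs[[i]] %*% rotation_about_axis(c(0, 1, 0), theta / 2) %*%
      c(1, 0, 0)
    centers[i + 1L, ] <- centers[i, ] + L[i] * as.vector(chord_dir)
    Rs[[i + 1L]] <- Rs[[i]] %*% rotation_about_axis(c(0, 1, 0), theta)
  }
  attr(centers, "rotations") <- Rs
  centers
}
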
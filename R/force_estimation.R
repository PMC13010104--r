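#' Set up the inverse-dynamics unknowns and tracked DoFs
#'
#' For planar trials the per-step unknowns are, for each segment `i`
#' (1..`n_sections - 1`): the dorsal longitudinal rod force `FL_dorsal_i`,
#' the ventral longitudinal rod force `FL_ventral_i`, and the radial force
#' `FR_i`, split equally over the four radial rods of the segment's distal
#' section. The lateral (B, A) and center (O) longitudinal rods carry the
#' mirrored mean longitudinal force `Fm_L = (FL_dorsal + FL_ventral)/2`
#' (the longitudinal musculature surrounds the whole cross-section, and
#' without this axial drive commanded elongations are unrealizable);
#' connective rods are always passive. For the full trunk this gives 27
#' unknowns per step.
#'
#' Tracked DoFs default to all three coordinates of every free node.
#' Tracking the outer ring is what makes `FR` identifiable (its symmetric
#' four-way split has no first-order effect on the center nodes); the
#' lateral nodes move in Y whenever the cross-section narrows, even for
#' planar backbone motion, so dropping Y lets the optimizer crush the ring
#' invisibly; and the actively driven center chain must be observed or it
#' can drift unchecked.
#'
#' @param structure a `trunk_structure` or `trunk_system`.
#' @param tracked_roles node roles to track (default all five).
#' @param axes coordinate axes to track, subset of `c("x", "y", "z")`.
#' @param lateral_longitudinal `"mirrored"` (lateral and center
#'   longitudinal rods carry `Fm_L`, the default) or `"passive"`.
#' @return An `estimation_setup`: unknown labels, the `n_rods x n_unknowns`
#'   map `U` from unknowns to per-rod forces, and tracked DoF indices.
#' @export
estimation_setup <- function(structure,
                             tracked_roles = c("O", "P", "B", "Q", "A"),
                             axes = c("x", "y", "z"),
                             lateral_longitudinal = c("mirrored",
                                                      "passive")) {
  lateral_longitudinal <- match.arg(lateral_longitudinal)
  sys <- as_trunk_system(structure)
  st <- sys$structure
  n_seg <- st$n_sections - 1L
  if (n_seg < 1) stop("structure has no segments")
  rods <- st$rods
  n_unknown <- 3L * n_seg
  U <- matrix(0, nrow(rods), n_unknown)
  labels <- character(n_unknown)
  for (i in seq_len(n_seg)) {
    base <- (i - 1L) * 3L
    rd <- which(rods$type == "longitudinal" & rods$segment == i &
                  rods$role == "P")
    rv <- which(rods$type == "longitudinal" & rods$segment == i &
                  rods$role == "Q")
    rr <- which(rods$type == "radial" & rods$section == i + 1L)
    if (length(rd) != 1 || length(rv) != 1 || length(rr) != 4) {
      stop("segment ", i, ": unexpected rod topology for estimation")
    }
    U[rd, base + 1L] <- 1
    U[rv, base + 2L] <- 1
    U[rr, base + 3L] <- 0.25
    if (lateral_longitudinal == "mirrored") {
      rl <- which(rods$type == "longitudinal" & rods$segment == i &
                    rods$role %in% c("O", "B", "A"))
      U[rl, base + 1L] <- 0.5  # each carries Fm_L = (FL_d + FL_v) / 2
      U[rl, base + 2L] <- 0.5
    }
    labels[base + 1:3] <- paste0(c("FL_dorsal_", "FL_ventral_", "FR_"), i)
  }
  axmap <- c(x = 1L, y = 2L, z = 3L)
  ax <- axmap[match(axes, names(axmap))]
  if (anyNA(ax)) stop("axes must be a subset of c('x','y','z')")
  keep <- which(st$nodes$role %in% tracked_roles &
                  !(st$nodes$node_id %in% st$fixed_nodes))
  tracked <- sort(as.vector(outer(ax, (keep - 1L) * 3L, `+`)))
  structure(list(U = U, labels = labels, n_segments = n_seg,
                 tracked_dofs = tracked, axes = axes),
            class = "estimation_setup")
}

# Exact step response of the linearized (frozen-geometry) free-DoF system
# zdot = A z + E F, A = [[0, I], [-Minv K, -c I]], via one matrix
# exponential of the augmented block matrix at dt/2; the full-step response
# follows from Phi(dt) = Phi(dt/2)^2, Gam(dt) = (Phi(dt/2) + I) Gam(dt/2).
# Reused for every step.
step_propagator <- function(sys, dt) {
  f <- sys$free_dofs
  n <- length(f)
  Kff <- sys$K[f, f, drop = FALSE]
  minv <- sys$minv[f]
  A <- rbind(cbind(matrix(0, n, n), diag(n)),
             cbind(-minv * Kff,
                   diag(-sys$damping, n) - sys$damping_beta * minv * Kff))
  E <- rbind(matrix(0, n, n), diag(minv, n))
  blk <- rbind(cbind(A, E), matrix(0, n, 3 * n))
  P <- as.matrix(Matrix::expm(blk * dt / 2))
  Phi_h <- P[1:(2 * n), 1:(2 * n)]
  Gam_h <- P[1:(2 * n), (2 * n + 1):(3 * n), drop = FALSE]
  list(Phi = Phi_h %*% Phi_h, Gam = Phi_h %*% Gam_h + Gam_h,
       Phi_h = Phi_h, Gam_h = Gam_h, free = f, n = n)
}

#' Trajectory-tracking objective for one timestep
#'
#' Integrates the dynamics over `[t, t + dt]` with the candidate forces held
#' constant and returns the summed squared discrepancy between the model's
#' and the observed node displacements over the tracked DoFs.
#'
#' @param unknowns numeric vector of candidate segment forces (see
#'   [estimation_setup()]).
#' @param structure a `trunk_structure` or `trunk_system`.
#' @param state current `system_state`.
#' @param target_disp observed displacement over the step: full-length DoF
#'   vector (m); only tracked entries are compared.
#' @param dt step duration, s, `> 0`.
#' @param setup an `estimation_setup`; defaults to the standard setup.
#' @param gravity_on logical.
#' @return Non-negative scalar objective (m^2). Integration failures return
#'   a large penalty with a warning instead of erroring, to keep outer
#'   optimizers alive.
#' @export
tracking_objective <- function(unknowns, structure, state, target_disp, dt,
                               setup = NULL, gravity_on = TRUE) {
  stopifnot(dt > 0)
  sys <- as_trunk_system(structure)
  if (is.null(setup)) setup <- estimation_setup(sys)
  r <- step_residual(unknowns, sys, state, target_disp, dt, setup,
                     gravity_on)
  sum(r^2)
}

# residual vector over tracked dofs; large finite penalty on failure.
# Tolerances are kept tight: the optimizer must not be able to hide force
# errors below the integrator's noise floor. When a terminal velocity
# target and weight are given, dt-scaled velocity mismatches are appended
# (the stabilizing term of the per-step tracking problem).
step_residual <- function(unknowns, sys, state, target_disp, dt, setup,
                          gravity_on, rtol = 1e-9, atol = 1e-12,
                          target_vel = NULL, vweight = 0, fpen = 0) {
  nres <- length(setup$tracked_dofs) *
    (1L + as.integer(vweight > 0 && !is.null(target_vel))) +
    as.integer(fpen > 0) * length(unknowns)
  f_rod <- as.vector(setup$U %*% unknowns)
  traj <- tryCatch(
    integrate_dynamics(sys, state, f_rod, times = c(state$time,
                                                    state$time + dt),
                       gravity_on = gravity_on, rtol = rtol, atol = atol),
    error = function(e) NULL)
  if (is.null(traj)) {
    warning("integration failed during force estimation; returning penalty",
            call. = FALSE)
    return(rep(1e3, nres))
  }
  dq <- traj$q[2, ] - state$q
  r <- (dq - target_disp)[setup$tracked_dofs]
  if (vweight > 0 && !is.null(target_vel)) {
    rv <- vweight * dt *
      (traj$qdot[2, ] - target_vel)[setup$tracked_dofs]
    r <- c(r, rv)
  }
  if (fpen > 0) r <- c(r, fpen * unknowns)
  r
}

#' Estimate the active forces for one timestep
#'
#' Bounded nonlinear least-squares (Levenberg-Marquardt) minimization of
#' the per-step tracking problem: the displacement discrepancy of
#' [tracking_objective()], optionally augmented with a dt-scaled terminal
#' velocity mismatch (`velocity_weight`, default 1 when a velocity target
#' is supplied). Matching only displacements leaves the step's final
#' velocity free, which destabilizes sequential tracking of data the model
#' cannot reproduce exactly; the velocity term is the standard remedy.
#'
#' The solver proceeds in three phases, exploiting the fact that the
#' passive dynamics are exactly linear (the stiffness matrix is assembled
#' once at rest) so the only nonlinearity is the active-force direction
#' matrix `B(x)`: (1) iterated linear least-squares solves against the
#' exact matrix-exponential step response, re-evaluating `B` at the
#' linearly predicted mid-step geometry -- no ODE integration at all;
#' (2) Levenberg-Marquardt on the true integrated residuals with that
#' analytic Jacobian; (3) further re-linearizations of `B` at the true
#' mid-step geometry while they pay off. The returned solution never has a
#' larger objective than the warm start.
#'
#' @param structure a `trunk_structure` or `trunk_system`.
#' @param state current `system_state`.
#' @param target_disp observed displacement over the step (full DoF vector).
#' @param dt step duration, s.
#' @param warm_start previous step's solution (zeros allowed).
#' @param setup an `estimation_setup` (defaults to the standard setup).
#' @param propagator optional precomputed [step_propagator] result.
#' @param target_vel optional observed velocity at the end of the step
#'   (full DoF vector, m/s).
#' @param control list: `force_bound` (N, default from config), `max_iter`,
#'   `ftol`, `rtol`, `atol`, `gravity_on`, `velocity_weight`.
#' @return List `forces` (the estimate), `objective` (combined residual
#'   sum of squares), `iterations`, `converged`.
#' @export
estimate_step_forces <- function(structure, state, target_disp, dt,
                                 warm_start = NULL, setup = NULL,
                                 propagator = NULL, target_vel = NULL,
                                 control = list()) {
  sys <- as_trunk_system(structure)
  cfg <- sys$structure$config
  if (is.null(setup)) setup <- estimation_setup(sys)
  ctl <- modifyList(list(force_bound = cfg$force_bound,
                         max_iter = cfg$max_iter, ftol = 1e-10,
                         rtol = 1e-9, atol = 1e-12,
                         velocity_weight = 1,
                         force_penalty = 1e-6,
                         gravity_on = TRUE), control)
  vweight <- if (is.null(target_vel)) 0 else ctl$velocity_weight
  fpen <- ctl$force_penalty
  n_unknown <- ncol(setup$U)
  if (is.null(warm_start)) warm_start <- numeric(n_unknown)
  if (is.null(propagator)) propagator <- step_propagator(sys, dt)

  free <- propagator$free
  n <- propagator$n
  GamQ <- propagator$Gam[1:n, , drop = FALSE]
  GamV <- propagator$Gam[(n + 1):(2 * n), , drop = FALSE]
  tracked_free <- match(setup$tracked_dofs, free)
  if (anyNA(tracked_free)) stop("tracked DoFs must be free DoFs")
  jac_at <- function(pos) {
    Bgeo <- vapply(seq_len(n_unknown), function(j) {
      nodal_active_resultants(sys, setup$U[, j], pos)
    }, numeric(sys$ndof))
    Jq <- (-GamQ %*% Bgeo[free, , drop = FALSE])[tracked_free, ,
                                                 drop = FALSE]
    J <- if (vweight > 0) {
      Jv <- (-GamV %*% Bgeo[free, , drop = FALSE])[tracked_free, ,
                                                   drop = FALSE]
      rbind(Jq, vweight * dt * Jv)
    } else Jq
    if (fpen > 0) J <- rbind(J, diag(fpen, n_unknown))
    J
  }
  pos0 <- sys$rest + matrix(state$q, ncol = 3, byrow = TRUE)
  J_tracked <- jac_at(pos0)

  # Phase 1 -- iterated linear solves, no ODE integration. The passive
  # force is nonlinear in q; its deviation from -K q at the step-start
  # state enters the linear prediction as a constant extra input, making
  # the prediction exact at the current configuration.
  fext <- if (ctl$gravity_on) gravity_load(sys) else numeric(sys$ndof)
  fext_eff <- fext + rod_internal_forces(sys, state$q,
                                         numeric(length(sys$i1))) +
    as.vector(sys$K %*% state$q)
  z0 <- c(state$q[free], state$qdot[free])
  z1_passive <- propagator$Phi %*% z0 + propagator$Gam %*% fext_eff[free]
  d0 <- numeric(sys$ndof)
  d0[free] <- z1_passive[1:n] - state$q[free]
  rhs <- (target_disp - d0)[setup$tracked_dofs]
  if (vweight > 0) {
    v0_pred <- numeric(sys$ndof)
    v0_pred[free] <- z1_passive[(n + 1):(2 * n)]
    rhs <- c(rhs, vweight * dt *
               (target_vel - v0_pred)[setup$tracked_dofs])
  }
  if (fpen > 0) rhs <- c(rhs, numeric(n_unknown))
  GamQ_h <- propagator$Gam_h[1:n, , drop = FALSE]
  q_mid_passive <- (propagator$Phi_h %*% z0 +
                      propagator$Gam_h %*% fext_eff[free])[1:n]
  f_lin <- warm_start
  J_cur <- J_tracked
  for (it in 1:3) {
    f_new <- tryCatch(qr.solve(J_cur, rhs), error = function(e) NULL)
    if (is.null(f_new)) break
    f_new <- pmin(pmax(f_new, -ctl$force_bound), ctl$force_bound)
    f_lin <- f_new
    # linear mid-step prediction under these forces, to refresh B
    Bf <- nodal_active_resultants(sys, as.vector(setup$U %*% f_lin), pos0)
    q_mid <- numeric(sys$ndof)
    q_mid[free] <- q_mid_passive - GamQ_h %*% Bf[free]
    J_cur <- jac_at(sys$rest + matrix(q_mid, ncol = 3, byrow = TRUE))
  }

  resid_fn <- function(par) {
    step_residual(par, sys, state, target_disp, dt, setup, ctl$gravity_on,
                  rtol = ctl$rtol, atol = ctl$atol,
                  target_vel = target_vel, vweight = vweight,
                  fpen = fpen)
  }
  obj <- function(par) sum(resid_fn(par)^2)
  candidates <- list(warm = warm_start, lin = f_lin)
  objs <- c(warm = obj(warm_start), lin = obj(f_lin))
  iters <- 3L
  converged <- FALSE
  run_lm <- function(start, J, label, maxiter) {
    fit <- suppressWarnings(tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = resid_fn, jac = function(par) J,
        lower = rep(-ctl$force_bound, n_unknown),
        upper = rep(ctl$force_bound, n_unknown),
        control = minpack.lm::nls.lm.control(
          maxiter = maxiter, ftol = ctl$ftol, ptol = ctl$ftol)),
      error = function(e) NULL))
    if (!is.null(fit)) {
      candidates[[label]] <<- fit$par
      objs[label] <<- fit$deviance
      iters <<- iters + fit$niter
      converged <<- converged || fit$info %in% 1:4
    }
  }

  # Phase 2 -- LM on the true integrated residuals
  run_lm(candidates[[names(objs)[which.min(objs)]]], J_cur, "lm",
         min(ctl$max_iter, 20L))

  # Phase 3 -- extra re-linearization at the true mid-step geometry, only
  # while it keeps paying off; for data the model cannot reproduce the
  # residual floor is irreducible and the loop stops immediately.
  refine_tol <- (1e-6 * sqrt(sum(rhs^2)) + 1e-10)^2
  for (pass in 1:2) {
    if (min(objs) <= refine_tol) break
    f_cur <- candidates[[names(objs)[which.min(objs)]]]
    obj_before <- min(objs)
    mid <- tryCatch(
      integrate_dynamics(sys, state, as.vector(setup$U %*% f_cur),
                         times = c(state$time, state$time + dt / 2),
                         gravity_on = ctl$gravity_on,
                         rtol = ctl$rtol, atol = ctl$atol),
      error = function(e) NULL)
    if (is.null(mid)) break
    J_mid <- jac_at(mid$positions[2, , ])
    run_lm(f_cur, J_mid, paste0("relin", pass), min(ctl$max_iter, 20L))
    if (min(objs) > 0.5 * obj_before) break  # no real progress
  }
  best <- names(objs)[which.min(objs)]
  forces <- candidates[[best]]
  names(forces) <- setup$labels
  list(forces = forces, objective = unname(objs[best]),
       iterations = iters,
       converged = converged || !(best %in% c("lm", "relin1", "relin2")))
}

#' Node position targets of a trial
#'
#' Reconstructs the five model node positions of each section from the
#' ellipse parameters: center `O`, dorsal/ventral nodes at `center +- b *`
#' (dorsal axis), lateral nodes at `center +- a *` (lateral axis).
#'
#' @param trial a `movement_trial` whose row count matches the structure's
#'   sections.
#' @return Array `n_times x (5 * n_rows) x 3` of positions, node id order.
#' @export
trial_node_positions <- function(trial) {
  stopifnot(inherits(trial, "movement_trial"))
  nt <- length(trial$times)
  n_nodes <- 5L * trial$n_rows
  out <- array(0, dim = c(nt, n_nodes, 3))
  for (s in seq_len(nt)) {
    secs <- trial_sample_sections(trial, s)
    for (i in seq_along(secs)) {
      sec <- secs[[i]]
      R <- sec$rotation
      a <- sec$semi_axes[1]; b <- sec$semi_axes[2]
      base <- (i - 1L) * 5L
      out[s, base + 1L, ] <- sec$center                 # O
      out[s, base + 2L, ] <- sec$center + b * R[, 3]    # P dorsal
      out[s, base + 3L, ] <- sec$center + a * R[, 2]    # B lateral
      out[s, base + 4L, ] <- sec$center - b * R[, 3]    # Q ventral
      out[s, base + 5L, ] <- sec$center - a * R[, 2]    # A lateral
    }
  }
  out
}

#' Sequential inverse dynamics over a whole trial
#'
#' Per-timestep estimation of the active rod forces that make the simulated
#' node displacements track the observed ones, warm-started from the
#' previous step. Two state-handling modes are available:
#'
#' * `"simulation"` (default for `movement_trial` input): each step is
#'   estimated from the current state of the evolving simulation, targeting
#'   the next observed sample; the estimation acts as a per-step tracking
#'   controller and the returned trajectory is the sequential simulation
#'   itself. This is the right mode for measured data that the model cannot
#'   reproduce exactly.
#' * `"data"` (default for `node_trajectory` / array input): each step is
#'   estimated from the data-synchronized state (observed positions;
#'   observed or finite-difference velocities), which keeps the per-step
#'   problems decoupled and recovers generating forces of model-produced
#'   trajectories essentially exactly; the returned trajectory is an
#'   open-loop replay of all estimates from the first sample's state.
#'
#' @param trial a `movement_trial` (row count must equal the structure's
#'   sections) or an `n_times x n_nodes x 3` position array /
#'   `node_trajectory` with matching node count.
#' @param structure a `trunk_structure` or `trunk_system`.
#' @param setup optional [estimation_setup()].
#' @param state_mode `"auto"` (see above), `"simulation"` or `"data"`.
#' @param control passed to [estimate_step_forces()]; additionally
#'   `gravity_on`, `rtol`, `atol`.
#' @return List of class `active_force_history`: `history` (data.frame
#'   `time, segment, FL_dorsal, FL_ventral, FR`), `diagnostics` (per-step
#'   objective, iterations, convergence flag), `trajectory` (simulated
#'   `node_trajectory`), `times`.
#' @export
run_inverse <- function(trial, structure, setup = NULL,
                        state_mode = c("auto", "simulation", "data"),
                        control = list()) {
  state_mode <- match.arg(state_mode)
  sys <- as_trunk_system(structure)
  st <- sys$structure
  if (inherits(trial, "movement_trial")) {
    if (trial$n_rows != st$n_sections) {
      stop("trial has ", trial$n_rows, " section rows but the structure has ",
           st$n_sections, " sections")
    }
    targets <- trial_node_positions(trial)
    times <- trial$times
    if (state_mode == "auto") state_mode <- "simulation"
  } else if (inherits(trial, "node_trajectory")) {
    targets <- trial$positions
    times <- trial$times
    if (state_mode == "auto") state_mode <- "data"
  } else {
    targets <- trial
    stopifnot(length(dim(targets)) == 3)
    times <- attr(targets, "times")
    if (is.null(times)) stop("position array needs a 'times' attribute")
    if (state_mode == "auto") state_mode <- "data"
  }
  if (dim(targets)[2] != sys$n_nodes) {
    stop("node count mismatch between targets and structure")
  }
  nt <- length(times)
  if (nt < 2) stop("need at least two samples")
  dt <- diff(times)
  if (max(dt) - min(dt) > 1e-6) stop("trial sample times must be uniform")
  dt <- mean(dt)

  if (is.null(setup)) setup <- estimation_setup(sys)
  default_tol <- if (state_mode == "data") c(1e-9, 1e-12) else c(1e-6, 1e-9)
  ctl <- modifyList(list(gravity_on = TRUE, rtol = default_tol[1],
                         atol = default_tol[2],
                         tracking_gain = 0.1), control)
  propagator <- step_propagator(sys, dt)

  rest_flat <- as.vector(t(sys$rest))
  q_data <- t(apply(targets, 1, function(p) as.vector(t(p)) - rest_flat))
  q_data[, sys$fixed_dofs] <- 0
  if (inherits(trial, "node_trajectory") && !is.null(trial$qdot)) {
    v_data <- trial$qdot
  } else {
    v_data <- matrix(0, nt, sys$ndof)
    v_data[1, ] <- (q_data[2, ] - q_data[1, ]) / dt
    if (nt > 2) {
      for (j in 2:(nt - 1L)) {
        v_data[j, ] <- (q_data[j + 1L, ] - q_data[j - 1L, ]) / (2 * dt)
      }
      v_data[nt, ] <- (q_data[nt, ] - q_data[nt - 1L, ]) / dt
    }
    v_data[, sys$fixed_dofs] <- 0
  }

  n_seg <- setup$n_segments
  hist_rows <- vector("list", nt - 1L)
  diag_rows <- vector("list", nt - 1L)
  warm <- numeric(ncol(setup$U))
  f_rod_steps <- vector("list", nt - 1L)
  qs <- matrix(0, nt, sys$ndof)
  vs <- matrix(0, nt, sys$ndof)
  sim_state <- system_state(q_data[1, ], v_data[1, ], times[1])
  qs[1, ] <- sim_state$q
  vs[1, ] <- sim_state$qdot
  for (j in seq_len(nt - 1L)) {
    state <- if (state_mode == "simulation") sim_state else
      system_state(q_data[j, ], v_data[j, ], times[j])
    # observed step plus a fractional correction of the accumulated
    # simulation error: a full (deadbeat) correction demands the whole
    # return within one sample, saturates the force bounds and
    # destabilizes; a fractional gain recovers the same drift over a few
    # samples with moderate forces. The velocity target carries the
    # matching closing rate -- demanding the data velocity while also
    # demanding a position correction is contradictory within one sample
    # and would freeze the correction into a persistent lag.
    err_j <- q_data[j, ] - state$q
    target_disp <- (q_data[j + 1L, ] - q_data[j, ]) +
      ctl$tracking_gain * err_j
    est <- estimate_step_forces(sys, state, target_disp, dt,
                                warm_start = warm, setup = setup,
                                propagator = propagator,
                                target_vel = v_data[j + 1L, ] +
                                  ctl$tracking_gain * err_j / dt,
                                control = ctl)
    warm <- est$forces
    f_rod_steps[[j]] <- as.vector(setup$U %*% est$forces)
    if (state_mode == "simulation") {
      tr <- integrate_dynamics(sys, sim_state, f_rod_steps[[j]],
                               times = c(times[j], times[j + 1L]),
                               gravity_on = ctl$gravity_on,
                               rtol = ctl$rtol, atol = ctl$atol)
      sim_state <- tr$final_state
      qs[j + 1L, ] <- sim_state$q
      vs[j + 1L, ] <- sim_state$qdot
    }
    hist_rows[[j]] <- data.frame(
      time = times[j], segment = seq_len(n_seg),
      FL_dorsal = est$forces[3 * (seq_len(n_seg) - 1L) + 1L],
      FL_ventral = est$forces[3 * (seq_len(n_seg) - 1L) + 2L],
      FR = est$forces[3 * (seq_len(n_seg) - 1L) + 3L])
    diag_rows[[j]] <- data.frame(
      time = times[j], objective = est$objective,
      iterations = est$iterations, converged = est$converged)
  }

  if (state_mode == "data") {
    # open-loop replay of the estimates from the first sample's state
    state <- system_state(q_data[1, ], v_data[1, ], times[1])
    for (j in seq_len(nt - 1L)) {
      traj <- integrate_dynamics(sys, state, f_rod_steps[[j]],
                                 times = c(times[j], times[j + 1L]),
                                 gravity_on = ctl$gravity_on,
                                 rtol = ctl$rtol, atol = ctl$atol)
      state <- traj$final_state
      qs[j + 1L, ] <- state$q
      vs[j + 1L, ] <- state$qdot
    }
  } else {
    state <- sim_state
  }
  positions <- array(0, dim = dim(targets))
  for (s in seq_len(nt)) {
    positions[s, , ] <- sys$rest + matrix(qs[s, ], ncol = 3, byrow = TRUE)
  }
  structure(list(
    history = do.call(rbind, hist_rows),
    diagnostics = do.call(rbind, diag_rows),
    trajectory = structure(list(times = times, positions = positions,
                                q = qs, qdot = vs,
                                final_state = state),
                           class = "node_trajectory"),
    times = times,
    state_mode = state_mode
  ), class = "active_force_history")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-segment aggregate force series
#'
#' `dFL = FL_dorsal - FL_ventral` (the bending drive), `FmL = (FL_dorsal +
#' FL_ventral) / 2` (the axial drive); `FR` is passed through.
#'
#' @param history an `active_force_history` or its `history` data.frame.
#' @return data.frame `time, segment, FR, dFL, FmL`.
#' @export
segment_force_summary <- function(history) {
  h <- if (inherits(history, "active_force_history")) history$history else
    history
  data.frame(time = h$time, segment = h$segment, FR = h$FR,
             dFL = h$FL_dorsal - h$FL_ventral,
             FmL = (h$FL_dorsal + h$FL_ventral) / 2)
}
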
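#' System state
#'
#' @param q node displacement vector (3 DoF per node, X/Y/Z), meters.
#' @param qdot velocity vector, m/s.
#' @param time seconds.
#' @return Object of class `system_state`.
#' @export
system_state <- function(q, qdot = numeric(length(q)), time = 0) {
  stopifnot(length(q) == length(qdot), all(is.finite(q)),
            all(is.finite(qdot)))
  structure(list(q = as.numeric(q), qdot = as.numeric(qdot),
                 time = as.numeric(time)), class = "system_state")
}

# resolve a trunk_structure or trunk_system argument to a trunk_system
as_trunk_system <- function(x) {
  if (inherits(x, "trunk_system")) return(x)
  if (inherits(x, "trunk_structure")) return(trunk_system(x))
  stop("expected a trunk_structure or trunk_system")
}

#' Gravitational load vector
#'
#' `-m*g` on each node's Z DoF, zeros elsewhere. Entries of fixed nodes are
#' retained (useful for reaction reporting) but are not applied during
#' integration, where fixed DoFs are clamped.
#'
#' @param structure a `trunk_structure` or `trunk_system`.
#' @param g gravitational acceleration, m/s^2; defaults to the structure
#'   config.
#' @return Numeric vector of length `3 * n_nodes`, N.
#' @export
gravity_load <- function(structure, g = NULL) {
  sys <- as_trunk_system(structure)
  if (is.null(g)) g <- sys$gravity
  f <- numeric(sys$ndof)
  f[seq(3, sys$ndof, by = 3)] <- -sys$mass[seq(3, sys$ndof, by = 3)] * g
  f
}

#' Nodal resultants of the active rod forces
#'
#' Each rod carries an axial active force `f` (positive = contraction) along
#' its current direction; the resultant on each node is the sum over the
#' rods converging there. The returned vector is the `Fact` term of the
#' governing equation `M qdd + K q + Fact = Fext`, i.e. the entry at a
#' rod's endpoint is `f` times the unit vector pointing away from the other
#' endpoint (so the physically applied force, `-Fact`, pulls the endpoints
#' together when `f > 0`). Contributions are equal and opposite, so the
#' vector sums to zero over all nodes.
#'
#' @param structure a `trunk_structure` or `trunk_system`.
#' @param forces per-rod axial forces, N (length `nrow(rods)`).
#' @param positions current node positions, `n_nodes x 3` matrix; defaults
#'   to the rest geometry.
#' @return Numeric vector of length `3 * n_nodes`, N.
#' @export
nodal_active_resultants <- function(structure, forces, positions = NULL) {
  sys <- as_trunk_system(structure)
  if (is.null(positions)) positions <- sys$rest
  stopifnot(length(forces) == length(sys$i1))
  out <- numeric(sys$ndof)
  active <- which(forces != 0)
  for (r in active) {
    p1 <- positions[sys$i1[r], ]
    p2 <- positions[sys$i2[r], ]
    d <- p2 - p1
    len <- sqrt(sum(d^2))
    if (len < 1e-12) {
      stop("rod ", r, " has zero length at the current configuration")
    }
    u <- d / len
    d1 <- (sys$i1[r] - 1L) * 3L
    d2 <- (sys$i2[r] - 1L) * 3L
    out[d1 + 1:3] <- out[d1 + 1:3] - forces[r] * u
    out[d2 + 1:3] <- out[d2 + 1:3] + forces[r] * u
  }
  out
}

# Total nodal forces from all rods at the current geometry: each rod
# carries the axial tension tau = k * (len - L0) + f_act (positive pulls
# its endpoints together) along its current direction, plus an optional
# Kelvin-Voigt axial viscous term beta * k * d(len)/dt when velocities are
# supplied. This is the geometrically nonlinear truss force -- tension
# stiffens the shear-soft inter-section modes, compression softens them
# (physical buckling).
rod_internal_forces <- function(sys, q, f_act, v = NULL) {
  P <- sys$rest + matrix(q, ncol = 3, byrow = TRUE)
  d <- P[sys$i2, , drop = FALSE] - P[sys$i1, , drop = FALSE]
  len <- sqrt(rowSums(d * d))
  if (any(len < 1e-12)) stop("rod collapsed to zero length")
  tau <- sys$k_rod * (len - sys$L0) + f_act
  if (!is.null(v) && sys$damping_beta > 0) {
    V <- matrix(v, ncol = 3, byrow = TRUE)
    dv <- V[sys$i2, , drop = FALSE] - V[sys$i1, , drop = FALSE]
    len_dot <- rowSums(d * dv) / len
    tau <- tau + sys$damping_beta * sys$k_rod * len_dot
  }
  contrib <- d * (tau / len)
  F <- matrix(0, sys$n_nodes, 3)
  s1 <- rowsum(contrib, sys$i1)
  F[as.integer(rownames(s1)), ] <- F[as.integer(rownames(s1)), ] + s1
  s2 <- rowsum(contrib, sys$i2)
  F[as.integer(rownames(s2)), ] <- F[as.integer(rownames(s2)), ] - s2
  as.vector(t(F))
}

#' Equations of motion
#'
#' `qdd = M^-1 (Fext + Fint(q, f) - C qdot)` with fixed DoFs clamped to
#' zero, where `Fint` collects every rod's axial force -- the passive
#' elastic tension `k * (len - L0)` plus the active force -- along its
#' current (deformed) direction, making the elastic term configuration
#' dependent as in the governing equation's `K(q)`. At small displacements
#' this reduces to `Fext - K_glob q - Fact - C qdot`. `C = c M` is an
#' optional mass-proportional viscous damping (`c = config$damping`,
#' s^-1); the underlying physical model is undamped, but piecewise-constant
#' force input into an undamped stiff network rings unphysically, so a
#' small default `c` is applied and can be set to zero.
#'
#' @param state a `system_state`.
#' @param forces per-rod axial active forces, N.
#' @param structure a `trunk_structure` or `trunk_system`.
#' @param gravity_on logical; include the gravitational load.
#' @return Acceleration vector `qdd`, m/s^2.
#' @export
equations_of_motion <- function(state, forces, structure, gravity_on = TRUE) {
  sys <- as_trunk_system(structure)
  if (any(!is.finite(sys$minv))) stop("singular mass matrix: zero-mass node")
  fext <- if (gravity_on) gravity_load(sys) else numeric(sys$ndof)
  fint <- rod_internal_forces(sys, state$q, forces, state$qdot)
  qdd <- sys$minv * (fext + fint - sys$damping * sys$mass * state$qdot)
  qdd[sys$fixed_dofs] <- 0
  qdd
}

# deSolve derivative closure shared by all integrations
make_deriv <- function(sys, force_fn, gravity_on) {
  ndof <- sys$ndof
  fext <- if (gravity_on) gravity_load(sys) else numeric(ndof)
  fext[sys$fixed_dofs] <- 0
  function(t, y, parms) {
    q <- y[1:ndof]
    v <- y[(ndof + 1):(2 * ndof)]
    fint <- rod_internal_forces(sys, q, force_fn(t), v)
    a <- sys$minv * (fext + fint - sys$damping * sys$mass * v)
    a[sys$fixed_dofs] <- 0
    v[sys$fixed_dofs] <- 0
    list(c(v, a))
  }
}

#' Integrate the trunk dynamics
#'
#' Adaptive Runge-Kutta (Dormand-Prince 4/5 via `deSolve::ode`,
#' method `"ode45"`) integration of the assembled equations of motion,
#' sampled at the requested output times. Fixed DoFs are identically zero
#' throughout.
#'
#' @param structure a `trunk_structure` or `trunk_system`.
#' @param state0 initial `system_state` (defaults to rest).
#' @param forces per-rod active forces: `NULL` (none), a numeric vector
#'   (constant in time), or a function `t -> vector`.
#' @param times output time points (first entry = initial time).
#' @param gravity_on logical.
#' @param rtol,atol solver tolerances; default from the structure config.
#' @return A `node_trajectory`: list with `times`, `positions`
#'   (`n_times x n_nodes x 3` array), `q`, `qdot` (matrices, one row per
#'   time) and `final_state`.
#' @export
integrate_dynamics <- function(structure, state0 = NULL, forces = NULL,
                               times, gravity_on = TRUE,
                               rtol = NULL, atol = NULL) {
  sys <- as_trunk_system(structure)
  if (is.null(state0)) state0 <- system_state(numeric(sys$ndof))
  if (is.null(rtol)) rtol <- sys$structure$config$solver_rtol
  if (is.null(atol)) atol <- sys$structure$config$solver_atol
  nrods <- length(sys$i1)
  force_fn <- if (is.null(forces)) {
    zero <- numeric(nrods); function(t) zero
  } else if (is.function(forces)) {
    forces
  } else {
    stopifnot(length(forces) == nrods)
    fconst <- as.numeric(forces); function(t) fconst
  }
  y0 <- c(state0$q, state0$qdot)
  y0[c(sys$fixed_dofs, sys$ndof + sys$fixed_dofs)] <- 0
  deriv <- make_deriv(sys, force_fn, gravity_on)
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (anyNA(sol)) {
    bad <- times[which(apply(sol, 1, anyNA))[1]]
    stop("integration failed (non-finite state) near t = ", bad)
  }
  qmat <- sol[, 1 + 1:sys$ndof, drop = FALSE]
  vmat <- sol[, 1 + sys$ndof + 1:sys$ndof, drop = FALSE]
  nt <- nrow(sol)
  positions <- array(0, dim = c(nt, sys$n_nodes, 3))
  for (s in seq_len(nt)) {
    positions[s, , ] <- sys$rest + matrix(qmat[s, ], ncol = 3, byrow = TRUE)
  }
  structure(list(
    times = as.numeric(sol[, 1]),
    positions = positions,
    q = qmat,
    qdot = vmat,
    final_state = system_state(qmat[nt, ], vmat[nt, ], sol[nt, 1])
  ), class = "node_trajectory")
}

#' Total mechanical energy along a trajectory
#'
#' Kinetic plus elastic strain energy (`0.5 * k * (len - L0)^2` summed over
#' rods), optionally plus gravitational potential. Useful for
#' integrator-accuracy audits on undamped systems.
#'
#' @param trajectory a `node_trajectory`.
#' @param structure the `trunk_structure` or `trunk_system` integrated.
#' @param gravity_on include gravitational potential energy.
#' @return Numeric vector of energies, J, one per output time.
#' @export
trajectory_energy <- function(trajectory, structure, gravity_on = FALSE) {
  sys <- as_trunk_system(structure)
  vapply(seq_along(trajectory$times), function(s) {
    q <- trajectory$q[s, ]
    v <- trajectory$qdot[s, ]
    P <- sys$rest + matrix(q, ncol = 3, byrow = TRUE)
    len <- sqrt(rowSums((P[sys$i2, , drop = FALSE] -
                           P[sys$i1, , drop = FALSE])^2))
    e <- 0.5 * sum(sys$mass * v^2) +
      0.5 * sum(sys$k_rod * (len - sys$L0)^2)
    if (gravity_on) {
      zidx <- seq(3, sys$ndof, by = 3)
      e <- e + sum(sys$mass[zidx] * sys$gravity * q[zidx])
    }
    e
  }, numeric(1))
}
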
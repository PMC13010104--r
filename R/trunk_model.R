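#' Allocate trunk mass to nodes via truncated-cone sub-volumes
#'
#' The trunk is divided into as many truncated-cone sub-volumes as there are
#' sections; each section receives mass proportional to its frustum volume
#' `V = pi*h/3 * (r1^2 + r1*r2 + r2^2)` and divides it equally over its five
#' nodes. With equal sub-volume heights only the radius ratios matter.
#'
#' @param total_mass kg.
#' @param radii numeric vector of `n_sections + 1` frustum radii, meters,
#'   expected monotone non-increasing from base to tip.
#' @param section_length frustum height, m (cancels out when equal; kept for
#'   completeness).
#' @return Numeric vector of `5 * n_sections` node masses (section-major
#'   order), summing exactly to `total_mass`.
#' @export
distribute_mass <- function(total_mass, radii, section_length = 1) {
  stopifnot(total_mass > 0, length(radii) >= 2, section_length > 0)
  if (any(radii <= 0)) stop("radii must be strictly positive")
  if (any(diff(radii) > 1e-12)) {
    warning("radii are not monotone non-increasing from base to tip")
  }
  n <- length(radii) - 1L
  r1 <- radii[-length(radii)]
  r2 <- radii[-1]
  vol <- pi * section_length / 3 * (r1^2 + r1 * r2 + r2^2)
  section_mass <- total_mass * vol / sum(vol)
  rep(section_mass / 5, each = 5)
}

#' Local stiffness matrix of an axial rod element
#'
#' A rod sustains only axial load; in its local frame (local x along the
#' rod) the 6x6 element matrix has `+k` at (1,1) and (4,4) and `-k` at
#' (1,4) and (4,1), zeros elsewhere.
#'
#' @param k axial stiffness `E*A/L0`, N/m, `> 0`.
#' @return 6x6 matrix.
#' @export
local_stiffness_matrix <- function(k) {
  if (!is.finite(k) || k <= 0) stop("axial stiffness k must be positive")
  K <- matrix(0, 6, 6)
  K[1, 1] <- K[4, 4] <- k
  K[1, 4] <- K[4, 1] <- -k
  K
}

#' Rod transformation matrix (direction cosines)
#'
#' Block-diagonal pair of 3x3 orthonormal matrices whose first row is the
#' unit vector along the rod, completing the local element frame.
#'
#' @param p1,p2 endpoint positions, 3-vectors, m.
#' @return 6x6 transformation with `t(R) %*% R = I`.
#' @export
rod_rotation_matrix <- function(p1, p2) {
  d <- as.numeric(p2) - as.numeric(p1)
  len <- sqrt(sum(d^2))
  if (len < 1e-14) stop("zero-length rod: endpoints coincide")
  u <- d / len
  helper <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w1 <- helper - sum(helper * u) * u
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- c(u[2] * w1[3] - u[3] * w1[2],
          u[3] * w1[1] - u[1] * w1[3],
          u[1] * w1[2] - u[2] * w1[1])
  T3 <- rbind(u, w1, w2)
  R <- matrix(0, 6, 6)
  R[1:3, 1:3] <- T3
  R[4:6, 4:6] <- T3
  R
}

#' Transform a local element matrix to the global frame
#'
#' `K_glob = t(R) %*% K_loc %*% R`; a similarity transform, so eigenvalues
#' and symmetry are preserved.
#'
#' @param K_loc 6x6 local stiffness matrix.
#' @param R 6x6 transformation from [rod_rotation_matrix()].
#' @return 6x6 global element matrix.
#' @export
globalize_stiffness <- function(K_loc, R) {
  t(R) %*% K_loc %*% R
}

# region (1 proximal, 2 middle, 3 distal) of a segment index
segment_region <- function(segment, n_segments) {
  pmin(3L, pmax(1L, ceiling(3 * segment / n_segments)))
}

#' Rest orientation of the trunk sections
#'
#' At rest the trunk hangs vertically (tip down, as the animal's resting
#' posture): the backbone tangent (local x) points along global -Z, the
#' lateral axis (local y) along +Y and the dorsal axis (local z) along +X,
#' so gravity is carried by tension in the longitudinal rods and planar
#' reaching movements unfold in the X-Z plane.
#'
#' @return 3x3 rotation matrix (columns: tangent, lateral, dorsal).
#' @export
trunk_rest_rotation <- function() {
  cbind(c(0, 0, -1), c(0, 1, 0), c(1, 0, 0))
}

#' Build the discrete trunk structure
#'
#' Constructs `n_sections` cross-sections of five point masses each (center
#' `O`, dorsal `P`, lateral `B`, ventral `Q`, lateral `A`) along a straight
#' rest backbone hanging along -Z (dorsal +X, gravity -Z; see
#' [trunk_rest_rotation()]), connected by three rod types: longitudinal
#' rods between same-role nodes of adjacent sections (including the center
#' chain), radial rods from each center to its four outer nodes, and
#' connective perimeter rods between adjacent outer nodes of a section. Rod
#' cross-sectional areas are type-specific fractions of the local section
#' area `pi*a*b`; Young's modulus follows the three-region
#' proximal/middle/distal profile. All five nodes of section 1 are fixed
#' (the trunk is grounded at the skull).
#'
#' @param config a `trunk_config` (or override list), see [default_config()].
#' @param n_sections optional override of `config$n_sections` (useful for
#'   small test-scale trunks).
#' @return A `trunk_structure`: list with `nodes` (data.frame: `node_id`
#'   0-based, `section`, `role`, `mass`, `x, y, z`), `rods` (data.frame:
#'   `rod_id`, `node1`, `node2`, `type`, `section`, `segment`, `L0`, `E`,
#'   `A`, `k`), `fixed_nodes` (0-based ids), `n_sections`, `n_nodes`,
#'   `segment_length`, `section_radii`, `config`.
#' @export
build_structure <- function(config = default_config(), n_sections = NULL) {
  cfg <- validate_config(unclass(config))
  if (!is.null(n_sections)) cfg$n_sections <- as.integer(n_sections)
  m <- cfg$n_sections
  if (m < 2) stop("need at least 2 sections")
  n_seg <- m - 1L
  seg_len <- cfg$total_length / n_seg
  sec_r <- seq(cfg$base_radius, cfg$tip_radius, length.out = m)
  mass_radii <- seq(cfg$base_radius, cfg$tip_radius, length.out = m + 1)
  masses <- distribute_mass(cfg$total_mass, mass_radii, seg_len)

  # rest pose: backbone hanging along -Z, dorsal +X, lateral +Y
  roles <- c("O", "P", "B", "Q", "A")
  nodes <- do.call(rbind, lapply(seq_len(m), function(i) {
    z <- -(i - 1) * seg_len
    r <- sec_r[i]
    data.frame(
      node_id = (i - 1L) * 5L + 0:4,
      section = i,
      role = roles,
      x = c(0, r, 0, -r, 0),
      y = c(0, 0, r, 0, -r),
      z = z
    )
  }))
  nodes$mass <- masses

  nid <- function(section, role) {
    (section - 1L) * 5L + match(role, roles) - 1L
  }
  pos_of <- function(id) as.numeric(nodes[nodes$node_id == id, c("x", "y", "z")])
  E_of_region <- c(cfg$E_proximal, cfg$E_middle, cfg$E_distal)

  rods <- list()
  # longitudinal rods between same-role nodes of adjacent sections; the
  # center chain O-O is included (without it the backbone centers have no
  # first-order axial support, since radial rods are perpendicular to the
  # backbone)
  for (i in seq_len(n_seg)) {
    reg <- segment_region(i, n_seg)
    area <- mean(cfg$area_fraction_longitudinal * pi * sec_r[c(i, i + 1)]^2)
    for (role in c("O", "P", "B", "Q", "A")) {
      rods[[length(rods) + 1L]] <- data.frame(
        node1 = nid(i, role), node2 = nid(i + 1L, role),
        type = "longitudinal", role = role, section = NA_integer_,
        segment = i, E = E_of_region[reg], A = area)
    }
  }
  # radial rods: center to the four outer nodes of each section
  for (i in seq_len(m)) {
    reg <- segment_region(max(i - 1L, 1L), n_seg)
    area <- cfg$area_fraction_radial * pi * sec_r[i]^2
    for (role in c("P", "B", "Q", "A")) {
      rods[[length(rods) + 1L]] <- data.frame(
        node1 = nid(i, "O"), node2 = nid(i, role),
        type = "radial", role = role, section = i,
        segment = if (i > 1L) i - 1L else NA_integer_,
        E = E_of_region[reg], A = area)
    }
  }
  # connective perimeter rods within each section
  perim <- list(c("P", "B"), c("B", "Q"), c("Q", "A"), c("A", "P"))
  for (i in seq_len(m)) {
    reg <- segment_region(max(i - 1L, 1L), n_seg)
    area <- cfg$area_fraction_connective * pi * sec_r[i]^2
    for (pr in perim) {
      rods[[length(rods) + 1L]] <- data.frame(
        node1 = nid(i, pr[1]), node2 = nid(i, pr[2]),
        type = "connective", role = NA_character_, section = i,
        segment = if (i > 1L) i - 1L else NA_integer_,
        E = E_of_region[reg], A = area)
    }
  }
  rods <- do.call(rbind, rods)
  rods$rod_id <- seq_len(nrow(rods))
  L0 <- vapply(seq_len(nrow(rods)), function(r) {
    sqrt(sum((pos_of(rods$node2[r]) - pos_of(rods$node1[r]))^2))
  }, numeric(1))
  rods$L0 <- L0
  rods$k <- rods$E * rods$A / rods$L0

  structure(list(
    nodes = nodes[, c("node_id", "section", "role", "mass", "x", "y", "z")],
    rods = rods[, c("rod_id", "node1", "node2", "type", "role", "section",
                    "segment", "L0", "E", "A", "k")],
    fixed_nodes = nodes$node_id[nodes$section == 1],
    n_sections = m,
    n_nodes = nrow(nodes),
    segment_length = seg_len,
    section_radii = sec_r,
    config = cfg
  ), class = "trunk_structure")
}

#' Low-level trunk structure constructor
#'
#' Builds a `trunk_structure` from explicit node and rod tables; intended
#' for toy systems (single masses, short chains) used in tests and method
#' validation. `k` is recomputed as `E*A/L0` when missing.
#'
#' @param nodes data.frame with `node_id` (0-based), `mass`, `x, y, z`
#'   (and optionally `section`, `role`).
#' @param rods data.frame with `node1`, `node2`, `k` (or `E`, `A`) and
#'   optionally `type`.
#' @param fixed_nodes integer vector of 0-based node ids held fixed.
#' @param config a `trunk_config`; only `damping`, `gravity` and solver
#'   settings are used.
#' @return A `trunk_structure`.
#' @export
trunk_structure <- function(nodes, rods, fixed_nodes = integer(),
                            config = default_config()) {
  stopifnot(all(c("node_id", "mass", "x", "y", "z") %in% names(nodes)))
  if (any(nodes$mass <= 0)) stop("node masses must be positive")
  if (!"section" %in% names(nodes)) nodes$section <- NA_integer_
  if (!"role" %in% names(nodes)) nodes$role <- NA_character_
  if (!"type" %in% names(rods)) rods$type <- "longitudinal"
  if (!"rod_id" %in% names(rods)) rods$rod_id <- seq_len(nrow(rods))
  if (!"segment" %in% names(rods)) rods$segment <- NA_integer_
  if (!"section" %in% names(rods)) rods$section <- NA_integer_
  if (!"role" %in% names(rods)) rods$role <- NA_character_
  p <- as.matrix(nodes[, c("x", "y", "z")])
  i1 <- match(rods$node1, nodes$node_id)
  i2 <- match(rods$node2, nodes$node_id)
  if (anyNA(i1) || anyNA(i2)) stop("rod endpoints must reference node ids")
  if (any(rods$node1 == rods$node2)) stop("rod endpoints must be distinct")
  rods$L0 <- sqrt(rowSums((p[i2, , drop = FALSE] - p[i1, , drop = FALSE])^2))
  if (!"k" %in% names(rods)) rods$k <- rods$E * rods$A / rods$L0
  if (any(rods$k <= 0) || any(rods$L0 <= 0)) {
    stop("rod stiffness and rest length must be positive")
  }
  structure(list(
    nodes = nodes, rods = rods, fixed_nodes = fixed_nodes,
    n_sections = length(unique(nodes$section[!is.na(nodes$section)])),
    n_nodes = nrow(nodes),
    segment_length = NA_real_, section_radii = NULL,
    config = validate_config(unclass(config))
  ), class = "trunk_structure")
}

#' Assemble the global stiffness and mass matrices
#'
#' Scatter-adds each rod's globalized 6x6 element matrix into the node DoF
#' slots (3 per node: X, Y, Z). The mass matrix is diagonal under the lumped
#' mass assumption, each node mass repeated three times. For the default
#' trunk both matrices are 150x150.
#'
#' @param structure a `trunk_structure`.
#' @return List with `K` (dense symmetric matrix) and `M` (diagonal matrix
#'   of the same size).
#' @export
assemble_global <- function(structure) {
  nodes <- structure$nodes
  rods <- structure$rods
  N <- nrow(nodes)
  ndof <- 3L * N
  K <- matrix(0, ndof, ndof)
  p <- as.matrix(nodes[, c("x", "y", "z")])
  row_of <- match(seq_len(N), seq_len(N))  # identity; node rows
  idx1 <- match(rods$node1, nodes$node_id)
  idx2 <- match(rods$node2, nodes$node_id)
  for (r in seq_len(nrow(rods))) {
    R <- rod_rotation_matrix(p[idx1[r], ], p[idx2[r], ])
    Ke <- globalize_stiffness(local_stiffness_matrix(rods$k[r]), R)
    dofs <- c((idx1[r] - 1L) * 3L + 1:3, (idx2[r] - 1L) * 3L + 1:3)
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  K <- (K + t(K)) / 2  # enforce exact symmetry against rounding
  M <- diag(rep(nodes$mass, each = 3), ndof, ndof)
  list(K = K, M = M)
}

# Precomputed simulation system: matrices, index maps, rest geometry.
# Internal but exported for reuse across many integration calls.

#' Precompute the simulation system for a structure
#'
#' Assembles matrices once and caches index maps and rest geometry so that
#' repeated integrations (inverse dynamics, reaching) do not re-assemble.
#'
#' @param structure a `trunk_structure`.
#' @return An object of class `trunk_system`.
#' @export
trunk_system <- function(structure) {
  asm <- assemble_global(structure)
  nodes <- structure$nodes
  N <- nrow(nodes)
  ndof <- 3L * N
  fixed_rows <- match(structure$fixed_nodes, nodes$node_id)
  fixed_dofs <- if (length(fixed_rows) > 0) {
    as.vector(t(outer((fixed_rows - 1L) * 3L, 1:3, `+`)))
  } else integer()
  free_dofs <- setdiff(seq_len(ndof), fixed_dofs)
  structure(list(
    structure = structure,
    K = asm$K,
    mass = rep(nodes$mass, each = 3),
    minv = 1 / rep(nodes$mass, each = 3),
    rest = as.matrix(nodes[, c("x", "y", "z")]),
    i1 = match(structure$rods$node1, nodes$node_id),
    i2 = match(structure$rods$node2, nodes$node_id),
    k_rod = structure$rods$k,
    L0 = structure$rods$L0,
    n_nodes = N,
    ndof = ndof,
    fixed_dofs = fixed_dofs,
    free_dofs = free_dofs,
    damping = structure$config$damping,
    damping_beta = structure$config$damping_beta,
    gravity = structure$config$gravity
  ), class = "trunk_system")
}
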
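#' Trajectory error metrics between simulated and reference motion
#'
#' Per node: MAE = mean over time of the planar (X, Z) Euclidean deviation,
#' RMSE analogously with squared deviations, and rel_MAE = MAE divided by
#' the arc length of the reference node's path, in percent. A node whose
#' reference path length is zero gets `NA` rel_MAE (flagged, never a
#' division by zero).
#'
#' @param sim,ref `node_trajectory` objects or `n_times x n_nodes x 3`
#'   arrays with matched nodes and equal length.
#' @param axes coordinates used for the deviation (default X and Z, the
#'   planar form).
#' @param tip_node 1-based index of the tip node for the tip summary;
#'   defaults to the center node of the most distal section when the node
#'   count is a multiple of 5.
#' @return An `error_report`: `per_node` data.frame (`node, mae, rmse,
#'   rel_mae, path_length`), `aggregate` (means over nodes), `tip` (the tip
#'   node's row, if identified).
#' @export
trajectory_errors <- function(sim, ref, axes = c("x", "z"),
                              tip_node = NULL) {
  P <- if (inherits(sim, "node_trajectory")) sim$positions else sim
  Q <- if (inherits(ref, "node_trajectory")) ref$positions else ref
  if (!all(dim(P) == dim(Q))) {
    stop("simulated and reference trajectories must have equal dimensions")
  }
  axmap <- c(x = 1L, y = 2L, z = 3L)
  ax <- axmap[match(axes, names(axmap))]
  n_nodes <- dim(P)[2]
  per_node <- do.call(rbind, lapply(seq_len(n_nodes), function(i) {
    d <- sqrt(rowSums((P[, i, ax, drop = FALSE] -
                         Q[, i, ax, drop = FALSE])^2))
    steps <- diff(Q[, i, ax, drop = FALSE][, 1, ])
    path <- if (is.null(dim(steps))) sum(abs(steps)) else
      sum(sqrt(rowSums(steps^2)))
    mae <- mean(d)
    data.frame(node = i, mae = mae, rmse = sqrt(mean(d^2)),
               rel_mae = if (path > 0) 100 * mae / path else NA_real_,
               path_length = path)
  }))
  if (is.null(tip_node) && n_nodes %% 5 == 0) {
    tip_node <- n_nodes - 4L  # center node O of the most distal section
  }
  structure(list(
    per_node = per_node,
    aggregate = list(mae = mean(per_node$mae), rmse = mean(per_node$rmse),
                     rel_mae = mean(per_node$rel_mae, na.rm = TRUE)),
    tip = if (!is.null(tip_node)) per_node[per_node$node == tip_node, ]
  ), class = "error_report")
}

# volume of one tetrahedron
tet_volume <- function(a, b, c, d) {
  abs(det(cbind(b - a, c - a, d - a))) / 6
}

#' Volume of a hexahedral trunk segment
#'
#' A segment is a truncated pyramid with non-parallel rectangular bases:
#' corners 1-4 are the outer nodes (P, B, Q, A) of the proximal section,
#' corners 5-8 the same roles of the distal section. The hexahedron is
#' decomposed into six tetrahedra sharing the fixed diagonal corner1-corner7
#' so that volumes are bit-reproducible.
#'
#' @param corners `8 x 3` matrix of corner positions, m.
#' @return Volume in m^3; degenerate (all-coplanar) corner sets return 0
#'   with a warning.
#' @export
segment_volume <- function(corners) {
  corners <- as.matrix(corners)
  stopifnot(nrow(corners) == 8, ncol(corners) == 3)
  X <- sweep(corners, 2, colMeans(corners))
  if (min(svd(X)$d) < 1e-12 * max(svd(X)$d, 1e-300)) {
    warning("degenerate hexahedron: all corners coplanar")
    return(0)
  }
  v <- lapply(seq_len(8), function(i) corners[i, ])
  tets <- list(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
               c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  sum(vapply(tets, function(tt) {
    tet_volume(v[[tt[1]]], v[[tt[2]]], v[[tt[3]]], v[[tt[4]]])
  }, numeric(1)))
}

# outer-node corner matrix of segment i at one time sample
segment_corners <- function(positions, structure, i) {
  roles <- c("P", "B", "Q", "A")
  idx <- function(section, role) {
    which(structure$nodes$section == section & structure$nodes$role == role)
  }
  rbind(
    do.call(rbind, lapply(roles, function(r) positions[idx(i, r), ])),
    do.call(rbind, lapply(roles, function(r) positions[idx(i + 1L, r), ]))
  )
}

#' Hexahedral trunk volume over a trajectory
#'
#' Per time sample, sums the hexahedral volumes of all segments; reports
#' the percentage mean absolute error relative to the resting reference
#' volume (computed from the structure's rest geometry).
#'
#' @param trajectory a `node_trajectory` (or position array).
#' @param structure the `trunk_structure`.
#' @return A `volume_series`: data.frame `series` (`time`, `total`, one
#'   `seg_i` column per segment), `reference` (resting volume, m^3) and
#'   `mae_percent`.
#' @export
volume_series <- function(trajectory, structure) {
  st <- if (inherits(structure, "trunk_system")) structure$structure else
    structure
  P <- if (inherits(trajectory, "node_trajectory")) trajectory$positions
  else trajectory
  times <- if (inherits(trajectory, "node_trajectory")) trajectory$times
  else seq_len(dim(P)[1])
  n_seg <- st$n_sections - 1L
  rest <- as.matrix(st$nodes[, c("x", "y", "z")])
  v_ref <- sum(vapply(seq_len(n_seg), function(i) {
    segment_volume(segment_corners(rest, st, i))
  }, numeric(1)))
  series <- do.call(rbind, lapply(seq_len(dim(P)[1]), function(s) {
    vols <- vapply(seq_len(n_seg), function(i) {
      segment_volume(segment_corners(P[s, , ], st, i))
    }, numeric(1))
    row <- data.frame(time = times[s], total = sum(vols))
    for (i in seq_len(n_seg)) row[[paste0("seg_", i)]] <- vols[i]
    row
  }))
  structure(list(series = series, reference = v_ref,
                 mae_percent = mean(abs(series$total - v_ref)) / v_ref *
                   100),
            class = "volume_series")
}

#' Elliptic-frustum trunk volume of a trial
#'
#' Alternative volume estimate computed directly from the fitted ellipses:
#' each segment is an elliptic frustum with
#' `V = h/3 * (A1 + A2 + sqrt(A1*A2))`, `A = pi*a*b`, `h` the
#' center-to-center distance. The reference is the first sample's volume.
#'
#' @param trial a `movement_trial`.
#' @return A `volume_series` (same layout as [volume_series()]).
#' @export
trial_volume_series <- function(trial) {
  stopifnot(inherits(trial, "movement_trial"))
  n_seg <- trial$n_rows - 1L
  series <- do.call(rbind, lapply(seq_along(trial$times), function(s) {
    secs <- trial_sample_sections(trial, s)
    vols <- vapply(seq_len(n_seg), function(i) {
      A1 <- pi * prod(secs[[i]]$semi_axes)
      A2 <- pi * prod(secs[[i + 1]]$semi_axes)
      h <- segment_length(secs[[i]]$center, secs[[i + 1]]$center)
      h / 3 * (A1 + A2 + sqrt(A1 * A2))
    }, numeric(1))
    row <- data.frame(time = trial$times[s], total = sum(vols))
    for (i in seq_len(n_seg)) row[[paste0("seg_", i)]] <- vols[i]
    row
  }))
  v_ref <- series$total[1]
  structure(list(series = series, reference = v_ref,
                 mae_percent = mean(abs(series$total - v_ref)) / v_ref *
                   100),
            class = "volume_series")
}
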
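#' Construct a cross-section ellipse
#'
#' One trunk cross-section is fully described by eight parameters: its 3D
#' center, its orientation as intrinsic ZYX Euler angles, and its two
#' semi-axis lengths. The local frame convention used throughout the package
#' is: local x = ellipse-plane normal (backbone tangent), local y = lateral
#' in-plane axis (semi-axis `a`), local z = dorsal in-plane axis
#' (semi-axis `b`).
#'
#' @param center numeric 3-vector, meters.
#' @param euler_zyx numeric 3-vector `(ez, ey, ex)`, radians.
#' @param semi_axes numeric `(a, b)`, meters, `a >= b > 0`.
#' @param row_index integer section row 1..10.
#' @param timestamp seconds.
#' @return An object of class `ellipse_section`.
#' @export
ellipse_section <- function(center, euler_zyx, semi_axes,
                            row_index = 1L, timestamp = 0) {
  stopifnot(length(center) == 3, all(is.finite(center)),
            length(euler_zyx) == 3, all(is.finite(euler_zyx)),
            length(semi_axes) == 2)
  if (any(semi_axes <= 0)) stop("semi-axes must be strictly positive")
  R <- euler_zyx_to_matrix(euler_zyx)
  if (max(abs(crossprod(R) - diag(3))) > 1e-10) {
    stop("orientation matrix is not orthonormal")
  }
  structure(list(
    row_index = as.integer(row_index),
    center = as.numeric(center),
    euler_zyx = as.numeric(euler_zyx),
    semi_axes = as.numeric(semi_axes),
    timestamp = as.numeric(timestamp),
    rotation = R
  ), class = "ellipse_section")
}

#' Construct a movement trial from a long section table
#'
#' @param sections data.frame with columns `time, row_index, cx, cy, cz, ez,
#'   ey, ex, semi_a, semi_b`, one line per section per sample. Every sample
#'   must contain the same `n_rows` rows in fixed order and timestamps must
#'   be strictly increasing and uniformly spaced (to 1e-6 s).
#' @param sample_rate Hz; inferred from the timestamps when `NULL`.
#' @param label optional movement class tag.
#' @return Object of class `movement_trial` with fields `sections`
#'   (the table), `times`, `n_rows`, `sample_rate`, `duration`, `label`.
#' @export
movement_trial <- function(sections, sample_rate = NULL, label = NULL) {
  need <- c("time", "row_index", "cx", "cy", "cz", "ez", "ey", "ex",
            "semi_a", "semi_b")
  missing_cols <- setdiff(need, names(sections))
  if (length(missing_cols) > 0) {
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sections[need] <- lapply(sections[need], as.numeric)
  times <- sort(unique(sections$time))
  n_rows <- length(unique(sections$row_index))
  sections <- sections[order(sections$time, sections$row_index), need]
  if (nrow(sections) != length(times) * n_rows) {
    stop("every sample must contain the same ", n_rows, " section rows")
  }
  if (!all(sections$row_index == rep(seq_len(n_rows), length(times)))) {
    stop("row_index must run 1..", n_rows, " within every sample")
  }
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || max(dt) - min(dt) > 1e-6) {
      stop("timestamps must be strictly increasing and uniform")
    }
    if (is.null(sample_rate)) sample_rate <- 1 / mean(dt)
  }
  if (is.null(sample_rate)) sample_rate <- NA_real_
  structure(list(
    sections = sections,
    times = times,
    n_rows = as.integer(n_rows),
    sample_rate = sample_rate,
    duration = if (length(times) > 1) diff(range(times)) else 0,
    label = label
  ), class = "movement_trial")
}

# one sample of a trial as a list of ellipse_section objects
trial_sample_sections <- function(trial, sample_index) {
  tt <- trial$times[sample_index]
  rows <- trial$sections[trial$sections$time == tt, ]
  lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    ellipse_section(center = c(r$cx, r$cy, r$cz),
                    euler_zyx = c(r$ez, r$ey, r$ex),
                    semi_axes = c(r$semi_a, r$semi_b),
                    row_index = r$row_index, timestamp = tt)
  })
}

#' Distance between two consecutive section centers
#'
#' The length of a segment is the Euclidean distance between the centers of
#' its two bounding cross-section ellipses.
#'
#' @param center_i,center_ip1 numeric 3-vectors, meters.
#' @return Length in meters.
#' @export
segment_length <- function(center_i, center_ip1) {
  stopifnot(all(is.finite(center_i)), all(is.finite(center_ip1)),
            length(center_i) == 3, length(center_ip1) == 3)
  sqrt(sum((center_ip1 - center_i)^2))
}

#' Relative bend angles between two consecutive sections
#'
#' Computes the relative rotation `R_rel = t(R_i) %*% R_ip1` between the two
#' section frames and projects its axis-angle (rotation) vector onto section
#' i's in-plane axes: `alpha` is the component about the dorsal ("normal")
#' axis, `beta` the component about the lateral ("binormal") axis. The
#' component about the tangent (torsion) is discarded; non-planar twisting
#' movements are out of scope.
#'
#' @param sec_i,sec_ip1 `ellipse_section` objects.
#' @return Named numeric `(alpha, beta)` in degrees.
#' @export
relative_bend_angles <- function(sec_i, sec_ip1) {
  stopifnot(inherits(sec_i, "ellipse_section"),
            inherits(sec_ip1, "ellipse_section"))
  R_rel <- crossprod(sec_i$rotation, sec_ip1$rotation)
  rv <- rotation_vector(R_rel)  # already expressed in section-i local axes
  c(alpha = rv[3] * 180 / pi,   # about local z (dorsal / "normal") axis
    beta = rv[2] * 180 / pi)    # about local y (lateral / "binormal") axis
}

#' Segment curvature from bend angles and length
#'
#' `K_alpha = alpha / L`, `K_beta = beta / L`, and the curvature magnitude is
#' the Euclidean norm of the two components. Angles in degrees, length in
#' meters, curvature in deg/m (the unit in which the classification
#' threshold of 20 deg/m is expressed).
#'
#' @param alpha,beta degrees.
#' @param L segment length, meters, `> 0`.
#' @return Named list `K, K_alpha, K_beta, alpha, beta, L`.
#' @export
segment_curvature <- function(alpha, beta, L) {
  if (!is.finite(L) || L <= 0) stop("invalid segment: length must be > 0")
  K_alpha <- alpha / L
  K_beta <- beta / L
  list(K = sqrt(K_alpha^2 + K_beta^2), K_alpha = K_alpha, K_beta = K_beta,
       alpha = alpha, beta = beta, L = L)
}

#' Per-segment shape time series of a trial
#'
#' For each time sample and each of the `n_rows - 1` segments, computes the
#' segment length (center-to-center distance) and the curvature components
#' from the relative rotation of consecutive section frames.
#'
#' @param trial a `movement_trial`.
#' @return data.frame with columns `time, segment, K, K_alpha, K_beta,
#'   alpha, beta, L`.
#' @export
shape_timeseries <- function(trial) {
  stopifnot(inherits(trial, "movement_trial"))
  n_seg <- trial$n_rows - 1L
  out <- vector("list", length(trial$times))
  for (s in seq_along(trial$times)) {
    secs <- trial_sample_sections(trial, s)
    rows <- lapply(seq_len(n_seg), function(i) {
      L <- segment_length(secs[[i]]$center, secs[[i + 1]]$center)
      ab <- relative_bend_angles(secs[[i]], secs[[i + 1]])
      sc <- segment_curvature(ab[["alpha"]], ab[["beta"]], L)
      data.frame(time = trial$times[s], segment = i, K = sc$K,
                 K_alpha = sc$K_alpha, K_beta = sc$K_beta,
                 alpha = sc$alpha, beta = sc$beta, L = sc$L)
    })
    out[[s]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Classify a movement as bending, bending+elongation, or other
#'
#' Let `Kmax` be the maximum curvature over segments and time and `dLmax`
#' the maximum increase of any segment's length over its value at the first
#' sample (the resting configuration). The movement is `B` when
#' `Kmax > k_thresh_bend` and `dLmax <= l_thresh_elong`, `BE` when both
#' thresholds are exceeded, and `OTHER` otherwise. Default thresholds are
#' 20 deg/m and 0.02 m (10% of a resting segment length).
#'
#' @param shapes data.frame from [shape_timeseries()].
#' @param k_thresh_bend deg/m.
#' @param l_thresh_elong meters.
#' @return One of `"B"`, `"BE"`, `"OTHER"`.
#' @export
classify_movement <- function(shapes, k_thresh_bend = 20,
                              l_thresh_elong = 0.02) {
  if (is.null(shapes) || nrow(shapes) == 0) stop("empty shape series")
  stopifnot(k_thresh_bend > 0, l_thresh_elong > 0)
  k_max <- max(shapes$K)
  t0 <- min(shapes$time)
  l0 <- shapes$L[shapes$time == t0]
  names(l0) <- shapes$segment[shapes$time == t0]
  dl_max <- max(shapes$L - l0[as.character(shapes$segment)])
  if (k_max > k_thresh_bend) {
    if (dl_max > l_thresh_elong) "BE" else "B"
  } else {
    "OTHER"
  }
}

#' Reconstruct cross-section ellipses from simulated node positions
#'
#' The inverse of the node layout used by [build_structure()]: for each
#' section the center is node O, the lateral semi-axis the mean distance to
#' nodes B and A, the dorsal semi-axis the mean distance to nodes P and Q,
#' and the frame is orthonormalized from the dorsal and lateral directions.
#' Used to measure the shape the dynamic model actually achieved.
#'
#' @param positions numeric `n_nodes x 3` matrix of current node positions.
#' @param structure a `trunk_structure`.
#' @param timestamp seconds.
#' @return List of `ellipse_section`, one per section.
#' @export
sections_from_nodes <- function(positions, structure, timestamp = 0) {
  lapply(seq_len(structure$n_sections), function(i) {
    idx <- function(role) {
      structure$nodes$node_id[structure$nodes$section == i &
                                structure$nodes$role == role] + 1L
    }
    O <- positions[idx("O"), ]
    P <- positions[idx("P"), ]
    B <- positions[idx("B"), ]
    Q <- positions[idx("Q"), ]
    A <- positions[idx("A"), ]
    dorsal <- P - Q
    lateral <- B - A
    tang <- c(lateral[2] * dorsal[3] - lateral[3] * dorsal[2],
              lateral[3] * dorsal[1] - lateral[1] * dorsal[3],
              lateral[1] * dorsal[2] - lateral[2] * dorsal[1])
    ex1 <- tang / sqrt(sum(tang^2))
    ez1 <- dorsal - sum(dorsal * ex1) * ex1
    ez1 <- ez1 / sqrt(sum(ez1^2))
    ey1 <- c(ez1[2] * ex1[3] - ez1[3] * ex1[2],
             ez1[3] * ex1[1] - ez1[1] * ex1[3],
             ez1[1] * ex1[2] - ez1[2] * ex1[1])
    R <- cbind(ex1, ey1, ez1)
    a <- (sqrt(sum((B - O)^2)) + sqrt(sum((A - O)^2))) / 2
    b <- (sqrt(sum((P - O)^2)) + sqrt(sum((Q - O)^2))) / 2
    ellipse_section(center = O, euler_zyx = matrix_to_euler_zyx(R),
                    semi_axes = c(a, b), row_index = i,
                    timestamp = timestamp)
  })
}

#' Shape series measured from a simulated node trajectory
#'
#' @param trajectory a `node_trajectory` (see [integrate_dynamics()]).
#' @param structure the `trunk_structure` that produced it.
#' @return data.frame as from [shape_timeseries()].
#' @export
shapes_from_trajectory <- function(trajectory, structure) {
  out <- vector("list", length(trajectory$times))
  for (s in seq_along(trajectory$times)) {
    secs <- sections_from_nodes(trajectory$positions[s, , ], structure,
                                trajectory$times[s])
    n_seg <- structure$n_sections - 1L
    rows <- lapply(seq_len(n_seg), function(i) {
      L <- segment_length(secs[[i]]$center, secs[[i + 1]]$center)
      ab <- relative_bend_angles(secs[[i]], secs[[i + 1]])
      sc <- segment_curvature(ab[["alpha"]], ab[["beta"]], L)
      data.frame(time = trajectory$times[s], segment = i, K = sc$K,
                 K_alpha = sc$K_alpha, K_beta = sc$K_beta,
                 alpha = sc$alpha, beta = sc$beta, L = sc$L)
    })
    out[[s]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}
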
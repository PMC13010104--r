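#' Fit a cross-section ellipse to 3D marker points
#'
#' Two-stage fit, as used for mocap marker rows: (1) total-least-squares
#' plane through the points (SVD of the centered coordinates); (2) direct
#' algebraic ellipse fit (Halir-Flusser stabilized Fitzgibbon fit, which is
#' ellipse-specific) on the in-plane 2D coordinates. Markers are typically
#' dorsal-only; any arc of at least 5 points is accepted, but a condition
#' warning is emitted when the angular arc coverage around the fitted center
#' is below 120 degrees, since narrow arcs make the fit ill-conditioned.
#'
#' @param points numeric `n x 3` matrix (or list of 3-vectors), `n >= 5`,
#'   meters.
#' @param row_index section row, used in error messages.
#' @param timestamp seconds.
#' @return An `ellipse_section` with attributes `residual_rms` (RMS distance
#'   of the points to the fitted ellipse, m) and `arc_coverage_deg`.
#' @export
fit_section_ellipse <- function(points, row_index = 1L, timestamp = 0) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, points)
  }
  points <- as.matrix(points)
  if (nrow(points) < 5) {
    stop("row ", row_index, ": at least 5 points are required to fit an ",
         "ellipse (got ", nrow(points), ")")
  }
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    stop("row ", row_index, ": points are collinear; cannot fit an ellipse")
  }
  v1 <- sv$v[, 1]; v2 <- sv$v[, 2]; nrm <- sv$v[, 3]
  u <- X %*% v1
  v <- X %*% v2

  cf <- fit_conic_ellipse(u, v)
  if (is.null(cf)) {
    stop("row ", row_index, ": degenerate point configuration, ellipse fit ",
         "failed")
  }

  # 3D center and frame: local x = plane normal (tangent), local y = major
  # in-plane axis, local z completes a right-handed frame.
  center <- ctr + cf$center[1] * v1 + cf$center[2] * v2
  major3 <- cos(cf$angle) * v1 + sin(cf$angle) * v2
  # deterministic sign convention
  if (nrm[which.max(abs(nrm))] < 0) nrm <- -nrm
  if (major3[which.max(abs(major3))] < 0) major3 <- -major3
  ez3 <- c(nrm[2] * major3[3] - nrm[3] * major3[2],
           nrm[3] * major3[1] - nrm[1] * major3[3],
           nrm[1] * major3[2] - nrm[2] * major3[1])
  R <- cbind(nrm, major3, ez3)

  sec <- ellipse_section(center = center,
                         euler_zyx = matrix_to_euler_zyx(R),
                         semi_axes = c(cf$a, cf$b),
                         row_index = row_index, timestamp = timestamp)

  # residual: in-plane distance to the ellipse plus out-of-plane offset
  du <- u - cf$center[1]
  dv <- v - cf$center[2]
  ca <- cos(cf$angle); sa <- sin(cf$angle)
  xe <- ca * du + sa * dv
  ye <- -sa * du + ca * dv
  d_in <- vapply(seq_along(xe), function(i) {
    point_ellipse_distance(xe[i], ye[i], cf$a, cf$b)
  }, numeric(1))
  d_out <- X %*% nrm
  residual <- sqrt(mean(d_in^2 + d_out^2))

  ang <- sort(atan2(ye, xe)) * 180 / pi
  gaps <- diff(c(ang, ang[1] + 360))
  coverage <- 360 - max(gaps)
  if (coverage < 120) {
    warning("row ", row_index, ": marker arc covers only ",
            round(coverage, 1), " deg (< 120 deg); ellipse fit is ",
            "ill-conditioned", call. = FALSE)
  }
  attr(sec, "residual_rms") <- residual
  attr(sec, "arc_coverage_deg") <- coverage
  sec
}

# Halir-Flusser direct least-squares ellipse fit on 2D points.
# Returns list(center = c(x0, y0), a, b, angle) with a >= b, or NULL.
fit_conic_ellipse <- function(u, v) {
  D1 <- cbind(u^2, u * v, v^2)
  D2 <- cbind(u, v, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T_ <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T_)) return(NULL)
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) return(NULL)
  a1 <- evec[, ok[1]]
  coefs <- c(a1, T_ %*% a1)  # A B C D E F
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F <- coefs[6]
  den <- 4 * A * C - B^2
  if (den <= 0) return(NULL)
  x0 <- (B * E - 2 * C * D) / den
  y0 <- (B * D - 2 * A * E) / den
  F0 <- F + (D * x0 + E * y0) / 2
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)
  lam <- eq$values
  axes_sq <- -F0 / lam  # the conic's overall sign is arbitrary
  if (any(axes_sq <= 0)) return(NULL)
  a <- sqrt(max(axes_sq)); b <- sqrt(min(axes_sq))
  major_vec <- eq$vectors[, which.max(axes_sq)]
  angle <- atan2(major_vec[2], major_vec[1])
  list(center = c(x0, y0), a = a, b = b, angle = angle)
}

# Distance from a 2D point (in the ellipse's principal frame) to the
# ellipse x^2/a^2 + y^2/b^2 = 1, by 1D minimization over the parameter.
point_ellipse_distance <- function(x, y, a, b) {
  f <- function(t) (a * cos(t) - x)^2 + (b * sin(t) - y)^2
  t0 <- atan2(y / b, x / a)
  opt <- stats::optimize(f, interval = c(t0 - pi / 2, t0 + pi / 2))
  sqrt(opt$objective)
}
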
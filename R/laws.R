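#' Ordinary least-squares multilinear fit
#'
#' Fits `Y = beta0 + beta1 X1 + beta2 X2 + beta3 X3 + eps` (up to three
#' predictors) and reports R-squared, adjusted R-squared (standard
#' `(n-1)/(n-p-1)` correction) and the RMSE of the residuals.
#'
#' @param y response vector.
#' @param X matrix or data.frame of predictors (1 to 3 columns).
#' @return A `law_coefficients` list: `beta` (named, intercept first),
#'   `r2`, `r2_adj`, `rmse`, `residual_sd`, `n_samples`.
#' @export
fit_multilinear <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(p >= 1, p <= 3, nrow(X) == n)
  if (n <= p + 1) stop("need more samples than predictors + 1")
  D <- cbind(1, X)
  qrD <- qr(D, tol = 1e-10)
  if (qrD$rank < ncol(D)) {
    # name the offending predictors for the error message
    bad <- character()
    for (j in seq_len(p)) {
      if (sd(X[, j]) == 0) bad <- c(bad, colnames(X)[j] %||% paste0("X", j))
    }
    stop("singular design matrix",
         if (length(bad)) paste0(" (degenerate predictor: ",
                                 paste(bad, collapse = ", "), ")") else
           " (collinear predictors)")
  }
  beta <- qr.coef(qrD, y)
  res <- y - as.vector(D %*% beta)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  r2_adj <- if (!is.na(r2)) 1 - (1 - r2) * (n - 1) / (n - p - 1) else
    NA_real_
  names(beta) <- c("beta0", paste0("beta", seq_len(p)))
  structure(list(beta = beta, r2 = r2, r2_adj = r2_adj,
                 rmse = sqrt(mean(res^2)),
                 residual_sd = sd(res), n_samples = n),
            class = "law_coefficients")
}

#' Fit the per-segment stereotypical laws
#'
#' For every segment fits three laws on aligned time series:
#' the K-law `K = b0 + b1 dFL + b2 FR + b3 FmL`, the L-law
#' `L = b0 + b1 dFL + b2 FR + b3 FmL`, and the F-law
#' `FR = b0 + b1 dFL + b3 FmL` (two predictors; the coefficient of `FmL`
#' is conventionally labelled `beta3`). Units: K in deg/m, L in m, forces
#' in N. Laws are normally fitted per movement class (B and BE separately);
#' pass pre-filtered data and tag it via `movement_class`.
#'
#' @param shapes data.frame with columns `time, segment, K, L` (e.g. from
#'   [shape_timeseries()]), possibly pooled over several trials.
#' @param forces data.frame with columns `time, segment, dFL, FR, FmL`
#'   (e.g. from [segment_force_summary()]), row-aligned with `shapes` per
#'   segment.
#' @param movement_class optional class tag stored as provenance.
#' @return A `law_set`: per-segment list of `K_law`, `L_law`, `F_law`
#'   `law_coefficients`, plus `n_segments` and `movement_class`.
#' @export
fit_segment_laws <- function(shapes, forces, movement_class = NULL) {
  segs <- sort(unique(shapes$segment))
  laws <- lapply(segs, function(i) {
    sh <- shapes[shapes$segment == i, ]
    fo <- forces[forces$segment == i, ]
    if (nrow(sh) != nrow(fo)) {
      stop("segment ", i, ": shape and force series are not aligned")
    }
    X3 <- cbind(dFL = fo$dFL, FR = fo$FR, FmL = fo$FmL)
    list(K_law = fit_multilinear(sh$K, X3),
         L_law = fit_multilinear(sh$L, X3),
         F_law = fit_multilinear(fo$FR, cbind(dFL = fo$dFL, FmL = fo$FmL)))
  })
  names(laws) <- paste0("segment_", segs)
  structure(list(laws = laws, segments = segs, n_segments = length(segs),
                 movement_class = movement_class), class = "law_set")
}

#' Pairwise Pearson correlations among the five key variables
#'
#' @param variables data.frame or matrix with columns among
#'   `K, L, FR, dFL, FmL` (equal-length series).
#' @return Symmetric correlation matrix with unit diagonal; rows/columns of
#'   zero-variance variables are `NA` and flagged via the
#'   `undefined` attribute.
#' @export
pairwise_correlations <- function(variables) {
  V <- as.matrix(variables)
  sds <- apply(V, 2, sd)
  C <- suppressWarnings(cor(V))
  undefined <- colnames(V)[sds == 0]
  C[sds == 0, ] <- NA_real_
  C[, sds == 0] <- NA_real_
  diag(C) <- ifelse(sds == 0, NA_real_, 1)
  attr(C, "undefined") <- undefined
  C
}

#' Compute internal forces from a desired segment shape
#'
#' Inverts the determined 3x3 linear system formed by the K-law, the L-law
#' and the F-law (rearranged as `FR - b1F dFL - b3F FmL = b0F`) for the
#' three unknown forces `(dFL, FR, FmL)` of one segment. Substituting the
#' solution back into the laws reproduces `(K, L, FR)` exactly.
#'
#' @param K desired curvature, deg/m.
#' @param L desired length, m.
#' @param laws a `law_set`.
#' @param segment segment index.
#' @return Named numeric `(dFL, FR, FmL)`, N.
#' @export
solve_forces_from_shape <- function(K, L, laws, segment) {
  key <- paste0("segment_", segment)
  lw <- laws$laws[[key]]
  if (is.null(lw)) stop("law set has no laws for segment ", segment)
  bK <- lw$K_law$beta
  bL <- lw$L_law$beta
  bF <- lw$F_law$beta
  A <- rbind(c(bK[2], bK[3], bK[4]),
             c(bL[2], bL[3], bL[4]),
             c(-bF[2], 1, -bF[3]))
  rhs <- c(K - bK[1], L - bL[1], bF[1])
  cn <- tryCatch(kappa(A, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cn) || cn > 1e12) {
    stop("segment ", segment, ": stereotypical-law system is singular or ",
         "ill-conditioned (condition number ", format(cn, digits = 3), ")")
  }
  sol <- solve(A, rhs)
  c(dFL = unname(sol[1]), FR = unname(sol[2]), FmL = unname(sol[3]))
}

#' Evaluate the fitted laws at given forces
#'
#' Forward application of the K- and L-laws of one segment; convenience
#' inverse of [solve_forces_from_shape()].
#'
#' @param forces named numeric `(dFL, FR, FmL)`.
#' @param laws a `law_set`.
#' @param segment segment index.
#' @return Named numeric `(K, L, FR_pred)`.
#' @export
evaluate_laws <- function(forces, laws, segment) {
  lw <- laws$laws[[paste0("segment_", segment)]]
  if (is.null(lw)) stop("law set has no laws for segment ", segment)
  x <- c(forces[["dFL"]], forces[["FR"]], forces[["FmL"]])
  bK <- lw$K_law$beta; bL <- lw$L_law$beta; bF <- lw$F_law$beta
  c(K = unname(bK[1] + sum(bK[2:4] * x)),
    L = unname(bL[1] + sum(bL[2:4] * x)),
    FR_pred = unname(bF[1] + bF[2] * x[1] + bF[3] * x[3]))
}
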
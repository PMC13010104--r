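test_that("multilinear fit recovers noiseless coefficients exactly", {
  set.seed(31)
  X <- matrix(runif(150), 50, 3)
  y <- 1 + 2 * X[, 1] - 3 * X[, 2] + 0.5 * X[, 3]
  law <- fit_multilinear(y, X)
  expect_equal(unname(law$beta), c(1, 2, -3, 0.5), tolerance = 1e-9)
  expect_equal(law$r2, 1, tolerance = 1e-12)
  expect_equal(law$rmse, 0, tolerance = 1e-9)
})

test_that("fit under Gaussian noise lands within standard errors", {
  set.seed(32)
  n <- 500
  X <- matrix(runif(3 * n), n, 3)
  beta_true <- c(1, 2, -3, 0.5)
  y <- cbind(1, X) %*% beta_true + rnorm(n, sd = 0.1)
  law <- fit_multilinear(as.vector(y), X)
  fit_ref <- lm(y ~ X)
  se <- summary(fit_ref)$coefficients[, "Std. Error"]
  expect_true(all(abs(law$beta - beta_true) < 3 * se))
  # against the stats::lm oracle (same numbers, different route)
  expect_equal(unname(law$beta), unname(coef(fit_ref)), tolerance = 1e-10)
  expect_equal(law$r2, summary(fit_ref)$r.squared, tolerance = 1e-10)
  expect_equal(law$r2_adj, summary(fit_ref)$adj.r.squared,
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected with a useful message", {
  X <- cbind(a = rep(1.5, 30), b = runif(30))
  expect_error(fit_multilinear(rnorm(30), X), "a")
  expect_error(fit_multilinear(rnorm(3), matrix(rnorm(9), 3, 3)),
               "samples")
})

test_that("OLS matches a normal-equations oracle on random designs", {
  set.seed(33)
  for (i in 1:10) {
    n <- 60
    X <- matrix(rnorm(3 * n), n, 3)
    y <- rnorm(n)
    law <- fit_multilinear(y, X)
    D <- cbind(1, X)
    beta_ne <- solve(crossprod(D), crossprod(D, y))
    expect_equal(unname(law$beta), as.vector(beta_ne), tolerance = 1e-8)
  }
})

test_that("rescaling a predictor rescales its beta and nothing else", {
  set.seed(34)
  X <- matrix(rnorm(180), 60, 3)
  y <- 2 + X %*% c(1, -2, 3) + rnorm(60, sd = 0.2)
  a <- fit_multilinear(as.vector(y), X)
  Xs <- X; Xs[, 2] <- X[, 2] * 10
  b <- fit_multilinear(as.vector(y), Xs)
  expect_equal(b$beta[["beta2"]], a$beta[["beta2"]] / 10,
               tolerance = 1e-10)
  expect_equal(b$r2, a$r2, tolerance = 1e-12)
  expect_equal(b$rmse, a$rmse, tolerance = 1e-12)
})

# planted per-segment laws: build force series, generate shapes from the
# laws, and check fitting + inversion round trips
planted_lawset <- function(n_seg = 3, n = 400, noise = 0, seed = 41) {
  set.seed(seed)
  shapes <- NULL; forces <- NULL; truth <- list()
  for (i in seq_len(n_seg)) {
    bK <- c(5, 0.8, -0.4, 0.3) * i
    bL <- c(0.2, 1e-3, 2e-3, -1e-3)
    bF <- c(2, -0.5, -0.8) * i   # FR = b0 + b1 dFL + b3 FmL
    dFL <- rnorm(n, sd = 8)
    FmL <- rnorm(n, sd = 10)
    FR <- bF[1] + bF[2] * dFL + bF[3] * FmL + rnorm(n, sd = noise)
    K <- bK[1] + bK[2] * dFL + bK[3] * FR + bK[4] * FmL +
      rnorm(n, sd = noise)
    L <- bL[1] + bL[2] * dFL + bL[3] * FR + bL[4] * FmL +
      rnorm(n, sd = noise * 1e-3)
    tt <- seq_len(n)
    shapes <- rbind(shapes, data.frame(time = tt, segment = i, K = K,
                                       L = L))
    forces <- rbind(forces, data.frame(time = tt, segment = i, dFL = dFL,
                                       FR = FR, FmL = FmL))
    truth[[i]] <- list(bK = bK, bL = bL, bF = bF)
  }
  list(shapes = shapes, forces = forces, truth = truth)
}

test_that("segment law fitting recovers planted coefficients", {
  pl <- planted_lawset(noise = 0.01)
  laws <- fit_segment_laws(pl$shapes, pl$forces, movement_class = "B")
  for (i in 1:3) {
    lw <- laws$laws[[paste0("segment_", i)]]
    expect_true(all(abs(lw$K_law$beta - pl$truth[[i]]$bK) <
                      0.05 * pmax(abs(pl$truth[[i]]$bK), 0.2)))
    expect_true(all(abs(lw$F_law$beta - pl$truth[[i]]$bF) <
                      0.05 * pmax(abs(pl$truth[[i]]$bF), 0.2)))
    expect_gt(lw$K_law$r2, 0.99)
  }
  # determinism: duplicated data gives the identical law set
  laws2 <- fit_segment_laws(rbind(pl$shapes, pl$shapes),
                            rbind(pl$forces, pl$forces),
                            movement_class = "B")
  expect_equal(laws$laws$segment_1$K_law$beta,
               laws2$laws$segment_1$K_law$beta, tolerance = 1e-12)
})

test_that("force solving inverts the fitted laws exactly", {
  pl <- planted_lawset(noise = 1e-7)
  laws <- fit_segment_laws(pl$shapes, pl$forces)
  # round trip through the determined 3x3 system
  f <- solve_forces_from_shape(K = 9, L = 0.21, laws, segment = 2)
  back <- evaluate_laws(f, laws, segment = 2)
  expect_equal(unname(back["K"]), 9, tolerance = 1e-9)
  expect_equal(unname(back["L"]), 0.21, tolerance = 1e-9)
  expect_equal(unname(back["FR_pred"]), unname(f["FR"]), tolerance = 1e-9)
  # planted-system oracle: a sample from the system solves back to itself
  i <- 35
  fo <- pl$forces[pl$forces$segment == 1, ][i, ]
  sh <- pl$shapes[pl$shapes$segment == 1, ][i, ]
  got <- solve_forces_from_shape(sh$K, sh$L, laws, 1)
  expect_equal(unname(got), c(fo$dFL, fo$FR, fo$FmL), tolerance = 1e-6)
})

test_that("degenerate laws raise a singular-system error", {
  pl <- planted_lawset(noise = 1e-7)
  laws <- fit_segment_laws(pl$shapes, pl$forces)
  broken <- laws
  broken$laws$segment_1$K_law$beta[2:4] <- 0
  expect_error(solve_forces_from_shape(5, 0.2, broken, 1), "segment 1")
})

test_that("pairwise correlations form a proper matrix and flag constants", {
  set.seed(42)
  x <- rnorm(100)
  V <- data.frame(K = x, L = -2 * x, FR = rnorm(100), dFL = rnorm(100),
                  FmL = rnorm(100))
  C <- pairwise_correlations(V)
  expect_equal(diag(C), rep(1, 5), ignore_attr = TRUE)
  expect_equal(C, t(C))
  expect_equal(C["K", "L"], -1, tolerance = 1e-12)
  V$FmL <- 3
  C2 <- pairwise_correlations(V)
  expect_true(all(is.na(C2["FmL", ])))
  expect_equal(attr(C2, "undefined"), "FmL")
})
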
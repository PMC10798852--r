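test_that("analytic CCA solves the covariance eigenproblem", {
  # independent blocks: all rho = 0
  m0 <- gaussian_pair_model(c(0, 0), c(0, 0), sigma = c(1, 2, 3, 4),
                            c_x = 0.3, c_y = 0.2, c_xy = 0)
  r0 <- analytic_cca(assemble_covariance(m0))
  expect_equal(r0$rho, c(0, 0), tolerance = 1e-10)

  # duplicated block: rho1 = 1
  A <- matrix(c(2, 0.5, 0.5, 1), 2)
  S <- rbind(cbind(A, A), cbind(A, A)) + diag(1e-9, 4)
  r1 <- analytic_cca(cc1decode:::joint_cov(S, 2, 2))
  expect_equal(r1$rho[1], 1, tolerance = 1e-3)

  # independent oracle: singular values of Sxx^-1/2 Sxy Syy^-1/2
  p <- sample_model_parameters(100, seed = 71)
  for (i in seq_len(100)) {
    mod <- as_gaussian_pair_model(p[i, ])
    Tc <- unconditioned_covariance(mod)
    b <- cov_blocks(Tc)
    isq <- function(M) {
      e <- eigen((M + t(M)) / 2, symmetric = TRUE)
      e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
    }
    sv <- svd(isq(b$xx) %*% b$xy %*% isq(b$yy))$d
    r <- analytic_cca(Tc)
    expect_equal(r$rho, sv, tolerance = 1e-10)
    expect_true(all(diff(r$rho) <= 1e-12))
    expect_true(all(r$rho >= 0 & r$rho <= 1))
  }
})

test_that("with zero cross-population noise correlation CC1 equals the Fisher direction", {
  p <- sample_model_parameters(50, seed = 72)
  p$c_xy <- 0
  for (i in seq_len(50)) {
    mod <- as_gaussian_pair_model(p[i, ])
    cca <- analytic_cca(unconditioned_covariance(mod))
    for (reg in c("x", "y")) {
      v_cc <- cca[[paste0("directions_", reg)]][, 1]
      v_f <- fisher_direction(mod, reg)$weights
      # sine of the angle, computed stably as the orthogonal-residual norm
      sin_ang <- sqrt(sum((v_cc - sum(v_cc * v_f) * v_f)^2))
      expect_lt(sin_ang, 1e-8)
    }
  }
})

test_that("sample CCA agrees with the base-R reference and with the analytic limit", {
  set.seed(81)
  X <- matrix(rnorm(400 * 3), 400)
  Y <- matrix(rnorm(400 * 2), 400)
  Y[, 1] <- 0.7 * X[, 2] + 0.5 * rnorm(400)
  f <- sample_cca(X, Y)
  ref <- cancor(X, Y)
  expect_equal(f$rho, ref$cor, tolerance = 1e-10)
  # directions match up to scale/sign
  for (j in 1:2) {
    a <- f$directions_x[, j]
    b <- ref$xcoef[, j] / sqrt(sum(ref$xcoef[, j]^2))
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-8)
  }

  # y = x: all rho = 1
  fxx <- sample_cca(X, X)
  expect_equal(fxx$rho, rep(1, 3), tolerance = 1e-8)

  # projections onto paired components achieve rho_j on the fitting data
  expect_equal(canonical_r(X, Y, f, 1), f$rho[1], tolerance = 1e-12)
  expect_equal(canonical_r(X, Y, f, 2), f$rho[2], tolerance = 1e-12)

  # independent noise: small but positive finite-sample rho1, shrinking with T
  set.seed(82)
  r_small <- mean(replicate(20, sample_cca(matrix(rnorm(50 * 2), 50),
                                           matrix(rnorm(50 * 2), 50))$rho[1]))
  r_big <- mean(replicate(20, sample_cca(matrix(rnorm(1000 * 2), 1000),
                                         matrix(rnorm(1000 * 2), 1000))$rho[1]))
  expect_gt(r_small, r_big)
  expect_lt(r_big, 0.15)

  # large-sample convergence to the analytic CCA of the mixture covariance
  mod <- fixture_model(0.2)
  sp <- split_regions(draw_trials(mod, 1e5, seed = 83))
  fs <- sample_cca(sp$x, sp$y)
  fa <- analytic_cca(unconditioned_covariance(mod))
  expect_lt(abs(fs$rho[1] - fa$rho[1]), 0.01)
  ang <- acos(min(1, abs(sum(fs$directions_y[, 1] * fa$directions_y[, 1]))))
  expect_lt(ang * 180 / pi, 2)
})

test_that("canonical correlation is invariant to invertible affine transforms of one region", {
  set.seed(91)
  X <- matrix(rnorm(300 * 2), 300)
  Y <- matrix(rnorm(300 * 2), 300)
  Y[, 2] <- X[, 1] + 0.5 * rnorm(300)
  A <- matrix(c(2, 1, -1, 0.5), 2)
  Xt <- X %*% A + matrix(rep(c(5, -3), each = 300), 300)
  r1 <- sample_cca(X, Y)$rho
  r2 <- sample_cca(Xt, Y)$rho
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("rank-deficient input is ridge-stabilized with a warning, and sign convention holds", {
  set.seed(101)
  X <- matrix(rnorm(60 * 2), 60)
  Y <- cbind(rnorm(60), 3)          # constant neuron
  expect_warning(f <- sample_cca(X, Y), "rank")
  expect_true(all(is.finite(f$rho)))

  expect_warning(sample_cca(matrix(rnorm(8), 4), matrix(rnorm(8), 4)),
                 "trial count")

  f2 <- sample_cca(X, matrix(rnorm(120), 60))
  firsts <- apply(f2$directions_x, 2, function(v) v[which(abs(v) > 1e-12)[1]])
  expect_true(all(firsts > 0))
})
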
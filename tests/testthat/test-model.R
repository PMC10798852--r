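test_that("assembled covariance is Lambda C Lambda with the uniform-block structure", {
  # independence: diagonal of sigma^2
  m0 <- gaussian_pair_model(c(1, 2), c(0, 1), sigma = c(1, 2, 3, 4),
                            c_x = 0, c_y = 0, c_xy = 0)
  expect_equal(unclass(assemble_covariance(m0)), diag(c(1, 4, 9, 16)),
               ignore_attr = TRUE)

  # cross-block entries only
  m1 <- gaussian_pair_model(c(0, 0), c(0, 0), sigma = rep(1, 4),
                            c_x = 0, c_y = 0, c_xy = 0.5)
  S1 <- unclass(assemble_covariance(m1))
  expect_equal(S1[1:2, 3:4], matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_equal(S1[1, 2], 0)
  expect_equal(S1[3, 4], 0)

  # Lambda C Lambda arithmetic: entry (1,2) = sigma1 sigma2 c_x
  m2 <- gaussian_pair_model(c(0, 0), c(0, 0), sigma = c(1, 2, 1, 2),
                            c_x = 0.3, c_y = 0, c_xy = 0)
  expect_equal(unclass(assemble_covariance(m2))[1, 2], 1 * 2 * 0.3)

  # exact symmetry and elementwise identity sigma_i sigma_j C_ij
  m3 <- fixture_model(0.15)
  S3 <- unclass(assemble_covariance(m3))
  expect_identical(S3, t(S3))
  C <- matrix(0.15, 4, 4)
  C[1:2, 1:2] <- 0.3; C[3:4, 3:4] <- 0.4; diag(C) <- 1
  expect_equal(S3, outer(m3$sigma, m3$sigma) * C, ignore_attr = TRUE)

  expect_error(gaussian_pair_model(c(1), c(1), sigma = c(1, -1),
                                   c_x = 0, c_y = 0, c_xy = 0), "positive")
  expect_error(gaussian_pair_model(c(1), c(1), sigma = c(1, 1),
                                   c_x = 1, c_y = 0, c_xy = 0), "c_x")
})

test_that("positive-definiteness test matches the analytic boundary for unit-variance 2x2 models", {
  expect_true(check_positive_definite(diag(4)))
  expect_error(check_positive_definite(matrix(c(1, 2, 0, 1), 2)), "symmetric")

  make_S <- function(c_x, c_y, c_xy) {
    C <- matrix(c_xy, 4, 4)
    C[1:2, 1:2] <- c_x; C[3:4, 3:4] <- c_y; diag(C) <- 1
    C
  }
  # example points around the c_x = c_y = 0 boundary at 0.5
  expect_false(check_positive_definite(make_S(0, 0, 0.8)))
  expect_true(check_positive_definite(make_S(0, 0, 0.4)))

  # c_x = 1 exactly: eigenvalue 1 - c_x = 0
  expect_false(check_positive_definite(make_S(1, 0.2, 0)))

  # derived closed form c_xy < sqrt((1+c_x)(1+c_y))/2 on a grid
  grid <- seq(0.025, 0.975, length.out = 12)
  for (cx in grid) for (cy in grid) for (cxy in grid) {
    analytic <- cxy < sqrt((1 + cx) * (1 + cy)) / 2 - 1e-9
    spectral <- check_positive_definite(make_S(cx, cy, cxy))
    if (abs(cxy - sqrt((1 + cx) * (1 + cy)) / 2) > 1e-6) {
      expect_identical(spectral, analytic)
    }
  }
})

test_that("parameter sampler follows the survey distributions and the rejection contract", {
  n <- 20000L
  p <- sample_model_parameters(n, seed = 123)
  expect_identical(nrow(p), as.integer(n))

  # every accepted draw is positive definite
  sub <- p[seq_len(500), ]
  pd <- vapply(seq_len(500), function(i) {
    check_positive_definite(assemble_covariance(as_gaussian_pair_model(sub[i, ])))
  }, logical(1))
  expect_true(all(pd))

  # rejection involves only the correlation triple, so the mu / sigma
  # marginals are the stated laws exactly: KS at alpha = 0.001
  pfold2 <- function(q) 2 * pnorm(q, 0, 2) - 1     # |N(0,2)| cdf
  pfold1 <- function(q) 2 * pnorm(q, 0, 1) - 1     # |N(0,1)| cdf
  expect_gt(ks.test(p$mu_x1, pnorm)$p.value, 0.001)
  expect_gt(ks.test(p$mu_y1, pnorm)$p.value, 0.001)
  expect_gt(ks.test(p$mu_x2, pfold1)$p.value, 0.001)
  expect_gt(ks.test(p$sigma_x1, pfold2)$p.value, 0.001)
  expect_gt(ks.test(p$sigma_y2, pfold2)$p.value, 0.001)

  # folded-normal moment: E|N(0,1)| = sqrt(2/pi), within 3 SE
  se <- sd(p$mu_x2) / sqrt(n)
  expect_lt(abs(mean(p$mu_x2) - sqrt(2 / pi)), 3 * se)

  # correlation marginals live in [0, 1); exact zeros only for c_xy, with
  # mass near (slightly above, post-rejection) the 1% of the raw rule
  expect_true(all(p$c_x >= 0 & p$c_x < 1))
  expect_true(all(p$c_xy >= 0 & p$c_xy < 1))
  expect_identical(sum(p$c_x == 0), 0L)
  frac0 <- mean(p$c_xy == 0)
  expect_gt(frac0, 0.005)
  expect_lt(frac0, 0.03)

  # reproducible under a fixed seed
  expect_identical(p, sample_model_parameters(n, seed = 123))
})

test_that("unconditioned covariance is the two-stimulus mixture covariance", {
  # mu = 0: unchanged
  m0 <- gaussian_pair_model(c(0, 0), c(0, 0), sigma = c(1, 2, 3, 4),
                            c_x = 0.2, c_y = 0.1, c_xy = 0.05)
  expect_equal(unclass(unconditioned_covariance(m0)),
               unclass(assemble_covariance(m0)), ignore_attr = TRUE)

  # mixture-variance identity in the scalar-like case: 1 + 0.25 * mu^2
  m1 <- gaussian_pair_model(2, 0, sigma = c(1, 1), c_x = 0, c_y = 0, c_xy = 0)
  expect_equal(unclass(unconditioned_covariance(m1, 0.5))[1, 1], 1 + 0.25 * 4)

  expect_error(unconditioned_covariance(m1, prior_b = 1), "between 0 and 1")

  # Monte-Carlo oracle: sample covariance of pooled two-stimulus draws
  m <- fixture_model(0.25)
  tr <- draw_trials(m, 5e5, seed = 99)
  sp <- split_regions(tr)
  emp <- cov(cbind(sp$x, sp$y))
  expect_lt(norm(emp - unclass(unconditioned_covariance(m)), "F") /
              norm(unclass(unconditioned_covariance(m)), "F"), 0.01)
})

test_that("drawn trials have the model's means and covariance and are seed-reproducible", {
  m <- fixture_model(0.1)
  tr <- draw_trials(m, 5e4, seed = 42)
  expect_identical(tr, draw_trials(m, 5e4, seed = 42))
  sp <- split_regions(tr)
  mu <- c(m$mu_x, m$mu_y)
  S <- unclass(assemble_covariance(m))
  R <- cbind(sp$x, sp$y)
  for (j in 1:4) {
    se <- sqrt(S[j, j] / 5e4)
    expect_lt(abs(mean(R[sp$labels == "A", j]) - 0), 4 * se)
    expect_lt(abs(mean(R[sp$labels == "B", j]) - mu[j]), 4 * se)
  }
  SA <- cov(R[sp$labels == "A", ])
  SB <- cov(R[sp$labels == "B", ])
  pooled <- (SA + SB) / 2
  expect_lt(norm(pooled - S, "F") / norm(S, "F"), 0.02)
})

test_that("models round-trip through flat JSON records", {
  m <- fixture_model(0.3)
  m2 <- model_from_json(model_to_json(m))
  expect_equal(m2, m)
  f <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, f)
  expect_equal(model_from_json(f), m)
})
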
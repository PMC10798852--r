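test_that("Fisher direction is the optimal linear readout", {
  # isotropic covariance: matched filter, weights parallel to mu
  m <- gaussian_pair_model(c(3, 4), c(1, 0), sigma = rep(1, 4),
                           c_x = 0, c_y = 0, c_xy = 0)
  w <- fisher_direction(m, "x")$weights
  expect_equal(w, c(3, 4) / 5)

  # mu aligned with a covariance eigenvector stays parallel to mu
  m2 <- gaussian_pair_model(c(1, 1), c(1, 1), sigma = rep(1, 4),
                            c_x = 0.5, c_y = 0, c_xy = 0)
  w2 <- fisher_direction(m2, "x")$weights
  expect_equal(abs(sum(w2 * c(1, 1) / sqrt(2))), 1, tolerance = 1e-12)

  # optimality: no random direction beats it, for several random models
  p <- sample_model_parameters(10, seed = 21)
  set.seed(22)
  for (i in seq_len(10)) {
    mod <- as_gaussian_pair_model(p[i, ])
    best <- analytic_accuracy(mod, fisher_direction(mod, "y"))
    for (r in seq_len(100)) {
      v <- rnorm(2)
      expect_lte(analytic_accuracy(mod, v / sqrt(sum(v^2)), region = "y"),
                 best + 1e-12)
    }
  }
})

test_that("analytic accuracy is the Gaussian-integral value and is scale-invariant", {
  # scalar case sigma = 1, mu = 2: Phi(1)
  m1 <- gaussian_pair_model(2, 0, sigma = c(1, 1), c_x = 0, c_y = 0, c_xy = 0)
  expect_equal(analytic_accuracy(m1, 1, region = "x"), pnorm(1))

  # Monte-Carlo cross-check of the same value (midpoint-threshold classifier)
  set.seed(31)
  nmc <- 2e6
  a <- rnorm(nmc / 2, 0, 1); b <- rnorm(nmc / 2, 2, 1)
  acc_mc <- (mean(a < 1) + mean(b > 1)) / 2
  expect_lt(abs(acc_mc - pnorm(1)), 0.002)

  # orthogonal readout: chance
  m2 <- gaussian_pair_model(c(1, 0), c(0, 0), sigma = rep(1, 4),
                            c_x = 0, c_y = 0, c_xy = 0)
  expect_equal(analytic_accuracy(m2, c(0, 1), region = "x"), 0.5)

  # invariance under positive rescaling of the weights
  m3 <- fixture_model(0.2)
  expect_equal(analytic_accuracy(m3, c(0.3, -0.2), region = "y"),
               analytic_accuracy(m3, 17 * c(0.3, -0.2), region = "y"))

  # closed form Phi(sqrt(mu' Sigma^-1 mu) / 2) for the Fisher readout
  S <- cov_blocks(assemble_covariance(m3))$yy
  expect_equal(analytic_accuracy(m3, fisher_direction(m3, "y")),
               pnorm(sqrt(drop(crossprod(m3$mu_y, solve(S, m3$mu_y)))) / 2))
})

test_that("best-threshold accuracy matches an exhaustive classification oracle", {
  expect_equal(empirical_accuracy(c(1, 2, 10, 11), c("A", "A", "B", "B"))$accuracy, 1)
  expect_equal(empirical_accuracy(c(1, 2, 1, 2), c("A", "A", "B", "B"))$accuracy, 0.5)
  expect_error(empirical_accuracy(c(1, 2), c("A", "A")), "two classes")
  expect_error(empirical_accuracy(numeric(0), character(0)), "empty|length")

  set.seed(41)
  for (rep in seq_len(200)) {
    Tn <- sample(4:8, 1)
    v <- sample(1:5, Tn, replace = TRUE) + rnorm(Tn, 0, 0.01)
    lab <- c("A", "B", sample(c("A", "B"), Tn - 2, replace = TRUE))
    res <- empirical_accuracy(v, lab)
    expect_equal(res$accuracy, naive_best_threshold(v, lab))
    expect_gte(res$accuracy, 0.5)
    # the returned rule itself achieves the returned accuracy
    lv <- sort(unique(lab))
    pred_b <- if (res$orientation > 0) v > res$threshold else v < res$threshold
    expect_equal(mean((lab == lv[2]) == pred_b), res$accuracy)
  }

  # accuracies are multiples of 1 / (total trials), e.g. 30 trials -> k/30
  set.seed(42)
  v <- rnorm(30); lab <- rep(c("A", "B"), each = 15)
  acc <- empirical_accuracy(v, lab)$accuracy
  expect_equal(acc * 30, round(acc * 30))
})

test_that("brute-force 2D search finds the optimal projection line", {
  # separable along axis 1 only: winning angle within a grid step of 0
  set.seed(51)
  n <- 60
  resp <- cbind(c(rnorm(n, 0, 0.2), rnorm(n, 5, 0.2)), rnorm(2 * n, 0, 3))
  lab <- rep(c("A", "B"), each = n)
  res <- brute_force_optimal_2d(resp, lab)
  expect_equal(res$d_opt, 1)
  expect_true(min(res$angle, pi - res$angle) <= pi / 200 + 1e-12)

  # the single-neuron axes are in the search set
  ax1 <- empirical_accuracy(resp[, 1], lab)$accuracy
  ax2 <- empirical_accuracy(resp[, 2], lab)$accuracy
  expect_gte(res$d_opt, max(ax1, ax2))

  # Gaussian samples: winning direction within one grid step of Fisher
  # (plus finite-sample wobble of the empirical optimum)
  mod <- fixture_model(0)
  tr <- draw_trials(mod, 1e4, seed = 52)
  sp <- split_regions(tr)
  bf <- brute_force_optimal_2d(sp$y, sp$labels)
  wf <- fisher_direction(mod, "y")$weights
  ang <- acos(min(1, abs(sum(bf$readout$weights * wf))))
  expect_lt(ang, pi / 200 + 0.03)

  # refining the grid never lowers the accuracy
  idx <- c(1:40, 1e4 + (1:40))          # balanced subset of both stimuli
  res10x <- brute_force_optimal_2d(sp$y[idx, ], sp$labels[idx], n_angles = 2000L)
  res1x <- brute_force_optimal_2d(sp$y[idx, ], sp$labels[idx], n_angles = 200L)
  expect_gte(res10x$d_opt, res1x$d_opt)
  expect_lte(res10x$d_opt - res1x$d_opt, 1 / 80 + 1e-12)
})

test_that("n-dimensional optimal bound is consistent with its 2D special case", {
  set.seed(61)
  n <- 40
  resp <- cbind(rnorm(2 * n), rnorm(2 * n), c(rnorm(n, 0), rnorm(n, 2)))
  lab <- rep(c("A", "B"), each = n)

  # k = 2 reduces exactly to the brute-force search
  two <- resp[, 2:3]
  expect_equal(optimal_accuracy_nd(two, lab, method = "pair_lower_bound")$d_opt,
               brute_force_optimal_2d(two, lab)$d_opt)

  # superset property: a 3-neuron bound >= any 2-neuron bound
  full <- optimal_accuracy_nd(resp, lab)
  for (ij in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_gte(full$pair_lower_bound,
               brute_force_optimal_2d(resp[, ij], lab)$d_opt)
  }
  expect_gte(full$d_opt, full$pair_lower_bound)
  expect_true(full$is_bound)
})
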
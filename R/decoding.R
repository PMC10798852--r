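#' Linear readout of a neural population
#'
#' A unit projection vector over one region's neurons together with a scalar
#' decision threshold and an orientation flag (+1: stimulus B lies above the
#' threshold; -1: below). Decoding accuracy is invariant to positive
#' rescaling of the weights, so they are stored unit-norm.
#'
#' @param weights Numeric weight vector; normalized internally.
#' @param threshold Decision boundary on the projected axis.
#' @param orientation `+1` or `-1`.
#' @param region Optional region tag ("x", "y" or "joint").
#' @return Object of class `linear_readout`.
#' @export
linear_readout <- function(weights, threshold = NA_real_, orientation = 1L,
                           region = NULL) {
  w <- as.numeric(weights)
  nrm <- sqrt(sum(w^2))
  if (!is.finite(nrm) || nrm == 0) {
    stop("`weights` must be a nonzero finite vector", call. = FALSE)
  }
  structure(list(weights = w / nrm, threshold = threshold,
                 orientation = as.integer(sign(orientation)),
                 region = region),
            class = "linear_readout")
}

#' @export
print.linear_readout <- function(x, ...) {
  cat("<linear_readout>", if (!is.null(x$region)) paste0("region ", x$region),
      "\n  weights: ", paste(format(x$weights, digits = 3), collapse = ", "),
      "\n  threshold: ", format(x$threshold, digits = 4),
      "  orientation: ", x$orientation, "\n", sep = "")
  invisible(x)
}

#' Optimal (Fisher) linear decoding direction of a Gaussian model
#'
#' For two equal-covariance Gaussian classes the optimal linear decoder
#' projects onto `Sigma^-1 mu`; this computes that direction for one region
#' of a dual-population model (or for the joint population), normalized to
#' unit length.
#'
#' @param model A [gaussian_pair_model()].
#' @param region `"x"`, `"y"` or `"joint"`.
#' @return A [linear_readout()] with the midpoint threshold
#'   `w' mu / 2` attached.
#' @export
fisher_direction <- function(model, region = c("y", "x", "joint")) {
  region <- match.arg(region)
  S <- assemble_covariance(model)
  b <- cov_blocks(S)
  pars <- switch(region,
    x = list(S = b$xx, mu = model$mu_x),
    y = list(S = b$yy, mu = model$mu_y),
    joint = list(S = unclass(S), mu = c(model$mu_x, model$mu_y))
  )
  w <- tryCatch(solve(pars$S, pars$mu),
                error = function(e) stop("singular covariance block for region ",
                                         region, call. = FALSE))
  if (sqrt(sum(w^2)) == 0) {
    # mu = 0: no signal; any direction is (equally bad); pick e1
    w <- c(1, rep(0, length(pars$mu) - 1L))
  }
  w <- w / sqrt(sum(w^2))
  linear_readout(w, threshold = sum(w * pars$mu) / 2,
                 orientation = if (sum(w * pars$mu) >= 0) 1L else -1L,
                 region = region)
}

#' Analytic decoding accuracy of a linear readout
#'
#' For the equal-covariance, equal-prior two-Gaussian problem, projecting
#' onto `w` gives two 1D Gaussians separated by `w' mu` with common SD
#' `sqrt(w' Sigma w)`; the best (midpoint) threshold achieves accuracy
#' `Phi(|w' mu| / (2 sqrt(w' Sigma w)))`.
#'
#' @param model A [gaussian_pair_model()].
#' @param readout A [linear_readout()] over one region (or the joint space);
#'   a plain numeric vector is also accepted.
#' @param region Region of the readout; defaults to the readout's own tag.
#' @return Accuracy in `[0.5, 1]`.
#' @export
analytic_accuracy <- function(model, readout, region = NULL) {
  if (inherits(readout, "linear_readout")) {
    w <- readout$weights
    if (is.null(region)) region <- readout$region
  } else {
    w <- as.numeric(readout)
  }
  if (is.null(region)) {
    region <- c("x", "y", "joint")[match(length(w),
                                         c(model$m, model$n, model$m + model$n))]
    if (is.na(region)) stop("cannot infer region from weight length", call. = FALSE)
  }
  S <- assemble_covariance(model)
  b <- cov_blocks(S)
  pars <- switch(region,
    x = list(S = b$xx, mu = model$mu_x),
    y = list(S = b$yy, mu = model$mu_y),
    joint = list(S = unclass(S), mu = c(model$mu_x, model$mu_y))
  )
  v <- drop(crossprod(w, pars$S %*% w))
  if (v <= 0) stop("zero projected variance", call. = FALSE)
  stats::pnorm(abs(sum(w * pars$mu)) / (2 * sqrt(v)))
}

#' Best-threshold decoding accuracy of a 1D projected response
#'
#' Scans every achievable threshold (midpoints between consecutive distinct
#' sorted projected values, plus the two extremes) and both class
#' orientations, and returns the highest fraction of correctly classified
#' trials. The attained accuracy is always a multiple of 1 / (total trials)
#' and at least 0.5. Accuracy ties are broken toward the threshold with the
#' largest margin (half-gap to the nearest projected point).
#'
#' @param projected Numeric vector of projected responses.
#' @param labels Vector with exactly two distinct values; the second sorted
#'   unique value plays the role of "stimulus B".
#' @return A list with `accuracy`, `threshold` and `orientation` (+1 if B is
#'   classified above the threshold).
#' @export
empirical_accuracy <- function(projected, labels) {
  projected <- as.numeric(projected)
  if (length(projected) == 0L) stop("empty input", call. = FALSE)
  if (length(projected) != length(labels)) {
    stop("`projected` and `labels` must have equal length", call. = FALSE)
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) {
    stop("`labels` must contain exactly two classes", call. = FALSE)
  }
  Tn <- length(projected)
  ord <- order(projected)
  v <- projected[ord]
  isB <- as.character(labels)[ord] == lv[2L]
  nB <- sum(isB)
  nA <- Tn - nB
  if (nA < 1L || nB < 1L) stop("both classes must be present", call. = FALSE)

  # cut after position i (i = 0..Tn): left of threshold = first i points
  cumB <- c(0L, cumsum(isB))
  cumA <- seq(0L, Tn) - cumB
  # orientation +1: A below, B above; orientation -1: the reverse
  correct_up <- cumA + (nB - cumB)
  correct_dn <- cumB + (nA - cumA)
  # only cuts between distinct values (or at the extremes) are realizable
  realizable <- c(TRUE, v[-1L] != v[-Tn], TRUE)
  gap <- c(2, v[-1L] - v[-Tn], 2)      # sentinel gap for the extreme cuts
  best <- pmax(correct_up, correct_dn)
  best[!realizable] <- -1L
  top <- max(best)
  cand <- which(best == top)
  cut <- cand[which.max(gap[cand])] - 1L   # margin tie-break
  thr <- if (cut == 0L) v[1L] - 1 else if (cut == Tn) v[Tn] + 1
         else (v[cut] + v[cut + 1L]) / 2
  orient <- if (correct_up[cut + 1L] >= correct_dn[cut + 1L]) 1L else -1L
  list(accuracy = top / Tn, threshold = thr, orientation = orient)
}

#' Brute-force optimal 2D linear decoding
#'
#' Projects two-neuron responses onto each of `n_angles` lines with angles
#' theta in `{0, pi/n, ..., pi - pi/n}` and returns the projection with the
#' highest best-threshold accuracy (ties broken toward the smallest angle).
#'
#' @param responses Trials x 2 numeric matrix.
#' @param labels Two-class label vector.
#' @param n_angles Angular grid resolution; default 200 (steps of pi/200).
#' @return List with `readout` (a [linear_readout()]), `d_opt` and the
#'   winning `angle`.
#' @export
brute_force_optimal_2d <- function(responses, labels, n_angles = 200L) {
  responses <- as.matrix(responses)
  if (ncol(responses) != 2L) stop("`responses` must have exactly 2 columns", call. = FALSE)
  if (nrow(unique(responses)) < 2L) {
    stop("need at least 2 distinct response points", call. = FALSE)
  }
  thetas <- (seq_len(n_angles) - 1L) * pi / n_angles
  best <- NULL
  for (th in thetas) {
    w <- c(cos(th), sin(th))
    acc <- empirical_accuracy(drop(responses %*% w), labels)
    if (is.null(best) || acc$accuracy > best$d_opt + 1e-12) {
      best <- list(readout = linear_readout(w, acc$threshold, acc$orientation),
                   d_opt = acc$accuracy, angle = th)
    }
  }
  best
}

#' Lower-bound optimal decoding for populations of more than two neurons
#'
#' The brute-force line search is exhaustive only in 2D. For k > 2 neurons
#' this reports an explicit lower bound on the optimal linear decoding
#' accuracy: the best over (a) `pair_lower_bound`, the maximum brute-force
#' 2D accuracy over all neuron pairs, and (b) `lda_direction`, the
#' best-threshold accuracy along the sample Fisher direction (pooled
#' within-class covariance, ridge-regularized with `1e-6 * trace / k`).
#'
#' @param responses Trials x k numeric matrix, k >= 2.
#' @param labels Two-class label vector.
#' @param method `"both"` (default), `"pair_lower_bound"` or
#'   `"lda_direction"`.
#' @param n_angles Grid resolution for the pairwise searches.
#' @return List with `d_opt` (the reported bound), `pair_lower_bound`,
#'   `lda_accuracy` and `is_bound = (k > 2)`.
#' @export
optimal_accuracy_nd <- function(responses, labels,
                                method = c("both", "pair_lower_bound", "lda_direction"),
                                n_angles = 200L) {
  method <- match.arg(method)
  responses <- as.matrix(responses)
  k <- ncol(responses)
  if (k < 2L) stop("need at least 2 neurons", call. = FALSE)
  pair_lb <- NA_real_
  lda_acc <- NA_real_
  if (method %in% c("both", "pair_lower_bound")) {
    prs <- utils::combn(k, 2L)
    pair_lb <- max(apply(prs, 2L, function(ij) {
      brute_force_optimal_2d(responses[, ij, drop = FALSE], labels, n_angles)$d_opt
    }))
  }
  if (method %in% c("both", "lda_direction")) {
    lv <- sort(unique(as.character(labels)))
    g <- as.character(labels) == lv[2L]
    d <- colMeans(responses[g, , drop = FALSE]) -
         colMeans(responses[!g, , drop = FALSE])
    Sw <- (stats::cov(responses[g, , drop = FALSE]) * (sum(g) - 1L) +
           stats::cov(responses[!g, , drop = FALSE]) * (sum(!g) - 1L)) /
          (length(g) - 2L)
    Sw <- Sw + diag(1e-6 * sum(diag(Sw)) / k, k)
    w <- solve(Sw, d)
    if (sum(abs(w)) > 0) {
      lda_acc <- empirical_accuracy(drop(responses %*% w), labels)$accuracy
    }
  }
  list(d_opt = max(pair_lb, lda_acc, na.rm = TRUE),
       pair_lower_bound = pair_lb, lda_accuracy = lda_acc,
       is_bound = k > 2L)
}
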
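#' Canonical correlation analysis results
#'
#' Internal constructor for the paired-component container shared by the
#' analytic and sample CCA routes.
#'
#' @noRd
new_cca_result <- function(dx, dy, rho, source) {
  k <- length(rho)
  colnames(dx) <- colnames(dy) <- paste0("CC", seq_len(k))
  structure(list(directions_x = dx, directions_y = dy,
                 rho = as.numeric(rho), k = k, source = source),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("<cca_result> (", x$source, ") k = ", x$k, "\n", sep = "")
  cat("  rho:", paste(format(x$rho, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# unit-normalize columns and fix sign: first nonzero weight positive
fix_directions <- function(V, tol = 1e-12) {
  apply(V, 2L, function(v) {
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v <- v / nrm
    nz <- which(abs(v) > tol)
    if (length(nz) && v[nz[1L]] < 0) v <- -v
    v
  })
}

#' Analytic canonical correlation analysis of a joint covariance
#'
#' Computes canonical directions and correlations directly from a
#' (stimulus-unconditioned) joint covariance by solving the eigenproblem
#' `Sxx^-1 Sxy Syy^-1 Syx v = rho^2 v` for the region-X directions; the
#' paired region-Y direction is `Syy^-1 Syx v_x`, normalized. Components are
#' ordered by decreasing rho, and each direction's first nonzero weight is
#' made positive.
#'
#' @param total_cov A `joint_covariance` (see [unconditioned_covariance()]),
#'   or a plain matrix with `m` supplied.
#' @param m X-block size when `total_cov` carries no `block_sizes`.
#' @return A `cca_result` with unit-norm `directions_x` (m x k),
#'   `directions_y` (n x k) and `rho` (length `k = min(m, n)`).
#' @export
analytic_cca <- function(total_cov, m = NULL) {
  b <- cov_blocks(total_cov, m = m)
  m <- nrow(b$xx); n <- nrow(b$yy)
  for (blk in list(b$xx, b$yy)) {
    if (min(eigen((blk + t(blk)) / 2, symmetric = TRUE, only.values = TRUE)$values) <= 1e-12) {
      stop("singular within-region covariance block", call. = FALSE)
    }
  }
  k <- min(m, n)
  M <- solve(b$xx, b$xy) %*% solve(b$yy, b$yx)
  ei <- eigen(M)
  lam <- Re(ei$values)
  ord <- order(lam, decreasing = TRUE)[seq_len(k)]
  rho <- sqrt(pmin(pmax(lam[ord], 0), 1))
  Vx <- Re(ei$vectors[, ord, drop = FALSE])
  Vy <- solve(b$yy, b$yx) %*% Vx
  # degenerate rho = 0 components: paired direction is arbitrary; keep e1
  zero <- sqrt(colSums(Vy^2)) < 1e-14
  if (any(zero)) Vy[1L, zero] <- 1
  new_cca_result(fix_directions(Vx), fix_directions(Vy), rho, "analytic")
}

#' Sample canonical correlation analysis of paired trial matrices
#'
#' Fits CCA to two trial-by-neuron response matrices with shared trials.
#' Columns are centered, each matrix is reduced by a QR decomposition and
#' the canonical correlations are the singular values of the product of the
#' orthonormal factors; this avoids explicitly inverting sample covariance
#' matrices and stays stable when the trial count is comparable to the
#' neuron count. Near rank deficiency (a constant neuron) triggers a small
#' ridge on the within-region covariances, with a warning.
#'
#' @param x Trials x m numeric matrix (region X).
#' @param y Trials x n numeric matrix (region Y), same trial count.
#' @return A `cca_result`; directions are unit-norm in neuron space and the
#'   projections of the centered data onto paired component j have Pearson
#'   correlation `rho[j]`.
#' @export
sample_cca <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("`x` and `y` must have the same trial count", call. = FALSE)
  Tn <- nrow(x); m <- ncol(x); n <- ncol(y)
  if (Tn < 3L) stop("need at least 3 trials", call. = FALSE)
  if (Tn <= m + n) {
    warning("trial count (", Tn, ") is not larger than total neuron count (",
            m + n, "); canonical correlations will be inflated", call. = FALSE)
  }
  Xc <- scale(x, center = TRUE, scale = FALSE)
  Yc <- scale(y, center = TRUE, scale = FALSE)
  qx <- qr(Xc); qy <- qr(Yc)
  tol <- 1e-9 * max(1, max(abs(Xc)), max(abs(Yc)))
  if (qx$rank < m || qy$rank < n ||
      min(abs(diag(qr.R(qx))[seq_len(m)])) < tol ||
      min(abs(diag(qr.R(qy))[seq_len(n)])) < tol) {
    warning("near rank-deficient responses; applying ridge 1e-8 to within-region covariances",
            call. = FALSE)
    Sxx <- stats::cov(x); Syy <- stats::cov(y); Sxy <- stats::cov(x, y)
    Sxx <- Sxx + diag(1e-8 * max(1, mean(diag(Sxx))), m)
    Syy <- Syy + diag(1e-8 * max(1, mean(diag(Syy))), n)
    S <- rbind(cbind(Sxx, Sxy), cbind(t(Sxy), Syy))
    return(local({
      r <- analytic_cca(joint_cov(S, m, n))
      r$source <- "sample"
      r
    }))
  }
  Qx <- qr.Q(qx)[, seq_len(m), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(n), drop = FALSE]
  sv <- svd(crossprod(Qx, Qy))
  k <- min(m, n)
  rho <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  Rx <- qr.R(qx)[seq_len(m), seq_len(m), drop = FALSE]
  Ry <- qr.R(qy)[seq_len(n), seq_len(n), drop = FALSE]
  Vx <- backsolve(Rx, sv$u[, seq_len(k), drop = FALSE])
  Vy <- backsolve(Ry, sv$v[, seq_len(k), drop = FALSE])
  # rows of Vx/Vy refer to qr-pivoted column order; map back to input order
  new_cca_result(fix_directions(unpivot(Vx, qx$pivot, m)),
                 fix_directions(unpivot(Vy, qy$pivot, n)), rho, "sample")
}

# map coefficients computed in pivoted column order back to input order
unpivot <- function(V, pivot, p) {
  out <- matrix(0, p, ncol(V))
  out[pivot[seq_len(p)], ] <- V
  out
}

#' Canonical correlation of projected trial series
#'
#' Projects paired trial matrices onto the j-th canonical component pair of
#' a fitted `cca_result` and returns the Pearson correlation of the two
#' projected series. On the data the result was fitted to this equals
#' `rho[j]`; on held-out data it is generally smaller. The headline summary
#' statistic R_CC1 is the absolute value of this quantity for component 1
#' (CCA determines paired signs only jointly).
#'
#' @param x,y Trial matrices over the same neurons the result was fitted to.
#' @param result A `cca_result`.
#' @param component Component index j <= k.
#' @param absolute Return `|r|` (default TRUE, the summary convention).
#' @return Pearson correlation (scalar).
#' @export
canonical_r <- function(x, y, result, component = 1L, absolute = TRUE) {
  stopifnot(inherits(result, "cca_result"))
  if (component < 1L || component > result$k) {
    stop("`component` must be in 1..k", call. = FALSE)
  }
  px <- drop(scale(as.matrix(x), center = TRUE, scale = FALSE) %*%
             result$directions_x[, component])
  py <- drop(scale(as.matrix(y), center = TRUE, scale = FALSE) %*%
             result$directions_y[, component])
  if (stats::sd(px) == 0 || stats::sd(py) == 0) {
    stop("zero-variance projection", call. = FALSE)
  }
  r <- stats::cor(px, py)
  if (absolute) abs(r) else r
}

#' Serialize a CCA result to JSON
#'
#' @param result A `cca_result`.
#' @param path Optional file path; when `NULL`, returns the JSON string.
#' @export
cca_to_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "cca_result"))
  rec <- list(directions_x = unname(apply(result$directions_x, 2L, c, simplify = FALSE)),
              directions_y = unname(apply(result$directions_y, 2L, c, simplify = FALSE)),
              rho = result$rho, k = result$k, source = result$source)
  if (is.null(path)) jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  else { jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA); invisible(path) }
}
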
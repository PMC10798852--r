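#' Dual-population Gaussian stimulus-response model
#'
#' Constructs the parametric model of two simultaneously recorded neural
#' populations (an upstream region X and a cortical region Y) responding to
#' two stimuli, A and B. Responses to each stimulus are multivariate Gaussian
#' with a shared, stimulus-independent covariance. By convention the mean
#' response to stimulus A is the zero vector, so `mu_x` and `mu_y` are the
#' mean responses to stimulus B.
#'
#' The noise-correlation structure is uniform: every within-X pair has
#' correlation `c_x`, every within-Y pair `c_y`, and every cross-population
#' pair `c_xy`. Per-neuron response SDs are given by `sigma` (X neurons first,
#' then Y neurons).
#'
#' @param mu_x Numeric vector, length m: mean stimulus-B response of region X.
#' @param mu_y Numeric vector, length n: mean stimulus-B response of region Y.
#' @param sigma Positive numeric vector, length m + n: per-neuron SDs.
#' @param c_x,c_y,c_xy Correlation parameters in `[0, 1)`.
#' @return An object of class `gaussian_pair_model`.
#' @examples
#' m <- gaussian_pair_model(mu_x = c(1, 0), mu_y = c(0.5, -0.5),
#'                          sigma = rep(1, 4), c_x = 0.2, c_y = 0.3, c_xy = 0)
#' assemble_covariance(m)
#' @export
gaussian_pair_model <- function(mu_x, mu_y, sigma, c_x, c_y, c_xy) {
  mu_x <- as.numeric(mu_x)
  mu_y <- as.numeric(mu_y)
  sigma <- as.numeric(sigma)
  m <- length(mu_x)
  n <- length(mu_y)
  if (m < 1L || n < 1L) {
    stop("both populations must contain at least one neuron", call. = FALSE)
  }
  if (length(sigma) != m + n) {
    stop("`sigma` must have length m + n = ", m + n, call. = FALSE)
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("all entries of `sigma` must be strictly positive", call. = FALSE)
  }
  for (nm in c("c_x", "c_y", "c_xy")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v >= 1) {
      stop("`", nm, "` must be a single value in [0, 1)", call. = FALSE)
    }
  }
  structure(
    list(mu_x = mu_x, mu_y = mu_y, sigma = sigma,
         c_x = c_x, c_y = c_y, c_xy = c_xy, m = m, n = n),
    class = "gaussian_pair_model"
  )
}

#' @export
print.gaussian_pair_model <- function(x, ...) {
  cat("<gaussian_pair_model> ", x$m, " x ", x$n, " neurons\n", sep = "")
  cat("  c_x = ", format(x$c_x, digits = 3),
      ", c_y = ", format(x$c_y, digits = 3),
      ", c_xy = ", format(x$c_xy, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Assemble the joint noise covariance of a dual-population model
#'
#' Builds the (m + n) x (m + n) stimulus-independent covariance
#' Sigma = Lambda C Lambda, where Lambda = diag(sigma) and C has unit
#' diagonal, `c_x` within the X block, `c_y` within the Y block and `c_xy`
#' in every cross-block entry.
#'
#' @param model A [gaussian_pair_model()].
#' @return A symmetric matrix with attribute `block_sizes = c(m, n)` and
#'   class `joint_covariance`.
#' @export
assemble_covariance <- function(model) {
  stopifnot(inherits(model, "gaussian_pair_model"))
  m <- model$m; n <- model$n
  C <- matrix(model$c_xy, m + n, m + n)
  C[seq_len(m), seq_len(m)] <- model$c_x
  C[m + seq_len(n), m + seq_len(n)] <- model$c_y
  diag(C) <- 1
  S <- C * tcrossprod(model$sigma)   # Lambda C Lambda, elementwise
  S <- (S + t(S)) / 2                # exact symmetry
  structure(S, block_sizes = c(m, n), class = c("joint_covariance", "matrix"))
}

joint_cov <- function(mat, m, n) {
  structure(mat, block_sizes = c(m, n), class = c("joint_covariance", "matrix"))
}

#' Extract the within- and cross-region blocks of a joint covariance
#'
#' @param cov A `joint_covariance` (or plain matrix plus `m`).
#' @param m Size of the X block; taken from the `block_sizes` attribute when
#'   present.
#' @return A list with elements `xx`, `yy`, `xy` (m x n) and `yx`.
#' @export
cov_blocks <- function(cov, m = NULL) {
  bs <- attr(cov, "block_sizes")
  if (is.null(m)) {
    if (is.null(bs)) stop("`m` required when `cov` has no block_sizes", call. = FALSE)
    m <- bs[1L]
  }
  S <- unclass(cov)
  ix <- seq_len(m)
  iy <- (m + 1L):nrow(S)
  list(xx = S[ix, ix, drop = FALSE], yy = S[iy, iy, drop = FALSE],
       xy = S[ix, iy, drop = FALSE], yx = S[iy, ix, drop = FALSE])
}

#' Test a symmetric matrix for positive definiteness
#'
#' Spectral test: TRUE iff the smallest eigenvalue exceeds `tol`. Used for
#' rejection sampling of model configurations.
#'
#' @param cov Symmetric numeric matrix.
#' @param tol Eigenvalue tolerance; default `1e-10`.
#' @return Logical scalar.
#' @export
check_positive_definite <- function(cov, tol = 1e-10) {
  S <- unclass(cov)
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop("`cov` must be a square matrix", call. = FALSE)
  }
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop("`cov` must be symmetric", call. = FALSE)
  }
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol
}

#' Sample random 2 x 2 model configurations
#'
#' Draws the 11 parameters of the 2 x 2 dual-population Gaussian model
#' independently from the survey distributions: SDs from the folded normal
#' `|N(0, 2)|`; first mean components from `N(0, 1)`; second mean components
#' from `|N(0, 1)|`; `c_x`, `c_y` from `U(0, 1)`; and
#' `c_xy = max(u - 0.01, 0)` with `u ~ U(0, 1)`, so about 1% of draws have
#' exactly zero cross-population correlation. Any parameter set whose
#' covariance is not positive definite is discarded and a whole new set is
#' drawn, so every returned configuration is valid.
#'
#' @param count Number of accepted configurations to return.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with one row per configuration and columns `mu_x1`,
#'   `mu_x2`, `mu_y1`, `mu_y2`, `sigma_x1`, `sigma_x2`, `sigma_y1`,
#'   `sigma_y2`, `c_x`, `c_y`, `c_xy`.
#' @export
sample_model_parameters <- function(count, seed = NULL) {
  stopifnot(count >= 1)
  if (!is.null(seed)) set.seed(seed)
  draw_batch <- function(k) {
    tibble::tibble(
      mu_x1 = stats::rnorm(k), mu_x2 = abs(stats::rnorm(k)),
      mu_y1 = stats::rnorm(k), mu_y2 = abs(stats::rnorm(k)),
      sigma_x1 = abs(stats::rnorm(k, 0, 2)), sigma_x2 = abs(stats::rnorm(k, 0, 2)),
      sigma_y1 = abs(stats::rnorm(k, 0, 2)), sigma_y2 = abs(stats::rnorm(k, 0, 2)),
      c_x = stats::runif(k), c_y = stats::runif(k),
      c_xy = pmax(stats::runif(k) - 0.01, 0)
    )
  }
  accepted <- list()
  n_have <- 0L
  while (n_have < count) {
    batch <- draw_batch(count - n_have)
    ok <- purrr::pmap_lgl(batch, function(...) {
      p <- list(...)
      # reject zero SDs (measure-zero but fatal) and non-PD covariances
      if (any(c(p$sigma_x1, p$sigma_x2, p$sigma_y1, p$sigma_y2) <= 0)) return(FALSE)
      mod <- gaussian_pair_model(
        mu_x = c(p$mu_x1, p$mu_x2), mu_y = c(p$mu_y1, p$mu_y2),
        sigma = c(p$sigma_x1, p$sigma_x2, p$sigma_y1, p$sigma_y2),
        c_x = p$c_x, c_y = p$c_y, c_xy = p$c_xy
      )
      check_positive_definite(assemble_covariance(mod))
    })
    keep <- batch[ok, , drop = FALSE]
    if (nrow(keep) > 0L) {
      accepted[[length(accepted) + 1L]] <- keep
      n_have <- n_have + nrow(keep)
    }
  }
  out <- dplyr::bind_rows(accepted)
  out <- out[seq_len(count), , drop = FALSE]
  dplyr::bind_cols(tibble::tibble(draw = seq_len(count)), out)
}

#' Turn one row of a parameter table into a model object
#'
#' @param params A one-row data frame as produced by
#'   [sample_model_parameters()].
#' @return A [gaussian_pair_model()].
#' @export
as_gaussian_pair_model <- function(params) {
  stopifnot(nrow(params) == 1L)
  gaussian_pair_model(
    mu_x = c(params$mu_x1, params$mu_x2),
    mu_y = c(params$mu_y1, params$mu_y2),
    sigma = c(params$sigma_x1, params$sigma_x2, params$sigma_y1, params$sigma_y2),
    c_x = params$c_x, c_y = params$c_y, c_xy = params$c_xy
  )
}

#' Stimulus-unconditioned (mixture) covariance
#'
#' Covariance of responses pooled across the two stimuli. With stimulus-B
#' prior `prior_b` and the centering convention (stimulus-A mean zero), the
#' mixture covariance is `Sigma + prior_b (1 - prior_b) mu mu'`, where `mu`
#' is the stacked mean vector. This is the matrix canonical correlation
#' analysis operates on.
#'
#' @param model A [gaussian_pair_model()].
#' @param prior_b Prior probability of stimulus B, in (0, 1). Default 0.5
#'   (equal trial counts).
#' @return A `joint_covariance`.
#' @export
unconditioned_covariance <- function(model, prior_b = 0.5) {
  stopifnot(inherits(model, "gaussian_pair_model"))
  if (!is.numeric(prior_b) || length(prior_b) != 1L || prior_b <= 0 || prior_b >= 1) {
    stop("`prior_b` must lie strictly between 0 and 1", call. = FALSE)
  }
  mu <- c(model$mu_x, model$mu_y)
  S <- unclass(assemble_covariance(model)) + prior_b * (1 - prior_b) * tcrossprod(mu)
  joint_cov((S + t(S)) / 2, model$m, model$n)
}

#' Draw trial-by-neuron responses from a model
#'
#' Samples equal numbers of stimulus-A (mean zero) and stimulus-B (mean mu)
#' trials with the shared covariance Sigma.
#'
#' @param model A [gaussian_pair_model()].
#' @param trials_per_stimulus Trials per stimulus (>= 2).
#' @param seed Optional integer seed.
#' @return A tibble with columns `trial`, `stimulus` ("A"/"B") and one
#'   response column per neuron, named `x1..xm`, `y1..yn`.
#' @export
draw_trials <- function(model, trials_per_stimulus, seed = NULL) {
  stopifnot(inherits(model, "gaussian_pair_model"), trials_per_stimulus >= 2)
  if (!is.null(seed)) set.seed(seed)
  S <- assemble_covariance(model)
  if (!check_positive_definite(S)) {
    stop("model covariance is not positive definite", call. = FALSE)
  }
  d <- model$m + model$n
  Tn <- 2L * trials_per_stimulus
  L <- chol(unclass(S))
  Z <- matrix(stats::rnorm(Tn * d), Tn, d) %*% L
  mu <- c(model$mu_x, model$mu_y)
  stim <- rep(c("A", "B"), each = trials_per_stimulus)
  Z[stim == "B", ] <- sweep(Z[stim == "B", , drop = FALSE], 2, mu, "+")
  colnames(Z) <- c(paste0("x", seq_len(model$m)), paste0("y", seq_len(model$n)))
  dplyr::bind_cols(tibble::tibble(trial = seq_len(Tn), stimulus = stim),
                   tibble::as_tibble(Z))
}

#' Split a drawn-trials tibble back into region matrices
#'
#' @param trials A tibble from [draw_trials()].
#' @return List with matrices `x`, `y` and the `labels` vector.
#' @export
split_regions <- function(trials) {
  xn <- grep("^x[0-9]+$", names(trials), value = TRUE)
  yn <- grep("^y[0-9]+$", names(trials), value = TRUE)
  list(x = as.matrix(trials[xn]), y = as.matrix(trials[yn]),
       labels = trials$stimulus)
}

#' Serialize / deserialize a model as a flat JSON record
#'
#' @param model A [gaussian_pair_model()].
#' @param path File path; when `NULL`, `model_to_json` returns the JSON string.
#' @return `model_to_json`: path or JSON string; `model_from_json`: a model.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "gaussian_pair_model"))
  rec <- list(mu_x = model$mu_x, mu_y = model$mu_y, sigma = model$sigma,
              c_x = model$c_x, c_y = model$c_y, c_xy = model$c_xy,
              m = model$m, n = model$n)
  if (is.null(path)) {
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname model_to_json
#' @param json A JSON string or file path produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  rec <- jsonlite::fromJSON(json)
  gaussian_pair_model(rec$mu_x, rec$mu_y, rec$sigma, rec$c_x, rec$c_y, rec$c_xy)
}
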
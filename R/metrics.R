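#' Average cross-population noise correlation C_xy
#'
#' For each neuron, the per-stimulus mean response is subtracted from every
#' trial of that stimulus; the Pearson correlation of the resulting residual
#' series is then computed for every cross-population neuron pair over all
#' pooled trials, and the mean over the m * n pairs is returned. Pairs
#' involving a zero-variance residual series are skipped with a warning.
#'
#' @param x Trials x m matrix (region X).
#' @param y Trials x n matrix (region Y).
#' @param labels Per-trial stimulus labels (any number of stimuli).
#' @return Mean cross-population noise correlation (scalar in `[-1, 1]`).
#' @export
noise_correlation_cxy <- function(x, y, labels) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), nrow(x) == length(labels))
  if (min(table(labels)) < 2L) {
    stop("need at least 2 trials per stimulus", call. = FALSE)
  }
  center_by_stim <- function(M) {
    for (s in unique(labels)) {
      i <- which(labels == s)
      M[i, ] <- sweep(M[i, , drop = FALSE], 2L, colMeans(M[i, , drop = FALSE]))
    }
    M
  }
  rx <- center_by_stim(x)
  ry <- center_by_stim(y)
  ok_x <- apply(rx, 2L, stats::sd) > 0
  ok_y <- apply(ry, 2L, stats::sd) > 0
  if (!all(ok_x) || !all(ok_y)) {
    warning(sum(!ok_x) + sum(!ok_y),
            " zero-variance neuron(s) after mean subtraction; their pairs are skipped",
            call. = FALSE)
  }
  if (!any(ok_x) || !any(ok_y)) return(NA_real_)
  cc <- stats::cor(rx[, ok_x, drop = FALSE], ry[, ok_y, drop = FALSE])
  mean(cc)
}

#' Normalized decoding error Delta
#'
#' Distance of CC1 decoding from the optimal linear decoder, normalized so
#' that 0 means optimal and 1 means chance:
#' `Delta = max(0, (d_opt - d_cc1) / (d_opt - 0.5))`, with `Delta = 0` when
#' `d_opt = 0.5` (no decodable signal). Vectorized.
#'
#' @param d_opt,d_cc1 Accuracies in `[0.5, 1]`.
#' @param normalize Use the chance-anchored normalization (default). With
#'   `FALSE` the raw shortfall `max(0, d_opt - d_cc1)` is returned, for
#'   sensitivity checks.
#' @return Error(s) in `[0, 1]` (normalized) or `[0, 0.5]` (raw).
#' @export
delta_error <- function(d_opt, d_cc1, normalize = TRUE) {
  eps <- 1e-12
  if (any(d_opt < 0.5 - eps | d_opt > 1 + eps, na.rm = TRUE) ||
      any(d_cc1 < 0.5 - eps | d_cc1 > 1 + eps, na.rm = TRUE)) {
    stop("accuracies must lie in [0.5, 1]", call. = FALSE)
  }
  raw <- pmax(0, d_opt - d_cc1)
  if (!normalize) return(raw)
  denom <- d_opt - 0.5
  ifelse(denom <= eps, 0, pmin(1, raw / denom))
}

#' Moving-average trend of a scatter
#'
#' Sorts the points by `x` and smooths `y` with a centered moving average of
#' `window` points; endpoints use truncated windows.
#'
#' @param data A data frame.
#' @param x,y Column names (tidyselect, unquoted) of the abscissa and the
#'   smoothed variable.
#' @param window Number of points in the averaging window (>= 1).
#' @return A tibble with the sorted `x`, the raw `y` and `y_smooth`.
#' @export
binned_trend <- function(data, x, y, window = 500L) {
  stopifnot(window >= 1L)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (length(xv) == 0L) stop("empty input", call. = FALSE)
  ord <- order(xv)
  xv <- xv[ord]; yv <- yv[ord]
  n <- length(xv)
  lo <- pmax(1L, seq_len(n) - floor((window - 1L) / 2))
  hi <- pmin(n, seq_len(n) + ceiling((window - 1L) / 2))
  cs <- c(0, cumsum(yv))
  tibble::tibble(x = xv, y = yv, y_smooth = (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Regression of decoding error on C_xy and R_CC1
#'
#' Fits the no-intercept linear model
#' `Delta = beta1 * C_xy + beta2 * R_CC1 + eps` by (weighted) least squares.
#' With the default `weights = NULL` this is ordinary least squares; a
#' weights vector provides a hook for heteroscedastic error structure.
#'
#' @param data Data frame holding the three variables.
#' @param delta,c_xy,r_cc1 Column names (unquoted).
#' @param weights Optional per-observation weights.
#' @param intercept Include an intercept (default `FALSE`, the headline
#'   model); available for robustness checks.
#' @return Object of class `delta_regression` wrapping the `lm` fit, with
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
gls_regression <- function(data, delta = delta, c_xy = c_xy, r_cc1 = r_cc1,
                           weights = NULL, intercept = FALSE) {
  df <- tibble::tibble(
    delta = dplyr::pull(data, {{ delta }}),
    c_xy = dplyr::pull(data, {{ c_xy }}),
    r_cc1 = dplyr::pull(data, {{ r_cc1 }})
  )
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10L) stop("need at least 10 complete observations", call. = FALSE)
  kappa_x <- kappa(cbind(df$c_xy, df$r_cc1), exact = TRUE)
  if (!is.finite(kappa_x) || kappa_x > 1e8) {
    warning("regressors nearly collinear (condition number ",
            format(kappa_x, digits = 3), ")", call. = FALSE)
  }
  fml <- if (intercept) delta ~ c_xy + r_cc1 else delta ~ 0 + c_xy + r_cc1
  fit <- stats::lm(fml, data = df, weights = weights)
  structure(list(fit = fit, n_obs = nrow(df), condition_number = kappa_x,
                 intercept = intercept,
                 weighting = if (is.null(weights)) "ols" else "wls"),
            class = "delta_regression")
}

#' @export
print.delta_regression <- function(x, ...) {
  co <- stats::coef(summary(x$fit))
  cat("<delta_regression> Delta ~ ", if (x$intercept) "1 + " else "",
      "C_xy + R_CC1  (", x$weighting, ", n = ", x$n_obs, ")\n", sep = "")
  print(round(co, 5))
  invisible(x)
}

#' Filter decoding summaries by the R_CC1 / C_xy cutoffs
#'
#' Two complementary filters isolate the effect of one summary statistic at
#' a time: `r_filter` keeps records with `r_cc1 > r_min` (used when relating
#' Delta to C_xy) and `c_filter` keeps records with `c_xy < c_max` (used
#' when relating Delta to R_CC1). Inequalities are strict.
#'
#' @param records Data frame with columns `r_cc1` and `c_xy`.
#' @param r_min,c_max Cutoff values.
#' @param mode `"r_filter"` or `"c_filter"`.
#' @return The filtered tibble.
#' @export
apply_cutoffs <- function(records, r_min = 0.75, c_max = 0.1,
                          mode = c("r_filter", "c_filter")) {
  mode <- match.arg(mode)
  if (mode == "r_filter") {
    dplyr::filter(records, .data$r_cc1 > r_min)
  } else {
    dplyr::filter(records, .data$c_xy < c_max)
  }
}

#' Per-dataset cutoff presets
#'
#' The filtering thresholds used for each analysis context: `analytic`
#' (`R_CC1 > 0.75`, `C_xy < 0.1`), `visual` (LGN-V1: `R_CC1 > 0.3`,
#' `C_xy < 0.06`) and `olfactory` (OB-PC: `R_CC1 > 0.4`, `C_xy < 0.1`).
#' Stored as a plain-text config shipped with the package.
#'
#' @param dataset One of `"analytic"`, `"visual"`, `"olfactory"`.
#' @return List with `r_min` and `c_max`.
#' @export
cutoff_presets <- function(dataset = c("analytic", "visual", "olfactory")) {
  dataset <- match.arg(dataset)
  cfg <- jsonlite::fromJSON(system.file("extdata", "cutoff_presets.json",
                                        package = "cc1decode"))
  cfg[[dataset]]
}
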
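#' Analytic random-parameter survey of 2 x 2 models
#'
#' Draws random 2 x 2 dual-population Gaussian model configurations and, for
#' each, computes fully analytically (no finite-sample noise): the optimal
#' linear decoding accuracy per region, the CC1 decoding accuracy per region
#' (CCA fitted on the stimulus-unconditioned covariance, accuracy by
#' Gaussian integration against the stimulus-conditioned covariance), the
#' first canonical correlation, and the normalized decoding errors.
#'
#' @param n_draws Number of accepted model configurations (default 50000,
#'   the full survey size; tests and examples use far fewer).
#' @param seed Integer seed.
#' @param prior_b Stimulus-B prior for the unconditioned covariance.
#' @return A tibble with one row per draw: the 11 parameters plus
#'   `d_opt_x`, `d_opt_y`, `d_cc1_x`, `d_cc1_y`, `rho1`, `delta_x`,
#'   `delta_y`.
#' @export
run_sweep <- function(n_draws = 50000L, seed = NULL, prior_b = 0.5) {
  params <- sample_model_parameters(n_draws, seed = seed)
  dplyr::bind_cols(params, sweep_evaluate(params, prior_b = prior_b))
}

# analytic evaluation of each parameter row; shared by run_sweep and the
# zero-c_xy intervention
sweep_evaluate <- function(params, prior_b = 0.5) {
  res <- purrr::pmap(params, function(...) {
    p <- tibble::as_tibble(list(...))
    mod <- as_gaussian_pair_model(p)
    cca <- analytic_cca(unconditioned_covariance(mod, prior_b = prior_b))
    d_opt_x <- analytic_accuracy(mod, fisher_direction(mod, "x"))
    d_opt_y <- analytic_accuracy(mod, fisher_direction(mod, "y"))
    d_cc1_x <- analytic_accuracy(mod, cca$directions_x[, 1L], region = "x")
    d_cc1_y <- analytic_accuracy(mod, cca$directions_y[, 1L], region = "y")
    tibble::tibble(
      d_opt_x = d_opt_x, d_opt_y = d_opt_y,
      d_cc1_x = d_cc1_x, d_cc1_y = d_cc1_y,
      rho1 = cca$rho[1L],
      delta_x = delta_error(d_opt_x, d_cc1_x),
      delta_y = delta_error(d_opt_y, d_cc1_y)
    )
  })
  dplyr::bind_rows(res)
}

#' Zero cross-population-correlation intervention
#'
#' For every record of a sweep, sets `c_xy` to zero while keeping the other
#' 10 parameters fixed, then recomputes the CCA on the revised unconditioned
#' covariance and all accuracies and errors. With no cross-population noise
#' correlation the CC1 direction coincides with the optimal decoder in each
#' region, so every recomputed Delta is zero to numerical precision; the
#' per-region optimal accuracies are unchanged (they depend only on the
#' within-region blocks and means).
#'
#' @param records A sweep tibble from [run_sweep()].
#' @param prior_b Stimulus-B prior.
#' @return A tibble of the same shape with `c_xy = 0` and recomputed
#'   decoding columns.
#' @export
zero_cxy_intervention <- function(records, prior_b = 0.5) {
  param_cols <- c("draw", "mu_x1", "mu_x2", "mu_y1", "mu_y2",
                  "sigma_x1", "sigma_x2", "sigma_y1", "sigma_y2",
                  "c_x", "c_y", "c_xy")
  params <- dplyr::mutate(records[param_cols], c_xy = 0)
  dplyr::bind_cols(params, sweep_evaluate(params, prior_b = prior_b))
}

#' Summarize a sweep: trend curves and the error regression
#'
#' Applies the two complementary cutoffs, computes the moving-average trend
#' of the cortical decoding error against `c_xy` (records with
#' `rho1 > r_min`) and against `rho1` (records with `c_xy < c_max`), and
#' fits the no-intercept regression of Delta on both statistics. In the
#' analytic track the model's first canonical correlation `rho1` plays the
#' role of R_CC1 and the parameter `c_xy` the role of the measured
#' cross-population noise correlation.
#'
#' @param records A sweep tibble.
#' @param r_min,c_max Cutoffs; defaults are the analytic presets
#'   (`R_CC1 > 0.75`, `C_xy < 0.1`).
#' @param window Moving-average window (points).
#' @param region Which region's Delta to summarize (`"y"`, the cortex, by
#'   default).
#' @return Object of class `sweep_summary`: trend tibbles `trend_cxy` and
#'   `trend_rho`, the `regression` ([gls_regression()] fit on all records),
#'   and bookkeeping counts. Has an [ggplot2::autoplot()] method.
#' @export
summarize_sweep <- function(records, r_min = 0.75, c_max = 0.1,
                            window = 500L, region = c("y", "x")) {
  region <- match.arg(region)
  delta_col <- paste0("delta_", region)
  recs <- dplyr::rename(records, delta = dplyr::all_of(delta_col),
                        r_cc1 = "rho1")
  by_c <- apply_cutoffs(recs, r_min = r_min, mode = "r_filter")
  by_r <- apply_cutoffs(recs, c_max = c_max, mode = "c_filter")
  if (nrow(by_c) == 0L || nrow(by_r) == 0L) {
    stop("no records survive the cutoffs", call. = FALSE)
  }
  structure(list(
    trend_cxy = binned_trend(by_c, c_xy, delta, window = min(window, nrow(by_c))),
    trend_rho = binned_trend(by_r, r_cc1, delta, window = min(window, nrow(by_r))),
    regression = gls_regression(recs),
    n_records = nrow(recs), n_after_r_filter = nrow(by_c),
    n_after_c_filter = nrow(by_r),
    r_min = r_min, c_max = c_max, region = region
  ), class = "sweep_summary")
}

#' @export
print.sweep_summary <- function(x, ...) {
  cat("<sweep_summary> region ", x$region, ", ", x$n_records, " records\n",
      "  Delta vs C_xy trend:  ", x$n_after_r_filter,
      " records (R_CC1 > ", x$r_min, ")\n",
      "  Delta vs R_CC1 trend: ", x$n_after_c_filter,
      " records (C_xy < ", x$c_max, ")\n", sep = "")
  print(x$regression)
  invisible(x)
}

#' Write a sweep and its summary to delimited files
#'
#' @param records Sweep tibble.
#' @param summary A `sweep_summary` (optional).
#' @param dir Output directory.
#' @param seed Seed to record in the manifest.
#' @return The manifest, invisibly (see [write_outputs()]).
#' @export
write_sweep <- function(records, summary = NULL, dir, seed = NULL) {
  tables <- list(sweep = records)
  jsons <- list()
  if (!is.null(summary)) {
    tables$trend_cxy <- summary$trend_cxy
    tables$trend_rho <- summary$trend_rho
    jsons$regression <- c(tidy_regression_list(summary$regression),
                          list(n_records = summary$n_records))
  }
  write_outputs(tables, jsons, dir, seed = seed,
                config = list(r_min = summary$r_min %||% NA,
                              c_max = summary$c_max %||% NA))
}
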
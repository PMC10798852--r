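#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

tidy_regression_list <- function(x) {
  co <- stats::coef(summary(x$fit))
  stats::setNames(
    purrr::map(rownames(co), ~ list(estimate = co[.x, 1L],
                                    std_error = co[.x, 2L],
                                    p_value = co[.x, 4L])),
    rownames(co)
  )
}

#' Tidy a decoding-error regression
#'
#' @param x A `delta_regression` from [gls_regression()].
#' @param ... Unused.
#' @return Tibble with one row per term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.delta_regression <- function(x, ...) {
  co <- stats::coef(summary(x$fit))
  tibble::tibble(term = rownames(co), estimate = co[, 1L],
                 std.error = co[, 2L], statistic = co[, 3L],
                 p.value = co[, 4L])
}

#' @rdname tidy.delta_regression
#' @return `glance`: one-row tibble with `sigma`, `nobs`,
#'   `condition.number` and `weighting`.
#' @export
glance.delta_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(sigma = s$sigma, nobs = x$n_obs,
                 condition.number = x$condition_number,
                 weighting = x$weighting)
}

#' Tidy a CCA result
#'
#' @param x A `cca_result`.
#' @param ... Unused.
#' @return Tibble with `component` and `rho`.
#' @export
tidy.cca_result <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k), rho = x$rho)
}

#' @rdname tidy.cca_result
#' @export
glance.cca_result <- function(x, ...) {
  tibble::tibble(k = x$k, rho1 = x$rho[1L], source = x$source)
}

#' Glance at a cross-validation result
#'
#' @param x A `cc1_crossval`.
#' @param ... Unused.
#' @return One-row tibble with `mean_accuracy`, `folds`, `sd_accuracy`.
#' @export
glance.cc1_crossval <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy, folds = x$folds,
                 sd_accuracy = stats::sd(x$fold_accuracy))
}

#' Plot sweep trend curves
#'
#' Two-panel scatter-plus-moving-average view of a [summarize_sweep()]
#' result: decoding error against the cross-population noise correlation
#' (records with high R_CC1) and against the first canonical correlation
#' (records with low C_xy).
#'
#' @param object A `sweep_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_summary <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::mutate(object$trend_cxy, panel = "Delta vs C_xy"),
    dplyr::mutate(object$trend_rho, panel = "Delta vs R_CC1")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$y), alpha = 0.15, size = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y_smooth), colour = "blue",
                       linewidth = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "decoding error Δ") +
    ggplot2::theme_minimal()
}

#' Plot CC1 vs optimal decoding for evaluated populations
#'
#' Scatter of `d_cc1` against `d_opt` with the identity line, the standard
#' view of how close CC1 decoding comes to the optimal linear decoder
#' across sampled populations.
#'
#' @param evaluated Output of [evaluate_populations()].
#' @return A ggplot object.
#' @export
plot_population_summary <- function(evaluated) {
  df <- dplyr::filter(evaluated, !.data$degenerate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_opt, y = .data$d_cc1)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::coord_equal(xlim = c(0.5, 1), ylim = c(0.5, 1)) +
    ggplot2::labs(x = "optimal D", y = expression(D[CC1])) +
    ggplot2::theme_minimal()
}
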
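#' Randomly sample dual-region sub-populations
#'
#' Draws `count` random population selections, each with `m` upstream
#' neurons and `n` cortical neurons sampled uniformly without replacement
#' within a draw. Neurons with zero spikes across the relevant trials are
#' excluded from the candidate pools first. If the combinatorial space is
#' smaller than `count`, repeats can occur and a warning is issued.
#'
#' @param session A [recording_session()].
#' @param m,n Neurons per selection in the upstream / cortex region.
#' @param count Number of selections (default 10000).
#' @param seed Integer seed.
#' @param stimulus_pair Optional stimulus pair used for the zero-spike
#'   screen; defaults to all trials.
#' @param upstream,cortex Region labels.
#' @return Tibble with `pop` (id) and list-columns `upstream_ids`,
#'   `cortex_ids` (column indices into the session counts).
#' @export
sample_populations <- function(session, m = 2L, n = 2L, count = 10000L,
                               seed = NULL, stimulus_pair = NULL,
                               upstream = "upstream", cortex = "cortex") {
  if (!is.null(seed)) set.seed(seed)
  keep_trials <- if (is.null(stimulus_pair)) seq_len(nrow(session$counts))
                 else which(session$stimulus %in% stimulus_pair)
  active <- colSums(session$counts[keep_trials, , drop = FALSE]) > 0L
  up_pool <- intersect(region_index(session, upstream), which(active))
  cx_pool <- intersect(region_index(session, cortex), which(active))
  if (length(up_pool) < m) stop("m exceeds the upstream pool size", call. = FALSE)
  if (length(cx_pool) < n) stop("n exceeds the cortex pool size", call. = FALSE)
  space <- choose(length(up_pool), m) * choose(length(cx_pool), n)
  if (space < count) {
    warning("only ", format(space), " distinct selections exist; repeats will occur",
            call. = FALSE)
  }
  tibble::tibble(
    pop = seq_len(count),
    upstream_ids = purrr::map(seq_len(count), ~ sort(sample(up_pool, m))),
    cortex_ids = purrr::map(seq_len(count), ~ sort(sample(cx_pool, n)))
  )
}

#' Evaluate CC1 decoding for one dual-region population
#'
#' The core empirical analysis step. Restricted to the trials of one
#' stimulus pair: CCA is fitted to the two populations on trials pooled
#' across both stimuli (stimulus-unconditioned, as in the analytic track);
#' the cortical responses are projected onto the cortical CC1 and decoded
#' with the best threshold (`d_cc1`); optimal decoding (`d_opt`) of the
#' cortical population uses the brute-force angular search for pairs and
#' the pair-lower-bound / LDA bound for larger populations; the
#' cross-population noise correlation and the first canonical correlation
#' complete the record.
#'
#' @param session A [recording_session()].
#' @param upstream_ids,cortex_ids Neuron column indices.
#' @param stimulus_pair Length-2 character vector.
#' @param n_angles Brute-force grid resolution.
#' @param component Canonical component used for decoding (default 1; see
#'   [higher_component_decoding()]).
#' @return One-row tibble: `d_opt`, `d_cc1`, `delta`, `c_xy`, `r_cc1`,
#'   `component`, `degenerate` (TRUE when a constant neuron forced a
#'   ridge-stabilized CCA; such records are excluded from summaries).
#' @export
evaluate_population <- function(session, upstream_ids, cortex_ids,
                                stimulus_pair, n_angles = 200L,
                                component = 1L) {
  sub <- subset_pair(session, stimulus_pair)
  x <- sub$counts[, upstream_ids, drop = FALSE]
  y <- sub$counts[, cortex_ids, drop = FALSE]
  labels <- sub$stimulus
  degenerate <- any(apply(x, 2L, stats::sd) == 0) || any(apply(y, 2L, stats::sd) == 0)
  if (degenerate) {
    return(tibble::tibble(d_opt = NA_real_, d_cc1 = NA_real_, delta = NA_real_,
                          c_xy = NA_real_, r_cc1 = NA_real_,
                          component = as.integer(component), degenerate = TRUE))
  }
  cca <- sample_cca(x, y)
  if (component > cca$k) stop("`component` exceeds min(m, n)", call. = FALSE)
  proj <- drop(scale(y, center = TRUE, scale = FALSE) %*%
               cca$directions_y[, component])
  d_cc1 <- empirical_accuracy(proj, labels)$accuracy
  d_opt <- if (ncol(y) == 2L) {
    brute_force_optimal_2d(y, labels, n_angles)$d_opt
  } else {
    optimal_accuracy_nd(y, labels, n_angles = n_angles)$d_opt
  }
  cxy <- suppressWarnings(noise_correlation_cxy(x, y, labels))
  r_cc <- canonical_r(x, y, cca, component = component)
  tibble::tibble(d_opt = d_opt, d_cc1 = d_cc1,
                 delta = delta_error(d_opt, d_cc1),
                 c_xy = cxy, r_cc1 = r_cc,
                 component = as.integer(component), degenerate = FALSE)
}

#' Evaluate many sampled populations
#'
#' Maps [evaluate_population()] over a selection table.
#'
#' @param session A [recording_session()].
#' @param selections Tibble from [sample_populations()].
#' @param stimulus_pair Length-2 character vector.
#' @param ... Passed to [evaluate_population()].
#' @return The selection tibble with the decoding-summary columns appended.
#' @export
evaluate_populations <- function(session, selections, stimulus_pair, ...) {
  res <- purrr::map2(selections$upstream_ids, selections$cortex_ids,
                     function(u, v) evaluate_population(session, u, v,
                                                        stimulus_pair, ...))
  dplyr::bind_cols(selections, dplyr::bind_rows(res))
}

#' Cross-validated CC1 decoding accuracy
#'
#' Stratified k-fold cross-validation of the full CC1 decoding pipeline:
#' within each fold, the CCA directions, the projection centering and the
#' decision threshold are fitted on the training trials only, and held-out
#' trials are classified by the trained threshold.
#'
#' @param session A [recording_session()].
#' @param upstream_ids,cortex_ids Neuron column indices.
#' @param stimulus_pair Length-2 character vector.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Object of class `cc1_crossval` with `mean_accuracy`,
#'   `fold_accuracy` and `folds`; [generics::glance()] returns a one-row
#'   tibble.
#' @export
crossvalidate_cc1 <- function(session, upstream_ids, cortex_ids,
                              stimulus_pair, folds = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sub <- subset_pair(session, stimulus_pair)
  x <- sub$counts[, upstream_ids, drop = FALSE]
  y <- sub$counts[, cortex_ids, drop = FALSE]
  labels <- sub$stimulus
  if (min(table(labels)) < folds) {
    stop("need at least `folds` trials per stimulus", call. = FALSE)
  }
  fold_of <- integer(length(labels))
  for (s in unique(labels)) {
    i <- which(labels == s)
    fold_of[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_of != f
    fit <- sample_cca(x[tr, , drop = FALSE], y[tr, , drop = FALSE])
    ytr_mean <- colMeans(y[tr, , drop = FALSE])
    w <- fit$directions_y[, 1L]
    proj_tr <- drop(sweep(y[tr, , drop = FALSE], 2L, ytr_mean) %*% w)
    rule <- empirical_accuracy(proj_tr, labels[tr])
    proj_te <- drop(sweep(y[!tr, , drop = FALSE], 2L, ytr_mean) %*% w)
    lv <- sort(unique(labels))
    pred_b <- if (rule$orientation > 0) proj_te > rule$threshold
              else proj_te < rule$threshold
    mean((labels[!tr] == lv[2L]) == pred_b)
  }, numeric(1L))
  structure(list(mean_accuracy = mean(acc), fold_accuracy = acc,
                 folds = folds), class = "cc1_crossval")
}

#' @export
print.cc1_crossval <- function(x, ...) {
  cat("<cc1_crossval> ", x$folds, "-fold held-out accuracy: ",
      format(x$mean_accuracy, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Fixed-cortex upstream-resampling experiment
#'
#' Ranks evaluated 2 x 2 populations by their cortical optimal accuracy,
#' keeps the `top_k` distinct cortical pairs, and re-evaluates each with
#' `n_upstream` freshly sampled upstream pairs. Because the optimal decoder
#' depends only on the cortical responses, `d_opt` is constant within a
#' cortical pair while `d_cc1`, `c_xy` and `r_cc1` vary with the upstream
#' choice — isolating how the upstream population shapes CC1 decoding.
#'
#' @param session A [recording_session()].
#' @param evaluated Output of [evaluate_populations()] for 2 x 2 selections.
#' @param stimulus_pair Length-2 character vector.
#' @param top_k Cortical pairs to keep (default 50).
#' @param n_upstream Upstream redraws per cortical pair (default 200).
#' @param seed Integer seed.
#' @param upstream Region label of the upstream pool.
#' @param m Upstream neurons per redraw.
#' @return Tibble of decoding summaries with `cortex_rank`, `resample` ids
#'   and the list-columns of the selections.
#' @export
upstream_resampling_experiment <- function(session, evaluated, stimulus_pair,
                                           top_k = 50L, n_upstream = 200L,
                                           seed = NULL, upstream = "upstream",
                                           m = 2L) {
  if (!is.null(seed)) set.seed(seed)
  ok <- dplyr::filter(evaluated, !.data$degenerate)
  ok <- ok[!duplicated(purrr::map_chr(ok$cortex_ids, paste, collapse = ",")), ]
  if (nrow(ok) < top_k) stop("fewer than `top_k` usable cortical pairs", call. = FALSE)
  top <- dplyr::slice_max(ok, .data$d_opt, n = top_k, with_ties = FALSE)
  keep_trials <- which(session$stimulus %in% stimulus_pair)
  active <- colSums(session$counts[keep_trials, , drop = FALSE]) > 0L
  up_pool <- intersect(region_index(session, upstream), which(active))
  out <- purrr::map(seq_len(nrow(top)), function(i) {
    cx <- top$cortex_ids[[i]]
    redraws <- purrr::map(seq_len(n_upstream), ~ sort(sample(up_pool, m)))
    res <- purrr::map(redraws, function(u) {
      evaluate_population(session, u, cx, stimulus_pair)
    })
    dplyr::bind_cols(
      tibble::tibble(cortex_rank = i, resample = seq_len(n_upstream),
                     upstream_ids = redraws,
                     cortex_ids = rep(list(cx), n_upstream)),
      dplyr::bind_rows(res)
    )
  })
  dplyr::bind_rows(out)
}

#' Build larger populations from well-performing pairs
#'
#' Assembles `size` x `size` dual-region selections seeded by 2 x 2
#' populations that decoded well: the seed pool is the `top_pool` records
#' with the highest `d_cc1`, restricted to `d_cc1 > d_cc1_min`. Each
#' selection extends one seed pair (both regions) with distinct neurons
#' drawn from the pooled seed neurons, so every selection contains a
#' qualifying 2 x 2 sub-pair and its pair-lower-bound optimal accuracy is
#' at least `d_cc1_min` by construction.
#'
#' @param evaluated Output of [evaluate_populations()] for 2 x 2 selections.
#' @param size Target region size (3 or 4; 2 degenerates to filtering).
#' @param d_cc1_min Qualification threshold (default 0.7).
#' @param top_pool Seed-pool size (default 1000).
#' @param count Number of selections to emit (default 100).
#' @param seed Integer seed.
#' @return Tibble with list-columns `upstream_ids`, `cortex_ids` and the
#'   seeding record's `seed_d_cc1`.
#' @export
build_larger_populations <- function(evaluated, size = 3L, d_cc1_min = 0.7,
                                     top_pool = 1000L, count = 100L,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ok <- dplyr::filter(evaluated, !.data$degenerate)
  pool <- dplyr::slice_max(ok, .data$d_cc1, n = min(top_pool, nrow(ok)),
                           with_ties = FALSE)
  pool <- dplyr::filter(pool, .data$d_cc1 > d_cc1_min)
  if (nrow(pool) == 0L) stop("no qualifying seed populations", call. = FALSE)
  if (size == 2L) {
    return(tibble::tibble(pop = seq_len(nrow(pool)),
                          upstream_ids = pool$upstream_ids,
                          cortex_ids = pool$cortex_ids,
                          seed_d_cc1 = pool$d_cc1))
  }
  up_all <- sort(unique(unlist(pool$upstream_ids)))
  cx_all <- sort(unique(unlist(pool$cortex_ids)))
  extra <- size - 2L
  if (length(up_all) < size || length(cx_all) < size) {
    stop("seed-neuron pool too small for size ", size, call. = FALSE)
  }
  rows <- purrr::map(seq_len(count), function(i) {
    s <- pool[sample(nrow(pool), 1L), ]
    u0 <- s$upstream_ids[[1L]]; v0 <- s$cortex_ids[[1L]]
    u_extra <- sample(setdiff(up_all, u0), extra)
    v_extra <- sample(setdiff(cx_all, v0), extra)
    tibble::tibble(pop = i,
                   upstream_ids = list(sort(c(u0, u_extra))),
                   cortex_ids = list(sort(c(v0, v_extra))),
                   seed_d_cc1 = s$d_cc1)
  })
  dplyr::bind_rows(rows)
}

#' Decode from canonical components beyond the first
#'
#' Identical to [evaluate_population()] but projecting the cortical
#' responses onto canonical component `component`; the reported canonical
#' correlation is that of component `component`.
#'
#' @inheritParams evaluate_population
#' @export
higher_component_decoding <- function(session, upstream_ids, cortex_ids,
                                      stimulus_pair, component = 1L,
                                      n_angles = 200L) {
  evaluate_population(session, upstream_ids, cortex_ids, stimulus_pair,
                      n_angles = n_angles, component = component)
}
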
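#' Dual-region spike-count recording session
#'
#' Container for a trial-by-neuron spike-count matrix with per-trial
#' stimulus labels and per-neuron region labels. Exactly two regions must be
#' present (conventionally `"upstream"` and `"cortex"`) and at least two
#' stimulus labels.
#'
#' @param counts Trials x neurons matrix of nonnegative integers.
#' @param region Character vector, one region label per neuron.
#' @param stimulus Character vector, one stimulus label per trial.
#' @param window_ms Response-window length in milliseconds (metadata).
#' @param id Optional session identifier.
#' @return Object of class `recording_session`.
#' @export
recording_session <- function(counts, region, stimulus, window_ms = 250,
                              id = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9)) {
    stop("`counts` must be nonnegative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  region <- as.character(region)
  stimulus <- as.character(stimulus)
  if (length(region) != ncol(counts)) {
    stop("`region` must have one entry per neuron (column)", call. = FALSE)
  }
  if (length(stimulus) != nrow(counts)) {
    stop("`stimulus` must have one entry per trial (row)", call. = FALSE)
  }
  if (length(unique(region)) != 2L) {
    stop("exactly two region labels required", call. = FALSE)
  }
  if (length(unique(stimulus)) < 2L) {
    stop("at least two stimulus labels required", call. = FALSE)
  }
  if (is.null(colnames(counts))) colnames(counts) <- paste0("n", seq_len(ncol(counts)))
  structure(list(counts = counts, region = region, stimulus = stimulus,
                 window_ms = window_ms, id = id),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  tab <- table(x$region)
  cat("<recording_session>", if (!is.null(x$id)) x$id, "\n",
      " ", nrow(x$counts), " trials x ", ncol(x$counts), " neurons (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n",
      "  stimuli: ", paste(sort(unique(x$stimulus)), collapse = ", "), "\n",
      "  window: ", x$window_ms, " ms\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.recording_session <- function(x, ...) {
  tibble::tibble(
    trial = rep(seq_len(nrow(x$counts)), times = ncol(x$counts)),
    neuron = rep(colnames(x$counts), each = nrow(x$counts)),
    region = rep(x$region, each = nrow(x$counts)),
    stimulus = rep(x$stimulus, times = ncol(x$counts)),
    count = as.integer(x$counts)
  )
}

# neuron column indices for one region
region_index <- function(session, region) {
  idx <- which(session$region == region)
  if (length(idx) == 0L) {
    stop("no neurons with region label '", region, "'", call. = FALSE)
  }
  idx
}

# restrict a session to the trials of one stimulus pair
subset_pair <- function(session, stimulus_pair) {
  stopifnot(length(stimulus_pair) == 2L)
  keep <- session$stimulus %in% stimulus_pair
  if (min(table(session$stimulus[keep])) < 2L) {
    stop("need at least 2 trials per stimulus in the pair", call. = FALSE)
  }
  list(counts = session$counts[keep, , drop = FALSE],
       stimulus = session$stimulus[keep])
}

#' Extract spike-count responses from event times
#'
#' Counts the spikes of each neuron in the half-open window
#' `[onset, onset + window_ms)` after each trial onset.
#'
#' @param spike_times List of numeric vectors, one per neuron, of event
#'   times (same units as `onsets`, conventionally milliseconds).
#' @param onsets Sorted numeric vector of per-trial stimulus-onset times.
#' @param window_ms Window length; default 250.
#' @param region Per-neuron region labels.
#' @param stimulus Per-trial stimulus labels.
#' @param id Optional session id.
#' @return A [recording_session()].
#' @export
extract_responses <- function(spike_times, onsets, window_ms = 250,
                              region, stimulus, id = NULL) {
  stopifnot(window_ms > 0)
  if (is.unsorted(onsets)) stop("`onsets` must be sorted", call. = FALSE)
  if (any(onsets < 0) || any(vapply(spike_times, function(s) any(s < 0), logical(1L)))) {
    stop("negative times are not allowed", call. = FALSE)
  }
  if (length(onsets) > 1L && any(diff(onsets) < window_ms)) {
    warning("response windows overlap adjacent onsets", call. = FALSE)
  }
  counts <- vapply(spike_times, function(s) {
    s <- sort(s)
    # spikes in [onset, onset + window): half-open interval
    findInterval(onsets + window_ms, s, left.open = TRUE) -
      findInterval(onsets, s, left.open = TRUE)
  }, integer(length(onsets)))
  if (length(onsets) == 1L) counts <- matrix(counts, nrow = 1L)
  recording_session(counts, region = region, stimulus = stimulus,
                    window_ms = window_ms, id = id)
}
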
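#' Read a recording session from delimited text
#'
#' Supported encodings (all comma-separated, UTF-8, header row):
#' * `"long"` — one file with columns `trial`, `neuron`, `region`,
#'   `stimulus`, `count`.
#' * `"wide"` — a trial x neuron count matrix (first column `trial`) plus
#'   two sidecar files: `neurons` (columns `neuron`, `region`) and
#'   `trials` (columns `trial`, `stimulus`).
#' * `"spiketimes"` — per-neuron event times (columns `neuron`, `time`)
#'   with a `neurons` sidecar as above and an `onsets` sidecar (columns
#'   `trial`, `onset`, `stimulus`); counts are extracted with
#'   [extract_responses()].
#'
#' @param path Path to the main file.
#' @param format One of `"long"`, `"wide"`, `"spiketimes"`.
#' @param neurons,trials,onsets Sidecar paths where required.
#' @param window_ms Response window for the spike-time route.
#' @param id Session id; defaults to the file name.
#' @return A validated [recording_session()].
#' @export
read_session <- function(path, format = c("long", "wide", "spiketimes"),
                         neurons = NULL, trials = NULL, onsets = NULL,
                         window_ms = 250, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(id)) id <- basename(path)
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop("missing column(s) in ", what, ": ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  if (format == "long") {
    df <- rd(path)
    need(df, c("trial", "neuron", "region", "stimulus", "count"), "long table")
    if (any(df$count < 0) || any(df$count != round(df$count))) {
      stop("counts must be nonnegative integers", call. = FALSE)
    }
    wide <- tidyr::pivot_wider(df, id_cols = "trial",
                               names_from = "neuron", values_from = "count")
    if (anyNA(wide)) {
      stop("trial/neuron grid is incomplete: trial-count mismatch between regions",
           call. = FALSE)
    }
    wide <- dplyr::arrange(wide, .data$trial)
    counts <- as.matrix(wide[-1L])
    nm <- dplyr::distinct(df, .data$neuron, .data$region)
    region <- nm$region[match(colnames(counts), nm$neuron)]
    tm <- dplyr::distinct(df, .data$trial, .data$stimulus)
    stim <- tm$stimulus[match(wide$trial, tm$trial)]
    ses <- recording_session(counts, region, stim, window_ms = window_ms, id = id)
  } else if (format == "wide") {
    if (is.null(neurons) || is.null(trials)) {
      stop("wide format needs `neurons` and `trials` sidecar files", call. = FALSE)
    }
    wide <- rd(path); nm <- rd(neurons); tm <- rd(trials)
    need(wide, "trial", "wide table"); need(nm, c("neuron", "region"), "neurons sidecar")
    need(tm, c("trial", "stimulus"), "trials sidecar")
    wide <- dplyr::arrange(wide, .data$trial)
    counts <- as.matrix(wide[setdiff(names(wide), "trial")])
    region <- nm$region[match(colnames(counts), nm$neuron)]
    if (anyNA(region)) stop("neurons sidecar does not cover all columns", call. = FALSE)
    stim <- tm$stimulus[match(wide$trial, tm$trial)]
    if (anyNA(stim)) stop("trials sidecar does not cover all trials", call. = FALSE)
    ses <- recording_session(counts, region, stim, window_ms = window_ms, id = id)
  } else {
    if (is.null(neurons) || is.null(onsets)) {
      stop("spiketimes format needs `neurons` and `onsets` sidecar files",
           call. = FALSE)
    }
    ev <- rd(path); nm <- rd(neurons); om <- rd(onsets)
    need(ev, c("neuron", "time"), "spike-times table")
    need(nm, c("neuron", "region"), "neurons sidecar")
    need(om, c("trial", "onset", "stimulus"), "onsets sidecar")
    om <- dplyr::arrange(om, .data$onset)
    spikes <- purrr::map(nm$neuron, ~ ev$time[ev$neuron == .x])
    ses <- extract_responses(spikes, om$onset, window_ms = window_ms,
                             region = nm$region, stimulus = om$stimulus, id = id)
    colnames(ses$counts) <- as.character(nm$neuron)
  }
  message("read session '", id, "': ", nrow(ses$counts), " trials, ",
          ncol(ses$counts), " neurons; regions: ",
          paste(sort(unique(ses$region)), collapse = ", "), "; stimuli: ",
          paste(sort(unique(ses$stimulus)), collapse = ", "))
  ses
}

#' Write a recording session as a long delimited table
#'
#' @param session A [recording_session()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  readr::write_csv(as_tibble.recording_session(session), path, progress = FALSE)
  invisible(path)
}

#' Write result tables and JSON summaries with a manifest
#'
#' Writes each table as CSV (deterministic column order as given) and each
#' summary as JSON, then a `manifest.json` listing every file, the seed,
#' a hash of the configuration and the package version. Re-running with the
#' same inputs produces byte-identical tables.
#'
#' @param tables Named list of data frames.
#' @param json_summaries Named list of JSON-serializable objects.
#' @param output_dir Directory (created if needed).
#' @param seed Seed to record.
#' @param config Arbitrary configuration recorded via its hash.
#' @return The manifest list, invisibly.
#' @export
write_outputs <- function(tables = list(), json_summaries = list(),
                          output_dir, seed = NULL, config = NULL) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create ", output_dir, call. = FALSE)
  files <- character()
  for (nm in names(tables)) {
    f <- file.path(output_dir, paste0(nm, ".csv"))
    tab <- tables[[nm]]
    tab <- dplyr::select(tab, !dplyr::where(is.list))  # drop list-columns
    readr::write_csv(tab, f, progress = FALSE)
    files <- c(files, basename(f))
  }
  for (nm in names(json_summaries)) {
    f <- file.path(output_dir, paste0(nm, ".json"))
    jsonlite::write_json(json_summaries[[nm]], f, auto_unbox = TRUE, digits = NA)
    files <- c(files, basename(f))
  }
  manifest <- list(files = files, seed = seed,
                   config_hash = rlang::hash(config),
                   package_version = as.character(utils::packageVersion("cc1decode")))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
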
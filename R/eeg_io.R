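#' Construct a multichannel EEG recording
#'
#' Bundles a channels-by-samples matrix of scalp potentials with its sampling
#' rate and 10-10 channel labels. All pipeline stages operate on this
#' container.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique 10-10 position names, one
#'   per row of `data`. Defaults to the standard 32-cap labels (or generic
#'   `Ch<k>` names) truncated to the channel count.
#' @param subject_id Identifier of the recorded subject (integer or string).
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(200), 2, 100), fs = 100,
#'                      channel_labels = c("Fp1", "Fp2"), subject_id = 1)
#' rec
eeg_recording <- function(data, fs, channel_labels = NULL, subject_id = NA) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix.", class = "eegauth_validation_error")
  }
  if (is.null(channel_labels)) channel_labels <- default_channel_labels(nrow(data))
  if (is.numeric(subject_id) && length(subject_id) == 1L && is.finite(subject_id) &&
      subject_id == round(subject_id)) {
    subject_id <- as.integer(subject_id)
  }
  validate_recording_fields(data, fs, channel_labels)
  structure(
    list(
      subject_id = subject_id,
      fs = as.numeric(fs),
      channel_labels = as.character(channel_labels),
      data = unname(data)
    ),
    class = "eeg_recording"
  )
}

validate_recording_fields <- function(data, fs, channel_labels) {
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).", class = "eegauth_validation_error")
  }
  if (ncol(data) < 1L) {
    abort("Recording must contain at least one sample.", class = "eegauth_validation_error")
  }
  if (length(channel_labels) != nrow(data)) {
    abort(
      sprintf(
        "Channel label count (%d) does not match matrix row count (%d).",
        length(channel_labels), nrow(data)
      ),
      class = "eegauth_validation_error"
    )
  }
  if (anyDuplicated(channel_labels)) {
    abort("Channel labels must be unique.", class = "eegauth_validation_error")
  }
  if (!all(is.finite(data))) {
    abort("Recording contains non-finite samples (NaN/Inf).", class = "eegauth_validation_error")
  }
  invisible(TRUE)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s: %d channels x %d samples @ %g Hz (%.2f s)\n",
    as.character(x$subject_id), nrow(x$data), ncol(x$data), x$fs,
    ncol(x$data) / x$fs
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Length of the recording in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

sidecar_path <- function(path) paste0(path, ".json")

#' Write an EEG recording to disk
#'
#' Writes the sample matrix plus a JSON metadata sidecar (`<path>.json`)
#' holding the subject id, sampling rate and channel labels. Two layouts are
#' supported: `"bin"`, a little-endian float64 matrix stored channel-major
#' (the canonical channels x samples orientation), and `"csv"`, a
#' human-readable samples x channels table with a header row of 10-10 labels,
#' transposed back on read.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path for the matrix file; the sidecar is written next
#'   to it. A `.csv` extension selects the delimited layout.
#' @param format `"bin"` or `"csv"`; defaults from the file extension.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "bin"
  }
  format <- match.arg(format, c("bin", "csv"))
  meta <- list(
    schema = "eegauth-recording/1",
    subject_id = rec$subject_id,
    fs = rec$fs,
    labels = rec$channel_labels,
    format = format,
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data)
  )
  if (format == "bin") {
    con <- file(path, "wb")
    on.exit(close(con))
    # channel-major: row i of the matrix is contiguous on disk
    writeBin(as.vector(t(rec$data)), con, size = 8L, endian = "little")
  } else {
    tab <- as.data.frame(t(rec$data))
    names(tab) <- rec$channel_labels
    utils::write.csv(tab, path, row.names = FALSE)
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EEG recording from disk
#'
#' Counterpart of [write_recording()]: loads the matrix file described by its
#' JSON sidecar and returns a validated [eeg_recording()]. Row order follows
#' the sidecar's label order; non-finite samples are rejected.
#'
#' @param path Path to the matrix file (its sidecar must be `<path>.json`).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    abort(sprintf("Missing metadata sidecar '%s'.", sc), class = "eegauth_format_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("Missing data file '%s'.", path), class = "eegauth_format_error")
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!identical(meta$schema, "eegauth-recording/1")) {
    abort("Unknown recording schema version.", class = "eegauth_format_error")
  }
  labels <- as.character(meta$labels)
  if (identical(meta$format, "csv")) {
    tab <- utils::read.csv(path, check.names = FALSE)
    if (!identical(names(tab), labels)) {
      abort("CSV header does not match sidecar labels.", class = "eegauth_validation_error")
    }
    mat <- t(as.matrix(tab))
  } else {
    nc <- as.integer(meta$n_channels)
    ns <- as.integer(meta$n_samples)
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "double", n = nc * ns, size = 8L, endian = "little")
    if (length(vals) != nc * ns) {
      abort("Binary matrix is truncated.", class = "eegauth_format_error")
    }
    mat <- matrix(vals, nrow = nc, ncol = ns, byrow = TRUE)
  }
  eeg_recording(mat, fs = meta$fs, channel_labels = labels,
                subject_id = meta$subject_id)
}

#' Serialize a results bundle to JSON
#'
#' Writes one authentication run's results file: the full-montage benchmark
#' score, the impurity-importance channel ranking, the per-ablation-step
#' accuracies, and the training/classification wall-clock times, as a single
#' schema-versioned JSON document.
#'
#' @param bundle An `auth_results` object (see [auth_results()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(bundle, path) {
  stopifnot(inherits(bundle, "auth_results"))
  if (nrow(bundle$steps) == 0L) {
    abort("Results bundle has no ablation steps.", class = "eegauth_validation_error")
  }
  doc <- list(
    schema = "eegauth-results/1",
    genuine_subject = bundle$genuine_subject,
    band = bundle$band,
    benchmark = bundle$benchmark_accuracy,
    tuned_params = bundle$tuned_params,
    ranking = list(
      channel = bundle$ranking$channel,
      importance = bundle$ranking$importance
    ),
    steps = lapply(seq_len(nrow(bundle$steps)), function(i) {
      list(
        n_channels = bundle$steps$n_channels[i],
        channels_used = bundle$steps$channels_used[[i]],
        accuracy = bundle$steps$accuracy[i]
      )
    }),
    times = list(
      train = bundle$steps$train_time,
      classify = bundle$steps$classify_time
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a results bundle from JSON
#'
#' @param path Path to a JSON file written by [write_results()].
#' @return An `auth_results` object.
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "eegauth-results/1")) {
    abort("Unknown results schema version.", class = "eegauth_format_error")
  }
  ranking <- channel_ranking(
    importances = unname(vapply(doc$ranking$importance, as.numeric, 0)),
    channels = unname(vapply(doc$ranking$channel, as.character, "")),
    genuine_subject = doc$genuine_subject,
    band = doc$band
  )
  steps <- tibble::tibble(
    n_channels = unname(vapply(doc$steps, function(s) as.integer(s$n_channels), 0L)),
    channels_used = lapply(doc$steps, function(s) {
      unname(vapply(s$channels_used, as.character, ""))
    }),
    accuracy = unname(vapply(doc$steps, function(s) as.numeric(s$accuracy), 0)),
    train_time = unname(vapply(doc$times$train, as.numeric, 0)),
    classify_time = unname(vapply(doc$times$classify, as.numeric, 0))
  )
  auth_results(
    genuine_subject = doc$genuine_subject,
    band = doc$band,
    ranking = ranking,
    steps = steps,
    tuned_params = doc$tuned_params
  )
}
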
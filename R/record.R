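#' Multichannel EEG record
#'
#' A record is a channels-by-samples numeric matrix with a sampling rate and
#' channel labels. The channels-in-rows convention is used throughout the
#' package.
#'
#' @param data M x N numeric matrix, channels in rows.
#' @param fs sampling rate in Hz.
#' @param labels channel names; default `ch1..chM`. Must be unique.
#' @return object of class `eeg_record` with fields `data`, `fs`, `labels`.
#' @export
eeg_record <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop_invalid("record data must be finite")
  if (nrow(data) < 2L) stop_invalid("a record needs at least 2 channels")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_invalid("fs must be a positive scalar (Hz)")
  if (is.null(labels)) labels <- sprintf("ch%d", seq_len(nrow(data)))
  labels <- as.character(labels)
  if (length(labels) != nrow(data)) stop_invalid("one label per channel required")
  if (anyDuplicated(labels)) stop_invalid("channel labels must be unique")
  if (nrow(data) > ncol(data))
    warning("record has more channels (rows) than samples (columns); ",
            "data are interpreted channels-in-rows and never auto-transposed",
            call. = FALSE)
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels), class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat("<eeg_record> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz (", round(ncol(x$data) / x$fs, 3), " s)\n",
      sep = "")
  invisible(x)
}

#' Read a record from delimited text
#'
#' Format: one channel per row, first column the channel label, remaining
#' columns the samples; no header. A JSON sidecar `<path>.json` written by
#' [write_record()] supplies `fs` (and is overridden by the `fs` argument).
#'
#' @param path `.csv` or `.tsv` file.
#' @param fs sampling rate override in Hz; required when no sidecar exists.
#' @return an [eeg_record()].
#' @export
load_record <- function(path, fs = NULL) {
  if (!file.exists(path)) stop_invalid("record file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  sep <- switch(ext, csv = ",", tsv = "\t",
                stop_invalid("unsupported record format '.", ext,
                             "'; use .csv or .tsv"))
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  dat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(dat)) stop_invalid("non-numeric sample values in ", path)
  sidecar <- paste0(path, ".json")
  if (is.null(fs)) {
    if (!file.exists(sidecar))
      stop_invalid("sampling rate unknown: pass fs= or provide ", sidecar)
    fs <- jsonlite::read_json(sidecar)$fs
  }
  eeg_record(unname(dat), fs, labels)
}

#' Write a record to delimited text (with JSON sidecar carrying fs/labels)
#' @param record an [eeg_record()].
#' @param path destination `.csv` or `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  ext <- tolower(tools::file_ext(path))
  sep <- switch(ext, csv = ",", tsv = "\t",
                stop_invalid("unsupported record format '.", ext, "'"))
  df <- data.frame(label = record$labels, record$data, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(fs = record$fs, labels = record$labels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Check that a record's channels can be aligned with a montage; returns the
# montage row indices matching the record's channel order.
align_record_montage <- function(record, m) {
  idx <- match(record$labels, m$labels)
  if (anyNA(idx)) {
    if (nrow(record$data) == length(m$labels) &&
        all(grepl("^ch[0-9]+$", record$labels))) {
      return(seq_along(m$labels))   # default labels: positional alignment
    }
    stop_invalid("record channels not found in montage: ",
                 paste(record$labels[is.na(idx)], collapse = ", "))
  }
  idx
}
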
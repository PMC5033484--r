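#' Continuous multi-channel recording
#'
#' @param data channels x samples matrix (µV) with channel-name rownames.
#' @param sampling_rate Hz.
#' @param montage an `erp_montage` covering the rownames of `data`.
#' @param events trial tibble with `onset_ms` (and condition labels).
#' @param reference reference label, `"recording"` or `"average"`.
#' @param meta free-form metadata list.
#' @return an `erp_recording`.
#' @export
erp_recording <- function(data, sampling_rate, montage, events = NULL,
                          reference = "recording", meta = list()) {
  stopifnot(is.matrix(data), !is.null(rownames(data)), sampling_rate > 0)
  if (!all(rownames(data) %in% montage$name)) stop("data channels missing from montage")
  if (!is.null(events)) {
    dur_ms <- ncol(data) * 1000 / sampling_rate
    if (any(events$onset_ms < 0 | events$onset_ms > dur_ms))
      stop("event onsets outside recording extent")
  }
  structure(list(data = data, sampling_rate = sampling_rate, montage = montage,
                 events = events, reference = reference, meta = meta),
            class = "erp_recording")
}

#' @export
print.erp_recording <- function(x, ...) {
  cat(sprintf("<erp_recording: %d channels x %d samples @ %g Hz, %d events, ref=%s>\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              if (is.null(x$events)) 0L else nrow(x$events), x$reference))
  invisible(x)
}

#' Epoched data set
#'
#' @param data channels x time x trials array (µV), channel dimnames set.
#' @param times epoch time axis, ms relative to stimulus onset.
#' @param sampling_rate Hz.
#' @param montage an `erp_montage`.
#' @param trials per-trial label tibble (one row per kept trial), including a
#'   logical `kept` column once rejection has run.
#' @param rejection_log tibble of dropped/rejected trials with reason codes.
#' @param baseline_state whether baseline correction has been applied.
#' @return an `erp_epochs`.
#' @export
erp_epochs <- function(data, times, sampling_rate, montage, trials,
                       rejection_log = NULL, baseline_state = FALSE) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(times),
            dim(data)[3] == nrow(trials))
  structure(list(data = data, times = times, sampling_rate = sampling_rate,
                 montage = montage, trials = trials,
                 rejection_log = rejection_log %||% empty_rejection_log(),
                 baseline_state = baseline_state),
            class = "erp_epochs")
}

empty_rejection_log <- function() {
  tibble::tibble(subject = integer(0), block = integer(0), trial = integer(0),
                 channel = character(0), max_abs_uV = numeric(0), reason = character(0))
}

#' @export
print.erp_epochs <- function(x, ...) {
  kept <- if ("kept" %in% names(x$trials)) sum(x$trials$kept) else nrow(x$trials)
  cat(sprintf("<erp_epochs: %d ch x %d samples x %d trials (%d kept), [%g, %g) ms>\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], kept,
              min(x$times), max(x$times) + 1000 / x$sampling_rate))
  invisible(x)
}

#' Condition-average evoked response
#'
#' @param data channels x time matrix (µV), channel rownames set.
#' @param times time axis, ms.
#' @param sampling_rate Hz.
#' @param montage an `erp_montage`.
#' @param condition named list of condition labels.
#' @param n_trials number of trials averaged.
#' @param reference `"recording"` or `"average"`.
#' @param subject optional subject id.
#' @return an `erp_evoked`.
#' @export
erp_evoked <- function(data, times, sampling_rate, montage, condition = list(),
                       n_trials = NA_integer_, reference = "recording", subject = NA_integer_) {
  stopifnot(is.matrix(data), ncol(data) == length(times), !is.null(rownames(data)))
  structure(list(data = data, times = times, sampling_rate = sampling_rate,
                 montage = montage, condition = condition, n_trials = n_trials,
                 reference = reference, subject = subject),
            class = "erp_evoked")
}

#' @export
print.erp_evoked <- function(x, ...) {
  lab <- paste(unlist(x$condition), collapse = "/")
  cat(sprintf("<erp_evoked %s: %d ch x %d samples, n=%s, ref=%s>\n",
              lab, nrow(x$data), ncol(x$data), x$n_trials, x$reference))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# column values at idx, or NA (or a supplied default) when the column is absent
col_or <- function(df, col, idx, default = NA) {
  if (!is.null(df) && col %in% names(df)) df[[col]][idx]
  else if (length(default) == 1) rep(default, length(idx)) else default
}

#' Write / read an evoked response as TSV + JSON sidecar
#'
#' The TSV holds the channels x time matrix (row names = channels, one column
#' per sample); the sidecar carries the time axis and labels.
#'
#' @param ev an `erp_evoked`.
#' @param path TSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_evoked <- function(ev, path) {
  utils::write.table(ev$data, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  meta <- list(times = ev$times, sampling_rate = ev$sampling_rate,
               condition = ev$condition, n_trials = ev$n_trials,
               reference = ev$reference, subject = ev$subject)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_evoked
#' @param montage montage to attach on read.
#' @export
read_evoked <- function(path, montage) {
  m <- as.matrix(utils::read.table(path, sep = "\t", row.names = 1))
  colnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  erp_evoked(m, times = meta$times, sampling_rate = meta$sampling_rate,
             montage = montage, condition = as.list(meta$condition),
             n_trials = meta$n_trials, reference = meta$reference,
             subject = meta$subject %||% NA_integer_)
}

#' Write / read an epoch set as a plain-text container
#'
#' The channels x time x trials array is flattened trial-major into a TSV
#' (rows = channels, columns = time within trial, trials concatenated), with a
#' JSON sidecar holding dimensions, the time axis and the trial labels (as an
#' adjacent TSV).
#'
#' @param ep an `erp_epochs`.
#' @param path base path; writes `<path>.tsv`, `<path>.json`,
#'   `<path>_trials.tsv`.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(ep, path) {
  d <- ep$data
  flat <- matrix(d, nrow = dim(d)[1])
  rownames(flat) <- dimnames(d)[[1]]
  utils::write.table(flat, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  utils::write.table(ep$trials, paste0(path, "_trials.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(n_channels = dim(d)[1], n_times = dim(d)[2], n_trials = dim(d)[3],
               times = ep$times, sampling_rate = ep$sampling_rate,
               baseline_state = ep$baseline_state)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @param montage montage to attach on read.
#' @export
read_epochs <- function(path, montage) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t", row.names = 1))
  trials <- tibble::as_tibble(utils::read.table(paste0(path, "_trials.tsv"),
                                                sep = "\t", header = TRUE))
  d <- array(flat, dim = c(meta$n_channels, meta$n_times, meta$n_trials),
             dimnames = list(rownames(flat), NULL, NULL))
  erp_epochs(d, times = meta$times, sampling_rate = meta$sampling_rate,
             montage = montage, trials = trials, baseline_state = meta$baseline_state)
}

#' Write an event/behaviour table as tab-delimited text
#'
#' @param events tibble with at least `onset_ms`, `role`, `category`, `colour`.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}
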
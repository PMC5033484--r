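#' Zero-phase low-pass filter
#'
#' 4th-order digital Butterworth run forward and backward
#' (`signal::filtfilt`), giving a combined 48 dB/octave roll-off with zero
#' group delay and unit DC gain — the standard offline ERP low-pass.
#'
#' @param rec an `erp_recording`.
#' @param cutoff -3 dB (per pass) cutoff frequency, Hz; must be below Nyquist.
#' @param order per-pass Butterworth order (default 4).
#' @return filtered `erp_recording` (filter realization noted in `meta`).
#' @export
lowpass_filter <- function(rec, cutoff = 30, order = 4) {
  nyq <- rec$sampling_rate / 2
  if (cutoff >= nyq) stop(sprintf("cutoff %g Hz >= Nyquist %g Hz", cutoff, nyq))
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  n <- ncol(rec$data)
  pad <- min(n - 1, ceiling(12 * rec$sampling_rate / cutoff))
  out <- t(apply(rec$data, 1, function(x) {
    # odd reflection at both ends suppresses filtfilt edge transients
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - pad)]
    y <- signal::filtfilt(bf, c(left, x, right))
    y[(pad + 1):(pad + n)]
  }))
  rownames(out) <- rownames(rec$data)
  rec$data <- out
  rec$meta$filter <- list(type = "butterworth", order = order, cutoff_hz = cutoff,
                          realization = "forward-backward (zero phase), 48 dB/oct combined")
  rec
}

#' Detect blink events on the EOG channel
#'
#' Local maxima of the EOG trace exceeding a z-score threshold, separated by a
#' minimum interval.
#'
#' @param rec an `erp_recording` containing the EOG channel.
#' @param eog_channel channel name (default `"VEOG"`).
#' @param z_threshold detection threshold in robust z units (default 3).
#' @param min_separation_ms minimum spacing between detected blinks.
#' @return integer vector of 1-based sample indices of blink maxima.
#' @export
detect_blinks <- function(rec, eog_channel = "VEOG", z_threshold = 3,
                          min_separation_ms = 400) {
  if (!eog_channel %in% rownames(rec$data)) stop(sprintf("EOG channel %s not present", eog_channel))
  x <- rec$data[eog_channel, ]
  med <- stats::median(x)
  s <- stats::mad(x)
  if (s < .Machine$double.eps) return(integer(0))
  z <- (x - med) / s
  above <- which(z > z_threshold)
  if (length(above) == 0) return(integer(0))
  min_gap <- round(min_separation_ms * rec$sampling_rate / 1000)
  # split threshold crossings into events, take the per-event maximum
  splits <- cumsum(c(1, diff(above) > min_gap / 2))
  peaks <- vapply(split(above, splits), function(idx) idx[which.max(x[idx])], integer(1))
  sort(unname(peaks))
}

#' Regression-based ocular artifact correction
#'
#' Estimates per-channel blink propagation coefficients by regressing each
#' scalp channel on the EOG over segments around detected blink maxima, then
#' subtracts `coefficient x EOG` from the whole recording. Before the
#' regression, the stimulus-locked average response (computed over the
#' recording's own events, when present) is subtracted so evoked activity does
#' not bias the coefficients, and each blink segment is demeaned.
#'
#' @param rec an `erp_recording`.
#' @param eog_channel EOG channel name.
#' @param blink_events sample indices of blink maxima; `NULL` auto-detects via
#'   [detect_blinks()]. With no blinks the recording is returned unchanged.
#' @param window_ms half-width of the blink segment around each maximum.
#' @param z_threshold passed to [detect_blinks()].
#' @return corrected `erp_recording` with `meta$blink_coefficients` and
#'   `meta$n_blinks` set.
#' @export
correct_ocular <- function(rec, eog_channel = "VEOG", blink_events = NULL,
                           window_ms = 200, z_threshold = 3) {
  if (!eog_channel %in% rownames(rec$data)) stop(sprintf("EOG channel %s not present", eog_channel))
  if (is.null(blink_events)) blink_events <- detect_blinks(rec, eog_channel, z_threshold)
  if (length(blink_events) == 0) {
    rec$meta$blink_coefficients <- NULL
    rec$meta$n_blinks <- 0L
    return(rec)
  }
  fs <- rec$sampling_rate
  hw <- round(window_ms * fs / 1000)
  n <- ncol(rec$data)
  scalp <- setdiff(rownames(rec$data), eog_channel)

  work <- rec$data
  # remove the stimulus-locked average so evoked activity does not enter the fit
  if (!is.null(rec$events) && nrow(rec$events) > 0) {
    win <- c(-100, 500)
    rel <- seq(round(win[1] * fs / 1000), round(win[2] * fs / 1000) - 1)
    onsets <- round(rec$events$onset_ms * fs / 1000) + 1
    ok <- onsets + rel[1] >= 1 & onsets + rel[length(rel)] <= n
    onsets <- onsets[ok]
    if (length(onsets) > 0) {
      acc <- matrix(0, nrow(work), length(rel))
      for (o in onsets) acc <- acc + work[, o + rel]
      acc <- acc / length(onsets)
      for (o in onsets) work[, o + rel] <- work[, o + rel] - acc
    }
  }

  seg_idx <- unique(unlist(lapply(blink_events, function(b) {
    seq(max(1, b - hw), min(n, b + hw))
  })))
  eog_seg <- work[eog_channel, seg_idx]
  eog_seg <- eog_seg - mean(eog_seg)
  v <- sum(eog_seg^2)
  if (v / length(eog_seg) < 1e-12) {
    warning("EOG variance ~ 0 over blink segments; returning data unchanged")
    rec$meta$blink_coefficients <- NULL
    rec$meta$n_blinks <- length(blink_events)
    return(rec)
  }
  seg <- work[scalp, seg_idx, drop = FALSE]
  seg <- seg - rowMeans(seg)
  coef <- as.vector(seg %*% eog_seg) / v
  names(coef) <- scalp

  rec$data[scalp, ] <- rec$data[scalp, , drop = FALSE] -
    outer(coef, rec$data[eog_channel, ])
  rec$meta$blink_coefficients <- coef
  rec$meta$n_blinks <- length(blink_events)
  rec
}

#' Cut a continuous recording into baseline-corrected epochs
#'
#' Epoch windows are half-open `[start, end)` in ms relative to each event
#' onset; at 1 kHz the default `[-100, 500)` window yields 600 samples. The
#' per-trial, per-channel mean over the (half-open) baseline window is
#' subtracted. Events too close to the recording edge are dropped and logged.
#'
#' @param rec an `erp_recording` with events.
#' @param window epoch window `[start, end)`, ms.
#' @param baseline baseline window `[start, end)`, ms; `NULL` skips baseline
#'   correction.
#' @return an `erp_epochs` (EOG channel retained for reference; drop it at
#'   averaging).
#' @export
make_epochs <- function(rec, window = c(-100, 500), baseline = c(-100, 0)) {
  if (is.null(rec$events) || nrow(rec$events) == 0) stop("recording has no events")
  fs <- rec$sampling_rate
  dt <- 1000 / fs
  rel <- seq(round(window[1] / dt), round(window[2] / dt) - 1)
  times <- rel * dt
  onsets <- round(rec$events$onset_ms / dt) + 1
  n <- ncol(rec$data)
  ok <- onsets + rel[1] >= 1 & onsets + rel[length(rel)] <= n
  dropped <- which(!ok)
  log <- empty_rejection_log()
  if (length(dropped) > 0) {
    log <- tibble::tibble(
      subject = as.integer(col_or(rec$events, "subject", dropped)),
      block = as.integer(col_or(rec$events, "block", dropped)),
      trial = as.integer(col_or(rec$events, "trial", dropped, default = dropped)),
      channel = NA_character_, max_abs_uV = NA_real_, reason = "edge"
    )
  }
  keep <- which(ok)
  d <- array(NA_real_, dim = c(nrow(rec$data), length(rel), length(keep)),
             dimnames = list(rownames(rec$data), NULL, NULL))
  for (i in seq_along(keep)) d[, , i] <- rec$data[, onsets[keep[i]] + rel]
  trials <- rec$events[keep, , drop = FALSE]
  baselined <- FALSE
  if (!is.null(baseline)) {
    bidx <- which(times >= baseline[1] & times < baseline[2])
    if (length(bidx) == 0) stop("baseline window contains no samples")
    for (i in seq_len(dim(d)[3])) {
      d[, , i] <- d[, , i] - rowMeans(d[, bidx, i, drop = FALSE])
    }
    baselined <- TRUE
  }
  trials$kept <- TRUE
  erp_epochs(d, times = times, sampling_rate = fs, montage = rec$montage,
             trials = trials, rejection_log = log, baseline_state = baselined)
}

#' Amplitude-threshold artifact rejection
#'
#' Flags every epoch whose absolute voltage exceeds the threshold on any scalp
#' channel (the EOG channel is excluded from the screen). Kept data are
#' unchanged; rejected trials are recorded in the rejection log with the
#' offending channel and its maximal absolute value.
#'
#' @param ep an `erp_epochs` (baseline-corrected).
#' @param threshold rejection threshold, µV (default 75, i.e. the ±75 µV screen).
#' @return `erp_epochs` with updated `kept` mask and rejection log.
#' @export
reject_artifacts <- function(ep, threshold = 75) {
  if (!ep$baseline_state) stop("reject_artifacts expects baseline-corrected epochs")
  ch <- dimnames(ep$data)[[1]]
  scalp <- ch[ch %in% scalp_channels(ep$montage)]
  rows <- match(scalp, ch)
  new_log <- list()
  for (i in seq_len(dim(ep$data)[3])) {
    if (!ep$trials$kept[i]) next
    m <- abs(ep$data[rows, , i, drop = FALSE])
    mx <- max(m)
    if (mx > threshold) {
      ep$trials$kept[i] <- FALSE
      wch <- scalp[which(m == mx, arr.ind = TRUE)[1, 1]]
      new_log[[length(new_log) + 1]] <- tibble::tibble(
        subject = as.integer(col_or(ep$trials, "subject", i)),
        block = as.integer(col_or(ep$trials, "block", i)),
        trial = as.integer(ep$trials$trial[i]),
        channel = wch, max_abs_uV = mx, reason = "amplitude"
      )
    }
  }
  if (length(new_log) > 0) {
    ep$rejection_log <- dplyr::bind_rows(ep$rejection_log, dplyr::bind_rows(new_log))
  }
  ep
}

#' Average kept (and correct) trials of a condition
#'
#' Arithmetic mean over epochs matching the condition filter that survived
#' rejection and, optionally, were answered correctly (requires a `correct`
#' column merged into the trial table). The EOG channel is dropped.
#'
#' @param ep an `erp_epochs`.
#' @param condition named list of trial-column values to match, e.g.
#'   `list(role = "target", category = "face")`.
#' @param correct_only average correct trials only (default `TRUE` when a
#'   `correct` column is present).
#' @return an `erp_evoked` (recording reference).
#' @export
average_condition <- function(ep, condition = list(),
                              correct_only = "correct" %in% names(ep$trials)) {
  sel <- ep$trials$kept
  for (f in names(condition)) sel <- sel & ep$trials[[f]] == condition[[f]]
  if (correct_only) {
    if (!"correct" %in% names(ep$trials)) stop("correct_only=TRUE but no 'correct' column")
    sel <- sel & ep$trials$correct
  }
  idx <- which(sel)
  if (length(idx) == 0) {
    subj <- unique(col_or(ep$trials, "subject", seq_len(nrow(ep$trials))))
    stop(sprintf("no surviving trials for subject %s, condition %s",
                 paste(subj, collapse = ","),
                 paste(names(condition), unlist(condition), sep = "=", collapse = ", ")))
  }
  ch <- dimnames(ep$data)[[1]]
  scalp <- ch[ch %in% scalp_channels(ep$montage)]
  avg <- apply(ep$data[match(scalp, ch), , idx, drop = FALSE], c(1, 2), mean)
  rownames(avg) <- scalp
  erp_evoked(avg, times = ep$times, sampling_rate = ep$sampling_rate,
             montage = ep$montage, condition = condition,
             n_trials = length(idx), reference = "recording",
             subject = unique(col_or(ep$trials, "subject", seq_len(nrow(ep$trials))))[1])
}

#' Re-reference an evoked response to the common average
#'
#' Subtracts the instantaneous mean over scalp channels, making the channel
#' mean zero at every timepoint. Idempotent; leaves GFP unchanged.
#'
#' @param ev an `erp_evoked`.
#' @return `erp_evoked` with `reference = "average"`.
#' @export
rereference_average <- function(ev) {
  ev$data <- sweep(ev$data, 2, colMeans(ev$data))
  ev$reference <- "average"
  ev
}

#' Grand average of per-subject evoked responses
#'
#' Unweighted subject mean. All inputs must share montage, time axis and
#' reference state.
#'
#' @param evs list of `erp_evoked` (one per subject), typically
#'   average-referenced.
#' @return an `erp_evoked` with `n_trials` = number of subjects.
#' @export
grand_average <- function(evs) {
  stopifnot(length(evs) >= 1)
  ref <- evs[[1]]
  for (ev in evs[-1]) {
    if (!identical(rownames(ev$data), rownames(ref$data)))
      stop("montage mismatch across evoked inputs")
    if (!isTRUE(all.equal(ev$times, ref$times)))
      stop("time-axis mismatch across evoked inputs")
  }
  acc <- Reduce(`+`, lapply(evs, `[[`, "data")) / length(evs)
  erp_evoked(acc, times = ref$times, sampling_rate = ref$sampling_rate,
             montage = ref$montage, condition = ref$condition,
             n_trials = length(evs), reference = ref$reference)
}

#' Preprocess one subject's simulated session into condition averages
#'
#' Runs the standard chain per block — zero-phase 30 Hz low-pass, ocular
#' regression correction, epoching with baseline, ±threshold rejection — then
#' pools blocks and averages kept correct trials per condition, re-referencing
#' each evoked to the common average.
#'
#' @param subject_data output of [simulate_subject()].
#' @param lowpass cutoff Hz.
#' @param reject_threshold µV.
#' @param window,baseline epoch and baseline windows, ms.
#' @param conditions tibble of condition label combinations (columns matched
#'   against trial columns); `NULL` derives all observed role x category x
#'   colour cells.
#' @param correct_only average correct trials only.
#' @return list: `evokeds` (named list of average-referenced `erp_evoked`),
#'   `rejection_log`, `blink_coefficients` (per block).
#' @export
preprocess_subject <- function(subject_data, lowpass = 30, reject_threshold = 75,
                               window = c(-100, 500), baseline = c(-100, 0),
                               conditions = NULL, correct_only = TRUE) {
  beh <- subject_data$behavior
  eps <- list(); logs <- list(); coefs <- list()
  for (rec in subject_data$recordings) {
    rec <- lowpass_filter(rec, lowpass)
    rec <- correct_ocular(rec)
    coefs[[length(coefs) + 1]] <- rec$meta$blink_coefficients
    ep <- make_epochs(rec, window, baseline)
    # merge behavioural outcomes into the trial table
    key <- paste(ep$trials$block, ep$trials$trial)
    bkey <- paste(beh$block, beh$trial)
    ep$trials$correct <- beh$correct[match(key, bkey)]
    ep$trials$rt_ms <- beh$rt_ms[match(key, bkey)]
    ep <- reject_artifacts(ep, reject_threshold)
    eps[[length(eps) + 1]] <- ep
    logs[[length(logs) + 1]] <- ep$rejection_log
  }
  pooled <- pool_epochs(eps)
  if (is.null(conditions)) {
    conditions <- unique(pooled$trials[, c("role", "category", "colour")])
  }
  evokeds <- list()
  for (i in seq_len(nrow(conditions))) {
    cond <- as.list(conditions[i, ])
    id <- paste(unlist(cond), collapse = "_")
    ev <- average_condition(pooled, cond, correct_only = correct_only)
    evokeds[[id]] <- rereference_average(ev)
  }
  list(evokeds = evokeds, rejection_log = dplyr::bind_rows(logs),
       blink_coefficients = coefs)
}

# Concatenate epoch sets sharing channels/time axis along the trial dimension.
pool_epochs <- function(eps) {
  stopifnot(length(eps) >= 1)
  ref <- eps[[1]]
  if (length(eps) == 1) return(ref)
  datas <- lapply(eps, `[[`, "data")
  d <- array(unlist(datas), dim = c(dim(ref$data)[1], dim(ref$data)[2],
                                    sum(vapply(datas, function(x) dim(x)[3], numeric(1)))),
             dimnames = list(dimnames(ref$data)[[1]], NULL, NULL))
  trials <- dplyr::bind_rows(lapply(eps, `[[`, "trials"))
  erp_epochs(d, ref$times, ref$sampling_rate, ref$montage, trials,
             rejection_log = dplyr::bind_rows(lapply(eps, `[[`, "rejection_log")),
             baseline_state = all(vapply(eps, `[[`, logical(1), "baseline_state")))
}
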
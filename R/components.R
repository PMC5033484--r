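#' ERP component definition
#'
#' @param name component label.
#' @param polarity `"+"` (e.g. P1) or `"-"` (e.g. N170).
#' @param search_window peak search window, ms. Defaults enclose the grand-
#'   average latency ranges of the emulated study (P1 114-119 ms, N170
#'   159-170 ms).
#' @param electrode_set channel names of the analysis ROI.
#' @param mean_amp_halfwidth half-width of the mean-amplitude window around
#'   the peak, ms (default 20, i.e. a 40 ms window).
#' @return list of class `component_def`.
#' @export
component_def <- function(name, polarity = c("+", "-"), search_window,
                          electrode_set, mean_amp_halfwidth = 20) {
  polarity <- match.arg(polarity)
  stopifnot(length(search_window) == 2, search_window[1] < search_window[2],
            mean_amp_halfwidth > 0, length(electrode_set) >= 1)
  structure(list(name = name, polarity = polarity, search_window = search_window,
                 electrode_set = electrode_set, mean_amp_halfwidth = mean_amp_halfwidth),
            class = "component_def")
}

#' @rdname component_def
#' @export
p1_component <- function() {
  component_def("P1", "+", c(80, 160),
                c("O1", "O2", "OZ", "POZ", "PO3", "PO4"))
}

#' @rdname component_def
#' @export
n170_component <- function() {
  component_def("N170", "-", c(130, 210),
                c("CB1", "CB2", "P7", "P8", "PO5", "PO6", "PO7", "PO8"))
}

#' Find a component peak in the ROI-mean waveform
#'
#' The ROI-mean waveform (mean over the component's electrode set) is scanned
#' within the search window for local extrema of the required polarity whose
#' value has the matching sign; the *first* (earliest) such extremum is
#' returned, matching the convention of marking the first observable peak.
#' Plateaus count once, at their first sample. If no qualifying extremum
#' exists the result is flagged missing rather than silently returning a
#' window edge.
#'
#' @param ev an `erp_evoked`.
#' @param comp a `component_def` whose electrodes all exist in the evoked.
#' @return list: `latency` (ms), `amplitude` (µV, ROI mean at the peak),
#'   `missing` (logical).
#' @export
find_peak <- function(ev, comp) {
  missing_el <- setdiff(comp$electrode_set, rownames(ev$data))
  if (length(missing_el) > 0)
    stop(sprintf("electrodes not in evoked: %s", paste(missing_el, collapse = ", ")))
  w <- colMeans(ev$data[comp$electrode_set, , drop = FALSE])
  sgn <- if (comp$polarity == "+") 1 else -1
  x <- sgn * w
  t_ok <- ev$times >= comp$search_window[1] & ev$times <= comp$search_window[2]
  n <- length(x)
  for (i in which(t_ok)) {
    if (i <= 1 || i >= n) next
    left <- x[i] > x[i - 1]
    right <- x[i] >= x[i + 1]
    if (left && right && x[i] > 0) {
      return(list(latency = ev$times[i], amplitude = w[i], missing = FALSE))
    }
  }
  list(latency = NA_real_, amplitude = NA_real_, missing = TRUE)
}

#' Mean amplitude in a window around a peak
#'
#' Per-electrode mean over `[peak - hw, peak + hw]` ms (closed interval; the
#' default half-width of 20 ms gives the conventional 40 ms window).
#'
#' @param ev an `erp_evoked`.
#' @param comp a `component_def`.
#' @param peak_latency peak latency, ms.
#' @return named numeric vector of per-electrode mean amplitudes, µV.
#' @export
mean_amplitude <- function(ev, comp, peak_latency) {
  hw <- comp$mean_amp_halfwidth
  lo <- peak_latency - hw
  hi <- peak_latency + hw
  dt <- 1000 / ev$sampling_rate
  if (lo < min(ev$times) - dt / 2 || hi > max(ev$times) + dt / 2)
    stop(sprintf("mean-amplitude window [%g, %g] ms clipped by epoch [%g, %g] ms",
                 lo, hi, min(ev$times), max(ev$times)))
  idx <- which(ev$times >= lo - dt / 2 & ev$times <= hi + dt / 2)
  rowMeans(ev$data[comp$electrode_set, idx, drop = FALSE])
}

#' Measure component peaks and mean amplitudes across subjects and conditions
#'
#' For every subject x condition evoked, finds the component peak on the
#' ROI-mean waveform and takes the per-electrode 40 ms mean amplitude around
#' it. Missing peaks are flagged (`peak_missing`), left `NA`, and reported
#' with a warning.
#'
#' @param evokeds nested list `[[subject]][[condition_id]]` of `erp_evoked`s.
#' @param comps list of `component_def`s.
#' @param conditions tibble with `condition_id` plus condition label columns.
#' @return measurement tibble: one row per subject x condition x component x
#'   electrode with `peak_latency`, `peak_amplitude`, `mean_amplitude`,
#'   `peak_missing`.
#' @export
measure_components <- function(evokeds, comps, conditions) {
  rows <- list()
  n_missing <- 0L
  for (s in seq_along(evokeds)) {
    for (ci in seq_len(nrow(conditions))) {
      id <- conditions$condition_id[ci]
      ev <- evokeds[[s]][[id]]
      if (is.null(ev)) stop(sprintf("missing evoked: subject %d, condition %s", s, id))
      for (comp in comps) {
        pk <- find_peak(ev, comp)
        if (pk$missing) {
          n_missing <- n_missing + 1L
          ma <- stats::setNames(rep(NA_real_, length(comp$electrode_set)), comp$electrode_set)
        } else {
          ma <- mean_amplitude(ev, comp, pk$latency)
        }
        lab <- conditions[ci, setdiff(names(conditions), "condition_id"), drop = FALSE]
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = s, condition_id = id, lab,
          component = comp$name, electrode = comp$electrode_set,
          peak_latency = pk$latency, peak_amplitude = pk$amplitude,
          mean_amplitude = unname(ma), peak_missing = pk$missing
        )
      }
    }
  }
  if (n_missing > 0)
    warning(sprintf("%d subject x condition cells had no qualifying peak; flagged NA", n_missing))
  dplyr::bind_rows(rows)
}

#' Map posterior electrodes to the Location/Site and Hemisphere/Site factors
#'
#' The P1 model splits its six electrodes into Location (occipital O1/OZ/O2
#' vs parieto-occipital PO3/POZ/PO4) by Site (3 levels); the N170 model splits
#' its eight into Hemisphere (left CB1/P7/PO5/PO7 vs right CB2/P8/PO6/PO8) by
#' Site (4 levels).
#'
#' @param electrodes character vector of electrode names.
#' @param scheme `"p1"` or `"n170"`.
#' @return tibble `electrode`, plus `location`+`site` (p1) or
#'   `hemisphere`+`site` (n170).
#' @export
electrode_factors <- function(electrodes, scheme = c("p1", "n170")) {
  scheme <- match.arg(scheme)
  if (scheme == "p1") {
    map <- tibble::tribble(
      ~electrode, ~location, ~site,
      "O1", "occipital", "1", "OZ", "occipital", "2", "O2", "occipital", "3",
      "PO3", "parieto-occipital", "1", "POZ", "parieto-occipital", "2",
      "PO4", "parieto-occipital", "3")
  } else {
    map <- tibble::tribble(
      ~electrode, ~hemisphere, ~site,
      "CB1", "left", "1", "P7", "left", "2", "PO5", "left", "3", "PO7", "left", "4",
      "CB2", "right", "1", "P8", "right", "2", "PO6", "right", "3", "PO8", "right", "4")
  }
  out <- map[match(electrodes, map$electrode), ]
  if (anyNA(out$electrode)) stop("electrode not covered by factor scheme")
  out
}

#' Behavioural accuracy and reaction-time ANOVAs
#'
#' Deviant-only repeated-measures ANOVAs with factors Deviant (non-target,
#' target) x Category x Colour: accuracy as the per-cell proportion correct,
#' RT as the per-cell mean of correct responses after removing responses
#' below the floor.
#'
#' @param beh behavioural tibble (from [simulate_behavior()]), pooled over
#'   subjects, with columns `subject`, `role`, `category`, `colour`,
#'   `correct`, `rt_ms`.
#' @param rt_floor responses faster than this (ms) are excluded from RT.
#' @return list of two ANOVA tables (`accuracy`, `rt`), see [rm_anova()].
#' @export
behavior_stats <- function(beh, rt_floor = 100) {
  dev <- beh[beh$role %in% c("nontarget", "target"), ]
  acc <- dplyr::summarise(
    dplyr::group_by(dev, .data$subject, .data$role, .data$category, .data$colour),
    accuracy = mean(.data$correct), .groups = "drop")
  rtd <- dev[dev$correct & dev$rt_ms >= rt_floor, ]
  rt <- dplyr::summarise(
    dplyr::group_by(rtd, .data$subject, .data$role, .data$category, .data$colour),
    rt = mean(.data$rt_ms), .groups = "drop")
  n_cells <- length(unique(dev$role)) * length(unique(dev$category)) * length(unique(dev$colour))
  counts <- table(rt$subject)
  if (any(counts < n_cells)) {
    bad <- names(counts)[counts < n_cells]
    stop(sprintf("subject(s) %s have empty RT cells after filtering", paste(bad, collapse = ", ")))
  }
  list(
    accuracy = rm_anova(acc, dv = "accuracy", subject = "subject",
                        within = c("role", "category", "colour")),
    rt = rm_anova(rt, dv = "rt", subject = "subject",
                  within = c("role", "category", "colour"))
  )
}
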
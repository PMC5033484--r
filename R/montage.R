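#' Default 64-channel scalp montage (extended 10-20) plus a vertical EOG channel
#'
#' Builds an idealized spherical montage for the 64 Ag/AgCl scalp channels used
#' throughout the package, with standard extended 10-20 names. Positions are
#' generated on a unit sphere from each electrode's sagittal row (FP through CB)
#' and lateral index, which yields a geometrically sensible layout (front-back
#' gradients, occipital clustering) without reproducing any manufacturer's
#' digitized coordinates. A `VEOG` channel is placed above the eyes; it is not a
#' scalp channel and is excluded from topographic statistics.
#'
#' @param include_eog add the `VEOG` channel (default `TRUE`).
#' @return A tibble of class `erp_montage` with columns `name`, `x` (right),
#'   `y` (front), `z` (up) and logical `eog`.
#' @export
default_montage <- function(include_eog = TRUE) {
  rows <- list(
    FP = list(angle = 72,  labels = c("FP1", "FPZ", "FP2")),
    AF = list(angle = 54,  labels = c("AF7", "AF3", "AF4", "AF8")),
    F  = list(angle = 36,  labels = c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8")),
    FC = list(angle = 18,  labels = c("FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8")),
    C  = list(angle = 0,   labels = c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8")),
    CP = list(angle = -18, labels = c("TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8")),
    P  = list(angle = -36, labels = c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8")),
    PO = list(angle = -54, labels = c("PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8")),
    O  = list(angle = -72, labels = c("O1", "OZ", "O2")),
    CB = list(angle = -81, labels = c("CB1", "CB2"))
  )
  out <- lapply(rows, function(r) {
    pos <- t(vapply(r$labels, electrode_xyz, numeric(3), row_angle = r$angle))
    tibble::tibble(name = r$labels, x = unname(pos[, 1]),
                   y = unname(pos[, 2]), z = unname(pos[, 3]))
  })
  mon <- dplyr::bind_rows(out)
  mon$eog <- FALSE
  if (include_eog) {
    mon <- dplyr::bind_rows(mon, tibble::tibble(
      name = "VEOG", x = 0.1, y = 0.97, z = -0.22, eog = TRUE
    ))
  }
  class(mon) <- c("erp_montage", class(mon))
  mon
}

# Unit-sphere position from sagittal row angle (deg from vertex, + = front)
# and the electrode label's lateral index (odd = left, even = right, Z = midline).
electrode_xyz <- function(label, row_angle) {
  num <- suppressWarnings(as.integer(gsub("[^0-9]", "", label)))
  if (is.na(num)) {              # midline
    lat <- 0
    side <- 0
  } else {
    lat <- 22.5 * ceiling(num / 2)
    side <- if (num %% 2 == 1) -1 else 1
  }
  a <- row_angle * pi / 180
  l <- side * lat * pi / 180
  c(cos(a) * sin(l), sin(a), cos(a) * cos(l))
}

#' @export
print.erp_montage <- function(x, ...) {
  cat(sprintf("<erp_montage: %d scalp + %d EOG channels>\n",
              sum(!x$eog), sum(x$eog)))
  NextMethod()
}

#' Scalp channel names of a montage
#' @param montage an `erp_montage`.
#' @return character vector of non-EOG channel names.
#' @export
scalp_channels <- function(montage) montage$name[!montage$eog]

#' Pairwise 3-D distances between montage channels
#' @param montage an `erp_montage`.
#' @param channels optional subset of channel names.
#' @return symmetric distance matrix with channel-name dimnames.
#' @export
channel_distances <- function(montage, channels = NULL) {
  if (!is.null(channels)) montage <- montage[match(channels, montage$name), , drop = FALSE]
  p <- as.matrix(montage[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(p))
  dimnames(d) <- list(montage$name, montage$name)
  d
}

#' Write a montage to an .sfp electrode-location file
#'
#' Plain text, one electrode per line: `name x y z`.
#' @param montage an `erp_montage`.
#' @param path output file path.
#' @export
write_sfp <- function(montage, path) {
  lines <- sprintf("%s\t%.6f\t%.6f\t%.6f", montage$name, montage$x, montage$y, montage$z)
  writeLines(lines, path)
  invisible(path)
}

#' Read an .sfp electrode-location file
#' @param path file path; whitespace-delimited `name x y z` lines.
#' @param eog_channels names to flag as EOG (default `"VEOG"`).
#' @return an `erp_montage` tibble.
#' @export
read_sfp <- function(path, eog_channels = "VEOG") {
  tab <- utils::read.table(path, header = FALSE, col.names = c("name", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  mon <- tibble::as_tibble(tab)
  mon$eog <- mon$name %in% eog_channels
  class(mon) <- c("erp_montage", class(mon))
  mon
}

#' Smooth scalp topography centred on named channels
#'
#' Builds a component topography as a sum of spherical Gaussians centred on the
#' given channels, then removes the channel mean (average-reference consistent)
#' and rescales to unit global field power. Only scalp channels get nonzero
#' loadings before centring; the EOG channel, if present in the montage, is
#' excluded.
#'
#' @param montage an `erp_montage`.
#' @param centers channel names at the topography's extremum.
#' @param width Gaussian width in unit-sphere distance (default 0.5).
#' @param sign `+1` for a positivity (P1-like), `-1` for a negativity (N1-like).
#' @return named numeric vector over scalp channels: zero mean, unit GFP.
#' @export
gaussian_topography <- function(montage, centers, width = 0.5, sign = 1) {
  ch <- scalp_channels(montage)
  stopifnot(all(centers %in% ch))
  d <- channel_distances(montage, ch)
  v <- rowSums(exp(-(d[, centers, drop = FALSE]^2) / (2 * width^2)))
  v <- sign * v
  v <- v - mean(v)
  g <- sqrt(mean(v^2))
  if (g < .Machine$double.eps) stop("degenerate topography: zero field power")
  out <- v / g
  names(out) <- ch
  out
}
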
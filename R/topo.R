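#' Global field power
#'
#' Spatial root-mean-square of an average-referenced scalp map — a
#' reference-free index of instantaneous signal strength. For a matrix
#' (channels x time) the GFP is returned per timepoint; for an `erp_evoked`
#' it is computed on its data matrix.
#'
#' @param x numeric vector (one map), channels x time matrix, or `erp_evoked`.
#' @return non-negative scalar or per-timepoint vector, µV.
#' @export
gfp <- function(x) {
  if (inherits(x, "erp_evoked")) x <- x$data
  if (is.matrix(x)) return(sqrt(colMeans(x^2)))
  sqrt(mean(x^2))
}

#' Spatial correlation between two maps
#'
#' Cosine similarity of average-referenced maps (equal to their Pearson
#' correlation when both have zero channel mean).
#'
#' @param u,v numeric vectors over the same channels.
#' @return correlation in `[-1, 1]`.
#' @export
spatial_correlation <- function(u, v) {
  sum(u * v) / sqrt(sum(u^2) * sum(v^2))
}

#' Global map dissimilarity (DISS)
#'
#' Root-mean-square difference between two GFP-normalized average-referenced
#' maps: 0 for proportional maps of the same polarity, 2 for an exact
#' polarity reversal, and `DISS^2 = 2 (1 - spatial correlation)` in general.
#'
#' @param u,v average-referenced maps over the same channels, nonzero GFP.
#' @return dissimilarity in `[0, 2]`.
#' @export
dissimilarity <- function(u, v) {
  gu <- gfp(u); gv <- gfp(v)
  if (gu < .Machine$double.eps || gv < .Machine$double.eps)
    stop("dissimilarity undefined for a zero-GFP map")
  sqrt(mean((u / gu - v / gv)^2))
}

#' Point-wise randomization TANOVA for paired conditions
#'
#' At each timepoint, the observed statistic is the global dissimilarity
#' between the two conditions' GFP-normalized group-mean maps. The null
#' distribution is built by randomly swapping each subject's condition
#' assignment (a paired, subject-level relabeling: `2^n` possibilities).
#' `method = "auto"` enumerates all relabelings exhaustively when
#' `2^n <= n_perm` (exact test; the identity relabeling keeps `p >= 2^-n`)
#' and otherwise samples `n_perm` relabelings with add-one smoothing,
#' `p = (count + 1) / (n_perm + 1)`. The same relabeling set is applied at
#' every timepoint.
#'
#' @param cond_a,cond_b paired per-subject inputs: lists of `erp_evoked`
#'   (same subject order) or arrays `subjects x channels x time`.
#' @param n_perm number of sampled permutations (default 1000; below 100 a
#'   warning is issued).
#' @param seed integer seed for the sampled relabelings.
#' @param method `"auto"`, `"exact"`, or `"sample"`.
#' @param alpha significance level used for window extraction.
#' @param min_duration minimum duration (ms) of a significant window.
#' @param times time axis (ms); taken from the evokeds when available.
#' @return object of class `tanova_result`: `times`, `observed`, `p`,
#'   `alpha`, `n_perm` (effective), `method`, `seed`, `windows`.
#' @export
tanova <- function(cond_a, cond_b, n_perm = 1000, seed = 1,
                   method = c("auto", "exact", "sample"),
                   alpha = 0.05, min_duration = 10, times = NULL) {
  method <- match.arg(method)
  to_array <- function(x) {
    if (is.array(x) && length(dim(x)) == 3) return(x)
    stopifnot(is.list(x), length(x) >= 1)
    mats <- lapply(x, function(ev) ev$data)
    arr <- array(unlist(mats), dim = c(dim(mats[[1]])[1], dim(mats[[1]])[2], length(mats)))
    aperm(arr, c(3, 1, 2))
  }
  if (is.null(times) && is.list(cond_a) && inherits(cond_a[[1]], "erp_evoked")) {
    times <- cond_a[[1]]$times
    if (inherits(cond_b[[1]], "erp_evoked") &&
        !isTRUE(all.equal(times, cond_b[[1]]$times)))
      stop("conditions have different time axes")
  }
  A <- to_array(cond_a)
  B <- to_array(cond_b)
  if (!all(dim(A) == dim(B))) stop("unpaired subjects or mismatched dimensions")
  n <- dim(A)[1]; C <- dim(A)[2]; TT <- dim(A)[3]
  if (is.null(times)) times <- seq_len(TT) - 1
  if (n_perm < 100) warning("n_perm < 100: permutation p-values will be coarse")

  use_exact <- method == "exact" || (method == "auto" && 2^n <= n_perm)
  if (use_exact) {
    S <- as.matrix(do.call(expand.grid, rep(list(0:1), n)))
    storage.mode(S) <- "double"
  } else {
    set.seed(as.integer(seed))
    S <- matrix(stats::rbinom(n_perm * n, 1, 0.5), n_perm, n)
  }
  P <- nrow(S)

  norm_rows <- function(M) {
    r <- sqrt(rowMeans(M^2))
    r[r < .Machine$double.eps] <- Inf
    M / r
  }
  observed <- numeric(TT)
  pvals <- numeric(TT)
  for (t in seq_len(TT)) {
    At <- A[, , t, drop = FALSE][, , 1]
    Bt <- B[, , t, drop = FALSE][, , 1]
    if (n == 1) { At <- matrix(At, 1); Bt <- matrix(Bt, 1) }
    ma <- colMeans(At); mb <- colMeans(Bt)
    observed[t] <- dissimilarity(ma, mb)
    D <- At - Bt
    Delta <- (S %*% D) / n
    MA <- norm_rows(sweep(-Delta, 2, ma, `+`))
    MB <- norm_rows(sweep(Delta, 2, mb, `+`))
    nulls <- sqrt(rowMeans((MA - MB)^2))
    cnt <- sum(nulls >= observed[t] - 1e-12)
    pvals[t] <- if (use_exact) cnt / P else (cnt + 1) / (P + 1)
  }
  res <- structure(list(times = times, observed = observed, p = pvals,
                        alpha = alpha, n_perm = P, method = if (use_exact) "exact" else "sample",
                        seed = seed, min_duration = min_duration),
                   class = "tanova_result")
  res$windows <- significant_windows(res, alpha, min_duration)
  res
}

#' @export
print.tanova_result <- function(x, ...) {
  cat(sprintf("<tanova_result: %d timepoints, %s test (%d relabelings), alpha=%g>\n",
              length(x$times), x$method, x$n_perm, x$alpha))
  if (length(x$windows) == 0) cat("  no significant windows\n")
  else for (w in x$windows) cat(sprintf("  significant: [%g, %g) ms\n", w[1], w[2]))
  invisible(x)
}

#' Extract significant windows from a TANOVA result
#'
#' Maximal runs of consecutive timepoints with `p < alpha` lasting at least
#' `min_duration` ms, reported as half-open `[start, end)` intervals in ms.
#'
#' @param res a `tanova_result` (or list with `times` and `p`).
#' @param alpha significance level.
#' @param min_duration minimum run duration, ms.
#' @return list of numeric `c(start, end)` pairs.
#' @export
significant_windows <- function(res, alpha = res$alpha, min_duration = res$min_duration) {
  sig <- res$p < alpha
  if (!any(sig)) return(list())
  dt <- if (length(res$times) > 1) res$times[2] - res$times[1] else 1
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    dur <- r$lengths[i] * dt
    if (dur >= min_duration) {
      out[[length(out) + 1]] <- c(res$times[starts[i]], res$times[ends[i]] + dt)
    }
  }
  out
}

#' Write a TANOVA result as delimited text plus a JSON window list
#'
#' @param res a `tanova_result`.
#' @param path_tsv TSV output (`time_ms`, `observed_diss`, `p`).
#' @param path_json JSON output (windows, alpha, n_perm, method, seed).
#' @export
write_tanova <- function(res, path_tsv, path_json) {
  utils::write.table(
    data.frame(time_ms = res$times, observed_diss = res$observed, p = res$p),
    path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(windows = res$windows, alpha = res$alpha, n_perm = res$n_perm,
         method = res$method, seed = res$seed, min_duration = res$min_duration),
    path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_tsv)
}
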
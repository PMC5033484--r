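#' Microstate segmentation by atomize-and-agglomerate hierarchical clustering
#'
#' Segments a series of average-referenced scalp maps (typically grand-average
#' ERPs concatenated across conditions) into K template topographies, for each
#' K in `k_range`. AAHC initializes every map (or, optionally, every GFP-peak
#' map) as its own cluster, then repeatedly *atomizes* the cluster that
#' contributes least to the global explained variance and reassigns each of
#' its members to the best-correlated surviving cluster, until the requested
#' K values have been visited. In polarity-sensitive mode (the ERP
#' convention) the template is the members' mean map and assignment uses the
#' signed spatial correlation; in polarity-insensitive mode the template is
#' the members' first principal orientation and assignment uses the absolute
#' correlation. Templates are unit-GFP and average-referenced.
#'
#' @param x input maps: a `T x channels` matrix of average-referenced maps, a
#'   single `erp_evoked`, or a list of `erp_evoked`s (concatenated in time).
#' @param k_range integer vector of K values to return (e.g. `2:8`).
#' @param polarity polarity-sensitive clustering (default `TRUE`).
#' @param use_gfp_peaks train on local GFP maxima only (default `FALSE`).
#' @return list of `microstate_model` objects, one per K (named `k<K>`), each
#'   with `K`, `templates` (K x channels, unit GFP), `labels` (training
#'   assignment), `gev_total`, `residual_variance`, `cv`, `polarity`,
#'   `frame_times`, `frame_condition`.
#' @export
segment_microstates <- function(x, k_range, polarity = TRUE, use_gfp_peaks = FALSE) {
  prep <- maps_from_input(x)
  X <- prep$maps
  TT <- nrow(X); C <- ncol(X)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > TT) stop("k_range exceeds the number of training maps")
  if (min(k_range) < 1) stop("k_range must be positive")

  train_idx <- seq_len(TT)
  if (use_gfp_peaks) {
    g <- sqrt(rowMeans(X^2))
    pk <- which(diff(sign(diff(g))) < 0) + 1
    if (length(pk) >= max(k_range)) train_idx <- pk
  }
  Xt <- X[train_idx, , drop = FALSE]
  Tn <- nrow(Xt)

  assign_vec <- seq_len(Tn)             # cluster id per training map
  active <- seq_len(Tn)                  # ids of live clusters
  templates <- Xt                        # row i = template of cluster i (unit GFP below)
  templates <- templates / pmax(sqrt(rowMeans(templates^2)), .Machine$double.eps)

  recompute_template <- function(members) {
    M <- Xt[members, , drop = FALSE]
    if (polarity || length(members) == 1) {
      v <- colMeans(M)
    } else {
      sv <- svd(M, nu = 0, nv = 1)
      v <- sv$v[, 1]
    }
    g <- sqrt(mean(v^2))
    if (g < .Machine$double.eps) v <- M[1, ] / sqrt(mean(M[1, ]^2)) else v <- v / g
    v
  }

  members_of <- function(k) which(assign_vec == k)
  models <- list()
  record_model <- function() {
    K <- length(active)
    ord <- active[order(vapply(active, function(k) min(members_of(k)), numeric(1)))]
    tpl <- templates[ord, , drop = FALSE]
    lab_train <- match(assign_vec, ord)
    # label all maps (incl. non-peak frames) by best-correlated template
    R <- corr_matrix(X, tpl)
    lab_all <- best_label(R, polarity)
    fit <- fit_quality(X, tpl, lab_all, polarity)
    m <- structure(list(K = K, templates = tpl, labels = lab_all,
                        train_labels = lab_train,
                        gev_total = fit$gev, residual_variance = fit$sigma2,
                        polarity = polarity,
                        frame_times = prep$frame_times,
                        frame_condition = prep$frame_condition,
                        channels = prep$channels),
                   class = "microstate_model")
    m$cv <- tryCatch(cross_validation_criterion(m, X), error = function(e) NA_real_)
    models[[paste0("k", K)]] <<- m
  }

  if (length(active) %in% k_range) record_model()
  while (length(active) > min(k_range)) {
    # contribution of cluster k to explained variance: sum (x . a_k)^2 over members
    contrib <- vapply(active, function(k) {
      mem <- members_of(k)
      a <- templates[k, ]
      sum((Xt[mem, , drop = FALSE] %*% a)^2)
    }, numeric(1))
    worst <- active[which.min(contrib)]
    orphans <- members_of(worst)
    active <- setdiff(active, worst)
    Rtmp <- corr_matrix(Xt[orphans, , drop = FALSE], templates[active, , drop = FALSE])
    new_cl <- active[best_label(Rtmp, polarity)]
    assign_vec[orphans] <- new_cl
    for (k in unique(new_cl)) templates[k, ] <- recompute_template(members_of(k))
    if (length(active) %in% k_range) record_model()
  }
  models[order(as.integer(sub("k", "", names(models))))]
}

# rows of X correlated with rows of templates -> T x K matrix
corr_matrix <- function(X, tpl) {
  nx <- sqrt(rowSums(X^2)); nx[nx < .Machine$double.eps] <- Inf
  nt <- sqrt(rowSums(tpl^2))
  (X %*% t(tpl)) / outer(nx, nt)
}

best_label <- function(R, polarity) {
  if (!polarity) R <- abs(R)
  max.col(R, ties.method = "first")
}

# GEV and predictive residual variance of a labeling
fit_quality <- function(X, tpl, labels, polarity) {
  C <- ncol(X)
  tot <- sum(X^2) / C                    # sum of gfp^2
  a <- tpl[labels, , drop = FALSE]
  proj <- rowSums(X * a) / C             # (x . a)/C with rms(a)=1 -> units of gfp
  gev <- sum(proj^2) / tot
  sigma2 <- sum(rowSums(X^2) - (rowSums(X * a))^2 / C) / (nrow(X) * (C - 1))
  list(gev = gev, sigma2 = sigma2)
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model: K=%d, GEV=%.3f, sigma2=%.4g, CV=%.4g, %s>\n",
              x$K, x$gev_total, x$residual_variance, x$cv,
              if (x$polarity) "polarity-sensitive" else "polarity-insensitive"))
  invisible(x)
}

#' Cross-validation criterion for microstate model selection
#'
#' Predictive residual variance penalized for the number of templates:
#' `sigma2 * ((C - 1) / (C - 1 - K))^2` with `C` channels. The optimal K
#' minimizes this criterion ([select_k()]).
#'
#' @param model a `microstate_model`.
#' @param maps the training maps (`T x channels`); `NULL` reuses the model's
#'   stored residual variance.
#' @return criterion value, µV².
#' @export
cross_validation_criterion <- function(model, maps = NULL) {
  C <- length(model$channels)
  K <- model$K
  if (K >= C - 1) stop("cross-validation criterion undefined for K >= channels - 1")
  sigma2 <- model$residual_variance
  if (!is.null(maps)) {
    a <- model$templates[model$labels, , drop = FALSE]
    sigma2 <- sum(rowSums(maps^2) - (rowSums(maps * a))^2 / C) /
      (nrow(maps) * (C - 1))
  }
  sigma2 * ((C - 1) / (C - 1 - K))^2
}

#' Select the optimal number of microstates
#'
#' @param models list of `microstate_model`s (from [segment_microstates()]).
#' @return the model minimizing the cross-validation criterion.
#' @export
select_k <- function(models) {
  cvs <- vapply(models, `[[`, numeric(1), "cv")
  models[[which.min(cvs)]]
}

#' Back-fit microstate templates to an evoked response
#'
#' Labels each timepoint with the template of maximal spatial correlation
#' (signed in polarity-sensitive mode, absolute otherwise; ties go to the
#' lowest template index; zero-GFP timepoints stay unassigned). Per map, the
#' explained variance is the GFP-weighted squared correlation summed over its
#' assigned timepoints, normalized by the total squared GFP of the (windowed)
#' evoked.
#'
#' @param model a `microstate_model`.
#' @param ev an `erp_evoked` on the same channels (average reference).
#' @param window optional `[start, end)` ms restriction.
#' @return `backfit_result`: `labels` (per timepoint, `NA` = unassigned),
#'   `times`, and `per_map` tibble (`map`, `explained_variance`, `mean_gfp`,
#'   `coverage_ms`).
#' @export
backfit <- function(model, ev, window = NULL) {
  if (!identical(rownames(ev$data), model$channels))
    stop("evoked channels do not match the microstate model")
  times <- ev$times
  X <- t(ev$data)
  if (!is.null(window)) {
    keep <- times >= window[1] & times < window[2]
    X <- X[keep, , drop = FALSE]
    times <- times[keep]
  }
  g <- sqrt(rowMeans(X^2))
  R <- corr_matrix(X, model$templates)
  labels <- best_label(R, model$polarity)
  labels[g < .Machine$double.eps] <- NA_integer_
  corr_assigned <- R[cbind(seq_len(nrow(R)), ifelse(is.na(labels), 1L, labels))]
  if (!model$polarity) corr_assigned <- abs(corr_assigned)
  tot <- sum(g^2)
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  per_map <- lapply(seq_len(model$K), function(k) {
    idx <- which(!is.na(labels) & labels == k)
    tibble::tibble(
      map = k,
      explained_variance = if (tot > 0) sum((g[idx] * corr_assigned[idx])^2) / tot else 0,
      mean_gfp = if (length(idx) > 0) mean(g[idx]) else NA_real_,
      coverage_ms = length(idx) * dt
    )
  })
  structure(list(labels = labels, times = times,
                 per_map = dplyr::bind_rows(per_map)),
            class = "backfit_result")
}

#' Back-fit statistics across subjects and conditions
#'
#' Runs [backfit()] for every subject x condition evoked and returns the long
#' table feeding the repeated-measures ANOVAs on explained variance and GFP
#' (Map x Deviant x Category in the deviant analysis).
#'
#' @param model a `microstate_model`.
#' @param evokeds nested list `[[subject]][[condition_id]]` of `erp_evoked`s.
#' @param conditions tibble with `condition_id` and condition label columns.
#' @param window optional backfit window `[start, end)` ms.
#' @param maps optional integer subset of template indices to retain.
#' @return tibble: `subject`, condition labels, `map`, `explained_variance`,
#'   `mean_gfp`, `coverage_ms`.
#' @export
fit_statistics <- function(model, evokeds, conditions, window = NULL, maps = NULL) {
  rows <- list()
  for (s in seq_along(evokeds)) {
    for (ci in seq_len(nrow(conditions))) {
      id <- conditions$condition_id[ci]
      ev <- evokeds[[s]][[id]]
      if (is.null(ev)) stop(sprintf("missing evoked: subject %d condition %s", s, id))
      bf <- backfit(model, ev, window)
      pm <- bf$per_map
      if (!is.null(maps)) pm <- pm[pm$map %in% maps, , drop = FALSE]
      lab <- conditions[ci, setdiff(names(conditions), "condition_id"), drop = FALSE]
      rows[[length(rows) + 1]] <- tibble::tibble(subject = s, lab, pm)
    }
  }
  dplyr::bind_rows(rows)
}

#' Assign component-range names to microstate maps
#'
#' Each template is named by the median latency of its assigned training
#' timepoints relative to the component windows (maps within the P1 window
#' become P1a, P1b, ... in latency order; likewise N1; others are labelled
#' `other<k>`).
#'
#' @param model a `microstate_model` trained on evokeds (so `frame_times` is
#'   set).
#' @param p1_window,n1_window component time ranges, ms; the defaults are the
#'   topographic windows of the emulated study (P1 80-120 ms, N1 140-180 ms).
#' @return tibble `map`, `median_latency_ms`, `range` (`"P1"`, `"N1"`,
#'   `"other"`), `name`.
#' @export
map_component_ranges <- function(model, p1_window = c(80, 120), n1_window = c(140, 180)) {
  if (is.null(model$frame_times)) stop("model was not trained on time-stamped evokeds")
  med <- vapply(seq_len(model$K), function(k) {
    idx <- which(model$labels == k)
    if (length(idx) == 0) return(NA_real_)
    stats::median(model$frame_times[idx])
  }, numeric(1))
  rng <- ifelse(is.na(med), "other",
                ifelse(med >= p1_window[1] & med < p1_window[2], "P1",
                       ifelse(med >= n1_window[1] & med < n1_window[2], "N1", "other")))
  out <- tibble::tibble(map = seq_len(model$K), median_latency_ms = med, range = rng)
  out <- out[order(out$median_latency_ms), ]
  nm <- character(nrow(out))
  for (r in unique(out$range)) {
    i <- which(out$range == r)
    nm[i] <- if (r == "other") paste0("other", seq_along(i))
    else paste0(r, letters[seq_along(i)])
  }
  out$name <- nm
  out[order(out$map), ]
}

#' Dissociation report: category vs attention effects by component range
#'
#' Back-fits the model's P1-range maps within the P1 window and its N1-range
#' maps within the N1 window (restricting each range's explained-variance
#' denominator to its own window, so the two component ranges do not couple
#' through a shared normalization), then runs Map x Deviant x Category
#' repeated-measures ANOVAs on explained variance per range. A range shows a
#' category effect when the Category main effect or the Map x Category
#' interaction is significant, and a deviant/attention effect when the
#' Deviant main effect or Map x Deviant interaction is. A clean dissociation
#' is a category effect without a deviant effect at P1 and the reverse at N1.
#'
#' @param model a `microstate_model`.
#' @param evokeds nested list `[[subject]][[condition_id]]` of deviant
#'   condition evokeds.
#' @param conditions tibble with `condition_id`, `role`, `category` (and
#'   optionally `colour`, averaged over).
#' @param ranges output of [map_component_ranges()]; `NULL` computes it with
#'   default windows.
#' @param windows named list of back-fit windows per range (ms, half-open).
#' @param alpha significance level.
#' @return list with logical `p1_category`, `p1_deviant`, `n1_deviant`,
#'   `n1_category`, `dissociated`, the two ANOVA tables, and the per-range
#'   fit tables.
#' @export
dissociation_report <- function(model, evokeds, conditions, ranges = NULL,
                                windows = list(P1 = c(80, 120), N1 = c(140, 180)),
                                alpha = 0.05) {
  if (is.null(ranges))
    ranges <- map_component_ranges(model, windows$P1, windows$N1)
  fits <- list()
  run_range <- function(which_range) {
    maps <- ranges$map[ranges$range == which_range]
    if (length(maps) == 0) return(NULL)
    fit <- fit_statistics(model, evokeds, conditions,
                          window = windows[[which_range]], maps = maps)
    fits[[which_range]] <<- fit
    # average over colour (absorbed) to the Map x Deviant x Category cells
    agg <- dplyr::summarise(
      dplyr::group_by(fit, .data$subject, .data$map, .data$role, .data$category),
      ev = mean(.data$explained_variance), .groups = "drop")
    within <- if (length(maps) > 1) c("map", "role", "category") else c("role", "category")
    rm_anova(agg, dv = "ev", subject = "subject", within = within)
  }
  effect_p <- function(tab, name) {
    if (is.null(tab)) return(NA_real_)
    hit <- tab$p_gg[tab$effect == name]
    if (length(hit) == 0) NA_real_ else hit
  }
  p1 <- run_range("P1"); n1 <- run_range("N1")
  min_p <- function(...) suppressWarnings(min(..., na.rm = TRUE))
  p1_cat <- isTRUE(min_p(effect_p(p1, "category"), effect_p(p1, "map:category")) < alpha)
  p1_dev <- isTRUE(effect_p(p1, "role") < alpha)
  n1_dev <- isTRUE(min_p(effect_p(n1, "role"), effect_p(n1, "map:role")) < alpha)
  n1_cat <- isTRUE(effect_p(n1, "category") < alpha)
  list(p1_category = p1_cat, p1_deviant = p1_dev,
       n1_deviant = n1_dev, n1_category = n1_cat,
       dissociated = p1_cat && !p1_dev && n1_dev && !n1_cat,
       p1_anova = p1, n1_anova = n1, fits = fits)
}

# Accept matrix / evoked / list of evokeds, return maps (T x C) + frame metadata.
maps_from_input <- function(x) {
  if (is.matrix(x)) {
    return(list(maps = x, frame_times = NULL, frame_condition = NULL,
                channels = colnames(x) %||% paste0("ch", seq_len(ncol(x)))))
  }
  if (inherits(x, "erp_evoked")) x <- list(x)
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "erp_evoked")))
  ch <- rownames(x[[1]]$data)
  maps <- do.call(rbind, lapply(x, function(ev) {
    if (!identical(rownames(ev$data), ch)) stop("evoked channel mismatch")
    if (ev$reference != "average") stop("segmentation requires average-referenced evokeds")
    t(ev$data)
  }))
  frame_times <- unlist(lapply(x, `[[`, "times"))
  frame_condition <- unlist(lapply(seq_along(x), function(i) {
    lab <- paste(unlist(x[[i]]$condition), collapse = "_")
    rep(if (nzchar(lab)) lab else as.character(i), length(x[[i]]$times))
  }))
  list(maps = maps, frame_times = frame_times, frame_condition = frame_condition,
       channels = ch)
}

#' Write microstate templates and metadata as text
#'
#' One template per row with a channel-name header; metadata (K, GEV, CV,
#' polarity) as JSON.
#'
#' @param model a `microstate_model`.
#' @param path_tsv template TSV path.
#' @param path_json metadata JSON path.
#' @export
write_templates <- function(model, path_tsv, path_json) {
  tpl <- model$templates
  colnames(tpl) <- model$channels
  utils::write.table(cbind(map = seq_len(model$K), as.data.frame(tpl)),
                     path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(K = model$K, gev_total = model$gev_total,
                            residual_variance = model$residual_variance,
                            cv = model$cv, polarity = model$polarity),
                       path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_tsv)
}
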
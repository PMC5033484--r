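#' Default end-to-end run configuration
#'
#' Bundles the design, simulation, preprocessing, component, TANOVA and
#' microstate parameters for [run_pipeline()]. The study-scale defaults come
#' from [design_config()] and [sim_config()]; `n_subjects`, trial counts and
#' the sampling rate can be overridden for smaller runs.
#'
#' @param design a `design_config`.
#' @param sim a `sim_config`.
#' @param seed master seed; every stage seed derives from it.
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output.
#' @return nested list of class `run_config`.
#' @export
default_config <- function(design = design_config(), sim = sim_config(),
                           seed = 1, out_dir = NULL) {
  structure(list(
    design = design,
    sim = sim,
    preprocess = list(lowpass = 30, reject_threshold = 75,
                      window = c(-100, 500), baseline = c(-100, 0),
                      correct_only = TRUE),
    components = list(p1 = p1_component(), n170 = n170_component()),
    tanova = list(n_perm = 1000, alpha = 0.05, min_duration = 10),
    microstates = list(k_range = 2:8, polarity = TRUE, window = c(0, 500),
                       decimate_ms = 4,
                       p1_range = c(80, 140), n1_range = c(140, 200)),
    behavior = list(rt_floor = 100),
    seed = as.integer(seed),
    out_dir = out_dir
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks, before any computation, that every referenced electrode exists in
#' the montage, that windows are consistent and that seeds are set.
#'
#' @param config a `run_config`.
#' @return `config`, invisibly; errors on the first violated constraint.
#' @export
validate_config <- function(config) {
  mon <- config$sim$montage
  ch <- scalp_channels(mon)
  for (comp in config$components) {
    bad <- setdiff(comp$electrode_set, ch)
    if (length(bad) > 0)
      stop(sprintf("configuration error: electrode(s) %s not in montage",
                   paste(bad, collapse = ", ")))
  }
  for (cs in config$sim$components) {
    bad <- setdiff(names(cs$topography), ch)
    if (length(bad) > 0)
      stop(sprintf("configuration error: topography channel(s) %s not in montage",
                   paste(bad, collapse = ", ")))
  }
  pw <- config$preprocess$window
  if (pw[1] >= pw[2]) stop("configuration error: empty epoch window")
  if (is.null(config$seed)) stop("configuration error: seed missing")
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' simulate -> preprocess -> component statistics -> TANOVA -> microstates.
#' Writes tables, a JSON provenance record and a plain-text summary under
#' `config$out_dir` when set. All randomness derives from `config$seed`, so a
#' fixed configuration regenerates identical outputs.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param stages subset of `c("simulate", "preprocess", "components",
#'   "tanova", "microstates")` to run (later stages need the earlier ones).
#' @param verbose print stage progress.
#' @return list with per-stage results: `subjects` (evokeds etc.),
#'   `measurements`, `anovas`, `behavior_anovas`, `tanova`, `microstates`.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "preprocess", "components",
                                    "tanova", "microstates"),
                         verbose = TRUE) {
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                                    sprintf(...)))
  out <- list(config = config)
  od <- config$out_dir
  if (!is.null(od)) dir.create(od, recursive = TRUE, showWarnings = FALSE)

  say("simulate: %d subjects, %d blocks", config$sim$n_subjects, config$design$n_blocks)
  study <- simulate_study(config$design, config$sim, config$seed)
  out$behavior <- dplyr::bind_rows(lapply(study, `[[`, "behavior"))
  if (!is.null(od)) {
    write_sfp(config$sim$montage, file.path(od, "montage.sfp"))
    write_events(dplyr::bind_rows(lapply(study, `[[`, "trials")),
                 file.path(od, "events.tsv"))
    write_events(out$behavior, file.path(od, "behavior.tsv"))
  }
  if (!"preprocess" %in% stages) return(finish_run(out, od))

  say("preprocess: filtering, ocular correction, epoching, rejection")
  pp <- lapply(study, function(sd) {
    preprocess_subject(sd, lowpass = config$preprocess$lowpass,
                       reject_threshold = config$preprocess$reject_threshold,
                       window = config$preprocess$window,
                       baseline = config$preprocess$baseline,
                       correct_only = config$preprocess$correct_only)
  })
  out$rejection_log <- dplyr::bind_rows(lapply(pp, `[[`, "rejection_log"))
  evokeds <- lapply(pp, `[[`, "evokeds")
  conditions <- condition_table(config$design)
  out$conditions <- conditions
  if (!is.null(od))
    write_events(out$rejection_log, file.path(od, "rejection_log.tsv"))

  if ("components" %in% stages) {
    say("components: peaks, mean amplitudes, repeated-measures ANOVAs")
    comps <- config$components
    meas <- measure_components(evokeds, comps, conditions)
    out$measurements <- meas
    out$anovas <- component_anovas(meas)
    out$behavior_anovas <- behavior_stats(out$behavior, config$behavior$rt_floor)
    if (!is.null(od)) {
      write_events(meas, file.path(od, "measurements.tsv"))
      write_events(dplyr::bind_rows(lapply(names(out$anovas), function(nm) {
        tibble::tibble(model = nm, out$anovas[[nm]])
      })), file.path(od, "component_anovas.tsv"))
    }
  }

  if ("tanova" %in% stages) {
    say("tanova: faces vs butterflies over all deviants")
    ta <- category_tanova(evokeds, conditions,
                          n_perm = config$tanova$n_perm,
                          alpha = config$tanova$alpha,
                          min_duration = config$tanova$min_duration,
                          seed = config$seed + 1L)
    out$tanova <- ta
    if (!is.null(od))
      write_tanova(ta, file.path(od, "tanova.tsv"), file.path(od, "tanova_windows.json"))
  }

  if ("microstates" %in% stages) {
    say("microstates: segmentation, model selection, back-fitting")
    dev_ids <- conditions$condition_id[conditions$role != "standard"]
    grand <- lapply(dev_ids, function(id) {
      grand_average(lapply(evokeds, `[[`, id))
    })
    ms_win <- config$microstates$window
    dec <- config$microstates$decimate_ms
    grand_dec <- lapply(grand, function(g) decimate_evoked(crop_evoked(g, ms_win), dec))
    models <- segment_microstates(grand_dec, k_range = config$microstates$k_range,
                                  polarity = config$microstates$polarity)
    best <- select_k(models)
    p1r <- config$microstates$p1_range
    n1r <- config$microstates$n1_range
    ranges <- map_component_ranges(best, p1r, n1r)
    dev_conditions <- conditions[conditions$role != "standard", ]
    fit <- fit_statistics(best, evokeds, dev_conditions, window = ms_win)
    out$microstates <- list(models = models, best = best, ranges = ranges,
                            fit = fit,
                            report = dissociation_report(best, evokeds, dev_conditions,
                                                         ranges = ranges,
                                                         windows = list(P1 = p1r, N1 = n1r),
                                                         alpha = config$tanova$alpha))
    if (!is.null(od)) {
      write_templates(best, file.path(od, "microstate_templates.tsv"),
                      file.path(od, "microstate_model.json"))
      write_events(fit, file.path(od, "microstate_fit.tsv"))
    }
  }
  finish_run(out, od)
}

# condition table: all role x category x colour cells realized by the design
condition_table <- function(design) {
  rr <- design$role_rotation
  std <- unique(rr[rr$role == "standard", c("category", "colour")])
  std$role <- "standard"
  dev <- expand.grid(role = c("nontarget", "target"),
                     category = design$categories, colour = design$colours,
                     stringsAsFactors = FALSE)
  tab <- dplyr::bind_rows(tibble::as_tibble(std[, c("role", "category", "colour")]),
                          tibble::as_tibble(dev))
  tab$condition_id <- paste(tab$role, tab$category, tab$colour, sep = "_")
  tab
}

# The deviant P1 and N170 ANOVA models plus behavioural-style planned contrasts.
component_anovas <- function(meas) {
  dev <- meas[meas$role != "standard" & !meas$peak_missing, ]
  p1 <- dev[dev$component == "P1", ]
  p1 <- dplyr::bind_cols(p1, electrode_factors(p1$electrode, "p1")[, c("location", "site")])
  n1 <- dev[dev$component == "N170", ]
  n1 <- dplyr::bind_cols(n1, electrode_factors(n1$electrode, "n170")[, c("hemisphere", "site")])
  list(
    p1_deviants = rm_anova(p1, dv = "mean_amplitude", subject = "subject",
                           within = c("role", "category", "colour", "location", "site")),
    n170_deviants = rm_anova(n1, dv = "mean_amplitude", subject = "subject",
                             within = c("role", "category", "colour", "hemisphere", "site")),
    p1_deviant_within_butterfly = planned_contrast(
      p1, list(category = "butterfly"), dv = "mean_amplitude",
      within = c("role", "colour", "location", "site")),
    p1_deviant_within_face = planned_contrast(
      p1, list(category = "face"), dv = "mean_amplitude",
      within = c("role", "colour", "location", "site"))
  )
}

# Paired per-subject TANOVA: all deviant faces vs all deviant butterflies.
category_tanova <- function(evokeds, conditions, n_perm, alpha, min_duration, seed) {
  dev <- conditions[conditions$role != "standard", ]
  pool <- function(category) {
    ids <- dev$condition_id[dev$category == category]
    lapply(evokeds, function(subj) {
      rereference_average(grand_average(subj[ids]))
    })
  }
  cats <- sort(unique(dev$category))
  tanova(pool(cats[1]), pool(cats[2]), n_perm = n_perm, seed = seed,
         alpha = alpha, min_duration = min_duration)
}

#' Crop an evoked response to a time window
#' @param ev an `erp_evoked`.
#' @param window `[start, end)` ms.
#' @return cropped `erp_evoked`.
#' @export
crop_evoked <- function(ev, window) {
  keep <- ev$times >= window[1] & ev$times < window[2]
  ev$data <- ev$data[, keep, drop = FALSE]
  ev$times <- ev$times[keep]
  ev
}

#' Decimate an evoked response to a coarser time grid
#' @param ev an `erp_evoked`.
#' @param step_ms target sample spacing, ms (no-op if already coarser).
#' @return decimated `erp_evoked`.
#' @export
decimate_evoked <- function(ev, step_ms) {
  dt <- 1000 / ev$sampling_rate
  by <- max(1L, round(step_ms / dt))
  idx <- seq(1, length(ev$times), by = by)
  ev$data <- ev$data[, idx, drop = FALSE]
  ev$times <- ev$times[idx]
  ev$sampling_rate <- ev$sampling_rate / by
  ev
}

finish_run <- function(out, od) {
  if (!is.null(od)) {
    prov <- list(
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("erpstates")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      seed = out$config$seed,
      n_subjects = out$config$sim$n_subjects,
      sampling_rate = out$config$sim$sampling_rate,
      lowpass_hz = out$config$preprocess$lowpass,
      filter = "butterworth order 4 forward-backward (48 dB/oct combined, zero phase)",
      reject_threshold_uV = out$config$preprocess$reject_threshold,
      tanova = out$config$tanova,
      microstates = out$config$microstates[c("k_range", "polarity", "window", "decimate_ms")]
    )
    jsonlite::write_json(prov, file.path(od, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(run_summary_text(out), file.path(od, "summary.txt"))
  }
  out
}

# Plain-text result summary mirroring the analysis structure.
run_summary_text <- function(out) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("Oddball ERP pipeline summary (seed %d, %d subjects)",
      out$config$seed, out$config$sim$n_subjects)
  if (!is.null(out$behavior_anovas)) {
    add("")
    add("Behaviour (deviants): accuracy and RT rmANOVAs")
    acc <- out$behavior_anovas$accuracy
    dvt <- acc[acc$effect == "role", ]
    add("  accuracy deviant effect: F(%g,%g) = %.2f, p_gg = %.4g, pes = %.3f",
        dvt$df_num, dvt$df_den, dvt$F, dvt$p_gg, dvt$partial_eta_sq)
    rt <- out$behavior_anovas$rt
    dvt <- rt[rt$effect == "role", ]
    add("  RT deviant effect: F(%g,%g) = %.2f, p_gg = %.4g, pes = %.3f",
        dvt$df_num, dvt$df_den, dvt$F, dvt$p_gg, dvt$partial_eta_sq)
  }
  if (!is.null(out$anovas)) {
    add("")
    add("Component amplitude ANOVAs (deviants)")
    for (nm in c("p1_deviants", "n170_deviants")) {
      tab <- out$anovas[[nm]]
      add("  %s:", nm)
      for (eff in c("category", "role", "colour")) {
        row <- tab[tab$effect == eff, ]
        if (nrow(row) == 1)
          add("    %s: F(%g,%g) = %.2f, p_gg = %.4g, pes = %.3f",
              eff, row$df_num, row$df_den, row$F, row$p_gg, row$partial_eta_sq)
      }
    }
  }
  if (!is.null(out$tanova)) {
    add("")
    add("TANOVA (deviant faces vs butterflies): %d significant window(s)",
        length(out$tanova$windows))
    for (w in out$tanova$windows) add("  [%g, %g) ms", w[1], w[2])
  }
  if (!is.null(out$microstates)) {
    ms <- out$microstates
    add("")
    add("Microstates: optimal K = %d (CV criterion), GEV = %.3f",
        ms$best$K, ms$best$gev_total)
    for (i in seq_len(nrow(ms$ranges)))
      add("  map %d -> %s (median latency %.0f ms)",
          ms$ranges$map[i], ms$ranges$name[i], ms$ranges$median_latency_ms[i])
    rep <- ms$report
    add("  P1-range: category effect = %s, deviant effect = %s",
        rep$p1_category, rep$p1_deviant)
    add("  N1-range: deviant effect = %s, category effect = %s",
        rep$n1_deviant, rep$n1_category)
  }
  ln
}
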
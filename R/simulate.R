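#' Specification of a planted ERP component
#'
#' A component is a fixed scalp topography (zero channel mean, unit global
#' field power) modulated by a Gaussian time course. Latency varies between
#' subjects; amplitude is scaled per condition by the effect table and per
#' subject by the subject-scaling factor.
#'
#' @param name component label, e.g. `"P1"`.
#' @param latency_mean mean peak latency, ms post-stimulus.
#' @param latency_sd between-subject latency standard deviation, ms.
#' @param width Gaussian time-course standard deviation, ms.
#' @param topography named numeric vector over scalp channels; must have zero
#'   mean and unit GFP (see [gaussian_topography()]).
#' @param base_amplitude peak amplitude in µV at condition multiplier 1.
#' @param condition optional named list restricting the component to trials
#'   matching all entries (e.g. `list(category = "face")`); `NULL` applies to
#'   all trials.
#' @return a list of class `component_spec`.
#' @export
component_spec <- function(name, latency_mean, latency_sd, width, topography,
                           base_amplitude, condition = NULL) {
  stopifnot(latency_sd >= 0, width > 0)
  if (abs(mean(topography)) > 1e-8) stop("component topography must have zero channel mean")
  if (abs(sqrt(mean(topography^2)) - 1) > 1e-8) stop("component topography must have unit GFP")
  structure(list(name = name, latency_mean = latency_mean, latency_sd = latency_sd,
                 width = width, topography = topography,
                 base_amplitude = base_amplitude, condition = condition),
            class = "component_spec")
}

#' Default P1 and N1/N170 component specifications
#'
#' P1: medial-occipital positivity peaking near 116 ms (the grand-average
#' latency range of the emulated study spans 114-119 ms). N1: lateral
#' occipito-temporal negativity near 165 ms (range 159-170 ms).
#'
#' @param montage an `erp_montage`.
#' @return list of two `component_spec`s named `P1` and `N1`.
#' @export
default_components <- function(montage) {
  list(
    P1 = component_spec("P1", latency_mean = 116.5, latency_sd = 2, width = 22,
                        topography = gaussian_topography(montage, c("OZ", "POZ"), width = 0.45, sign = 1),
                        base_amplitude = 5),
    N1 = component_spec("N1", latency_mean = 164.5, latency_sd = 3, width = 26,
                        topography = gaussian_topography(montage, c("P7", "PO7", "CB1", "P8", "PO8", "CB2"),
                                                         width = 0.4, sign = -1),
                        base_amplitude = 5)
  )
}

#' Default condition-effect table
#'
#' Multiplicative amplitude modulation per component. `NA` entries are
#' wildcards; a trial's multiplier is the product over all matching rows.
#' The defaults mirror the emulated study's observed effect structure:
#' standards elicit the largest P1, faces a larger P1 than butterflies, blue
#' non-target deviants a larger P1 than green, and targets a larger N1 than
#' non-targets (no N1 category effect).
#'
#' @return tibble with columns `component`, `role`, `category`, `colour`,
#'   `multiplier`.
#' @export
default_effects <- function() {
  tibble::tribble(
    ~component, ~role,        ~category,   ~colour, ~multiplier,
    "P1",       "standard",   NA,          NA,      1.25,
    "P1",       "nontarget",  NA,          NA,      1.10,
    "P1",       NA,           "face",      NA,      1.35,
    "P1",       "nontarget",  NA,          "blue",  1.15,
    "N1",       "target",     NA,          NA,      1.35
  )
}

# Gaussian temporal smoothing approximating a low-pass at `cutoff` Hz,
# renormalized to unit marginal sd (so noise_sd keeps its meaning).
smooth_columns <- function(M, cutoff, fs) {
  sigma_ms <- 1000 * 0.1325 / cutoff   # Gaussian with ~-3 dB at the cutoff
  sigma_s <- sigma_ms * fs / 1000
  half <- max(1L, ceiling(3 * sigma_s))
  k <- stats::dnorm(seq(-half, half), sd = sigma_s)
  k <- k / sqrt(sum(k^2))              # unit output variance for white input
  n <- nrow(M)
  pad <- rbind(M[rev(seq_len(half)), , drop = FALSE], M,
               M[n + 1 - seq_len(half), , drop = FALSE])
  out <- apply(pad, 2, function(x) stats::filter(x, k, sides = 2))
  out[(half + 1):(half + n), , drop = FALSE]
}

# Product of multipliers of all effect rows matching a trial's labels.
effect_multiplier <- function(effects, component, role, category, colour) {
  if (is.null(effects) || nrow(effects) == 0) return(1)
  m <- effects$component == component &
    (is.na(effects$role) | effects$role == role) &
    (is.na(effects$category) | effects$category == category) &
    (is.na(effects$colour) | effects$colour == colour)
  if (!any(m)) return(1)
  prod(effects$multiplier[m])
}

#' Simulation configuration
#'
#' @param n_subjects number of subjects (19 in the emulated study).
#' @param montage an `erp_montage`; default [default_montage()] (64 scalp
#'   channels + VEOG).
#' @param sampling_rate Hz.
#' @param epoch_window analysis epoch in ms, half-open `[start, end)`.
#' @param components list of `component_spec`s; default [default_components()].
#' @param effects condition-effect table; default [default_effects()].
#' @param noise_sd trial-level noise standard deviation per channel, µV.
#' @param spatial_noise_smoothness Gaussian kernel width (unit-sphere
#'   distance) used to spatially correlate the noise; 0 = white across
#'   channels.
#' @param blink_rate blink events per minute.
#' @param blink_amplitude blink peak amplitude at the EOG channel, µV.
#' @param blink_propagation named per-scalp-channel propagation coefficients;
#'   `NULL` uses a front-to-back gradient derived from the montage.
#' @param subject_sd between-subject log-normal amplitude-scaling sd.
#' @param behavior list of behavioural parameters (per-role accuracy means and
#'   between-subject sds, per-role RT means and sds in ms, trial RT sd, RT
#'   shift, anticipation rate); see [default_behavior_params()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 19,
                       montage = default_montage(),
                       sampling_rate = 1000,
                       epoch_window = c(-100, 500),
                       components = default_components(montage),
                       effects = default_effects(),
                       noise_sd = 8,
                       spatial_noise_smoothness = 0.6,
                       blink_rate = 12,
                       blink_amplitude = 200,
                       blink_propagation = NULL,
                       subject_sd = 0.15,
                       behavior = default_behavior_params()) {
  stopifnot(n_subjects >= 1, sampling_rate > 0, noise_sd >= 0,
            spatial_noise_smoothness >= 0, blink_rate >= 0, subject_sd >= 0)
  for (cs in components) {
    if (cs$latency_mean < epoch_window[1] || cs$latency_mean >= epoch_window[2])
      stop(sprintf("component %s latency %.1f ms outside epoch window", cs$name, cs$latency_mean))
  }
  if (is.null(blink_propagation)) blink_propagation <- default_blink_propagation(montage)
  structure(list(n_subjects = as.integer(n_subjects), montage = montage,
                 sampling_rate = sampling_rate, epoch_window = epoch_window,
                 components = components, effects = effects, noise_sd = noise_sd,
                 spatial_noise_smoothness = spatial_noise_smoothness,
                 blink_rate = blink_rate, blink_amplitude = blink_amplitude,
                 blink_propagation = blink_propagation, subject_sd = subject_sd,
                 behavior = behavior),
            class = "sim_config")
}

#' Front-to-back blink propagation gradient
#'
#' Coefficients decrease from ~0.4 at frontal sites to ~0.05 occipitally,
#' proportional to each electrode's anterior position.
#'
#' @param montage an `erp_montage`.
#' @return named vector over scalp channels.
#' @export
default_blink_propagation <- function(montage) {
  ch <- scalp_channels(montage)
  y <- montage$y[match(ch, montage$name)]
  stats::setNames(0.05 + 0.35 * (y + 1) / 2, ch)
}

#' Default behavioural model parameters
#'
#' Accuracy is Bernoulli per trial with subject-level means; RT is a shifted
#' log-normal with subject-level means; a small anticipation rate produces
#' fast guesses below the 100 ms analysis floor. The per-role means and
#' between-subject sds are centred on the emulated study's printed values
#' (non-target accuracy 93.71 +/- 4.6%, target 68.3 +/- 21.1%; non-target RT
#' 270.79 +/- 39.63 ms, target RT 442.86 +/- 38.59 ms). `rt_cat_interaction`
#' makes faces slightly faster than butterflies as targets and slower as
#' non-targets.
#'
#' @return a named list of parameters.
#' @export
default_behavior_params <- function() {
  list(
    acc_mean = c(standard = 0.97, nontarget = 0.9371, target = 0.683),
    acc_sd = c(standard = 0.02, nontarget = 0.046, target = 0.211),
    rt_mean = c(standard = 265, nontarget = 270.79, target = 442.86),
    rt_subject_sd = c(standard = 39, nontarget = 39.63, target = 38.59),
    rt_trial_sd = 80,
    rt_shift = 120,
    rt_cat_interaction = 10,
    anticipation_rate = 0.01
  )
}

# Cholesky factor of the spatially smoothed noise correlation matrix.
noise_mixing_matrix <- function(montage, smoothness) {
  ch <- scalp_channels(montage)
  if (smoothness <= 0) return(diag(length(ch)))
  d <- channel_distances(montage, ch)
  K <- exp(-d^2 / (2 * smoothness^2))
  K <- K + diag(1e-8, nrow(K))
  R <- chol(K)
  # scale so each channel's marginal sd is 1
  R %*% diag(1 / sqrt(colSums(R^2)))
}

# Gaussian time course sampled on epoch-relative times (ms), peak 1.
component_timecourse <- function(times_ms, latency, width) {
  exp(-((times_ms - latency)^2) / (2 * width^2))
}

#' Simulate one subject's oddball session
#'
#' Produces, per block, a continuous multi-channel recording (scalp channels
#' plus a VEOG channel carrying blink transients that propagate to the scalp
#' by the configured coefficients), together with the trial sequence and a
#' behavioural table. Each trial's evoked response is the sum over planted
#' components of topography x Gaussian time course x condition multiplier x
#' subject scaling, embedded at the trial onset; noise is temporally white and
#' spatially smoothed.
#'
#' @param design a `design_config`.
#' @param sim a `sim_config`.
#' @param subject subject index (recorded in the outputs).
#' @param seed integer seed; output is deterministic given all arguments.
#' @param blocks which blocks to simulate (default all).
#' @return list with elements `recordings` (list of `erp_recording`, one per
#'   block), `trials` (tibble), `behavior` (tibble), `subject_scale`,
#'   `latency_offsets`.
#' @export
simulate_subject <- function(design, sim, subject, seed, blocks = seq_len(design$n_blocks)) {
  if (missing(seed) || is.null(seed)) stop("a seed is required for reproducible simulation")
  set.seed(as.integer(seed))
  sub_scale <- exp(stats::rnorm(1, 0, sim$subject_sd))
  lat_off <- vapply(sim$components, function(cs) stats::rnorm(1, 0, cs$latency_sd), numeric(1))
  names(lat_off) <- vapply(sim$components, `[[`, character(1), "name")
  block_seeds <- sample.int(.Machine$integer.max - 1L, design$n_blocks + 1L)

  mon <- sim$montage
  ch_scalp <- scalp_channels(mon)
  has_eog <- any(mon$eog)
  mix <- noise_mixing_matrix(mon, sim$spatial_noise_smoothness)

  recordings <- list(); all_trials <- list(); all_beh <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    trials <- build_block_sequence(design, b, block_seeds[b])
    set.seed((block_seeds[design$n_blocks + 1L] + b) %% .Machine$integer.max)
    fs <- sim$sampling_rate
    dt <- 1000 / fs
    dur_ms <- max(trials$onset_ms) + design$stim_duration + 1000
    n_samp <- ceiling(dur_ms / dt)
    times <- (seq_len(n_samp) - 1) * dt

    # spatially smoothed white noise
    noise <- matrix(stats::rnorm(n_samp * length(ch_scalp), 0, sim$noise_sd), n_samp) %*% mix
    data <- t(noise)
    rownames(data) <- ch_scalp

    # planted evoked responses
    ep_rel <- seq(sim$epoch_window[1], sim$epoch_window[2] - dt, by = dt)
    for (cs in sim$components) {
      topo <- cs$topography[ch_scalp]
      lat <- cs$latency_mean + lat_off[[cs$name]]
      tc <- component_timecourse(ep_rel, lat, cs$width)
      for (ti in seq_len(nrow(trials))) {
        tr <- trials[ti, ]
        if (!is.null(cs$condition)) {
          ok <- all(vapply(names(cs$condition), function(f) tr[[f]] == cs$condition[[f]], logical(1)))
          if (!ok) next
        }
        mult <- effect_multiplier(sim$effects, cs$name, tr$role, tr$category, tr$colour)
        amp <- cs$base_amplitude * mult * sub_scale
        i0 <- round(tr$onset_ms / dt) + round(sim$epoch_window[1] / dt)
        idx <- i0 + seq_along(ep_rel)   # 1-based sample indices
        keep <- idx >= 1 & idx <= n_samp
        data[, idx[keep]] <- data[, idx[keep]] + outer(topo, amp * tc[keep])
      }
    }

    # blinks on the EOG channel, propagated to the scalp
    if (has_eog) {
      eog <- stats::rnorm(n_samp, 0, sim$noise_sd / 2)
      n_blinks <- stats::rpois(1, sim$blink_rate * dur_ms / 60000)
      blink_onsets <- numeric(0)
      if (n_blinks > 0) {
        blink_onsets <- sort(stats::runif(n_blinks, 500, dur_ms - 500))
        for (bo in blink_onsets) {
          shape <- sim$blink_amplitude * exp(-((times - bo)^2) / (2 * 60^2))
          eog <- eog + shape
          coef <- sim$blink_propagation[ch_scalp]
          data <- data + outer(coef, shape)
        }
      }
      data <- rbind(data, VEOG = eog)
    }

    beh <- simulate_behavior(trials, sim$behavior, sub_scale = sub_scale, subject = subject)
    trials$subject <- as.integer(subject)
    recordings[[bi]] <- erp_recording(data, sampling_rate = fs, montage = mon,
                                      events = trials, reference = "recording",
                                      meta = list(subject = subject, block = b,
                                                  blink_onsets_ms = if (has_eog) blink_onsets else numeric(0)))
    all_trials[[bi]] <- trials
    all_beh[[bi]] <- beh
  }
  list(recordings = recordings,
       trials = dplyr::bind_rows(all_trials),
       behavior = dplyr::bind_rows(all_beh),
       subject_scale = sub_scale,
       latency_offsets = lat_off)
}

#' Simulate behavioural responses for a trial sequence
#'
#' Accuracy is Bernoulli with a per-role subject-level mean; RT is a shifted
#' log-normal around a per-role subject-level mean, with a small anticipation
#' rate producing sub-100 ms guesses. Targets are slower and less accurate
#' than non-targets; a role-by-category interaction makes faces slightly
#' faster than butterflies as targets and slower as non-targets.
#'
#' @param trials trial tibble from [build_block_sequence()].
#' @param params behavioural parameters, see [default_behavior_params()].
#' @param sub_scale unused scaling hook (subject-level effects are drawn here).
#' @param subject subject id recorded in the output.
#' @return tibble: `subject`, `block`, `trial`, `role`, `category`, `colour`,
#'   `response`, `correct`, `rt_ms`.
#' @export
simulate_behavior <- function(trials, params, sub_scale = 1, subject = 1L) {
  roles <- names(params$acc_mean)
  acc_sub <- pmin(0.999, pmax(0.01, stats::rnorm(length(roles), params$acc_mean, params$acc_sd)))
  names(acc_sub) <- roles
  rt_sub <- pmax(params$rt_shift + 30, stats::rnorm(length(roles), params$rt_mean, params$rt_subject_sd))
  names(rt_sub) <- roles

  n <- nrow(trials)
  p_acc <- acc_sub[trials$role]
  correct <- stats::runif(n) < p_acc
  m <- rt_sub[trials$role]
  # role x category interaction (faces faster as targets, slower as non-targets)
  cat2 <- trials$category == sort(unique(trials$category))[length(unique(trials$category))]
  is_face <- trials$category == "face"
  delta <- ifelse(trials$role == "target", -1, 1) * ifelse(is_face, params$rt_cat_interaction, 0)
  m <- m + delta
  mu_ln <- m - params$rt_shift
  s2 <- log(1 + (params$rt_trial_sd / mu_ln)^2)
  rt <- params$rt_shift + stats::rlnorm(n, log(mu_ln) - s2 / 2, sqrt(s2))
  anticip <- stats::runif(n) < params$anticipation_rate
  rt[anticip] <- stats::runif(sum(anticip), 0, 100)
  correct[anticip] <- stats::runif(sum(anticip)) < 0.5
  response <- ifelse(correct, trials$required_response,
                     ifelse(trials$required_response == 5L, 1L, 5L))
  tibble::tibble(subject = as.integer(subject), block = trials$block, trial = trials$trial,
                 role = trials$role, category = trials$category, colour = trials$colour,
                 response = as.integer(response), correct = correct, rt_ms = rt)
}

#' Simulate a whole study
#'
#' Runs [simulate_subject()] for each subject with deterministically derived
#' per-subject seeds.
#'
#' @param design a `design_config`.
#' @param sim a `sim_config`.
#' @param seed integer base seed.
#' @return list of per-subject results (see [simulate_subject()]).
#' @export
simulate_study <- function(design, sim, seed) {
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, sim$n_subjects)
  lapply(seq_len(sim$n_subjects), function(s) {
    simulate_subject(design, sim, subject = s, seed = subject_seeds[s])
  })
}

#' Directly simulate subject-level condition-average ERPs
#'
#' Shortcut generator for statistical property studies: produces per-subject,
#' per-condition average-referenced evoked responses without synthesizing the
#' continuous recordings — the evoked is the planted component sum plus noise
#' scaled by `1/sqrt(n_trials)`, which is what averaging `n_trials` clean
#' epochs of the full generator converges to. Conditions default to the eight
#' deviant cells (role x category x colour).
#'
#' @param design a `design_config`.
#' @param sim a `sim_config`.
#' @param conditions tibble of condition labels with columns `role`,
#'   `category`, `colour`; default the eight deviant cells.
#' @param n_trials nominal trial count per condition (sets the noise scale).
#' @param noise_lowpass temporal band limit of the evoked-level noise, Hz
#'   (default 30, matching the pipeline's offline low-pass; `NULL` leaves the
#'   noise temporally white).
#' @param seed integer seed.
#' @return list with `evokeds` (nested list `[[subject]][[condition_id]]` of
#'   `erp_evoked`) and `conditions` (the condition tibble with `condition_id`).
#' @export
simulate_condition_evokeds <- function(design, sim, conditions = NULL, n_trials = 80,
                                       noise_lowpass = 30, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (is.null(conditions)) {
    conditions <- expand.grid(role = c("nontarget", "target"),
                              category = design$categories,
                              colour = design$colours,
                              stringsAsFactors = FALSE)
  }
  conditions <- tibble::as_tibble(conditions)
  conditions$condition_id <- apply(conditions, 1, function(r) paste(r, collapse = "_"))
  mon <- sim$montage
  ch <- scalp_channels(mon)
  fs <- sim$sampling_rate
  dt <- 1000 / fs
  times <- seq(sim$epoch_window[1], sim$epoch_window[2] - dt, by = dt)
  mix <- noise_mixing_matrix(mon, sim$spatial_noise_smoothness)

  set.seed(as.integer(seed))
  evokeds <- lapply(seq_len(sim$n_subjects), function(s) {
    sub_scale <- exp(stats::rnorm(1, 0, sim$subject_sd))
    lat_off <- vapply(sim$components, function(cs) stats::rnorm(1, 0, cs$latency_sd), numeric(1))
    names(lat_off) <- vapply(sim$components, `[[`, character(1), "name")
    out <- list()
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, ]
      sig <- matrix(0, length(ch), length(times), dimnames = list(ch, NULL))
      for (cs in sim$components) {
        if (!is.null(cs$condition)) {
          ok <- all(vapply(names(cs$condition), function(f) cond[[f]] == cs$condition[[f]], logical(1)))
          if (!ok) next
        }
        mult <- effect_multiplier(sim$effects, cs$name, cond$role, cond$category, cond$colour)
        tc <- component_timecourse(times, cs$latency_mean + lat_off[[cs$name]], cs$width)
        sig <- sig + outer(cs$topography[ch], cs$base_amplitude * mult * sub_scale * tc)
      }
      noise_t <- matrix(stats::rnorm(length(times) * length(ch), 0, 1), length(times))
      if (!is.null(noise_lowpass)) noise_t <- smooth_columns(noise_t, noise_lowpass, fs)
      noise <- t((sim$noise_sd / sqrt(n_trials)) * noise_t %*% mix)
      ev <- erp_evoked(sig + noise, times = times, sampling_rate = fs, montage = mon,
                       condition = as.list(cond[, setdiff(names(cond), "condition_id")]),
                       n_trials = n_trials, reference = "recording",
                       subject = s)
      out[[cond$condition_id]] <- rereference_average(ev)
    }
    out
  })
  list(evokeds = evokeds, conditions = conditions)
}

#' Component and effect recipe for the dissociation study
#'
#' Plants a category effect only in the P1 range — faces and butterflies
#' evoke *topographically distinct* P1 maps of equal amplitude — and an
#' attention effect only in the N1 range — targets evoke a distinct (and
#' larger) N1 map than non-targets. No other condition effects are present,
#' so any deviant effect detected at P1, or category effect at N1, is a false
#' positive.
#'
#' @param montage an `erp_montage`.
#' @return list with `components` and `effects` suitable for [sim_config()].
#' @export
dissociation_recipe <- function(montage) {
  # narrow time courses (FWHM ~ 30 ms) keep the P1 and N1 windows separated,
  # so the planted effects really are confined to their own component range
  comps <- list(
    component_spec("P1a", 116.5, 2, 12,
                   gaussian_topography(montage, c("OZ", "O1"), width = 0.4, sign = 1),
                   base_amplitude = 5, condition = list(category = "butterfly")),
    component_spec("P1b", 116.5, 2, 12,
                   gaussian_topography(montage, c("POZ", "PO4", "O2"), width = 0.4, sign = 1),
                   base_amplitude = 5, condition = list(category = "face")),
    component_spec("N1a", 164.5, 3, 14,
                   gaussian_topography(montage, c("P7", "PO7", "P8", "PO8"), width = 0.4, sign = -1),
                   base_amplitude = 5, condition = list(role = "nontarget")),
    component_spec("N1b", 164.5, 3, 14,
                   gaussian_topography(montage, c("CB1", "PO5", "CB2", "PO6"), width = 0.35, sign = -1),
                   base_amplitude = 6.5, condition = list(role = "target"))
  )
  list(components = comps, effects = tibble::tibble(component = character(0), role = character(0),
                                                    category = character(0), colour = character(0),
                                                    multiplier = numeric(0)))
}
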
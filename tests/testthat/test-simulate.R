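noiseless_sim <- function(mon, comps, effects = NULL) {
  if (is.null(effects))
    effects <- tibble::tibble(component = character(0), role = character(0),
                              category = character(0), colour = character(0),
                              multiplier = numeric(0))
  sim_config(n_subjects = 1, montage = mon, sampling_rate = 500,
             components = comps, effects = effects, noise_sd = 0,
             blink_rate = 0, subject_sd = 0)
}

test_that("a noiseless single-component trial reproduces amplitude x topography", {
  mon <- default_montage()
  p1 <- component_spec("P1", 116, 0, 22,
                       gaussian_topography(mon, "OZ", 0.4), base_amplitude = 5)
  s <- noiseless_sim(mon, list(P1 = p1))
  d <- design_config(n_standards_per_block = 3, n_nontarget_deviants = 1,
                     n_target_deviants = 0, run_lengths = 3, n_blocks = 4)
  out <- simulate_subject(d, s, 1, 5, blocks = 1)
  rec <- out$recordings[[1]]
  ep <- make_epochs(rec, window = c(-100, 500), baseline = NULL)
  scalp <- scalp_channels(mon)
  peak_idx <- which.min(abs(ep$times - 116))
  planted <- 5 * p1$topography[scalp]
  expect_equal(ep$data[scalp, peak_idx, 1], planted, tolerance = 1e-10)
  # half-way down the Gaussian flank too
  t_off <- which.min(abs(ep$times - (116 + 22)))
  expect_equal(ep$data[scalp, t_off, 1], planted * exp(-0.5), tolerance = 1e-10)
})

test_that("planted category effect appears in every noiseless subject", {
  mon <- default_montage()
  s <- sim_config(n_subjects = 5, montage = mon, sampling_rate = 500,
                  noise_sd = 0, subject_sd = 0.15)
  sim <- simulate_condition_evokeds(design_config(), s, n_trials = 10, seed = 2)
  comp <- p1_component()
  for (subj in sim$evokeds) {
    f <- find_peak(subj[["nontarget_face_blue"]], comp)
    b <- find_peak(subj[["nontarget_butterfly_blue"]], comp)
    expect_gt(f$amplitude, b$amplitude)
  }
})

test_that("raising the N1 target multiplier raises noiseless N1 magnitude", {
  mon <- default_montage()
  comp <- n170_component()
  mags <- vapply(c(1.1, 1.35, 1.8), function(mult) {
    eff <- default_effects()
    eff$multiplier[eff$component == "N1" & eff$role == "target"] <- mult
    s <- sim_config(n_subjects = 3, montage = mon, sampling_rate = 500,
                    effects = eff, noise_sd = 0, subject_sd = 0)
    sim <- simulate_condition_evokeds(design_config(), s, n_trials = 10, seed = 3)
    ga <- grand_average(lapply(sim$evokeds, `[[`, "target_face_green"))
    pk <- find_peak(ga, comp)
    -pk$amplitude
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("simulation is bit-identical given identical configuration and seed", {
  d <- design_config(n_standards_per_block = 8, n_nontarget_deviants = 1,
                     n_target_deviants = 1, run_lengths = c(3, 5))
  s <- sim_config(n_subjects = 1, sampling_rate = 250, noise_sd = 4)
  a <- simulate_subject(d, s, 1, 77, blocks = 1)
  b <- simulate_subject(d, s, 1, 77, blocks = 1)
  expect_identical(a$recordings[[1]]$data, b$recordings[[1]]$data)
  expect_identical(a$behavior, b$behavior)
  expect_error(simulate_subject(d, s, 1), "seed")
})

test_that("behavioural outcomes show the planted target costs", {
  d <- design_config()
  trials <- build_block_sequence(d, 1, 3)
  set.seed(42)
  beh <- simulate_behavior(trials, default_behavior_params())
  agg <- aggregate(rt_ms ~ role, beh[beh$correct & beh$rt_ms >= 100, ], mean)
  expect_gt(agg$rt_ms[agg$role == "target"], agg$rt_ms[agg$role == "nontarget"])
  acc <- aggregate(correct ~ role, beh, mean)
  expect_gt(acc$correct[acc$role == "nontarget"], acc$correct[acc$role == "target"])
  expect_true(all(beh$rt_ms >= 0))
})

test_that("between-subject amplitude spread matches a resampling oracle", {
  mon <- default_montage()
  p1 <- component_spec("P1", 116, 2, 22,
                       gaussian_topography(mon, c("OZ", "POZ"), 0.45), base_amplitude = 5)
  s <- sim_config(n_subjects = 19, montage = mon, sampling_rate = 500,
                  components = list(P1 = p1),
                  effects = tibble::tibble(component = character(0), role = character(0),
                                           category = character(0), colour = character(0),
                                           multiplier = numeric(0)),
                  noise_sd = 0, subject_sd = 0.15)
  sim <- simulate_condition_evokeds(design_config(), s, n_trials = 10, seed = 11)
  comp <- p1_component()
  amps <- vapply(sim$evokeds, function(subj) {
    find_peak(subj[["nontarget_face_blue"]], comp)$amplitude
  }, numeric(1))
  emp_sd <- sd(amps)
  # oracle: per-subject peak amplitude is k * exp(N(0, 0.15)) with
  # k = base_amplitude x ROI-mean topography
  k <- 5 * mean(p1$topography[comp$electrode_set])
  set.seed(1)
  draws <- replicate(10000, sd(k * exp(rnorm(19, 0, 0.15))))
  expect_lt(abs(emp_sd - mean(draws)), 3 * sd(draws))
})

test_that("EOG blinks propagate front-to-back with the configured gradient", {
  d <- design_config(n_standards_per_block = 8, n_nontarget_deviants = 1,
                     n_target_deviants = 1, run_lengths = c(3, 5))
  s <- sim_config(n_subjects = 1, sampling_rate = 250, noise_sd = 0,
                  blink_rate = 60, subject_sd = 0)
  out <- simulate_subject(d, s, 1, 9, blocks = 1)
  rec <- out$recordings[[1]]
  expect_gt(length(rec$meta$blink_onsets_ms), 0)
  b <- round(rec$meta$blink_onsets_ms[1] * rec$sampling_rate / 1000) + 1
  frontal <- unname(rec$data["FPZ", b] / rec$data["VEOG", b])
  occip <- unname(rec$data["OZ", b] / rec$data["VEOG", b])
  expect_gt(frontal, occip)
  expect_equal(frontal, unname(default_blink_propagation(s$montage)["FPZ"]),
               tolerance = 0.05)
})
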
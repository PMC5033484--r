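make_rec <- function(data, fs = 1000, events = NULL, mon = NULL) {
  if (is.null(mon)) mon <- tiny_montage(nrow(data))
  rownames(data) <- mon$name[seq_len(nrow(data))]
  erp_recording(data, sampling_rate = fs, montage = mon, events = events)
}

test_that("the low-pass filter has unit DC gain and a transparent passband", {
  fs <- 1000
  n <- 4000
  const <- make_rec(matrix(3, 2, n), fs)
  out <- lowpass_filter(const, 30)
  expect_equal(out$data, const$data, tolerance = 1e-9)

  t <- seq_len(n) / fs
  s5 <- make_rec(matrix(sin(2 * pi * 5 * t), 1, n), fs)
  out5 <- lowpass_filter(s5, 30)
  mid <- 1000:3000
  amp <- max(abs(out5$data[1, mid]))
  expect_gt(amp, 0.99)
})

test_that("stop-band attenuation matches the analytic Butterworth response", {
  fs <- 1000; fc <- 30; f <- 100; order <- 4
  n <- 8000
  t <- seq_len(n) / fs
  rec <- make_rec(matrix(sin(2 * pi * f * t), 1, n), fs)
  out <- lowpass_filter(rec, fc, order = order)
  mid <- 3000:5000
  measured <- sqrt(mean(out$data[1, mid]^2)) / sqrt(0.5)
  # bilinear-transform Butterworth magnitude with prewarped frequencies,
  # squared for the forward-backward double pass
  warp <- function(fr) tan(pi * fr / fs)
  expected <- (1 / sqrt(1 + (warp(f) / warp(fc))^(2 * order)))^2
  expect_equal(measured, expected, tolerance = 0.02)
})

test_that("the filter rejects cutoffs at or beyond Nyquist", {
  rec <- make_rec(matrix(0, 1, 100), fs = 100)
  expect_error(lowpass_filter(rec, 50), "Nyquist")
})

test_that("exactly collinear EOG contamination is removed", {
  set.seed(1)
  mon <- tiny_montage(3, eog = TRUE)
  n <- 5000
  eog <- rep(0, n)
  for (b in c(1000, 2500, 4000)) eog <- eog + 200 * exp(-((seq_len(n) - b)^2) / (2 * 60^2))
  data <- rbind(0.4 * eog, 0.2 * eog, 0.1 * eog, eog)
  rec <- make_rec(data, fs = 1000, mon = mon)
  out <- correct_ocular(rec)
  for (chan in 1:3) {
    expect_lt(sum(out$data[chan, ]^2), 1e-6 * sum(data[chan, ]^2))
  }
})

test_that("correction without blink events is the identity", {
  set.seed(2)
  mon <- tiny_montage(3, eog = TRUE)
  data <- matrix(rnorm(4 * 1000), 4, 1000)  # no blink-scale excursions
  rec <- make_rec(data, fs = 1000, mon = mon)
  out <- correct_ocular(rec, blink_events = integer(0))
  expect_identical(out$data, rec$data)
  expect_equal(out$meta$n_blinks, 0L)
})

test_that("planted propagation coefficients are recovered within 5%", {
  d <- design_config(n_standards_per_block = 16, n_nontarget_deviants = 2,
                     n_target_deviants = 2, run_lengths = c(3, 5))
  s <- sim_config(n_subjects = 1, sampling_rate = 250, noise_sd = 1,
                  blink_rate = 20, subject_sd = 0)
  truth <- default_blink_propagation(s$montage)
  errs <- vapply(1:20, function(seed) {
    out <- simulate_subject(d, s, 1, seed, blocks = 1)
    rec <- correct_ocular(lowpass_filter(out$recordings[[1]], 30))
    co <- rec$meta$blink_coefficients
    mean(abs(co - truth[names(co)]) / truth[names(co)])
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("epoching follows the half-open window convention", {
  mon <- tiny_montage(2)
  n <- 2000
  events <- tibble::tibble(onset_ms = c(500, 1000), trial = 1:2)
  rec <- make_rec(matrix(3, 2, n), fs = 1000, events = events)
  ep <- make_epochs(rec, window = c(-100, 500), baseline = c(-100, 0))
  expect_equal(dim(ep$data)[2], 600)
  expect_equal(min(ep$times), -100)
  expect_equal(max(ep$times), 499)
  # constant channel is nulled by baseline correction
  expect_true(all(abs(ep$data) < 1e-12))
  expect_true(ep$baseline_state)
})

test_that("events too close to the recording edge are dropped with a reason", {
  mon <- tiny_montage(2)
  events <- tibble::tibble(onset_ms = c(50, 800), trial = 1:2)
  rec <- make_rec(matrix(0, 2, 1500), fs = 1000, events = events)
  ep <- make_epochs(rec, window = c(-100, 500))
  expect_equal(dim(ep$data)[3], 1)
  expect_equal(ep$rejection_log$reason, "edge")
  expect_equal(ep$rejection_log$trial, 1L)
})

test_that("amplitude rejection flags exactly the planted excursions", {
  mon <- tiny_montage(4)
  set.seed(3)
  d <- array(rnorm(4 * 100 * 10, 0, 5), c(4, 100, 10),
             dimnames = list(mon$name[1:4], NULL, NULL))
  bad <- c(2, 5, 9)
  for (i in bad) d[2, 50, i] <- 80 * sign(rnorm(1))
  ep <- erp_epochs(d, times = 0:99, sampling_rate = 1000, montage = mon,
                   trials = tibble::tibble(trial = 1:10, kept = TRUE),
                   baseline_state = TRUE)
  out <- reject_artifacts(ep, 75)
  expect_equal(which(!out$trials$kept), bad)
  expect_equal(nrow(out$rejection_log), length(bad))
  expect_true(all(out$rejection_log$max_abs_uV > 75))
  # bounded epochs are never rejected
  ep2 <- ep; ep2$data <- ep2$data / 10
  expect_true(all(reject_artifacts(ep2, 75)$trials$kept))
  # rejection is monotone in the threshold
  out60 <- reject_artifacts(ep, 60)
  expect_true(all(which(!out$trials$kept) %in% which(!out60$trials$kept)))
})

test_that("condition averaging is the arithmetic mean over kept correct trials", {
  mon <- tiny_montage(3)
  v <- matrix(rnorm(3 * 50), 3, 50)
  d <- array(c(v, v, -v), c(3, 50, 3), dimnames = list(mon$name, NULL, NULL))
  trials <- tibble::tibble(trial = 1:3, role = c("a", "a", "a"),
                           kept = TRUE, correct = c(TRUE, TRUE, TRUE))
  ep <- erp_epochs(d, times = 0:49, sampling_rate = 1000, montage = mon,
                   trials = trials, baseline_state = TRUE)
  # two identical trials -> the trial itself
  ev2 <- average_condition(ep_subset(ep, 1:2), list(role = "a"))
  expect_equal(ev2$data, v, ignore_attr = TRUE)
  # v and -v -> zero map
  ev0 <- average_condition(ep_subset(ep, 2:3), list(role = "a"))
  expect_true(all(abs(ev0$data) < 1e-12))
  # empty condition errors informatively
  expect_error(average_condition(ep, list(role = "missing")), "no surviving trials")
})

test_that("noisy averages converge at the CLT rate to the planted signal", {
  mon <- default_montage()
  p1 <- component_spec("P1", 116, 0, 22, gaussian_topography(mon, "OZ", 0.4), 5)
  scalp <- scalp_channels(mon)
  times <- seq(-100, 499, by = 2)
  sig <- outer(p1$topography[scalp], 5 * exp(-((times - 116)^2) / (2 * 22^2)))
  set.seed(4)
  noise_sd <- 3; n_tr <- 50
  d <- array(rep(sig, n_tr) + rnorm(length(sig) * n_tr, 0, noise_sd),
             c(length(scalp), length(times), n_tr),
             dimnames = list(scalp, NULL, NULL))
  ep <- erp_epochs(d, times = times, sampling_rate = 500, montage = mon,
                   trials = tibble::tibble(trial = seq_len(n_tr), kept = TRUE),
                   baseline_state = TRUE)
  ev <- average_condition(ep, list(), correct_only = FALSE)
  err <- abs(ev$data - sig)
  se <- noise_sd / sqrt(n_tr)
  expect_gt(mean(err < 3 * se), 0.99)   # per-sample CLT bound
  expect_lt(max(err), 6 * se)
  expect_equal(ev$n_trials, n_tr)
})

test_that("average re-referencing nulls the channel mean and preserves GFP", {
  mon <- tiny_montage(6)
  set.seed(5)
  data <- matrix(rnorm(6 * 40), 6, 40, dimnames = list(mon$name, NULL))
  ev <- make_evoked(data, 0:39, mon, ref = "recording")
  re <- rereference_average(ev)
  expect_lt(max(abs(colMeans(re$data))), 1e-9)
  # uniform map goes to zero
  ones <- make_evoked(matrix(1, 6, 1, dimnames = list(mon$name, NULL)), 0, mon)
  expect_true(all(rereference_average(ones)$data == 0))
  # idempotent
  expect_equal(rereference_average(re)$data, re$data)
  # GFP invariant under re-referencing from an arbitrary reference shift
  shifted <- ev
  shifted$data <- sweep(ev$data, 2, rnorm(40), `+`)  # random reference offsets
  expect_equal(gfp(rereference_average(shifted)), gfp(re), tolerance = 1e-10)
})

test_that("re-referencing and averaging commute (linearity)", {
  mon <- tiny_montage(5)
  set.seed(6)
  evs <- lapply(1:4, function(i) {
    make_evoked(matrix(rnorm(5 * 20), 5, 20, dimnames = list(mon$name, NULL)),
                0:19, mon, ref = "recording")
  })
  a <- grand_average(lapply(evs, rereference_average))
  b <- rereference_average(grand_average(evs))
  expect_equal(a$data, b$data, tolerance = 1e-12)
  # montage mismatch errors
  bad <- evs[[1]]
  rownames(bad$data) <- rev(rownames(bad$data))
  expect_error(grand_average(list(evs[[2]], bad)), "montage mismatch")
})
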
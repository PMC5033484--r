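planted_maps <- function(mon = default_montage()) {
  rbind(gaussian_topography(mon, c("OZ", "O1"), 0.4, 1),
        gaussian_topography(mon, c("POZ", "PO4"), 0.4, 1),
        gaussian_topography(mon, c("P7", "PO7"), 0.4, -1),
        gaussian_topography(mon, c("CB2", "PO6"), 0.35, -1))
}

# planted alternation of K maps at a given SNR (GFP_signal / GFP_noise)
planted_series <- function(tpl, per_map = 40, snr = 5, seed = 1) {
  set.seed(seed)
  K <- nrow(tpl); C <- ncol(tpl)
  lab <- rep(seq_len(K), each = per_map)
  amp <- runif(length(lab), 0.8, 1.6)
  X <- tpl[lab, , drop = FALSE] * amp
  noise <- matrix(rnorm(length(lab) * C, 0, mean(amp) / snr), length(lab))
  X <- X + noise
  X <- X - rowMeans(X)
  list(X = X, labels = lab)
}

test_that("a noiseless two-map alternation is recovered exactly", {
  tpl <- planted_maps()[c(1, 3), ]
  X <- tpl[rep(1:2, each = 20), ] * runif(40, 0.5, 2)
  models <- segment_microstates(X, k_range = 2)
  m <- models[[1]]
  cors <- abs(tpl %*% t(m$templates)) / ncol(tpl)   # unit-GFP rows: x.y/C = corr
  expect_equal(unname(apply(cors, 1, max)), c(1, 1), tolerance = 1e-10)
  expect_equal(m$gev_total, 1, tolerance = 1e-10)
  expect_lt(m$residual_variance, 1e-20)
})

test_that("K equal to the number of maps saturates the fit", {
  set.seed(2)
  mon <- default_montage()
  X <- matrix(rnorm(6 * 64), 6)
  X <- X - rowMeans(X)
  m <- segment_microstates(X, k_range = 6)[[1]]
  expect_equal(m$gev_total, 1, tolerance = 1e-10)
  expect_lt(m$residual_variance, 1e-20)
  expect_error(segment_microstates(X, k_range = 7), "exceeds")
})

test_that("the CV criterion penalty is monotone in K at fixed residual", {
  mon <- default_montage()
  base <- list(K = 3, residual_variance = 2, channels = scalp_channels(mon))
  class(base) <- "microstate_model"
  vals <- vapply(2:8, function(K) {
    m <- base; m$K <- K
    cross_validation_criterion(m)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # zero residual gives zero criterion regardless of K
  z <- base; z$residual_variance <- 0; z$K <- 5
  expect_equal(cross_validation_criterion(z), 0)
  # undefined beyond the channel bound
  small <- base; small$channels <- paste0("c", 1:4); small$K <- 3
  expect_error(cross_validation_criterion(small), "undefined")
})

test_that("planted maps and the planted K are recovered at SNR 5", {
  tpl <- planted_maps()
  k_hits <- 0; cors_all <- numeric(0)
  n_seed <- 50
  for (seed in seq_len(n_seed)) {
    ser <- planted_series(tpl, per_map = 40, snr = 5, seed = seed)
    models <- segment_microstates(ser$X, k_range = 2:8)
    best <- select_k(models)
    if (best$K == 4) k_hits <- k_hits + 1
    m4 <- models[["k4"]]
    cors <- apply(abs(tpl %*% t(m4$templates)) / ncol(tpl), 1, max)
    cors_all <- c(cors_all, cors)
  }
  expect_gte(k_hits / n_seed, 0.9)
  expect_gte(mean(cors_all), 0.95)
})

test_that("training GEV is non-decreasing in K", {
  ser <- planted_series(planted_maps(), per_map = 30, snr = 3, seed = 99)
  models <- segment_microstates(ser$X, k_range = 2:8)
  gevs <- vapply(models, `[[`, numeric(1), "gev_total")
  expect_true(all(diff(gevs) >= -1e-9))
})

test_that("segmentation is invariant to scaling and channel permutation", {
  ser <- planted_series(planted_maps(), per_map = 20, snr = 5, seed = 7)
  m1 <- segment_microstates(ser$X, k_range = 4)[[1]]
  m2 <- segment_microstates(ser$X * 3.7, k_range = 4)[[1]]
  expect_equal(m1$labels, m2$labels)
  expect_equal(m1$templates, m2$templates, tolerance = 1e-9)
  expect_equal(m1$gev_total, m2$gev_total, tolerance = 1e-12)
  perm <- sample(ncol(ser$X))
  m3 <- segment_microstates(ser$X[, perm], k_range = 4)[[1]]
  expect_equal(m3$labels, m1$labels)
  expect_equal(m3$templates, m1$templates[, perm], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("polarity-sensitive mode flips templates but not fit under sign flip", {
  ser <- planted_series(planted_maps(), per_map = 20, snr = 5, seed = 8)
  m1 <- segment_microstates(ser$X, k_range = 4, polarity = TRUE)[[1]]
  m2 <- segment_microstates(-ser$X, k_range = 4, polarity = TRUE)[[1]]
  expect_equal(m2$templates, -m1$templates, tolerance = 1e-9)
  expect_equal(m2$labels, m1$labels)
  expect_equal(m2$gev_total, m1$gev_total, tolerance = 1e-12)
  expect_equal(m2$cv, m1$cv, tolerance = 1e-12)
})

test_that("back-fitting labels and explained variance behave at the extremes", {
  mon <- default_montage()
  tpl <- planted_maps()
  scalp <- scalp_channels(mon)
  models <- segment_microstates(tpl[rep(1:4, each = 5), ], k_range = 4)
  m <- models[[1]]
  # evoked built purely from template 2 (as stored in the model)
  t2 <- m$templates[2, ]
  data <- t(outer(seq(0.5, 2, length.out = 30), t2))
  rownames(data) <- scalp
  ev <- make_evoked(data, 0:29, mon)
  bf <- backfit(m, ev)
  expect_true(all(bf$labels == 2))
  expect_equal(bf$per_map$explained_variance[2], 1, tolerance = 1e-10)
  expect_equal(sum(bf$per_map$explained_variance[-2]), 0)
  expect_equal(bf$per_map$coverage_ms[2], 30)
})

test_that("back-fit explained variance matches the direct summation oracle", {
  set.seed(10)
  mon <- default_montage()
  scalp <- scalp_channels(mon)
  ser <- planted_series(planted_maps(), per_map = 15, snr = 2, seed = 10)
  m <- segment_microstates(ser$X, k_range = 4)[[1]]
  X <- matrix(rnorm(40 * 64), 40)
  X <- X - rowMeans(X)
  ev <- make_evoked(t(X), 0:39, mon)
  rownames(ev$data) <- scalp
  bf <- backfit(m, ev)
  expect_equal(bf$per_map$explained_variance,
               oracle_backfit_ev(m$templates, X, polarity = TRUE),
               tolerance = 1e-10)
})

test_that("fit statistics produce one row per subject x condition x map", {
  mon <- default_montage()
  d <- design_config()
  rec <- dissociation_recipe(mon)
  s <- sim_config(n_subjects = 3, montage = mon, sampling_rate = 250,
                  components = rec$components, effects = rec$effects, noise_sd = 8)
  sim <- simulate_condition_evokeds(d, s, n_trials = 40, seed = 15)
  ga <- lapply(sim$conditions$condition_id, function(id)
    grand_average(lapply(sim$evokeds, `[[`, id)))
  gad <- lapply(ga, function(g) decimate_evoked(crop_evoked(g, c(0, 300)), 4))
  m <- segment_microstates(gad, k_range = 4)[[1]]
  fit <- fit_statistics(m, sim$evokeds, sim$conditions, window = c(0, 300))
  expect_equal(nrow(fit), 3 * 8 * 4)
  expect_true(all(fit$explained_variance >= 0 & fit$explained_variance <= 1 + 1e-12))
  rng <- map_component_ranges(m)
  expect_true(all(rng$range %in% c("P1", "N1", "other")))
})
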
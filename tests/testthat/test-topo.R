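test_that("GFP is the spatial RMS of an average-referenced map", {
  expect_equal(gfp(rep(0, 10)), 0)
  expect_equal(gfp(c(1, -1)), 1)
  set.seed(1)
  v <- random_map(paste0("ch", 1:64))
  expect_equal(gfp(v), sqrt(mean(v^2)), tolerance = 1e-12)
})

test_that("dissimilarity satisfies its algebraic identities and bounds", {
  set.seed(2)
  u <- random_map(paste0("ch", 1:64))
  v <- random_map(paste0("ch", 1:64))
  expect_equal(dissimilarity(u, 3 * u), 0, tolerance = 1e-12)
  expect_equal(dissimilarity(u, -u), 2)
  expect_equal(dissimilarity(u, v), dissimilarity(v, u))
  expect_equal(dissimilarity(u, v)^2, 2 * (1 - spatial_correlation(u, v)),
               tolerance = 1e-10)
  expect_error(dissimilarity(u, rep(0, 64)), "zero-GFP")
})

test_that("GFP and DISS are invariant to the original reference", {
  set.seed(3)
  mon <- tiny_montage(12)
  for (i in 1:20) {
    u <- rnorm(12); v <- rnorm(12)
    offset_u <- rnorm(1); offset_v <- rnorm(1)   # arbitrary reference shifts
    ru <- (u + offset_u) - mean(u + offset_u)
    rv <- (v + offset_v) - mean(v + offset_v)
    expect_equal(gfp(ru), gfp(u - mean(u)), tolerance = 1e-12)
    expect_equal(dissimilarity(ru, rv), dissimilarity(u - mean(u), v - mean(v)),
                 tolerance = 1e-12)
  }
})

test_that("identical conditions give zero dissimilarity and maximal p", {
  set.seed(4)
  n <- 6; C <- 8; TT <- 12
  A <- array(rnorm(n * C * TT), c(n, C, TT))
  A <- sweep(A, c(1, 3), apply(A, c(1, 3), mean))
  res <- tanova(A, A, n_perm = 200, seed = 1)
  expect_true(all(res$observed == 0))
  expect_true(all(res$p == 1))
  expect_equal(length(res$windows), 0)
})

test_that("exact TANOVA p-values match exhaustive enumeration at n = 5", {
  set.seed(5)
  n <- 5; C <- 6; TT <- 5
  A <- array(rnorm(n * C * TT), c(n, C, TT))
  B <- array(rnorm(n * C * TT, 0.4), c(n, C, TT))
  A <- sweep(A, c(1, 3), apply(A, c(1, 3), mean))
  B <- sweep(B, c(1, 3), apply(B, c(1, 3), mean))
  res <- tanova(A, B, n_perm = 200, seed = 2)
  expect_equal(res$method, "exact")
  expect_equal(res$n_perm, 32)
  expect_equal(res$p, oracle_tanova_p(A, B), tolerance = 1e-12)
  expect_true(all(res$p >= 1 / 32 & res$p <= 1))
})

test_that("TANOVA p-values are invariant to a consistent channel permutation", {
  set.seed(6)
  n <- 5; C <- 8; TT <- 4
  A <- array(rnorm(n * C * TT), c(n, C, TT))
  B <- array(rnorm(n * C * TT, 0.3), c(n, C, TT))
  A <- sweep(A, c(1, 3), apply(A, c(1, 3), mean))
  B <- sweep(B, c(1, 3), apply(B, c(1, 3), mean))
  perm <- sample(C)
  res1 <- tanova(A, B, n_perm = 200, seed = 3)
  res2 <- tanova(A[, perm, , drop = FALSE], B[, perm, , drop = FALSE],
                 n_perm = 200, seed = 3)
  expect_equal(res1$p, res2$p, tolerance = 1e-12)
  expect_equal(res1$observed, res2$observed, tolerance = 1e-12)
})

test_that("unpaired inputs and tiny permutation counts are rejected/flagged", {
  A <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  B <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  expect_error(tanova(A, B), "unpaired|mismatch")
  A <- sweep(A, c(1, 3), apply(A, c(1, 3), mean))
  expect_warning(tanova(A, A, n_perm = 50, seed = 1), "n_perm")
})

test_that("significant windows are maximal runs above the duration floor", {
  times <- 0:199
  p <- rep(1, 200)
  res <- list(times = times, p = p, alpha = 0.05, min_duration = 10)
  expect_equal(significant_windows(res, 0.05, 10), list())
  p[86:155] <- 0.01          # indices 86..155 -> times 85..154
  p[180:183] <- 0.01         # 4 ms: below the floor
  res$p <- p
  w <- significant_windows(res, 0.05, 10)
  expect_equal(length(w), 1)
  expect_equal(w[[1]], c(85, 155))
})

test_that("a planted topographic difference is detected where it was planted", {
  mon <- default_montage()
  rec <- dissociation_recipe(mon)
  s <- sim_config(n_subjects = 10, montage = mon, sampling_rate = 250,
                  components = rec$components, effects = rec$effects, noise_sd = 8)
  d <- design_config()
  hits <- 0
  n_rep <- 20
  for (seed in seq_len(n_rep)) {
    sim <- simulate_condition_evokeds(
      d, s, n_trials = 60, seed = 400 + seed,
      conditions = expand.grid(role = c("nontarget", "target"),
                               category = c("butterfly", "face"),
                               colour = "blue", stringsAsFactors = FALSE))
    faces <- lapply(sim$evokeds, function(e) {
      rereference_average(grand_average(e[grep("face", names(e))]))
    })
    butts <- lapply(sim$evokeds, function(e) {
      rereference_average(grand_average(e[grep("butterfly", names(e))]))
    })
    res <- tanova(faces, butts, n_perm = 500, seed = 500 + seed)
    ok <- any(vapply(res$windows, function(w) w[1] < 130 && w[2] > 100, logical(1)))
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.95)
})
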
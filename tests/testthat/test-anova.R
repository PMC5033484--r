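fixture_2x2 <- function(n = 6, seed = 1, effect_a = 0.8, effect_b = 0, inter = 0) {
  set.seed(seed)
  g <- expand.grid(subject = seq_len(n), A = c("a1", "a2"), B = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  g$y <- rnorm(nrow(g)) + rep(rnorm(n), 4) +
    ifelse(g$A == "a2", effect_a, 0) + ifelse(g$B == "b2", effect_b, 0) +
    ifelse(g$A == "a2" & g$B == "b2", inter, 0)
  g
}

test_that("two-level effects have epsilon exactly 1 and error df n-1", {
  g <- fixture_2x2(n = 19)
  tab <- rm_anova(g, dv = "y", within = c("A", "B"))
  expect_true(all(tab$gg_epsilon == 1))
  expect_true(all(tab$df_num == 1))
  expect_true(all(tab$df_den == 18))
})

test_that("identical values across conditions give F = 0", {
  g <- fixture_2x2(n = 6)
  g$y <- rep(rnorm(6), 4)                     # subject effect only
  tab <- rm_anova(g, dv = "y", within = c("A", "B"))
  expect_true(all(tab$F < 1e-20))
})

test_that("F, epsilon and partial eta squared match the brute-force oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    g <- expand.grid(subject = 1:6, A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                     C = c("c1", "c2"), stringsAsFactors = FALSE)
    g$y <- rnorm(nrow(g)) + rep(rnorm(6), 12)
    tab <- rm_anova(g, dv = "y", within = c("A", "B", "C"))
    ora <- oracle_rm_anova(g, dv = "y", subject = "subject", within = c("A", "B", "C"))
    m <- match(tab$effect, ora$effect)
    expect_false(anyNA(m))
    expect_equal(tab$F, ora$F[m], tolerance = 1e-8)
    expect_equal(tab$partial_eta_sq, ora$partial_eta_sq[m], tolerance = 1e-8)
    expect_equal(tab$gg_epsilon, ora$gg_epsilon[m], tolerance = 1e-8)
    expect_equal(tab$df_num, ora$df_num[m])
    expect_equal(tab$df_den, ora$df_den[m])
  }
})

test_that("F ratios agree with base-R aov error strata", {
  g <- fixture_2x2(n = 8, seed = 4, effect_a = 0.5, inter = 0.4)
  tab <- rm_anova(g, dv = "y", within = c("A", "B"))
  g2 <- g
  g2$subject <- factor(g2$subject); g2$A <- factor(g2$A); g2$B <- factor(g2$B)
  fit <- summary(stats::aov(y ~ A * B + Error(subject / (A * B)), data = g2))
  get_f <- function(stratum, term) {
    tb <- fit[[stratum]][[1]]
    tb[trimws(rownames(tb)) == term, "F value"]
  }
  expect_equal(tab$F[tab$effect == "A"], get_f("Error: subject:A", "A"), tolerance = 1e-10)
  expect_equal(tab$F[tab$effect == "B"], get_f("Error: subject:B", "B"), tolerance = 1e-10)
  expect_equal(tab$F[tab$effect == "A:B"], get_f("Error: subject:A:B", "A:B"), tolerance = 1e-10)
})

test_that("the partial eta squared identity holds for every effect", {
  set.seed(9)
  g <- expand.grid(subject = 1:7, A = c("a1", "a2", "a3"), B = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  g$y <- rnorm(nrow(g))
  tab <- rm_anova(g, dv = "y", within = c("A", "B"))
  expect_equal(tab$partial_eta_sq,
               tab$F * tab$df_num / (tab$F * tab$df_num + tab$df_den),
               tolerance = 1e-12)
  expect_true(all(tab$partial_eta_sq >= 0 & tab$partial_eta_sq <= 1))
  expect_true(all(tab$gg_epsilon <= 1 + 1e-12))
  expect_true(all(tab$gg_epsilon >= 1 / tab$df_num - 1e-12))
})

test_that("results are invariant to subject relabeling and dv shifts", {
  g <- fixture_2x2(n = 6, seed = 5, effect_a = 0.6)
  tab <- rm_anova(g, dv = "y", within = c("A", "B"))
  set.seed(6)
  perm <- sample(6)
  g_rel <- g; g_rel$subject <- perm[g_rel$subject]
  tab_rel <- rm_anova(g_rel, dv = "y", within = c("A", "B"))
  expect_equal(tab$F, tab_rel$F, tolerance = 1e-12)
  g_shift <- g; g_shift$y <- g_shift$y + 100
  tab_shift <- rm_anova(g_shift, dv = "y", within = c("A", "B"))
  expect_equal(tab$F, tab_shift$F, tolerance = 1e-8)
})

test_that("incomplete designs raise an error naming the missing cells", {
  g <- fixture_2x2(n = 4)
  g <- g[!(g$subject == 2 & g$A == "a2" & g$B == "b1"), ]
  expect_error(rm_anova(g, dv = "y", within = c("A", "B")), "incomplete cells")
})

test_that("type-I error of the F test is calibrated under the null", {
  set.seed(123)
  hits <- 0L
  for (i in 1:500) {
    g <- fixture_2x2(n = 6, seed = 1000 + i, effect_a = 0)
    tab <- rm_anova(g, dv = "y", within = c("A", "B"))
    if (tab$p_uncorrected[tab$effect == "A"] < 0.05) hits <- hits + 1L
  }
  rate <- hits / 500
  band <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 500)
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
})

test_that("planned contrasts equal the full model on balanced identity subsets", {
  g <- fixture_2x2(n = 6, seed = 7, effect_a = 0.5)
  sub <- planned_contrast(g, list(B = "b1"), dv = "y", within = "A")
  direct <- rm_anova(g[g$B == "b1", ], dv = "y", within = "A")
  expect_equal(sub$F, direct$F)
  expect_error(planned_contrast(g, list(B = "zzz"), dv = "y", within = "A"), "empty")
})
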
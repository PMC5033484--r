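#!/usr/bin/env Rscript
# Stage 3 — P1 and N170 component statistics.
#
# Finds the first qualifying peak on each condition's ROI-mean waveform,
# takes 40 ms mean amplitudes per electrode, and runs the repeated-measures
# ANOVA family: the five-factor deviant models (Deviant x Category x Colour x
# Location/Hemisphere x Site), the standards models, planned deviant-within-
# category contrasts, and the behavioural accuracy/RT models. Greenhouse-
# Geisser corrections and partial eta squared are reported throughout.

source("analysis/config.R")

sim <- analysis_sim()
conds <- analysis_conditions()
evokeds <- load_evokeds(sim$montage)
comps <- list(p1_component(), n170_component())

meas <- measure_components(evokeds, comps, conds)
write_events(meas, file.path(RESULTS_DIR, "measurements.tsv"))

show <- function(tab, effects = c("role", "category", "colour", "role:category")) {
  for (eff in effects) {
    row <- tab[tab$effect == eff, ]
    if (nrow(row) == 1)
      cat(sprintf("  %-14s F(%g,%g) = %6.2f, p_gg = %.4f, pes = %.3f\n",
                  eff, row$df_num, row$df_den, row$F, row$p_gg, row$partial_eta_sq))
  }
}

dev <- meas[meas$role != "standard" & !meas$peak_missing, ]
p1 <- dplyr::bind_cols(dev[dev$component == "P1", ],
                       electrode_factors(dev$electrode[dev$component == "P1"], "p1")[, c("location", "site")])
n1 <- dplyr::bind_cols(dev[dev$component == "N170", ],
                       electrode_factors(dev$electrode[dev$component == "N170"], "n170")[, c("hemisphere", "site")])

cat("— P1 deviants (mean amplitude) —\n")
p1_tab <- rm_anova(p1, dv = "mean_amplitude", subject = "subject",
                   within = c("role", "category", "colour", "location", "site"))
show(p1_tab)

cat("— N170 deviants (mean amplitude) —\n")
n1_tab <- rm_anova(n1, dv = "mean_amplitude", subject = "subject",
                   within = c("role", "category", "colour", "hemisphere", "site"))
show(n1_tab)

cat("— planned contrasts: deviant effect within each category (P1) —\n")
pc_b <- planned_contrast(p1, list(category = "butterfly"), dv = "mean_amplitude",
                         within = c("role", "colour", "location", "site"))
pc_f <- planned_contrast(p1, list(category = "face"), dv = "mean_amplitude",
                         within = c("role", "colour", "location", "site"))
show(pc_b, "role"); show(pc_f, "role")

cat("— standards (category/colour models) —\n")
std <- meas[meas$role == "standard" & !meas$peak_missing, ]
std_p1 <- dplyr::bind_cols(std[std$component == "P1", ],
                           electrode_factors(std$electrode[std$component == "P1"], "p1")[, c("location", "site")])
std_tab <- rm_anova(std_p1, dv = "mean_amplitude", subject = "subject",
                    within = c("category", "colour", "location", "site"))
show(std_tab, c("category", "colour"))

cat("— behaviour (deviants) —\n")
beh <- read_events(file.path(RESULTS_DIR, "behavior.tsv"))
bst <- behavior_stats(beh, rt_floor = 100)
cat(" accuracy:\n"); show(bst$accuracy)
cat(" reaction time:\n"); show(bst$rt)

anovas <- dplyr::bind_rows(
  tibble::tibble(model = "p1_deviants", p1_tab),
  tibble::tibble(model = "n170_deviants", n1_tab),
  tibble::tibble(model = "p1_dev_within_butterfly", pc_b),
  tibble::tibble(model = "p1_dev_within_face", pc_f),
  tibble::tibble(model = "p1_standards", std_tab),
  tibble::tibble(model = "behavior_accuracy", bst$accuracy),
  tibble::tibble(model = "behavior_rt", bst$rt)
)
write_events(anovas, file.path(RESULTS_DIR, "component_anovas.tsv"))
cat(sprintf("wrote %s/{measurements,component_anovas}.tsv\n", RESULTS_DIR))
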
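#!/usr/bin/env Rscript
# Generate the synthetic study inputs used by the downstream analysis
# scripts: bridge-crossing movies for both conditions, goal-network day
# stacks, a thickness-oscillation movie and a study table with programmed
# day effects.  Everything is seeded, and each artefact's ground truth is
# written alongside it.

library(physhab)

seed <- 2024L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## crossing movies: control crosses at 0.18 mm/min (te = 100 min), quinine
## at 0.06 mm/min (te = 300 min), matching the order of magnitude of typical
## observed crossing times (control ~1-2.5 h, quinine ~1.5-3.5 h and above)
speeds <- c(control = 0.18, quinine = 0.06)
for (cond in names(speeds)) {
  mv <- make_crossing_movie(crossing_movie_spec(
    speeds[[cond]], footprint = if (cond == "control") "sheet" else "string",
    seed = seed + match(cond, names(speeds))))
  write_image_stack(mv$stack, file.path(out, paste0("crossing_", cond, ".tif")),
                    ground_truth = list(te_min = mv$te_min,
                                        final_area_mm2 = mv$final_area_mm2))
  cat(sprintf("%s crossing movie: te = %g min, final area = %.2f mm2\n",
              cond, mv$te_min, mv$final_area_mm2))
}

## goal-network day stacks: control stays tree all four days; quinine turns
## mesh from Day 2 (the typical habituation trajectory)
for (cond in c("control", "quinine")) {
  for (day in 1:4) {
    state <- if (cond == "control" || day == 1) "tree" else "mesh"
    ds <- make_goal_day_stack(state, seed = seed + 100L + 10L * day +
                                match(cond, c("control", "quinine")))
    write_image_stack(ds$stack,
                      file.path(out, sprintf("goal_%s_day%d.tif", cond, day)),
                      ground_truth = list(state = state,
                                          network_times = ds$network_times))
  }
}
cat("goal day stacks written (control: tree x4; quinine: tree, mesh x3)\n")

## oscillation movie: two-region period field, 100 s and 150 s
pf <- matrix(100, 32, 32)
pf[, 17:32] <- 150
osc <- make_oscillation_movie(oscillation_movie_spec(
  pf, amplitude = 30, noise_sd = 6, seed = seed + 200L))
write_image_stack(osc$stack, file.path(out, "oscillation.tif"),
                  ground_truth = list(period_left_s = 100, period_right_s = 150))
cat(sprintf("oscillation movie: %d frames, true median omega = %.5f rad/s\n",
            n_frames(osc$stack), median(osc$omega_field)))

## study table: quinine area and speed rise over days, oscillation frequency
## dips then rises; control flat
tab <- make_study_table(study_table_spec(
  n_per_cell = 16,
  day_effects = list(quinine = list(area = c(0, 4, 8, 12),
                                    speed = c(0, 0.01, 0.02, 0.04),
                                    omega = c(-0.01, -0.005, 0.005, 0.01))),
  seed = seed + 300L))
write.csv(tab, file.path(out, "study_table.csv"), row.names = FALSE)
cat(sprintf("study table: %d samples x %d columns\n", nrow(tab), ncol(tab)))
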
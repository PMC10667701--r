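#!/usr/bin/env Rscript
# Behavioural indices from the simulated crossing movies: crossing times,
# bridge area at completion, speed and same-day control-mean normalization.

library(physhab)

roi <- bridge_roi(0, 0, 288, 288, far_edge = "top")
rows <- list()
for (cond in c("control", "quinine")) {
  mv <- read_image_stack(file.path("results/sim",
                                   paste0("crossing_", cond, ".tif")))
  st <- detect_crossing_times(mv, roi)
  # fixed threshold: the control sheet covers the whole bridge, leaving an
  # automatic threshold nothing to separate in the difference image
  area <- estimate_bridge_area(get_frame(mv, st$te_frame),
                               get_frame(mv, st$t0_frame), roi,
                               threshold_policy = 60)
  rows[[cond]] <- data.frame(condition = cond, te_min = st$te_min,
                             area_mm2 = area,
                             speed_mm_min = crossing_speed(18, st))
}
beh <- do.call(rbind, rows)
beh$normalized_speed <- normalize_by_control(
  beh$speed_mm_min, beh$speed_mm_min[beh$condition == "control"])

dir.create("results", showWarnings = FALSE)
write.csv(beh, "results/behavior_indices.csv", row.names = FALSE)
print(beh, row.names = FALSE)
cat(sprintf("\nquinine crosses at %.2fx the control speed and leaves %.1f mm2 on the bridge\n",
            beh$normalized_speed[beh$condition == "quinine"],
            beh$area_mm2[beh$condition == "quinine"]))
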
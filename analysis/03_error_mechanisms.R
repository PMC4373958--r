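#!/usr/bin/env Rscript

# Step 3: isolate the individual error mechanisms on the 5 cm plan and show
# what each does to the QA metrics: a +4% calibration offset (recovered by
# the reconstruction), a 2 mm setup shift (absorbed by the DTA), and the
# field-size diode response alone (a systematic underdose for these < 10 cm
# fields, growing more negative as the field shrinks). Writes
# results/error_mechanisms.csv.

suppressPackageStartupMessages(library(virtualqa))

spacing <- if (length(commandArgs(TRUE))) as.numeric(commandArgs(TRUE)[1]) else 2
dir.create("results", showWarnings = FALSE)

grid <- make_grid(spacing_mm = rep(spacing, 3))
rois <- roi_set(grid, 50)
plan <- compose_plan(50, 600, grid, rois = rois)
geo <- build_geometry()
pr <- sample_dose_at_diodes(plan, geo)

scenarios <- list(
  clean = error_model(field_size_response = FALSE),
  global_plus4 = error_model(global_scale = 0.04,
                             field_size_response = FALSE),
  shift_2mm = error_model(field_size_response = FALSE,
                          shift_mm = c(2, 0, 0)),
  field_size_only = error_model(field_size_response = TRUE, noise_sd = 0)
)

rows <- lapply(names(scenarios), function(nm) {
  em <- scenarios[[nm]]
  m <- simulate_measurement(pr, plan, em)
  p <- reconstruct_dose(plan, m, pr)
  g33 <- gamma_map_diode(m, plan$total_dose, geo, gamma_criteria(3, 3))
  g22 <- gamma_map_diode(m, plan$total_dose, geo, gamma_criteria(2, 2))
  data.frame(scenario = nm,
             pass2d_3_3 = g33$passing_rate,
             pass2d_2_2 = g22$passing_rate,
             iso_dev_pct = dose_deviation_pct(
               predicted_isocenter(p), isocenter_dose(plan$total_dose)),
             target_dmean_dev_pct = dose_deviation_pct(
               mean_dose(p, rois$target),
               mean_dose(plan$total_dose, rois$target)))
})
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
write.csv(tab, "results/error_mechanisms.csv", row.names = FALSE)

cat("\nfield-size response factor by plan equivalent square:\n")
for (d in c(10, 30, 50, 70, 90)) {
  ap <- bev_aperture(cylinder_mask(grid, d, 50), 72)
  sq <- equivalent_square_side(ap)
  cat(sprintf("  %d cm target: eq. square %.2f cm -> %+0.2f%%\n", d / 10, sq,
              100 * (field_size_response(sq) - 1)))
}
cat("\nall plans sit below the calibration zero crossing (~14.2 cm), so the\n")
cat("diode response is negative throughout and shrinks with field size.\n")
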
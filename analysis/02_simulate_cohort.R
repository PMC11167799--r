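#!/usr/bin/env Rscript
# Simulate a small cohort of tagged bass end to end through the full
# pipeline (track -> archive -> event -> fate -> geolocation -> export).
# Three fish: one clean fishery recovery, one predation, one premature
# detachment. Outputs land in results/pipeline_demo/.

library(bassgeo)

cfg <- run_config(
  seed = 42, n_fish = 3, n_days = 90,
  grid = list(nx = 30, ny = 30, cell_km = 5.2, style = "coastal_gradient"),
  events = list(
    NULL,
    list(kind = "predation", event_day = 60, stomach_days = 1.2,
         drift_days = 6),
    list(kind = "premature_detachment", event_day = 70, drift_days = 10)
  ))

out <- run_pipeline(cfg, "results/pipeline_demo")

for (r in out) {
  if (!is.null(r$error)) { cat("fish failed:", r$error, "\n"); next }
  cat(sprintf("%s: fate %-10s D_hat=(%6.2f, %6.2f) km^2/day\n",
              r$fish, r$fate$fate, r$model$D_res, r$model$D_mig))
}
cat("\nFates found:",
    paste(vapply(out, function(r) r$fate$fate, ""), collapse = ", "), "\n")
cat("Tracks and logs in results/pipeline_demo/\n")
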
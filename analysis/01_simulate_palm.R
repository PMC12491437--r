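#!/usr/bin/env Rscript
# Simulate single-molecule localization maps for the oligomer census.
#
# Generates ground-truth-labelled 7 x 7 um localization maps: a
# well-separated basal-like composition (mostly monomers and dimers with a
# tail of higher oligomers), plus a blinking variant used to exercise the
# 20 nm duplicate-discounting stage.  Outputs land in results/palm/.

library(gpcrdimer)

seed <- 20260921L
out <- file.path("results", "palm")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

composition <- c("1" = 50, "2" = 30, "3" = 15, "5" = 5)

clean <- simulate_localizations(palm_sim_config(
  composition, cluster_radius_nm = 10, loc_error_sd_nm = 5,
  blink_rate = 0, min_center_sep_nm = 300,
  seed = stage_seed(seed, "palm-clean")))

blinky <- simulate_localizations(palm_sim_config(
  composition, cluster_radius_nm = 10, loc_error_sd_nm = 5,
  blink_rate = 1, blink_sd_nm = 5, min_center_sep_nm = 300,
  seed = stage_seed(seed, "palm-blink")))

write_localizations(clean$map, file.path(out, "localizations_clean.csv"))
write_localizations(blinky$map, file.path(out, "localizations_blinking.csv"))
jsonlite::write_json(
  list(composition = as.list(composition),
       n_receptors = nrow(clean$truth$receptors),
       n_localizations_clean = n_points(clean$map),
       n_localizations_blinking = n_points(blinky$map),
       seed = seed),
  file.path(out, "simulation_truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "Simulated %d true receptors (%s). Clean map: %d localizations; blinking map: %d (x%.2f inflation from Poisson(1) re-blinks).\n",
  nrow(clean$truth$receptors),
  paste(sprintf("%s-mers: %d", names(composition), composition),
        collapse = ", "),
  n_points(clean$map), n_points(blinky$map),
  n_points(blinky$map) / n_points(clean$map)))
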
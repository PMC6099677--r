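#!/usr/bin/env Rscript
# StDev*Coeff contour fields for every CoMSIA field of the fitted model,
# with 80/20 percentile display levels, exported as OpenDX volumes.

suppressMessages(library(fieldqsar))
seed <- as.integer(Sys.getenv("FIELDQSAR_SEED", "1"))
dir.create("results", showWarnings = FALSE)

ds <- generate_dataset(generator_spec(seed = seed))$dataset
m <- qsar_model(ds, "comsia")
for (ft in unique(m$summary$column_meta$field_type)) {
  cf <- stdev_coeff_field(m, ft)
  lv <- threshold_levels(cf, 80, 20)
  path <- file.path("results", paste0("comsia_", sub("comsia_", "", ft), ".dx"))
  export_volumetric(cf, path, format = "dx")
  cat(sprintf("%-22s favored level %.4g, disfavored %.4g -> %s\n",
              ft, lv["favored"], lv["disfavored"], path))
}
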
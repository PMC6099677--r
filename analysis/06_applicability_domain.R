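#!/usr/bin/env Rscript
# Standardization-approach applicability domain: classify the simulated
# test compounds against the CoMSIA model's training descriptor space.

suppressMessages(library(fieldqsar))
seed <- as.integer(Sys.getenv("FIELDQSAR_SEED", "1"))
dir.create("results", showWarnings = FALSE)

ds <- generate_dataset(generator_spec(seed = seed))$dataset
m <- qsar_model(ds, "comsia")
rep <- ad_report(m)
utils::write.csv(rep, "results/applicability_domain.csv", row.names = FALSE)
print(rep, digits = 3)
cat(sprintf("%d / %d test compounds inside the domain\n",
            sum(rep$status == "inside"), nrow(rep)))
cat("wrote results/applicability_domain.csv\n")
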
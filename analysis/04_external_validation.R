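#!/usr/bin/env Rscript
# External validation, twice:
#  (a) the Golbraikh-Tropsha battery + rm2 on the simulated test set for the
#      full-field CoMFA and CoMSIA models;
#  (b) reproduction of the published condition table from the shipped
#      reference predictions (test set minus each model's flagged outliers).

suppressMessages(library(fieldqsar))
seed <- as.integer(Sys.getenv("FIELDQSAR_SEED", "1"))
dir.create("results", showWarnings = FALSE)

ds <- generate_dataset(generator_spec(seed = seed))$dataset
m_comfa <- qsar_model(ds, "comfa")
m_comsia <- qsar_model(ds, "comsia")
v_comfa <- validate_model(m_comfa)
v_comsia <- validate_model(m_comsia)
rep_syn <- validation_report(comfa = v_comfa$without_outliers,
                             comsia = v_comsia$without_outliers)
utils::write.csv(rep_syn, "results/validation_synthetic.csv",
                 row.names = FALSE)
cat("synthetic test set:\n")
print(rep_syn, digits = 3)

pred <- load_reference_tables()$predictions
metric_for <- function(model) {
  rows <- pred$test_set & !pred[[paste0(model, "_outlier")]]
  external_metrics(setNames(pred$experimental[rows], pred$compound[rows]),
                   setNames(pred[[paste0(model, "_predicted")]][rows],
                            pred$compound[rows]))
}
rep_ref <- validation_report(comfa = metric_for("comfa"),
                             comsia = metric_for("comsia"))
utils::write.csv(rep_ref, "results/validation_reference.csv",
                 row.names = FALSE)
cat("\npublished test set (outliers excluded):\n")
print(rep_ref, digits = 3)
cat("\nwrote results/validation_synthetic.csv, validation_reference.csv\n")
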
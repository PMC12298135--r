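#!/usr/bin/env Rscript
# Fit all six dwell models (GM, SWM, WM, UGM, UGM-18, TPM) to the virtual
# cohorts written by 01_simulate_cohorts.R and write the comparison tables
# (per-model Cerror mean +/- SD, per-solute SSE, population MTAC means, UF
# predicted vs measured, fitted lymphatic flow, plausibility flags) under
# results/benchmark/<species>/.

suppressPackageStartupMessages(library(pdwell))

seed <- 2027
for (species in c("pig", "human")) {
  dir <- file.path("results/cohorts", species)
  files <- list.files(dir, pattern = "^[PH]\\d+.*\\.json$", full.names = TRUE)
  files <- files[!grepl("_truth", files)]
  if (length(files) == 0) stop("run analysis/01_simulate_cohorts.R first")
  sessions <- lapply(files, read_session)
  message(sprintf("benchmarking %d %s sessions ...", length(sessions), species))
  rep <- run_benchmark(sessions, models = pd_models(), seed = seed)
  out <- file.path("results/benchmark", species)
  write_report(rep, out)
  message(sprintf("%s Cerror by model (mean +/- SD over sessions):", species))
  print(rep$cerror_by_model, row.names = FALSE)
  neg <- subset(rep$plausibility, flag_negative)
  if (nrow(neg) > 0) {
    message(sprintf("negative fitted MTACs (n = %d), by model/solute:", nrow(neg)))
    print(table(neg$model, neg$solute))
  }
}
message("tables written under results/benchmark/")
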
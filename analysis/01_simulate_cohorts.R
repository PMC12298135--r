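#!/usr/bin/env Rscript
# Generate the virtual study cohorts: 20 pig dwells and 9 human PETs with
# known ground-truth transport parameters, mirroring the measurement
# protocols of a 4 h test dwell (pig grid 0/10/20/30/60/120/180/240 min with
# blue dextran; human PET grid 20/120/240 min, plasma at 120 min only).
# Sessions and truths are written as JSON under results/cohorts/.

suppressPackageStartupMessages(library(pdwell))

seed <- 2026
out <- "results/cohorts"
dir.create(file.path(out, "pig"), recursive = TRUE, showWarnings = FALSE)
dir.create(file.path(out, "human"), recursive = TRUE, showWarnings = FALSE)

pig <- generate_cohort(20, "pig", seed = seed, noise = noise_model())
human <- generate_cohort(9, "human", seed = seed + 1, noise = noise_model())

save_cohort <- function(cohort, dir) {
  for (i in seq_along(cohort$sessions)) {
    ses <- cohort$sessions[[i]]
    write_session(ses, file.path(dir, paste0(ses$session_id, ".json")))
    tr <- cohort$truths[[i]]
    tr$pores <- unclass(tr$pores)
    jsonlite::write_json(tr, file.path(dir, paste0(ses$session_id, "_truth.json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
}
save_cohort(pig, file.path(out, "pig"))
save_cohort(human, file.path(out, "human"))

message(sprintf("wrote %d pig and %d human sessions under %s",
                length(pig$sessions), length(human$sessions), out))
message("example session:")
print(pig$sessions[[1]])
message(sprintf("measured UF of that session: %.0f mL", uf_measured(pig$sessions[[1]])))
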
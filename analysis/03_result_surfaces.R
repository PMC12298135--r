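#!/usr/bin/env Rscript
# Assemble the result surfaces from the benchmark tables: concentration
# profiles of a representative dwell under every model, the Cerror/SSE
# comparison, population MTAC means against the literature band, predicted
# vs measured ultrafiltration, and the fitted lymphatic flow distribution.
# Figures go to results/figures/ (PNG), a combined summary to
# results/summary.csv.

suppressPackageStartupMessages({
  library(pdwell)
  library(ggplot2)
})

fig_dir <- "results/figures"
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

read_tbl <- function(species, name) {
  path <- file.path("results/benchmark", species, paste0(name, ".csv"))
  if (!file.exists(path)) stop("run analysis/02_benchmark_models.R first")
  cbind(read.csv(path), species = species)
}

ce <- rbind(read_tbl("pig", "cerror_by_model"), read_tbl("human", "cerror_by_model"))
sse <- rbind(read_tbl("pig", "sse_by_model_solute"), read_tbl("human", "sse_by_model_solute"))
mt <- rbind(read_tbl("pig", "mtac_by_model_solute"), read_tbl("human", "mtac_by_model_solute"))
uf <- rbind(read_tbl("pig", "uf_pairs"), read_tbl("human", "uf_pairs"))
ly <- rbind(read_tbl("pig", "lymph_flow"), read_tbl("human", "lymph_flow"))

p1 <- ggplot(ce, aes(model, mean_cerror, fill = species)) +
  geom_col(position = position_dodge()) +
  geom_errorbar(aes(ymin = pmax(0, mean_cerror - sd_cerror),
                    ymax = mean_cerror + sd_cerror),
                position = position_dodge(0.9), width = 0.3) +
  labs(y = "Cerror (mean +/- SD)", x = NULL,
       title = "Total normalized concentration error by model") +
  theme_minimal()
ggsave(file.path(fig_dir, "cerror_by_model.png"), p1, width = 7, height = 4, dpi = 150)

p2 <- ggplot(sse, aes(model, solute, fill = mean_sse)) +
  geom_tile() +
  facet_wrap(~species) +
  scale_fill_viridis_c() +
  labs(title = "Per-solute normalized error (SSE)", x = NULL, y = NULL) +
  theme_minimal()
ggsave(file.path(fig_dir, "sse_matrix.png"), p2, width = 8, height = 4, dpi = 150)

ref <- data.frame(solute = names(literature_mtac()), ref = unname(literature_mtac()))
p3 <- ggplot(mt, aes(model, mean_mtac, fill = species)) +
  geom_col(position = position_dodge()) +
  geom_hline(data = ref, aes(yintercept = ref), linetype = "dashed") +
  geom_hline(data = ref, aes(yintercept = 0.9 * ref), linetype = "dotted") +
  geom_hline(data = ref, aes(yintercept = 1.1 * ref), linetype = "dotted") +
  facet_wrap(~solute, scales = "free_y") +
  labs(y = "MTAC (mL/min)", x = NULL,
       title = "Population-mean fitted MTAC vs literature band") +
  theme_minimal() +
  theme(axis.text.x = element_text(angle = 45, hjust = 1))
ggsave(file.path(fig_dir, "mtac_population.png"), p3, width = 9, height = 6, dpi = 150)

p4 <- ggplot(uf, aes(uf_measured, uf_tpm_predicted, colour = species)) +
  geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
  geom_point() +
  labs(x = "measured UF (mL)", y = "TPM-predicted UF (mL)",
       title = "Predicted vs measured ultrafiltration") +
  theme_minimal()
ggsave(file.path(fig_dir, "uf_predicted_vs_measured.png"), p4,
       width = 5.5, height = 4.5, dpi = 150)

p5 <- ggplot(ly, aes(species, L)) +
  geom_boxplot() +
  labs(y = "fitted lymphatic flow L (mL/min)", x = NULL,
       title = "Fitted lymphatic flow") +
  theme_minimal()
ggsave(file.path(fig_dir, "lymph_flow.png"), p5, width = 4, height = 4, dpi = 150)

# representative dwell: measured points vs every model's prediction
ses <- read_session(list.files("results/cohorts/pig", pattern = "^P01.*[0-9]\\.json$",
                               full.names = TRUE)[1])
vol <- session_volume_profile(ses)
fits <- lapply(setNames(pd_models(), pd_models()),
               function(m) fit_model(m, ses, vol, seed = 42))
prof <- do.call(rbind, lapply(names(fits), function(m) {
  p <- fits[[m]]$pred
  data.frame(model = m, solute = rep(rownames(p), ncol(p)),
             time = rep(ses$dialysate_times, each = nrow(p)),
             cd = as.vector(p))
}))
meas <- data.frame(solute = rep(ses$solutes, length(ses$dialysate_times)),
                   time = rep(ses$dialysate_times, each = length(ses$solutes)),
                   cd = as.vector(ses$dialysate_conc))
p6 <- ggplot(prof, aes(time, cd, colour = model)) +
  geom_line() +
  geom_point(data = meas, aes(time, cd), inherit.aes = FALSE, size = 1) +
  facet_wrap(~solute, scales = "free_y") +
  labs(x = "dwell time (min)", y = "dialysate concentration (mmol/L)",
       title = paste("Model predictions vs measurements,", ses$session_id)) +
  theme_minimal()
ggsave(file.path(fig_dir, "profiles_example.png"), p6, width = 9, height = 5.5, dpi = 150)

write.csv(ce, "results/summary.csv", row.names = FALSE)
message("figures under ", fig_dir, "; summary at results/summary.csv")
message("Cerror summary:")
print(ce, row.names = FALSE)
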
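# Benchmark driver: fit all six models to a cohort of dwell sessions and
# assemble the comparison surfaces (per-model Cerror mean +/- SD, per-solute
# SSE matrix, population MTAC means, UF predicted vs measured, fitted
# lymphatic flow, plausibility flags).

#' Literature MTAC reference values for the plausibility band
#'
#' @param config YAML file of per-solute reference MTACs (mL/min).
#' @return Named numeric vector.
#' @export
literature_mtac <- function(config = system.file("extdata", "literature_mtac.yaml",
                                                 package = "pdwell")) {
  unlist(yaml::read_yaml(config))
}

#' Fit one model to one session
#'
#' Dispatcher over the model registry ([pd_models()]): GM/SWM are derived in
#' closed form (zero fitted parameters), WM by linear regression, UGM,
#' UGM-18 and TPM by bounded multistart minimization.
#'
#' @param model_id One of `"GM", "SWM", "WM", "UGM", "UGM18", "TPM"`.
#' @param session A [dwell_session()].
#' @param volume A [volume_profile()]; defaults to the session's own
#'   (indicator-based when a blue-dextran series is present, else linear).
#' @param seed Seed for the multistart models.
#' @param n_restarts Restarts for the multistart models.
#' @param ... Passed through to the model-specific fitter.
#' @return A [fit_result()].
#' @export
fit_model <- function(model_id, session, volume = session_volume_profile(session),
                      seed = 1, n_restarts = 10, ...) {
  model_id <- match.arg(model_id, pd_models())
  switch(model_id,
    GM = fit_garred(session, volume, f = 0, ...),
    SWM = fit_garred(session, volume, f = 0.5, ...),
    WM = fit_wm(session, volume, ...),
    UGM = fit_ugm(session, volume, free_fct = FALSE, seed = seed,
                  n_restarts = n_restarts, ...),
    UGM18 = fit_ugm(session, volume, free_fct = TRUE, seed = seed,
                    n_restarts = n_restarts, ...),
    TPM = fit_tpm(session, volume, seed = seed, n_restarts = n_restarts, ...))
}

#' Run the full model benchmark on a cohort
#'
#' Fits every requested model to every session, never aborting the cohort on
#' an individual failure (failures are recorded and excluded from the
#' aggregates, with a count). Returns a `benchmark_report` carrying all fits
#' plus the aggregate tables.
#'
#' @param sessions List of [dwell_session()]s.
#' @param models Character vector from [pd_models()].
#' @param seed Master seed; per-(session, model) seeds derive from it.
#' @param n_restarts Restarts for the multistart models.
#' @param reference Named literature MTAC vector for the plausibility band
#'   (`NULL` disables the band; negative-MTAC flags always fire).
#' @param plaus_band Half-width of the plausibility band (default 0.10).
#' @param ... Passed to [fit_model()].
#' @return Object of class `benchmark_report`; see [write_report()].
#' @export
run_benchmark <- function(sessions, models = pd_models(), seed = 1,
                          n_restarts = 10, reference = literature_mtac(),
                          plaus_band = 0.10, ...) {
  stopifnot(length(sessions) >= 1)
  set.seed(seed)
  fit_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 length(sessions) * length(models)),
                      nrow = length(sessions))
  fits <- list()
  failures <- list()
  for (i in seq_along(sessions)) {
    ses <- sessions[[i]]
    vol <- session_volume_profile(ses)
    for (j in seq_along(models)) {
      m <- models[j]
      key <- paste(ses$session_id, m, sep = ":")
      fit <- tryCatch(
        fit_model(m, ses, vol, seed = fit_seeds[i, j],
                  n_restarts = n_restarts, ...),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures[[key]] <- conditionMessage(fit)
      } else {
        fits[[key]] <- fit
      }
    }
  }
  structure(list(
    fits = fits, failures = failures,
    models = models,
    session_ids = vapply(sessions, `[[`, "", "session_id"),
    cerror_by_model = aggregate_cerror(fits, models),
    sse_by_model_solute = aggregate_sse(fits, models),
    mtac_by_model_solute = aggregate_mtac(fits, models),
    uf_pairs = uf_table(fits, sessions),
    lymph_flow = lymph_table(fits),
    plausibility = plausibility_table(fits, reference, plaus_band),
    seed = seed
  ), class = "benchmark_report")
}

fit_field <- function(fits, field) lapply(fits, `[[`, field)

rbind_or_empty <- function(rows, template) {
  if (length(rows) == 0) return(template)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

aggregate_cerror <- function(fits, models) {
  mid <- vapply(fits, `[[`, "", "model_id")
  rbind_or_empty(lapply(models, function(m) {
    ce <- vapply(fits[mid == m], `[[`, numeric(1), "cerror")
    ce <- ce[is.finite(ce)]
    data.frame(model = m, mean_cerror = mean(ce),
               sd_cerror = if (length(ce) > 1) sd(ce) else 0,
               n = length(ce))
  }), data.frame(model = character(0), mean_cerror = numeric(0),
                 sd_cerror = numeric(0), n = integer(0)))
}

aggregate_sse <- function(fits, models) {
  mid <- vapply(fits, `[[`, "", "model_id")
  rows <- list()
  for (m in models) {
    ss <- fit_field(fits[mid == m], "sse")
    solutes <- unique(unlist(lapply(ss, names)))
    for (s in solutes) {
      v <- vapply(ss, function(x) x[[s]] %||% NA_real_, numeric(1))
      v <- v[is.finite(v)]
      rows[[paste(m, s)]] <- data.frame(model = m, solute = s,
                                        mean_sse = mean(v), n = length(v))
    }
  }
  rbind_or_empty(rows, data.frame(model = character(0), solute = character(0),
                                  mean_sse = numeric(0), n = integer(0)))
}

aggregate_mtac <- function(fits, models) {
  mid <- vapply(fits, `[[`, "", "model_id")
  rows <- list()
  for (m in models) {
    mt <- lapply(fits[mid == m], function(f) f$params$mtac)
    solutes <- unique(unlist(lapply(mt, names)))
    for (s in solutes) {
      v <- vapply(mt, function(x) x[[s]] %||% NA_real_, numeric(1))
      ok <- v[is.finite(v)]
      rows[[paste(m, s)]] <- data.frame(
        model = m, solute = s, mean_mtac = mean(ok),
        sd_mtac = if (length(ok) > 1) sd(ok) else 0,
        n = length(ok), n_negative = sum(ok < 0))
    }
  }
  rbind_or_empty(rows, data.frame(model = character(0), solute = character(0),
                                  mean_mtac = numeric(0), sd_mtac = numeric(0),
                                  n = integer(0), n_negative = integer(0)))
}

uf_table <- function(fits, sessions) {
  mid <- vapply(fits, `[[`, "", "model_id")
  tpm <- fits[mid == "TPM"]
  tpm_by_session <- setNames(tpm, vapply(tpm, `[[`, "", "session_id"))
  do.call(rbind, lapply(sessions, function(ses) {
    f <- tpm_by_session[[ses$session_id]]
    data.frame(session_id = ses$session_id,
               uf_measured = uf_measured(ses),
               uf_tpm_predicted = if (is.null(f)) NA_real_ else f$params$uf_pred)
  }))
}

lymph_table <- function(fits) {
  mid <- vapply(fits, `[[`, "", "model_id")
  tpm <- fits[mid == "TPM"]
  if (length(tpm) == 0) {
    return(data.frame(session_id = character(0), L = numeric(0)))
  }
  data.frame(session_id = vapply(tpm, `[[`, "", "session_id"),
             L = vapply(tpm, function(f) f$params$L, numeric(1)),
             row.names = NULL)
}

plausibility_table <- function(fits, reference, band) {
  rows <- lapply(fits, function(f) {
    mt <- f$params$mtac
    do.call(rbind, lapply(names(mt), function(s) {
      v <- mt[[s]]
      ref <- if (!is.null(reference) && s %in% names(reference)) reference[[s]] else NA_real_
      data.frame(session_id = f$session_id, model = f$model_id, solute = s,
                 mtac = v,
                 flag_negative = is.finite(v) && v < 0,
                 flag_outside_band = is.finite(ref) && is.finite(v) &&
                   abs(v - ref) > band * ref)
    }))
  })
  rbind_or_empty(rows, data.frame(
    session_id = character(0), model = character(0), solute = character(0),
    mtac = numeric(0), flag_negative = logical(0),
    flag_outside_band = logical(0)))
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d sessions x %d models (%d fits, %d failures)\n",
              length(x$session_ids), length(x$models), length(x$fits),
              length(x$failures)))
  print(x$cerror_by_model, row.names = FALSE)
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' CSV tables (`cerror_by_model.csv`, `sse_by_model_solute.csv`,
#' `mtac_by_model_solute.csv`, `uf_pairs.csv`, `lymph_flow.csv`,
#' `plausibility.csv`) plus a JSON summary (`summary.json`).
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("cerror_by_model", "sse_by_model_solute", "mtac_by_model_solute",
              "uf_pairs", "lymph_flow", "plausibility")
  for (tb in tables) {
    write.csv(report[[tb]], file.path(dir, paste0(tb, ".csv")), row.names = FALSE)
  }
  summary <- list(
    n_sessions = length(report$session_ids),
    models = report$models,
    n_fits = length(report$fits),
    n_failures = length(report$failures),
    failures = report$failures,
    seed = report$seed)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
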
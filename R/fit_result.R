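# FitResult: fitted parameters plus error metrics for one (model, session).

#' Assemble a fit result with normalized error metrics
#'
#' Given a model's dialysate prediction on the session's measured grid,
#' computes the normalized per-solute SSE, the total Cerror, and (when a
#' predicted volume trajectory is supplied) Verror and the combined TPM
#' criterion `Cerror + Verror`. Solutes whose derivation failed (all-`NA`
#' prediction rows) are excluded from the error sums and flagged.
#'
#' @param model_id One of `"GM", "SWM", "WM", "UGM", "UGM18", "TPM"`.
#' @param session_id Session identifier.
#' @param params Named list of fitted/derived parameters.
#' @param pred Predicted dialysate matrix (solutes x measured times), mmol/L.
#' @param session The [dwell_session()] that was fitted.
#' @param V_pred,V_meas Optional predicted/measured volumes for Verror.
#' @param n_restarts,best_restart,converged,seed Multistart metadata.
#' @param elapsed Wall time in seconds (informational only).
#' @param flags Character vector of anomalies (failed solutes, sign changes).
#' @param combined_root Cerror reading, see [cerror()].
#' @return An object of class `pd_fit`.
#' @export
fit_result <- function(model_id, session_id, params, pred, session,
                       V_pred = NULL, V_meas = NULL,
                       n_restarts = 0L, best_restart = NA_integer_,
                       converged = TRUE, seed = NA_integer_,
                       elapsed = NA_real_, flags = character(0),
                       combined_root = FALSE) {
  meas <- session$dialysate_conc
  ok <- rownames(pred)[apply(pred, 1, function(r) all(is.finite(r)))]
  if (length(ok) < nrow(pred)) {
    flags <- c(flags, paste0("no prediction for solute(s): ",
                             paste(setdiff(rownames(pred), ok), collapse = ", ")))
  }
  pred_n <- normalize_matrix(pred[ok, , drop = FALSE], session)
  meas_n <- normalize_matrix(meas[ok, , drop = FALSE], session)
  sse <- setNames(rep(NA_real_, nrow(pred)), rownames(pred))
  for (s in ok) sse[[s]] <- sse_solute(pred_n[s, ], meas_n[s, ])
  ce <- cerror(pred_n, meas_n, combined_root = combined_root)
  ve <- if (!is.null(V_pred)) verror(V_pred, V_meas) else NA_real_
  structure(list(
    model_id = model_id, session_id = session_id, params = params,
    pred = pred, cerror = ce, sse = sse, verror = ve,
    criteria = if (is.finite(ve)) ce + ve else NA_real_,
    n_restarts = n_restarts, best_restart = best_restart,
    converged = converged, seed = seed, elapsed = elapsed, flags = flags
  ), class = "pd_fit")
}

#' @export
print.pd_fit <- function(x, ...) {
  cat(sprintf("<pd_fit> %s on %s: Cerror = %.4g", x$model_id, x$session_id,
              x$cerror))
  if (is.finite(x$verror)) cat(sprintf(", Verror = %.4g", x$verror))
  cat("\n")
  if (!is.null(x$params$mtac)) {
    cat("  MTAC (mL/min): ",
        paste(sprintf("%s=%.3g", names(x$params$mtac), x$params$mtac),
              collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$params$L)) cat(sprintf("  L = %.3g mL/min\n", x$params$L))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' The model registry
#' @return Character vector of implemented model identifiers.
#' @export
pd_models <- function() c("GM", "SWM", "WM", "UGM", "UGM18", "TPM")
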
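# Error functionals and ultrafiltration accounting.

#' Per-solute normalized concentration error (SSE)
#'
#' Root mean square of the residuals between normalized predicted and
#' measured dialysate concentrations for one solute:
#' `sqrt(sum((pred - meas)^2) / nt)`.
#'
#' @param pred,meas Normalized concentration series on a shared time grid.
#' @return Dimensionless scalar.
#' @export
sse_solute <- function(pred, meas) {
  if (length(pred) == 0) stop("empty concentration series", call. = FALSE)
  if (length(pred) != length(meas)) {
    stop("prediction and measurement grids differ", call. = FALSE)
  }
  sqrt(sum((pred - meas)^2) / length(pred))
}

#' Total normalized concentration error (Cerror)
#'
#' Default reading: the sum over solutes of the per-solute normalized RMSE
#' ([sse_solute()]), so that for a single solute Cerror equals SSE. With
#' `combined_root = TRUE` a single root is taken over the pooled
#' solute-and-time sum of squares instead.
#'
#' @param pred,meas Normalized concentration matrices (solutes x times) with
#'   matching dimnames.
#' @param combined_root Use the pooled single-root reading.
#' @return Dimensionless scalar, >= 0.
#' @export
cerror <- function(pred, meas, combined_root = FALSE) {
  if (!identical(dim(pred), dim(meas))) {
    stop("prediction and measurement grids differ", call. = FALSE)
  }
  if (!is.null(rownames(pred)) && !is.null(rownames(meas))) {
    meas <- meas[rownames(pred), , drop = FALSE]
  }
  if (combined_root) {
    return(sqrt(sum((pred - meas)^2) / ncol(pred)))
  }
  sum(vapply(seq_len(nrow(pred)),
             function(i) sse_solute(pred[i, ], meas[i, ]), numeric(1)))
}

#' Normalized intraperitoneal volume error (Verror)
#'
#' `sqrt(sum(((V_pred - V_meas) / max(V_meas))^2) / nt)` over the times at
#' which the volume was measured. Scale-invariant: multiplying all volumes by
#' a constant leaves it unchanged.
#'
#' @param V_pred,V_meas Predicted and measured volumes (mL) on a shared grid.
#' @return Dimensionless scalar.
#' @export
verror <- function(V_pred, V_meas) {
  if (length(V_meas) < 1) stop("need at least one measured volume", call. = FALSE)
  if (length(V_pred) != length(V_meas)) {
    stop("prediction and measurement grids differ", call. = FALSE)
  }
  vmax <- max(V_meas)
  if (vmax == 0) stop("max measured volume is zero", call. = FALSE)
  sqrt(sum(((V_pred - V_meas) / vmax)^2) / length(V_meas))
}

#' Measured ultrafiltration over the dwell
#'
#' `UF = drain + residual_after - (fill + residual_before)`; negative values
#' indicate net fluid absorption.
#'
#' @param session A [dwell_session()].
#' @return UF in mL.
#' @export
uf_measured <- function(session) {
  v <- c(session$drain_volume, session$residual_after,
         session$fill_volume, session$residual_before)
  if (any(vapply(v, is.null, logical(1))) || any(!is.finite(v))) {
    stop("uf_measured requires fill, drain and both residual volumes",
         call. = FALSE)
  }
  session$drain_volume + session$residual_after -
    (session$fill_volume + session$residual_before)
}
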
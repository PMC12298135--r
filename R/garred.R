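# Garred-family models: closed-form MTAC derivation (GM: f = 0;
# simplified Waniewski variant SWM: f = 0.5) and the matching forward
# predictor used to score the derived MTAC against the measured series.

#' Closed-form MTAC from dwell endpoints (Garred family)
#'
#' `MTAC = (Vmean / dt) * ln( V_start^(1-f) * (cp_mean - cd_start) /
#' (V_end^(1-f) * (cp_mean - cd_end)) )` with natural log. `f = 0` gives the
#' Garred model, `f = 0.5` the simplified Waniewski variant; when the start
#' and end volumes are equal the two coincide. Pig endpoints are t = 0 and
#' 240 min; for humans the first measured time (20 min) substitutes for t = 0
#' and, by default, the elapsed time between the substituted endpoints
#' (220 min) is used as `dt`.
#'
#' @param session A [dwell_session()].
#' @param volume A [volume_profile()] for the dwell.
#' @param f Convective factor, 0 (GM) or 0.5 (SWM).
#' @param solute Solute name.
#' @param eq2_elapsed_time If `TRUE` (default) `dt` is the elapsed time
#'   between the endpoint samples; if `FALSE`, the nominal 240 min.
#' @return MTAC in mL/min, or `NA` (with a warning) when the plasma-dialysate
#'   gradient changes sign between the endpoints and the log is undefined.
#' @export
mtac_garred <- function(session, volume, f, solute, eq2_elapsed_time = TRUE) {
  stopifnot(f %in% c(0, 0.5))
  tt <- session$dialysate_times
  t_start <- tt[1]
  t_end <- tt[length(tt)]
  dt <- if (eq2_elapsed_time) t_end - t_start else 240
  cp_mean <- mean(session$plasma_conc[solute, ])
  cd <- session$dialysate_conc[solute, ]
  V_start <- volume_at(volume, t_start)
  V_end <- volume_at(volume, t_end)
  num <- V_start^(1 - f) * (cp_mean - cd[1])
  den <- V_end^(1 - f) * (cp_mean - cd[length(cd)])
  if (!is.finite(num / den) || num / den <= 0) {
    warning("undefined log argument for solute '", solute,
            "': plasma-dialysate gradient changes sign between endpoints")
    return(NA_real_)
  }
  unname(volume_mean(volume) / dt * log(num / den))
}

#' Forward dialysate prediction for the Garred family
#'
#' Algebraic inverse of [mtac_garred()]:
#' `cd(t) = cp_mean - (cp_mean - cd_start) * (V_start / V(t))^(1-f) *
#' exp(-MTAC * (t - t_start) / Vmean)`.
#'
#' @param mtac MTAC (mL/min).
#' @param f Convective factor, 0 or 0.5.
#' @param volume A [volume_profile()].
#' @param cp_mean Mean plasma concentration (mmol/L).
#' @param cd_start Dialysate concentration at `t_start` (mmol/L).
#' @param times Prediction times (min).
#' @param t_start Time of `cd_start` (min); defaults to the profile start.
#' @return Predicted dialysate concentrations (mmol/L) at `times`.
#' @export
forward_garred <- function(mtac, f, volume, cp_mean, cd_start, times,
                           t_start = volume$times[1]) {
  V_start <- volume_at(volume, t_start)
  Vt <- volume_at(volume, times)
  cp_mean - (cp_mean - cd_start) * (V_start / Vt)^(1 - f) *
    exp(-mtac * (times - t_start) / volume_mean(volume))
}

#' Derive Garred-family MTACs for every solute and score the fit
#'
#' Runs [mtac_garred()] per solute, predicts the full measured grid with
#' [forward_garred()], and assembles a [fit_result()] with normalized error
#' metrics. Zero parameters are fitted; the derivation is closed-form.
#'
#' @param session A [dwell_session()].
#' @param volume A [volume_profile()]; defaults to the session's own.
#' @param f 0 (GM) or 0.5 (SWM).
#' @param eq2_elapsed_time See [mtac_garred()].
#' @return A [fit_result()].
#' @export
fit_garred <- function(session, volume = session_volume_profile(session), f = 0,
                       eq2_elapsed_time = TRUE) {
  tt <- session$dialysate_times
  solutes <- session$solutes
  pred <- session$dialysate_conc
  pred[] <- NA_real_
  mtac <- setNames(rep(NA_real_, length(solutes)), solutes)
  flags <- character(0)
  for (s in solutes) {
    m <- withCallingHandlers(
      mtac_garred(session, volume, f, s, eq2_elapsed_time),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    mtac[[s]] <- m
    if (is.finite(m)) {
      pred[s, ] <- forward_garred(m, f, volume, mean(session$plasma_conc[s, ]),
                                  session$dialysate_conc[s, 1], tt,
                                  t_start = tt[1])
    }
  }
  fit_result(
    model_id = if (f == 0) "GM" else "SWM",
    session_id = session$session_id,
    params = list(mtac = mtac, f = f),
    pred = pred, session = session, flags = flags)
}
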
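# Volume estimation and preprocessing: residual-volume dilution,
# intraperitoneal volume profiles, plasma interpolation, normalization.

#' Residual volume from indicator (total protein / albumin) dilution
#'
#' After a complete drain, the cavity retains an unknown residual volume
#' `Vres` of fluid with protein concentration `c_pre`. Flushing with
#' `flush_volume` mL of protein-free fluid and remixing gives concentration
#' `c_post`. Mass balance `c_post * (Vres + flush_volume) = c_pre * Vres`
#' solves to `Vres = flush_volume * c_post / (c_pre - c_post)`.
#'
#' @param c_pre Indicator concentration in the drained fluid (g/L).
#' @param c_post Indicator concentration after the flush (g/L).
#' @param flush_volume Flush volume (mL).
#' @return Residual volume in mL.
#' @export
residual_volume <- function(c_pre, c_post, flush_volume) {
  stopifnot(flush_volume > 0, c_post >= 0)
  if (c_post >= c_pre) {
    stop("non-physical dilution: post-flush concentration (", c_post,
         ") not below pre-flush concentration (", c_pre,
         "); residual volume unreliable", call. = FALSE)
  }
  flush_volume * c_post / (c_pre - c_post)
}

# VolumeProfile ----------------------------------------------------------------

#' Intraperitoneal volume profile
#'
#' @param times Times (min).
#' @param V Volumes (mL), one per time.
#' @param provenance `"linear"`, `"indicator"` or `"simulated"`.
#' @return An object of class `volume_profile` with fields `times`, `V`,
#'   `provenance`, `V0` (first) and `V240` (last).
#' @export
volume_profile <- function(times, V, provenance = c("linear", "indicator", "simulated")) {
  provenance <- match.arg(provenance)
  stopifnot(length(times) == length(V), all(diff(times) > 0))
  if (any(V <= 0)) stop("non-physical volume profile: V <= 0", call. = FALSE)
  structure(list(times = as.numeric(times), V = as.numeric(V),
                 provenance = provenance,
                 V0 = V[[1]], V240 = V[[length(V)]]),
            class = "volume_profile")
}

#' @export
print.volume_profile <- function(x, ...) {
  cat(sprintf("<volume_profile> %s, t = [%g, %g] min, V = [%g, %g] mL\n",
              x$provenance, min(x$times), max(x$times), x$V0, x$V240))
  invisible(x)
}

#' Evaluate a volume profile at arbitrary times
#'
#' Linear interpolation on the profile grid; clamped at the grid ends.
#'
#' @param profile A [volume_profile()].
#' @param t Times (min), vectorized.
#' @return Volumes in mL.
#' @export
volume_at <- function(profile, t) {
  stats::approx(profile$times, profile$V, xout = t, rule = 2)$y
}

#' Mean intraperitoneal volume over the profile grid (mL)
#' @param profile A [volume_profile()].
#' @export
volume_mean <- function(profile) mean(profile$V)

#' Volume rate of change on the profile grid (mL/min)
#'
#' For a linear profile this is the constant slope; otherwise central
#' differences on the grid (one-sided at the ends).
#'
#' @param profile A [volume_profile()].
#' @return Numeric vector aligned with `profile$times`.
#' @export
volume_slope <- function(profile) {
  tt <- profile$times
  V <- profile$V
  if (profile$provenance == "linear") {
    return(rep((V[length(V)] - V[1]) / (tt[length(tt)] - tt[1]), length(tt)))
  }
  n <- length(tt)
  d <- numeric(n)
  d[1] <- (V[2] - V[1]) / (tt[2] - tt[1])
  d[n] <- (V[n] - V[n - 1]) / (tt[n] - tt[n - 1])
  if (n > 2) {
    d[2:(n - 1)] <- (V[3:n] - V[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
  }
  d
}

#' Linear intraperitoneal volume profile from session endpoints
#'
#' The initial/final intraperitoneal volume is the sum of the
#' instilled/drained volume and the corresponding residual volume; the
#' profile is affine in time between them on the session's dialysate grid.
#' For human sessions the first measured time (20 min) anchors the initial
#' volume.
#'
#' @param session A [dwell_session()].
#' @return A [volume_profile()] with provenance `"linear"`.
#' @export
volume_profile_linear <- function(session) {
  for (f in c("fill_volume", "drain_volume", "residual_before", "residual_after")) {
    if (is.null(session[[f]]) || !is.finite(session[[f]])) {
      stop("cannot build linear volume profile: missing field '", f, "'",
           call. = FALSE)
    }
  }
  tt <- session$dialysate_times
  V0 <- session$fill_volume + session$residual_before
  V240 <- session$drain_volume + session$residual_after
  t0 <- tt[1]
  tend <- tt[length(tt)]
  V <- V0 + (V240 - V0) * (tt - t0) / (tend - t0)
  volume_profile(tt, V, "linear")
}

#' Indicator-dilution intraperitoneal volume profile
#'
#' Blue dextran is assumed impermeant, so indicator mass is conserved and
#' `V(t) = V(0) * c_ind(0) / c_ind(t)`, with `V(0) = fill + residual_before`
#' and `c_ind(0)` the post-mixing measurement at the first grid time.
#'
#' @param session A [dwell_session()] carrying `indicator_conc`.
#' @return A [volume_profile()] with provenance `"indicator"`.
#' @export
volume_profile_indicator <- function(session) {
  ci <- session$indicator_conc
  if (is.null(ci) || sum(!is.na(ci)) < 2) {
    stop("indicator profile requires indicator concentrations at >= 2 times",
         call. = FALSE)
  }
  if (any(ci <= 0, na.rm = TRUE)) {
    stop("non-positive indicator concentration", call. = FALSE)
  }
  V0 <- session$fill_volume + session$residual_before
  V <- V0 * ci[1] / ci
  if (any(V <= 0, na.rm = TRUE)) stop("non-physical indicator volume", call. = FALSE)
  volume_profile(session$dialysate_times, V, "indicator")
}

#' Build the session's volume profile, preferring the indicator when present
#' @param session A [dwell_session()].
#' @return A [volume_profile()].
#' @export
session_volume_profile <- function(session) {
  if (!is.null(session$indicator_conc)) volume_profile_indicator(session)
  else volume_profile_linear(session)
}

# Plasma ----------------------------------------------------------------------

#' Plasma concentration of a solute at arbitrary dwell times
#'
#' Pigs: piecewise-linear interpolation between the plasma sampling points,
#' clamped (not extrapolated) outside the measured range. Humans: constant,
#' equal to the single mid-dwell (t = 120 min) measurement.
#'
#' @param session A [dwell_session()].
#' @param solute Solute name.
#' @param t Times (min), vectorized.
#' @return Plasma concentration(s) in mmol/L.
#' @export
plasma_at <- function(session, solute, t) {
  cp <- session$plasma_conc[solute, ]
  if (session$species == "human" || length(cp) == 1) {
    return(rep(unname(cp[length(cp)]), length(t)))
  }
  stats::approx(session$plasma_times, cp, xout = t, rule = 2)$y
}

#' Plasma interpolant for a solute
#' @param session A [dwell_session()].
#' @param solute Solute name.
#' @return A function of time returning mmol/L.
#' @export
plasma_fn <- function(session, solute) {
  cp <- session$plasma_conc[solute, ]
  if (session$species == "human" || length(cp) == 1) {
    v <- unname(cp[length(cp)])
    return(function(t) rep(v, length(t)))
  }
  stats::approxfun(session$plasma_times, cp, rule = 2)
}

# Normalization ----------------------------------------------------------------

#' Normalization denominator for a solute
#'
#' Non-glucose solutes are normalized by the plasma concentration at the
#' start of the dwell; glucose by its own initial dialysate concentration
#' (the measured t = 0 sample when the grid starts at 0, otherwise the
#' labelled fresh-bag value), so that normalized glucose runs from 1 toward
#' its plasma level.
#'
#' @param session A [dwell_session()].
#' @param solute Solute name.
#' @return Scalar denominator (mmol/L).
#' @export
norm_constant <- function(session, solute) {
  if (solute == "glucose") {
    tt <- session$dialysate_times
    d <- if (tt[1] == 0) session$dialysate_conc["glucose", 1]
         else glucose_strength_mmol(session$glucose_strength)
  } else {
    d <- plasma_at(session, solute, 0)
  }
  if (!is.finite(d) || d <= 0) {
    stop("zero or invalid normalization denominator for solute '", solute, "'",
         call. = FALSE)
  }
  d
}

#' Normalize a dialysate concentration series
#'
#' @param values Concentration series (mmol/L).
#' @param solute Solute name.
#' @param session A [dwell_session()] providing the denominator.
#' @return Dimensionless series.
#' @export
normalize_concentration <- function(values, solute, session) {
  values / norm_constant(session, solute)
}

#' Normalize a full dialysate matrix (solutes x times)
#' @param cd Matrix with solute rownames.
#' @param session A [dwell_session()].
#' @return Matrix of the same shape, dimensionless.
#' @export
normalize_matrix <- function(cd, session) {
  out <- cd
  for (s in rownames(cd)) out[s, ] <- normalize_concentration(cd[s, ], s, session)
  out
}
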
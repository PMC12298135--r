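# Lumped diffusion-convection solute models on a prescribed volume profile:
# the canonical weighted mass balance
#   d(V cd)/dt = MTAC (cp - cd) + SiCo dV/dt [(1-w) cp + w cd]
# with w = 0.5 for the Waniewski model and w = fct for the Graff models
# (glucose SiCo fixed at 0 in UGM).

#' Forward lumped diffusion-convection ODE
#'
#' Integrates `d(V cd)/dt = MTAC (cp - cd) + SiCo dV/dt ((1-w) cp + w cd)`
#' for one solute on a prescribed intraperitoneal volume profile, using an
#' adaptive stiff-capable integrator.
#'
#' @param mtac MTAC (mL/min).
#' @param sico Sieving coefficient in `[0, 1]` (unbounded as a WM regression
#'   output).
#' @param w Convection weighting in `[0, 1]` (0.5 for WM, `fct` for Graff).
#' @param volume A [volume_profile()]; the ODE sees its piecewise-linear
#'   interpolant and the per-segment slope.
#' @param plasma Plasma concentration (mmol/L): a scalar (constant), a knot
#'   list `list(times =, conc =)` (piecewise-linear, clamped), or a function
#'   of time. The first two forms run through the compiled derivative; a
#'   function falls back to the R right-hand side.
#' @param times Output times (min); the first is the initial time.
#' @param cd0 Initial dialysate concentration at `times[1]` (mmol/L).
#' @param rtol,atol Solver tolerances.
#' @return Numeric vector of dialysate concentrations at `times`.
#' @export
forward_lumped_ode <- function(mtac, sico, w, volume, plasma, times, cd0,
                               rtol = 1e-8, atol = 1e-10) {
  if (is.function(plasma)) {
    slope <- volume_slope(volume)
    if (volume$provenance == "linear") {
      t0 <- volume$times[1]
      Va <- volume$V[1]
      sl <- slope[1]
      Vfun <- function(t) Va + sl * (t - t0)
      dVfun <- function(t) sl
    } else {
      Vfun <- stats::approxfun(volume$times, volume$V, rule = 2)
      dVfun <- stats::approxfun(volume$times, slope, rule = 2)
    }
    rhs <- function(t, y, p) {
      cd <- y[1]
      cp <- plasma(t)
      dV <- dVfun(t)
      V <- Vfun(t)
      dM <- mtac * (cp - cd) + sico * dV * ((1 - w) * cp + w * cd)
      list((dM - cd * dV) / V)
    }
    sol <- deSolve::lsoda(y = c(cd = unname(cd0)), times = times, func = rhs,
                          parms = NULL, rtol = rtol, atol = atol)
  } else {
    if (is.list(plasma)) {
      pkt <- plasma$times
      pkv <- plasma$conc
    } else {
      pkt <- 0
      pkv <- plasma
    }
    pvec <- c(mtac, sico, w, length(volume$times), length(pkt),
              volume$times, volume$V, pkt, pkv)
    invisible(.C("lump_set_pars", as.double(pvec), as.integer(length(pvec)),
                 PACKAGE = "pdwell"))
    sol <- deSolve::lsoda(y = c(cd = unname(cd0)), times = times,
                          func = "lump_derivs", parms = NULL,
                          dllname = "pdwell", initfunc = NULL,
                          rtol = rtol, atol = atol)
  }
  if (attr(sol, "istate")[1] < 0) {
    stop("lumped ODE solver failed (istate ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  }
  unname(sol[, 2])
}

# Per-solute plasma knots in the form forward_lumped_ode accepts (constant
# scalar for humans, piecewise-linear knots for pigs).
plasma_knots_solute <- function(session, solute) {
  cp <- session$plasma_conc[solute, ]
  if (session$species == "human" || length(cp) == 1) {
    return(unname(cp[length(cp)]))
  }
  list(times = session$plasma_times, conc = unname(cp))
}

#' Waniewski regression fit of MTAC and SiCo
#'
#' Ordinary least squares on the integrated mass balance over the measured
#' intervals: `delta(V cd)_k = MTAC * I1_k + SiCo * I2_k`, with
#' `I1_k = integral of (cp - cd) dt` and
#' `I2_k = integral of dV/dt * (0.5 cp + 0.5 cd) dt`, both by trapezoidal
#' quadrature on the measured grid. The regression is unbounded, so negative
#' MTACs are possible outputs (and are flagged downstream, not clipped).
#' When the design is rank-deficient (e.g. a constant volume makes `I2`
#' identically zero) SiCo is unidentifiable: an MTAC-only fit is returned
#' with SiCo `NA` and a flag.
#'
#' @param session A [dwell_session()] with at least 3 dialysate time points.
#' @param volume A [volume_profile()].
#' @return List with named vectors `mtac`, `sico` and character vector
#'   `flags`.
#' @export
fit_wm_regression <- function(session, volume = session_volume_profile(session)) {
  tt <- session$dialysate_times
  if (length(tt) < 3) stop("WM regression needs >= 3 time points", call. = FALSE)
  Vt <- volume_at(volume, tt)
  dVt <- volume_slope(volume)
  if (volume$provenance == "linear") dVt <- rep(dVt[1], length(tt))
  solutes <- session$solutes
  mtac <- setNames(rep(NA_real_, length(solutes)), solutes)
  sico <- mtac
  flags <- character(0)
  for (s in solutes) {
    cd <- session$dialysate_conc[s, ]
    cp <- plasma_at(session, s, tt)
    M <- Vt * cd
    dM <- diff(M)
    f1 <- cp - cd
    f2 <- dVt * (0.5 * cp + 0.5 * cd)
    I1 <- trapz_intervals(tt, f1)
    I2 <- trapz_intervals(tt, f2)
    if (max(abs(I2)) < 1e-8 * max(1, max(abs(I1)))) {
      fit <- lm(dM ~ 0 + I1)
      mtac[[s]] <- coef(fit)[["I1"]]
      flags <- c(flags, paste0("SiCo unidentifiable for '", s,
                               "' (convective design column is zero)"))
    } else {
      fit <- lm(dM ~ 0 + I1 + I2)
      mtac[[s]] <- coef(fit)[["I1"]]
      sico[[s]] <- coef(fit)[["I2"]]
    }
  }
  list(mtac = mtac, sico = sico, flags = flags)
}

# Trapezoid integral of f over each grid interval.
trapz_intervals <- function(t, f) {
  diff(t) * (f[-length(f)] + f[-1]) / 2
}

#' Fit the Waniewski model to a session and score it
#'
#' [fit_wm_regression()] per solute, then a forward integration with the
#' fitted `(MTAC, SiCo)` and `w = 0.5` to score the prediction on the
#' measured grid. Unidentifiable SiCo is treated as 0 in the forward pass.
#'
#' @param session A [dwell_session()].
#' @param volume A [volume_profile()].
#' @param rtol,atol Solver tolerances for the forward pass.
#' @return A [fit_result()].
#' @export
fit_wm <- function(session, volume = session_volume_profile(session),
                   rtol = 1e-8, atol = 1e-10) {
  reg <- fit_wm_regression(session, volume)
  tt <- session$dialysate_times
  pred <- session$dialysate_conc
  pred[] <- NA_real_
  for (s in session$solutes) {
    sc <- if (is.finite(reg$sico[[s]])) reg$sico[[s]] else 0
    pred[s, ] <- forward_lumped_ode(reg$mtac[[s]], sc, 0.5, volume,
                                    plasma_knots_solute(session, s), tt,
                                    cd0 = session$dialysate_conc[s, 1],
                                    rtol = rtol, atol = atol)
  }
  fit_result("WM", session$session_id,
             params = list(mtac = reg$mtac, sico = reg$sico, w = 0.5),
             pred = pred, session = session, flags = reg$flags)
}

#' Fit the unified Graff model (UGM) or its full-fit variant (UGM-18)
#'
#' Per-solute bounded multistart minimization of the normalized per-solute
#' RMSE. Under UGM the diffusion-convection weight `fct` is fixed (default
#' 0.5) and glucose SiCo is fixed at 0, giving the canonical parameter
#' counts (pigs: 11 = 6 MTAC + 5 SiCo); UGM-18 frees `fct` per solute
#' (pigs: 18 = 6 MTAC + 6 SiCo + 6 fct).
#'
#' @param session A [dwell_session()].
#' @param volume A [volume_profile()].
#' @param free_fct `FALSE` for UGM, `TRUE` for UGM-18.
#' @param fct Fixed weight used when `free_fct = FALSE`; scalar or named
#'   per-solute vector.
#' @param n_restarts,seed Multistart settings, see [multistart_fit()].
#' @param mtac_bounds,rtol,atol Numerical settings.
#' @return A [fit_result()].
#' @export
fit_ugm <- function(session, volume = session_volume_profile(session),
                    free_fct = FALSE, fct = 0.5, n_restarts = 10, seed = 1,
                    mtac_bounds = c(0, 200), rtol = 1e-6, atol = 1e-8) {
  tt <- session$dialysate_times
  solutes <- session$solutes
  pred <- session$dialysate_conc
  pred[] <- NA_real_
  mtac <- setNames(rep(NA_real_, length(solutes)), solutes)
  sico <- mtac
  fct_out <- mtac
  conv <- TRUE
  n_used <- 0L
  if (length(fct) == 1) fct <- setNames(rep(fct, length(solutes)), solutes)
  for (i in seq_along(solutes)) {
    s <- solutes[i]
    cd_meas <- session$dialysate_conc[s, ]
    cd_meas_n <- normalize_concentration(cd_meas, s, session)
    pfn <- plasma_knots_solute(session, s)
    nc <- norm_constant(session, s)
    fix_sico <- (!free_fct && s == "glucose")
    lower <- c(mtac_bounds[1], if (!fix_sico) 0, if (free_fct) 0)
    upper <- c(mtac_bounds[2], if (!fix_sico) 1, if (free_fct) 1)
    obj <- function(p) {
      m <- p[1]
      sc <- if (fix_sico) 0 else p[2]
      ww <- if (free_fct) p[length(p)] else fct[[s]]
      cd_hat <- tryCatch(
        forward_lumped_ode(m, sc, ww, volume, pfn, tt, cd0 = cd_meas[1],
                           rtol = rtol, atol = atol),
        error = function(e) rep(NA_real_, length(tt)))
      if (anyNA(cd_hat)) return(1e6)
      sse_solute(cd_hat / nc, cd_meas_n)
    }
    ms <- multistart_fit(obj, lower, upper, n_restarts = n_restarts,
                         seed = seed + i)
    mtac[[s]] <- ms$par[1]
    sico[[s]] <- if (fix_sico) 0 else ms$par[2]
    fct_out[[s]] <- if (free_fct) ms$par[length(ms$par)] else fct[[s]]
    conv <- conv && ms$converged
    n_used <- ms$n_restarts
    pred[s, ] <- forward_lumped_ode(mtac[[s]], sico[[s]], fct_out[[s]], volume,
                                    pfn, tt, cd0 = cd_meas[1],
                                    rtol = rtol, atol = atol)
  }
  fit_result(if (free_fct) "UGM18" else "UGM", session$session_id,
             params = list(mtac = mtac, sico = sico, fct = fct_out),
             pred = pred, session = session,
             n_restarts = n_used, converged = conv, seed = seed)
}
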
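# Three-pore model (TPM): dynamic intraperitoneal fluid ODE with three
# parallel pathways (ultrasmall/aquaporin, small, large), crystalloid-osmosis
# driven volume flux, Patlak convection-diffusion solute flux, and lymphatic
# absorption. Serves both as a fitting target and as the ground-truth engine
# of the synthetic cohort generator.

#' Three-pore membrane constants
#'
#' Loads the default pore system from the packaged YAML config and applies
#' any overrides. Fields: `alpha` (named fractions of hydraulic conductance:
#' ultrasmall/small/large, summing to 1), `r_small`/`r_large` (pore radii,
#' Angstrom), `LpS` (mL/(min*mmHg)), `dP` (hydrostatic pressure difference,
#' mmHg), `pi_p` (plasma colloid osmotic pressure, mmHg), `RT` (mmHg per
#' mmol/L), `protein_radius` and `solute_radii` (Angstrom).
#'
#' @param ... Named overrides of the defaults.
#' @param config Path to an alternative YAML config.
#' @return Object of class `pore_system`.
#' @export
pore_system <- function(..., config = system.file("extdata", "pore_defaults.yaml",
                                                  package = "pdwell")) {
  ps <- yaml::read_yaml(config)
  dots <- list(...)
  for (nm in names(dots)) ps[[nm]] <- dots[[nm]]
  ps$alpha <- unlist(ps$alpha)[c("ultrasmall", "small", "large")]
  ps$solute_radii <- unlist(ps$solute_radii)
  stopifnot(abs(sum(ps$alpha) - 1) < 1e-8)
  class(ps) <- "pore_system"
  ps
}

# Low-order hindered-transport approximations: partition coefficient
# phi = (1 - lambda)^2 and reflection sigma = (1 - phi)^2, lambda = a/r.
hindrance <- function(a, r) {
  lambda <- a / r
  if (lambda >= 1) return(list(phi = 0, sigma = 1))
  phi <- (1 - lambda)^2
  list(phi = phi, sigma = (1 - phi)^2)
}

#' Per-pore reflection coefficients and diffusive MTAC split
#'
#' For a solute of radius `a`, computes the reflection coefficient at the
#' small and large pores from the low-order hindrance approximation
#' (`sigma = (1 - phi)^2`, `phi = (1 - a/r)^2`) and splits the solute's MTAC
#' into small- and large-pore diffusive permeabilities in proportion to
#' `alpha_i * phi_i / r_i^2`. A solute at least as large as the small pore
#' has that pathway closed (`sigma = 1`, `PS = 0`). The ultrasmall pathway
#' carries water only (`sigma = 1` for every solute).
#'
#' @param a Solute radius (Angstrom), `0 < a < r_large`.
#' @param pores A [pore_system()].
#' @param mtac Total MTAC (mL/min) to split.
#' @return List with named vectors `sigma = c(small, large)` and
#'   `ps = c(small, large)` with `sum(ps) == mtac`.
#' @export
sigma_and_split <- function(a, pores, mtac) {
  stopifnot(a > 0, a < pores$r_large)
  hs <- hindrance(a, pores$r_small)
  hl <- hindrance(a, pores$r_large)
  w <- c(small = pores$alpha[["small"]] * hs$phi / pores$r_small^2,
         large = pores$alpha[["large"]] * hl$phi / pores$r_large^2)
  ps <- if (sum(w) > 0) mtac * w / sum(w) else c(small = 0, large = 0)
  list(sigma = c(small = hs$sigma, large = hl$sigma), ps = ps)
}

# Patlak convection-diffusion flux through one pore pathway, vectorized over
# solutes. Positive flux = into the cavity.
patlak_flux <- function(jv, sigma, ps, cp, cd) {
  conv <- jv * (1 - sigma)
  out <- numeric(length(cp))
  closed <- sigma >= 1 | (ps <= 0 & conv == 0)
  pure_conv <- !closed & ps <= 0
  out[pure_conv] <- conv[pure_conv] *
    ifelse(conv[pure_conv] > 0, cp[pure_conv], cd[pure_conv])
  open <- !closed & ps > 0
  if (any(open)) {
    pe <- conv[open] / ps[open]
    cp_o <- cp[open]; cd_o <- cd[open]
    j <- numeric(length(pe))
    small <- abs(pe) < 1e-6
    # series expansion around Pe = 0 avoids the 0/0 of the exact expression
    j[small] <- ps[open][small] * (cp_o[small] - cd_o[small]) +
      conv[open][small] * (cp_o[small] + cd_o[small]) / 2
    hi <- pe > 50
    lo <- pe < -50
    j[hi] <- conv[open][hi] * cp_o[hi]
    j[lo] <- conv[open][lo] * cd_o[lo]
    mid <- !small & !hi & !lo
    em <- exp(-pe[mid])
    j[mid] <- conv[open][mid] * (cp_o[mid] - cd_o[mid] * em) / (1 - em)
    out[open] <- j
  }
  out
}

# Precompute the per-solute pore constants for a given MTAC vector.
tpm_solute_pars <- function(mtac, pores) {
  solutes <- names(mtac)
  sig <- matrix(1, 2, length(solutes),
                dimnames = list(c("small", "large"), solutes))
  ps <- matrix(0, 2, length(solutes),
               dimnames = list(c("small", "large"), solutes))
  for (s in solutes) {
    a <- pores$solute_radii[[s]]
    if (is.null(a) || is.na(a)) stop("no radius configured for solute '", s, "'")
    sp <- sigma_and_split(a, pores, mtac[[s]])
    sig[, s] <- sp$sigma
    ps[, s] <- sp$ps
  }
  hp_s <- hindrance(pores$protein_radius, pores$r_small)$sigma
  hp_l <- hindrance(pores$protein_radius, pores$r_large)$sigma
  list(sigma = sig, ps = ps, sigma_prot = c(ultrasmall = 1, small = hp_s, large = hp_l))
}

#' Instantaneous pore fluxes for a TPM state
#'
#' Volume flux per pathway:
#' `Jv_i = alpha_i * LpS * (dP - sigma_prot_i * pi_p + RT * sum_s sigma_s_i *
#' (cd_s - cp_s))`, with the sign convention that dialysate-hypertonic
#' glucose drives water into the cavity. Solute flux through the small and
#' large pores follows the Patlak expression
#' `Js_i = Jv_i (1 - sigma) (cp - cd e^(-Pe)) / (1 - e^(-Pe))`,
#' `Pe = Jv_i (1 - sigma) / PS_i`, with a series expansion near `Pe = 0`.
#' The ultrasmall (aquaporin) pathway carries water only.
#'
#' @param V Intraperitoneal volume (mL; not used by the fluxes themselves but
#'   part of the state contract).
#' @param cd Named dialysate concentrations (mmol/L).
#' @param cp Named plasma concentrations (mmol/L), same solutes.
#' @param mtac Named MTAC vector (mL/min).
#' @param pores A [pore_system()].
#' @param solute_pars Optional precomputed [sigma_and_split()] table.
#' @return List: `Jv` (named ultrasmall/small/large, mL/min) and `Js`
#'   (matrix small/large x solutes, mmol/min).
#' @export
pore_fluxes <- function(V, cd, cp, mtac, pores,
                        solute_pars = tpm_solute_pars(mtac, pores)) {
  sp <- solute_pars
  dc <- cd - cp[names(cd)]
  osm <- c(ultrasmall = sum(dc),
           small = sum(sp$sigma["small", ] * dc),
           large = sum(sp$sigma["large", ] * dc))
  Jv <- pores$alpha * pores$LpS *
    (pores$dP - sp$sigma_prot * pores$pi_p + pores$RT * osm)
  names(Jv) <- c("ultrasmall", "small", "large")
  Js <- rbind(
    small = patlak_flux(Jv[["small"]], sp$sigma["small", ], sp$ps["small", ],
                        cp[names(cd)], cd),
    large = patlak_flux(Jv[["large"]], sp$sigma["large", ], sp$ps["large", ],
                        cp[names(cd)], cd))
  colnames(Js) <- names(cd)
  list(Jv = Jv, Js = Js)
}

#' Simulate a TPM dwell
#'
#' Integrates the coupled fluid and solute balance
#' `dV/dt = Jv_u + Jv_s + Jv_l - L` and
#' `d(V cd_s)/dt = Js_small + Js_large - L cd_s`
#' from instantaneous instillation at `times[1]` with an adaptive
#' stiff-capable integrator.
#'
#' @param mtac Named per-solute MTAC vector (mL/min).
#' @param L Lymphatic absorption rate (mL/min).
#' @param V0 Initial intraperitoneal volume (mL).
#' @param cd0 Named initial dialysate concentrations (mmol/L), same solutes
#'   as `mtac`.
#' @param plasma Plasma concentrations: a named constant vector (mmol/L), a
#'   knot list `list(times =, conc =)` with `conc` a solutes x knots matrix
#'   (piecewise-linear, clamped), or a function of time returning a named
#'   vector. The first two forms run through the compiled derivative; a
#'   function falls back to the (slower) R right-hand side.
#' @param times Output times (min).
#' @param pores A [pore_system()].
#' @param rtol,atol Solver tolerances.
#' @param track_mass If `TRUE`, integrate the cumulative net solute inflow
#'   per solute alongside the state for mass-bookkeeping checks.
#' @return Object of class `tpm_sim`: `times`, `V`, `cd` (solutes x times),
#'   `uf` (`V(end) - V(0)`, mL), `volume_profile`, and `cum_mass` when
#'   tracked.
#' @useDynLib pdwell, .registration = TRUE
#' @export
tpm_simulate <- function(mtac, L, V0, cd0, plasma, times,
                         pores = pore_system(), rtol = 1e-8, atol = 1e-10,
                         track_mass = FALSE) {
  solutes <- names(mtac)
  stopifnot(setequal(solutes, names(cd0)))
  cd0 <- cd0[solutes]
  sp <- tpm_solute_pars(mtac, pores)
  n <- length(solutes)
  y0 <- c(V = V0, cd0)
  if (track_mass) y0 <- c(y0, setNames(numeric(n), paste0("cum_", solutes)))
  # integration terminates at V = 1 mL: parameter sets that drain the cavity
  # dry are non-physical and would otherwise collapse the step size
  if (is.function(plasma)) {
    pfun <- plasma
    rhs <- function(t, y, p) {
      V <- y[1]
      cd <- y[2:(n + 1)]
      names(cd) <- solutes
      cp <- pfun(t)
      fl <- pore_fluxes(V, cd, cp, mtac, pores, sp)
      dV <- sum(fl$Jv) - L
      net <- fl$Js["small", ] + fl$Js["large", ] - L * cd
      dcd <- (net - cd * dV) / V
      if (track_mass) list(c(dV, dcd, net)) else list(c(dV, dcd))
    }
    sol <- deSolve::lsodar(y0, times, rhs, parms = NULL, rtol = rtol,
                           atol = atol, rootfunc = function(t, y, p) y[1] - 1)
  } else {
    if (is.list(plasma)) {
      kt <- plasma$times
      kv <- plasma$conc[solutes, , drop = FALSE]
    } else {
      kt <- 0
      kv <- matrix(plasma[solutes], ncol = 1, dimnames = list(solutes, NULL))
    }
    pvec <- c(n, length(kt), as.integer(track_mass), L,
              pores$alpha * pores$LpS, sp$sigma_prot,
              pores$dP, pores$pi_p, pores$RT,
              sp$sigma["small", ], sp$sigma["large", ],
              sp$ps["small", ], sp$ps["large", ],
              kt, as.vector(t(kv)))
    invisible(.C("tpm_set_pars", as.double(pvec), as.integer(length(pvec)),
                 PACKAGE = "pdwell"))
    sol <- deSolve::lsodar(y0, times, func = "tpm_derivs", parms = NULL,
                           dllname = "pdwell", initfunc = NULL,
                           rootfunc = "tpm_root", nroot = 1,
                           rtol = rtol, atol = atol)
  }
  if (attr(sol, "istate")[1] < 0) {
    stop("TPM solver failed (istate ", attr(sol, "istate")[1], ")", call. = FALSE)
  }
  if (nrow(sol) < length(times) ||
      sol[nrow(sol), 1] < times[length(times)] - 1e-9) {
    stop("TPM simulation drained the cavity (V reached ~0) before the dwell end",
         call. = FALSE)
  }
  sol <- sol[seq_along(times), , drop = FALSE]
  V <- sol[, "V"]
  if (any(V <= 0)) stop("TPM simulation reached non-physical V <= 0", call. = FALSE)
  cd <- t(sol[, solutes, drop = FALSE])
  rownames(cd) <- solutes
  colnames(cd) <- as.character(times)
  out <- structure(list(
    times = times, V = unname(V), cd = cd,
    uf = unname(V[length(V)] - V[1]),
    volume_profile = volume_profile(times, unname(V), "simulated"),
    mtac = mtac, L = L, pores = pores
  ), class = "tpm_sim")
  if (track_mass) {
    cm <- t(sol[, paste0("cum_", solutes), drop = FALSE])
    rownames(cm) <- solutes
    out$cum_mass <- cm
  }
  out
}

#' @export
print.tpm_sim <- function(x, ...) {
  cat(sprintf("<tpm_sim> %d solutes, t = [%g, %g] min, UF = %.1f mL, L = %.2f mL/min\n",
              nrow(x$cd), min(x$times), max(x$times), x$uf, x$L))
  invisible(x)
}

#' Initial intraperitoneal state at instillation
#'
#' Volume is fill + residual; solute concentrations are the volume-weighted
#' mix of the fresh bag with the residual fluid, whose composition defaults
#' to plasma-like (the overnight dwell is near-equilibrated) but may be set
#' to the fresh-bag composition.
#'
#' @param session A [dwell_session()].
#' @param residual_composition `"plasma"` or `"bag"`.
#' @return List with `V0` (mL) and named `cd0` (mmol/L).
#' @export
tpm_initial_state <- function(session, residual_composition = c("plasma", "bag")) {
  residual_composition <- match.arg(residual_composition)
  solutes <- session$solutes
  bag <- fresh_bag_composition(solutes, session$glucose_strength)
  c_res <- if (residual_composition == "plasma") {
    setNames(vapply(solutes, function(s) plasma_at(session, s, 0), numeric(1)),
             solutes)
  } else bag
  V0 <- session$fill_volume + session$residual_before
  cd0 <- (session$fill_volume * bag + session$residual_before * c_res) / V0
  list(V0 = V0, cd0 = cd0)
}

# Plasma knots over all solutes for a session, in the list form accepted by
# tpm_simulate (constant for humans, piecewise-linear for pigs).
session_plasma_knots <- function(session) {
  solutes <- session$solutes
  if (session$species == "human" || length(session$plasma_times) == 1) {
    cp <- vapply(solutes, function(s) plasma_at(session, s, 120), numeric(1))
    return(setNames(cp, solutes))
  }
  list(times = session$plasma_times, conc = session$plasma_conc)
}

# Plasma function over all solutes for a session (named vector per time).
session_plasma_fn <- function(session) {
  solutes <- session$solutes
  if (session$species == "human" || length(session$plasma_times) == 1) {
    cp <- setNames(vapply(solutes, function(s) plasma_at(session, s, 120),
                          numeric(1)), solutes)
    return(function(t) cp)
  }
  fns <- lapply(setNames(solutes, solutes), function(s) {
    stats::approxfun(session$plasma_times, session$plasma_conc[s, ], rule = 2)
  })
  function(t) vapply(fns, function(f) f(t), numeric(1))
}

#' Fit the three-pore model to a session
#'
#' Bounded multistart minimization of `Cerror + Verror` over the per-solute
#' MTACs and the lymphatic flow rate `L`; all pore constants are fixed
#' ([pore_system()]). Measured volumes for Verror are the indicator-derived
#' profile when present, otherwise the two endpoint volumes.
#'
#' @param session A [dwell_session()].
#' @param volume A [volume_profile()] supplying the measured volumes.
#' @param pores A [pore_system()].
#' @param n_restarts,seed Multistart settings.
#' @param mtac_bounds,L_bounds Box bounds (mL/min).
#' @param rtol,atol Solver tolerances inside the objective.
#' @param residual_composition See [tpm_initial_state()].
#' @return A [fit_result()] with `params$mtac`, `params$L` and
#'   `params$uf_pred` (predicted `V(end) - V(0)`, mL).
#' @export
fit_tpm <- function(session, volume = session_volume_profile(session),
                    pores = pore_system(), n_restarts = 10, seed = 1,
                    mtac_bounds = c(0, 200), L_bounds = c(0, 10),
                    rtol = 1e-6, atol = 1e-8,
                    residual_composition = "plasma") {
  t_start <- Sys.time()
  solutes <- session$solutes
  tt <- session$dialysate_times
  sim_times <- if (tt[1] > 0) c(0, tt) else tt
  grid_idx <- match(tt, sim_times)
  init <- tpm_initial_state(session, residual_composition)
  pfun <- session_plasma_knots(session)
  meas_n <- normalize_matrix(session$dialysate_conc, session)
  nc <- vapply(solutes, function(s) norm_constant(session, s), numeric(1))
  if (volume$provenance == "indicator") {
    v_times <- volume$times
    V_meas <- volume$V
  } else {
    v_times <- range(volume$times)
    V_meas <- volume_at(volume, v_times)
  }
  v_idx <- match(v_times, sim_times)
  stopifnot(!anyNA(v_idx), !anyNA(grid_idx))
  n <- length(solutes)
  simulate_once <- function(p, rtol_, atol_) {
    mtac <- setNames(p[1:n], solutes)
    tpm_simulate(mtac, L = p[n + 1], V0 = init$V0, cd0 = init$cd0,
                 plasma = pfun, times = sim_times, pores = pores,
                 rtol = rtol_, atol = atol_)
  }
  obj <- function(p) {
    sim <- tryCatch(simulate_once(p, rtol, atol), error = function(e) NULL)
    if (is.null(sim)) return(1e6)
    pred_n <- sim$cd[, grid_idx, drop = FALSE] / nc
    cerror(pred_n, meas_n) + verror(sim$V[v_idx], V_meas)
  }
  lower <- c(rep(mtac_bounds[1], n), L_bounds[1])
  upper <- c(rep(mtac_bounds[2], n), L_bounds[2])
  ms <- multistart_fit(obj, lower, upper, n_restarts = n_restarts, seed = seed)
  best <- simulate_once(ms$par, 1e-8, 1e-10)
  pred <- best$cd[, grid_idx, drop = FALSE]
  mtac_hat <- setNames(ms$par[1:n], solutes)
  fit_result("TPM", session$session_id,
             params = list(mtac = mtac_hat, L = ms$par[n + 1],
                           uf_pred = best$uf, objective = ms$value),
             pred = pred, session = session,
             V_pred = best$V[v_idx], V_meas = V_meas,
             n_restarts = ms$n_restarts, best_restart = ms$best_restart,
             converged = ms$converged, seed = seed,
             elapsed = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
}
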
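# Synthetic dwell-session generator: virtual pig and human dwells with known
# ground-truth transport parameters, emulating the measurement protocol of a
# 4 h test dwell (timed dialysate sampling, sparse plasma sampling, blue
# dextran volume indicator, protein-dilution residual volumes).

#' Measurement noise model
#'
#' Multiplicative Gaussian noise, one coefficient of variation per
#' measurement class. Defaults reflect clinical assay precision.
#'
#' @param cv_dialysate,cv_plasma,cv_protein,cv_indicator CVs (0 = noise-free).
#' @return Named list of CVs.
#' @export
noise_model <- function(cv_dialysate = 0.02, cv_plasma = 0.03,
                        cv_protein = 0.05, cv_indicator = 0.05) {
  list(cv_dialysate = cv_dialysate, cv_plasma = cv_plasma,
       cv_protein = cv_protein, cv_indicator = cv_indicator)
}

#' Zero-noise model
#' @return A [noise_model()] with all CVs 0.
#' @export
no_noise <- function() noise_model(0, 0, 0, 0)

#' Default ground-truth parameter priors
#'
#' Uniform ranges from which per-session truths are drawn: per-solute MTAC
#' and lymphatic flow (mL/min), plasma concentrations (mmol/L) and residual
#' volumes (mL). Plausibility ranges for a 4 h dwell, configurable; not
#' asserted as measured values of any real cohort.
#'
#' @param species `"pig"` or `"human"`.
#' @return Nested list of `c(min, max)` ranges.
#' @export
default_priors <- function(species = "pig") {
  solutes <- species_solutes(species)
  mtac <- list(urea = c(10, 25), creatinine = c(5, 12), glucose = c(8, 15),
               sodium = c(2, 8), phosphate = c(4, 10), potassium = c(8, 20))
  plasma <- list(urea = c(15, 30), creatinine = c(0.5, 1.0),
                 sodium = c(135, 145), potassium = c(3.5, 5.5),
                 phosphate = c(1.2, 2.4), glucose = c(4, 8))
  list(mtac = mtac[solutes], plasma = plasma[solutes],
       L = c(0.3, 3), residual = c(150, 350), protein = c(0.6, 1.5))
}

draw_range <- function(r) runif(1, r[1], r[2])

#' Draw a ground-truth parameter set from priors
#'
#' @param species `"pig"` or `"human"`.
#' @param priors See [default_priors()].
#' @param glucose_strength Bag strength; defaults to 1.36\% for pigs (the
#'   low-convection experimental choice) and 3.86\% for humans (standard PET).
#' @param pores A [pore_system()].
#' @return Object of class `synthetic_truth`.
#' @export
draw_truth <- function(species, priors = default_priors(species),
                       glucose_strength = NULL, pores = pore_system()) {
  solutes <- species_solutes(species)
  if (is.null(glucose_strength)) {
    glucose_strength <- if (species == "pig") "1.36%" else "3.86%"
  }
  structure(list(
    species = species,
    solutes = solutes,
    glucose_strength = glucose_strength,
    mtac = vapply(priors$mtac[solutes], draw_range, numeric(1)),
    L = draw_range(priors$L),
    plasma = vapply(priors$plasma[solutes], draw_range, numeric(1)),
    fill_volume = 2000,
    residual_before = draw_range(priors$residual),
    residual_after = draw_range(priors$residual),
    protein_before = draw_range(priors$protein),
    protein_after = draw_range(priors$protein),
    indicator_bag = 0.49,
    flush_volume = 1000,
    pores = pores
  ), class = "synthetic_truth")
}

mult_noise <- function(x, cv) {
  if (cv <= 0) return(x)
  pmax(0, x * (1 + cv * rnorm(length(x))))
}

#' Generate one synthetic dwell session with known ground truth
#'
#' Simulates the dwell with the truth parameters (by default through the
#' three-pore model, the richest available engine), samples dialysate at the
#' species grid and plasma at the species plasma times, synthesizes
#' blue-dextran concentrations consistent with the simulated volume
#' trajectory and protein-dilution observables consistent with the chosen
#' residual volumes, applies the noise model, and emits a schema-valid
#' [dwell_session()]. The session's residual-volume fields are what an
#' analyst would compute from the (noisy) protein record, so at zero noise
#' they equal the truth exactly.
#'
#' The `engine` flag switches the generating model, for exact round-trip
#' checks of the simpler fitters: `"garred"` uses the closed-form Garred
#' forward predictor on a linear volume profile, `"lumped"` the weighted
#' diffusion-convection ODE (`w = 0.5`, Waniewski).
#'
#' @param species `"pig"` or `"human"`.
#' @param seed Integer seed; the session is reproducible given it.
#' @param truth Optional [draw_truth()] output; drawn from `priors` if `NULL`.
#' @param priors See [default_priors()].
#' @param noise A [noise_model()].
#' @param session_id Identifier; autogenerated if `NULL`.
#' @param include_indicator Emit a blue-dextran series (default: pigs only).
#' @param engine `"tpm"`, `"garred"` or `"lumped"`.
#' @param engine_pars Extra truth parameters for the non-TPM engines:
#'   `uf_total` (mL, linear volume ramp), `f` (Garred), `sico`, `w` (lumped).
#' @return List with elements `session` and `truth`.
#' @export
generate_session <- function(species, seed, truth = NULL,
                             priors = default_priors(species),
                             noise = noise_model(), session_id = NULL,
                             include_indicator = (species == "pig"),
                             engine = c("tpm", "garred", "lumped"),
                             engine_pars = list()) {
  engine <- match.arg(engine)
  set.seed(seed)
  if (is.null(truth)) truth <- draw_truth(species, priors)
  truth$seed <- seed
  truth$noise <- noise
  truth$engine <- engine
  solutes <- truth$solutes
  grid <- species_grid(species)
  plasma_times <- species_plasma_times(species)
  bag <- fresh_bag_composition(solutes, truth$glucose_strength)
  V0 <- truth$fill_volume + truth$residual_before
  cd0 <- (truth$fill_volume * bag + truth$residual_before * truth$plasma) / V0
  sim_times <- sort(unique(c(0, grid)))

  if (engine == "tpm") {
    sim <- tpm_simulate(truth$mtac, truth$L, V0 = V0, cd0 = cd0,
                        plasma = truth$plasma, times = sim_times,
                        pores = truth$pores)
    V_grid <- sim$V[match(grid, sim_times)]
    cd_grid <- sim$cd[, match(grid, sim_times), drop = FALSE]
    V_end <- sim$V[length(sim$V)]
  } else {
    uf <- engine_pars$uf_total %||% 0
    V_end <- V0 + uf
    vp <- volume_profile(sim_times, V0 + uf * sim_times / 240, "linear")
    V_grid <- volume_at(vp, grid)
    cd_grid <- matrix(NA_real_, length(solutes), length(grid),
                      dimnames = list(solutes, as.character(grid)))
    for (s in solutes) {
      if (engine == "garred") {
        f <- engine_pars$f %||% 0
        cd_grid[s, ] <- forward_garred(truth$mtac[[s]], f, vp,
                                       truth$plasma[[s]], cd0[[s]], grid,
                                       t_start = 0)
      } else {
        sico <- (engine_pars$sico %||% setNames(rep(0.5, length(solutes)), solutes))[[s]]
        w <- engine_pars$w %||% 0.5
        out_times <- if (grid[1] == 0) grid else c(0, grid)
        cd_all <- forward_lumped_ode(truth$mtac[[s]], sico, w, vp,
                                     function(t) truth$plasma[[s]],
                                     out_times, cd0 = cd0[[s]])
        cd_grid[s, ] <- if (grid[1] == 0) cd_all else cd_all[-1]
      }
    }
    truth$engine_pars <- engine_pars
  }
  truth$V_grid <- setNames(V_grid, as.character(grid))

  cd_meas <- cd_grid
  cd_meas[] <- mult_noise(as.numeric(cd_grid), noise$cv_dialysate)
  cp <- matrix(rep(truth$plasma, length(plasma_times)),
               nrow = length(solutes),
               dimnames = list(solutes, as.character(plasma_times)))
  cp[] <- mult_noise(as.numeric(cp), noise$cv_plasma)

  indicator <- NULL
  if (include_indicator) {
    ind_mass <- truth$indicator_bag * truth$fill_volume
    indicator <- mult_noise(ind_mass / V_grid, noise$cv_indicator)
  }

  # protein-dilution observables: the pre-dwell record uses the fill itself
  # as the diluting flush; the post-dwell record a dedicated 1 L flush
  prot_before <- list(
    c_pre = mult_noise(truth$protein_before, noise$cv_protein),
    c_post = mult_noise(
      truth$protein_before * truth$residual_before /
        (truth$residual_before + truth$fill_volume), noise$cv_protein),
    flush_volume = truth$fill_volume)
  prot_after <- list(
    c_pre = mult_noise(truth$protein_after, noise$cv_protein),
    c_post = mult_noise(
      truth$protein_after * truth$residual_after /
        (truth$residual_after + truth$flush_volume), noise$cv_protein),
    flush_volume = truth$flush_volume)
  res_before_hat <- residual_volume(prot_before$c_pre, prot_before$c_post,
                                    prot_before$flush_volume)
  res_after_hat <- residual_volume(prot_after$c_pre, prot_after$c_post,
                                   prot_after$flush_volume)

  if (is.null(session_id)) {
    session_id <- sprintf("%s-%06d", if (species == "pig") "P" else "H", seed %% 1e6)
  }
  session <- dwell_session(
    session_id = session_id, species = species,
    glucose_strength = truth$glucose_strength,
    fill_volume = truth$fill_volume,
    drain_volume = V_end - truth$residual_after,
    residual_before = res_before_hat, residual_after = res_after_hat,
    dialysate_times = grid, dialysate_conc = cd_meas,
    plasma_times = plasma_times, plasma_conc = cp,
    indicator_conc = indicator,
    protein = list(before = prot_before, after = prot_after),
    flush_volume = truth$flush_volume)
  validate_dwell_session(session)
  list(session = session, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a cohort of synthetic dwell sessions
#'
#' Per-session truths are drawn independently from the priors; per-session
#' seeds derive deterministically from the master seed, so the same master
#' seed reproduces the identical cohort.
#'
#' @param n Number of sessions (>= 1).
#' @param species `"pig"` or `"human"`.
#' @param seed Master seed.
#' @param priors,noise,engine,engine_pars Passed to [generate_session()].
#' @return List with `sessions` and `truths` (parallel lists).
#' @export
generate_cohort <- function(n, species, seed, priors = default_priors(species),
                            noise = noise_model(),
                            engine = "tpm", engine_pars = list()) {
  stopifnot(n >= 1)
  set.seed(seed)
  session_seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- lapply(seq_len(n), function(i) {
    generate_session(species, seed = session_seeds[i], priors = priors,
                     noise = noise,
                     session_id = sprintf("%s%02d-%d",
                                          if (species == "pig") "P" else "H",
                                          i, seed),
                     engine = engine, engine_pars = engine_pars)
  })
  list(sessions = lapply(out, `[[`, "session"),
       truths = lapply(out, `[[`, "truth"))
}
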
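#' @importFrom stats approxfun coef lm median na.omit optim quantile rnorm runif sd setNames cor
#' @importFrom utils read.csv write.csv
NULL

# Species-specific measurement protocol constants ----------------------------

#' Solutes measured for a species
#'
#' Pig dwell protocols measure six solutes, human peritoneal equilibration
#' tests (PETs) four.
#'
#' @param species `"pig"` or `"human"`.
#' @return Character vector of solute names.
#' @export
species_solutes <- function(species) {
  species <- match.arg(species, c("pig", "human"))
  if (species == "pig") {
    c("urea", "creatinine", "sodium", "phosphate", "glucose", "potassium")
  } else {
    c("urea", "creatinine", "sodium", "glucose")
  }
}

#' Default dialysate sampling grid for a species (minutes)
#' @param species `"pig"` or `"human"`.
#' @return Numeric vector of sampling times in minutes.
#' @export
species_grid <- function(species) {
  species <- match.arg(species, c("pig", "human"))
  if (species == "pig") c(0, 10, 20, 30, 60, 120, 180, 240) else c(20, 120, 240)
}

#' Default plasma sampling times for a species (minutes)
#' @param species `"pig"` or `"human"`.
#' @return Numeric vector of times in minutes.
#' @export
species_plasma_times <- function(species) {
  species <- match.arg(species, c("pig", "human"))
  if (species == "pig") c(0, 120, 240) else 120
}

#' Fresh-bag glucose concentration for a labelled strength
#'
#' @param strength One of `"1.36%"`, `"2.27%"`, `"3.86%"`.
#' @return Glucose concentration in mmol/L (75.6, 126.1 or 214).
#' @export
glucose_strength_mmol <- function(strength) {
  map <- c("1.36%" = 75.6, "2.27%" = 126.1, "3.86%" = 214)
  if (!strength %in% names(map)) {
    stop("unknown glucose strength: ", strength, call. = FALSE)
  }
  unname(map[[strength]])
}

#' Fresh-bag dialysate composition
#'
#' Glucose-based PD fluid: sodium 132 mmol/L, glucose at the labelled
#' strength, and zero for urea, creatinine, phosphate and potassium.
#'
#' @param solutes Character vector of solute names.
#' @param glucose_strength Labelled strength, see [glucose_strength_mmol()].
#' @return Named numeric vector (mmol/L), one entry per solute.
#' @export
fresh_bag_composition <- function(solutes, glucose_strength = "1.36%") {
  comp <- setNames(numeric(length(solutes)), solutes)
  if ("sodium" %in% solutes) comp[["sodium"]] <- 132
  if ("glucose" %in% solutes) comp[["glucose"]] <- glucose_strength_mmol(glucose_strength)
  comp
}

# DwellSession ----------------------------------------------------------------

#' Construct a dwell session record
#'
#' A `dwell_session` holds one PD exchange: instilled/drained volumes,
#' residual volumes before and after the dwell, timed dialysate solute
#' concentrations, sparse plasma concentrations, and (optionally) the raw
#' dilution observables behind the residual volumes (total-protein records)
#' and an impermeant volume indicator (blue dextran) series.
#'
#' @param session_id Character identifier.
#' @param species `"pig"` or `"human"`.
#' @param glucose_strength Labelled bag strength (`"1.36%"`, `"2.27%"`,
#'   `"3.86%"`).
#' @param fill_volume,drain_volume Instilled and drained volume (mL).
#' @param residual_before,residual_after Residual volume before instillation
#'   and after the final drain (mL).
#' @param dialysate_times Sampling times (min), strictly increasing, within
#'   `[0, 240]`.
#' @param dialysate_conc Numeric matrix (solutes x times) of dialysate
#'   concentrations in mmol/L; rownames are solute names, colnames the times.
#' @param plasma_times Plasma sampling times (min).
#' @param plasma_conc Numeric matrix (solutes x plasma times), mmol/L.
#' @param indicator_conc Optional numeric vector of blue-dextran dialysate
#'   concentrations (g/L) at `dialysate_times`.
#' @param protein Optional list with elements `before` and `after`, each a
#'   list `(c_pre, c_post, flush_volume)` in g/L and mL: the total-protein
#'   dilution observables from which the residual volumes derive.
#' @param flush_volume Volume of the post-dwell flush (mL), default 1000.
#' @return An object of class `dwell_session`.
#' @seealso [validate_dwell_session()], [read_session()], [write_session()]
#' @export
dwell_session <- function(session_id, species, glucose_strength,
                          fill_volume, drain_volume,
                          residual_before, residual_after,
                          dialysate_times, dialysate_conc,
                          plasma_times, plasma_conc,
                          indicator_conc = NULL, protein = NULL,
                          flush_volume = 1000) {
  species <- match.arg(species, c("pig", "human"))
  dialysate_conc <- as.matrix(dialysate_conc)
  plasma_conc <- as.matrix(plasma_conc)
  colnames(dialysate_conc) <- as.character(dialysate_times)
  colnames(plasma_conc) <- as.character(plasma_times)
  x <- structure(list(
    schema_version = 1L,
    session_id = as.character(session_id),
    species = species,
    solutes = rownames(dialysate_conc),
    glucose_strength = glucose_strength,
    fill_volume = fill_volume,
    drain_volume = drain_volume,
    residual_before = residual_before,
    residual_after = residual_after,
    dialysate_times = as.numeric(dialysate_times),
    dialysate_conc = dialysate_conc,
    plasma_times = as.numeric(plasma_times),
    plasma_conc = plasma_conc,
    indicator_conc = if (is.null(indicator_conc)) NULL else as.numeric(indicator_conc),
    protein = protein,
    flush_volume = flush_volume
  ), class = "dwell_session")
  x
}

#' @export
print.dwell_session <- function(x, ...) {
  cat(sprintf("<dwell_session> %s (%s, %s glucose)\n", x$session_id,
              x$species, x$glucose_strength))
  cat(sprintf("  fill %.0f mL, drain %.0f mL, residual %.0f/%.0f mL\n",
              x$fill_volume, x$drain_volume, x$residual_before, x$residual_after))
  cat(sprintf("  dialysate: %s at t = %s min\n",
              paste(x$solutes, collapse = ", "),
              paste(x$dialysate_times, collapse = ", ")))
  invisible(x)
}

#' Validate a dwell session record
#'
#' Checks the structural invariants of a session: non-negative volumes and
#' concentrations, a strictly increasing dialysate time grid inside
#' `[0, 240]` min, a complete dialysate matrix, species-consistent solutes,
#' and (when a t = 0 sample exists) that the initial glucose concentration is
#' consistent with the labelled bag strength. The glucose check is tolerant
#' (25% by default) because the t = 0 sample is drawn after mixing with
#' residual fluid, which alone can dilute the bag value by 10-15%; the check
#' guards against gross unit or labelling errors, not mixing.
#'
#' @param session A [dwell_session()].
#' @param tol_glucose Relative tolerance for the t = 0 glucose check.
#' @return Invisibly `TRUE`; stops with an informative message otherwise.
#' @export
validate_dwell_session <- function(session, tol_glucose = 0.25) {
  stopifnot(inherits(session, "dwell_session"))
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  vols <- c(fill_volume = session$fill_volume, drain_volume = session$drain_volume,
            residual_before = session$residual_before,
            residual_after = session$residual_after)
  if (any(!is.finite(vols)) || any(vols < 0)) {
    note("all volumes must be finite and >= 0")
  }
  tt <- session$dialysate_times
  if (any(diff(tt) <= 0)) note("dialysate_times must be strictly increasing")
  if (min(tt) < 0 || max(tt) > 240) note("dialysate_times must lie in [0, 240]")
  if (!setequal(session$solutes, species_solutes(session$species))) {
    note(sprintf("solute set does not match species '%s'", session$species))
  }
  cd <- session$dialysate_conc
  if (ncol(cd) != length(tt) || anyNA(cd)) {
    note("dialysate_conc must have a value for every solute at every time")
  }
  if (any(cd < 0, na.rm = TRUE)) note("dialysate concentrations must be >= 0")
  if ("glucose" %in% rownames(cd) && 0 %in% tt) {
    lab <- glucose_strength_mmol(session$glucose_strength)
    g0 <- cd["glucose", match(0, tt)]
    if (abs(g0 - lab) > tol_glucose * lab) {
      note(sprintf(
        "glucose at t=0 (%.1f mmol/L) inconsistent with labelled strength (%.1f mmol/L)",
        g0, lab))
    }
  }
  if (!is.null(session$indicator_conc) &&
      length(session$indicator_conc) != length(tt)) {
    note("indicator_conc must align with dialysate_times")
  }
  if (length(errs) > 0) {
    stop("invalid dwell session '", session$session_id, "':\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

# Serialization ----------------------------------------------------------------

#' Write a dwell session to a JSON file
#'
#' One JSON document per session; the schema is versioned via the
#' `schema_version` field. Matrices are stored with explicit solute and time
#' labels so the round trip is lossless.
#'
#' @param session A [dwell_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  x <- unclass(session)
  x$dialysate_conc <- mat_to_list(session$dialysate_conc)
  x$plasma_conc <- mat_to_list(session$plasma_conc)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a dwell session from a JSON file
#' @param path File written by [write_session()].
#' @return A [dwell_session()].
#' @export
read_session <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  protein <- x$protein
  if (!is.null(protein)) protein <- lapply(protein, as.list)
  dwell_session(
    session_id = x$session_id, species = x$species,
    glucose_strength = x$glucose_strength,
    fill_volume = x$fill_volume, drain_volume = x$drain_volume,
    residual_before = x$residual_before, residual_after = x$residual_after,
    dialysate_times = x$dialysate_times,
    dialysate_conc = list_to_mat(x$dialysate_conc, x$solutes, x$dialysate_times),
    plasma_times = x$plasma_times,
    plasma_conc = list_to_mat(x$plasma_conc, x$solutes, x$plasma_times),
    indicator_conc = x$indicator_conc,
    protein = protein,
    flush_volume = x$flush_volume
  )
}

mat_to_list <- function(m) {
  lapply(setNames(seq_len(nrow(m)), rownames(m)), function(i) unname(m[i, ]))
}

list_to_mat <- function(lst, solutes, times) {
  m <- do.call(rbind, lapply(lst[solutes], as.numeric))
  rownames(m) <- solutes
  colnames(m) <- as.character(times)
  m
}

#' Convert a dwell session to/from a long-format table
#'
#' The long form has columns `session_id, kind, solute, time_min, value,
#' unit`, with `kind` one of `dialysate`, `plasma`, `indicator`, `protein`,
#' `volume`, `meta`. Scalar fields ride along as `volume` (numeric) and
#' `meta` (character) rows so the representation is lossless.
#'
#' @param session A [dwell_session()].
#' @return A `data.frame` in long format.
#' @export
session_to_long <- function(session) {
  rows <- list()
  add <- function(kind, solute, time_min, value, unit) {
    rows[[length(rows) + 1L]] <<- data.frame(
      session_id = session$session_id, kind = kind, solute = solute,
      time_min = time_min, value = as.character(value), unit = unit,
      stringsAsFactors = FALSE)
  }
  for (s in session$solutes) {
    add("dialysate", s, session$dialysate_times,
        session$dialysate_conc[s, ], "mmol/L")
    add("plasma", s, session$plasma_times, session$plasma_conc[s, ], "mmol/L")
  }
  if (!is.null(session$indicator_conc)) {
    add("indicator", "blue_dextran", session$dialysate_times,
        session$indicator_conc, "g/L")
  }
  if (!is.null(session$protein)) {
    for (stage in names(session$protein)) {
      p <- session$protein[[stage]]
      for (f in names(p)) {
        add("protein", paste(stage, f, sep = "."), NA_real_, p[[f]],
            if (f == "flush_volume") "mL" else "g/L")
      }
    }
  }
  for (f in c("fill_volume", "drain_volume", "residual_before",
              "residual_after", "flush_volume")) {
    add("volume", f, NA_real_, session[[f]], "mL")
  }
  add("meta", "species", NA_real_, session$species, "")
  add("meta", "glucose_strength", NA_real_, session$glucose_strength, "")
  do.call(rbind, rows)
}

#' @rdname session_to_long
#' @param long A data frame produced by [session_to_long()] (one session).
#' @export
session_from_long <- function(long) {
  stopifnot(length(unique(long$session_id)) == 1)
  get_meta <- function(name) long$value[long$kind == "meta" & long$solute == name]
  get_vol <- function(name) as.numeric(long$value[long$kind == "volume" & long$solute == name])
  dia <- long[long$kind == "dialysate", ]
  pla <- long[long$kind == "plasma", ]
  solutes <- unique(dia$solute)
  dt <- sort(unique(dia$time_min))
  pt <- sort(unique(pla$time_min))
  cd <- sapply(as.character(dt), function(tm) {
    sapply(solutes, function(s)
      as.numeric(dia$value[dia$solute == s & dia$time_min == as.numeric(tm)]))
  })
  cp <- sapply(as.character(pt), function(tm) {
    sapply(solutes, function(s)
      as.numeric(pla$value[pla$solute == s & pla$time_min == as.numeric(tm)]))
  })
  cd <- matrix(cd, nrow = length(solutes), dimnames = list(solutes, as.character(dt)))
  cp <- matrix(cp, nrow = length(solutes), dimnames = list(solutes, as.character(pt)))
  ind <- long[long$kind == "indicator", ]
  indicator <- if (nrow(ind) > 0) as.numeric(ind$value[order(ind$time_min)]) else NULL
  prot <- long[long$kind == "protein", ]
  protein <- NULL
  if (nrow(prot) > 0) {
    parts <- strsplit(prot$solute, ".", fixed = TRUE)
    stages <- unique(vapply(parts, `[[`, "", 1L))
    protein <- lapply(setNames(stages, stages), function(st) {
      sel <- vapply(parts, `[[`, "", 1L) == st
      setNames(as.list(as.numeric(prot$value[sel])),
               vapply(parts[sel], `[[`, "", 2L))
    })
  }
  dwell_session(
    session_id = long$session_id[[1]], species = get_meta("species"),
    glucose_strength = get_meta("glucose_strength"),
    fill_volume = get_vol("fill_volume"), drain_volume = get_vol("drain_volume"),
    residual_before = get_vol("residual_before"),
    residual_after = get_vol("residual_after"),
    dialysate_times = dt, dialysate_conc = cd,
    plasma_times = pt, plasma_conc = cp,
    indicator_conc = indicator, protein = protein,
    flush_volume = get_vol("flush_volume")
  )
}
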
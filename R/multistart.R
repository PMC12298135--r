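# Bounded multistart minimization driver shared by the UGM, UGM-18 and TPM
# fitting routines.

#' Bounded multistart minimization
#'
#' Runs a box-constrained quasi-Newton minimizer (`stats::optim`,
#' `method = "L-BFGS-B"`) from `n_restarts` initializations drawn uniformly
#' within the bounds from a seeded generator, and returns the best restart.
#' Ties are broken toward the lowest restart index, and the whole procedure
#' is deterministic given `seed`.
#'
#' @param objective Function of a parameter vector returning a scalar >= 0.
#' @param lower,upper Bounds, one per parameter.
#' @param n_restarts Number of random initializations (default 10).
#' @param seed Integer seed for the initialization draws.
#' @param init Optional matrix (`n_restarts` x `n_par`) of explicit
#'   initializations overriding the random draws.
#' @param maxit Iteration cap per restart.
#' @param factr Objective convergence tolerance factor passed to the
#'   minimizer (`factr * .Machine$double.eps` is the tolerance); the default
#'   corresponds to an absolute objective tolerance of 1e-8.
#' @return List: `par` (best parameters), `value` (best objective),
#'   `best_restart`, `n_restarts`, `converged` (best restart's flag),
#'   `restarts` (data frame of per-restart value/convergence), `seed`.
#' @export
multistart_fit <- function(objective, lower, upper, n_restarts = 10, seed = 1,
                           init = NULL, maxit = 500,
                           factr = 1e-8 / .Machine$double.eps) {
  n_par <- length(lower)
  stopifnot(length(upper) == n_par, all(upper >= lower))
  if (is.null(init)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    init <- matrix(runif(n_restarts * n_par, rep(lower, each = n_restarts),
                         rep(upper, each = n_restarts)),
                   nrow = n_restarts)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  parscale <- pmax((upper - lower) / 10, 1e-8)
  best <- NULL
  rows <- vector("list", n_restarts)
  for (k in seq_len(n_restarts)) {
    res <- tryCatch(
      optim(init[k, ], objective, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = maxit, factr = factr, parscale = parscale)),
      error = function(e) NULL)
    if (is.null(res)) {
      rows[[k]] <- data.frame(restart = k, value = NA_real_, converged = FALSE)
      next
    }
    rows[[k]] <- data.frame(restart = k, value = res$value,
                            converged = res$convergence == 0)
    if (is.null(best) || res$value < best$value) {
      best <- list(par = res$par, value = res$value, restart = k,
                   converged = res$convergence == 0)
    }
    if (res$value == 0) break  # objective already exact; no restart can improve
  }
  restarts <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(best)) {
    stop("all restarts failed:\n",
         paste(utils::capture.output(print(restarts)), collapse = "\n"),
         call. = FALSE)
  }
  list(par = unname(best$par), value = best$value, best_restart = best$restart,
       n_restarts = n_restarts, converged = best$converged,
       restarts = restarts, seed = seed)
}
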
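# Builders for small synthetic sessions used across the test files.

pig_solutes <- function() species_solutes("pig")

# A pig session with an arbitrary dialysate matrix; volumes default to a
# constant 2000 mL profile (fill 2000, drain 2000, zero residuals).
make_pig_session <- function(cd, times = species_grid("pig"),
                             fill = 2000, drain = 2000,
                             res_before = 0, res_after = 0,
                             cp = 20, plasma_times = c(0, 120, 240),
                             indicator = NULL) {
  solutes <- rownames(cd)
  cp_mat <- matrix(cp, length(solutes), length(plasma_times),
                   dimnames = list(solutes, plasma_times))
  dwell_session("test-pig", "pig", "1.36%", fill, drain, res_before, res_after,
                times, cd, plasma_times, cp_mat, indicator_conc = indicator)
}

# Dialysate series following the constant-volume pure-diffusion closed form
# cd(t) = cp (1 - exp(-MTAC t / V)), identical for every solute.
make_decay_session <- function(mtac = 10, V = 2000, cp = 20,
                               times = species_grid("pig")) {
  decay <- cp * (1 - exp(-mtac * times / V))
  cd <- matrix(rep(decay, each = 6), nrow = 6,
               dimnames = list(pig_solutes(), times))
  make_pig_session(cd, times, fill = V, drain = V, cp = cp)
}

# Independent oracle for the Patlak membrane flux: solve the steady
# convection-diffusion boundary problem c' = (v c - J)/D on [0, 1] with
# c(0) = cp, c(1) = cd by RK4 shooting; c(1) is affine in J, so two
# integrations determine the flux.
patlak_oracle <- function(jv, sigma, ps, cp, cd, n = 4000) {
  v <- jv * (1 - sigma)
  D <- ps
  integrate_c <- function(J) {
    co <- cp
    h <- 1 / n
    for (i in seq_len(n)) {
      f <- function(x) (v * x - J) / D
      k1 <- f(co); k2 <- f(co + h * k1 / 2)
      k3 <- f(co + h * k2 / 2); k4 <- f(co + h * k3)
      co <- co + h * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    }
    co
  }
  c0 <- integrate_c(0)
  c1 <- integrate_c(1)
  (cd - c0) / (c1 - c0)
}

# Simpson-rule integral on a uniform grid (odd number of points).
simpson <- function(x, y) {
  n <- length(x)
  stopifnot(n %% 2 == 1)
  h <- (x[n] - x[1]) / (n - 1)
  h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, by = 2)]) +
             2 * sum(y[seq(3, n - 2, by = 2)]))
}
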
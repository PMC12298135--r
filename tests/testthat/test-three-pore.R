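test_that("reflection coefficients and MTAC split follow the hindrance model", {
  pores <- pore_system()
  # urea, a = 2.6 A against r_s = 43 A: lambda 0.0605, phi 0.8827,
  # sigma = (1 - phi)^2 ~ 0.01376 (hand evaluation)
  sp <- sigma_and_split(2.6, pores, mtac = 20)
  expect_equal(unname(sp$sigma[["small"]]), 0.013757, tolerance = 1e-3)
  expect_equal(sum(sp$ps), 20)
  # point-solute limit: unrestricted diffusion
  sp0 <- sigma_and_split(1e-9, pores, 10)
  expect_lt(max(sp0$sigma), 1e-6)
  # solute as large as the small pore: that pathway closes
  spl <- sigma_and_split(43, pores, 10)
  expect_equal(unname(spl$sigma[["small"]]), 1)
  expect_equal(unname(spl$ps[["small"]]), 0)
  expect_equal(unname(spl$ps[["large"]]), 10)
  # excluded solute: large pore too
  expect_error(sigma_and_split(260, pores, 10))
})

test_that("pore fluxes vanish at osmotic-hydrostatic equilibrium", {
  # protein radius >= large pore makes sigma_prot = 1 at every pathway, so
  # dP = pi_p with cp = cd is an exact equilibrium
  pores <- pore_system(protein_radius = 250, dP = 22, pi_p = 22)
  mtac <- c(urea = 15, glucose = 10)
  pores$solute_radii <- c(urea = 2.6, glucose = 3.7)
  cp <- c(urea = 20, glucose = 6)
  fl <- pore_fluxes(2000, cd = cp, cp = cp, mtac, pores)
  expect_equal(unname(fl$Jv), rep(0, 3))
  expect_equal(max(abs(fl$Js)), 0)
})

test_that("Patlak flux approaches the diffusive limit as Pe -> 0", {
  jv <- 1e-9
  expect_equal(pdwell:::patlak_flux(jv, sigma = 0, ps = 5, cp = 20, cd = 4),
               5 * (20 - 4), tolerance = 1e-6)
})

test_that("Patlak flux matches the boundary-value shooting oracle", {
  for (jv in c(-3, -0.4, 0.7, 4)) {
    for (ps in c(2, 8)) {
      got <- pdwell:::patlak_flux(jv, sigma = 0, ps = ps, cp = 20, cd = 4)
      expect_equal(got, patlak_oracle(jv, 0, ps, 20, 4), tolerance = 1e-6)
    }
  }
  # sigma scales the convective velocity
  got <- pdwell:::patlak_flux(2, sigma = 0.3, ps = 5, cp = 18, cd = 9)
  expect_equal(got, patlak_oracle(2, 0.3, 5, 18, 9), tolerance = 1e-6)
})

test_that("closed system and lymph-only dwells behave analytically", {
  solutes <- species_solutes("human")
  mtac0 <- setNames(rep(0, 4), solutes)
  cd0 <- c(urea = 1, creatinine = 0.1, sodium = 132, glucose = 100)
  cp <- c(urea = 20, creatinine = 0.9, sodium = 140, glucose = 6)
  tt <- seq(0, 240, by = 20)
  closed <- tpm_simulate(mtac0, L = 0, V0 = 2200, cd0, cp, tt,
                         pores = pore_system(LpS = 0))
  expect_equal(closed$V, rep(2200, length(tt)))
  expect_equal(max(abs(closed$cd - cd0)), 0, tolerance = 1e-10)
  # lymph removes fluid and solute isotonically: V linear, cd frozen
  lymph <- tpm_simulate(mtac0, L = 2, V0 = 2200, cd0, cp, tt,
                        pores = pore_system(LpS = 0))
  expect_equal(lymph$V, 2200 - 2 * tt, tolerance = 1e-8)
  expect_equal(max(abs(lymph$cd - cd0)), 0, tolerance = 1e-8)
  expect_equal(lymph$uf, -480, tolerance = 1e-6)
})

test_that("volume and solute mass bookkeeping close within solver tolerance", {
  solutes <- species_solutes("pig")
  mtac <- c(urea = 18, creatinine = 8, sodium = 4, phosphate = 6,
            glucose = 12, potassium = 14)
  plasma <- c(urea = 22, creatinine = 0.8, sodium = 140, phosphate = 1.8,
              glucose = 5, potassium = 4.2)
  bag <- fresh_bag_composition(solutes, "1.36%")
  cd0 <- (2000 * bag + 200 * plasma) / 2200
  tt <- seq(0, 240, by = 0.5)
  sim <- tpm_simulate(mtac, L = 1.2, V0 = 2200, cd0, plasma, tt,
                      rtol = 1e-8, atol = 1e-10, track_mass = TRUE)
  # per-solute mass: V cd - V0 cd0 vs the co-integrated net flux
  mass <- sweep(sim$cd, 2, sim$V, `*`)
  drift <- abs(mass - mass[, 1] - sim$cum_mass)
  tol <- 10 * (1e-10 + 1e-8 * max(mass))
  expect_lt(max(drift), tol)
  # volume: V(t) - V(0) vs Simpson quadrature of the R-side fluxes
  net_jv <- vapply(seq_along(tt), function(i) {
    fl <- pore_fluxes(sim$V[i], sim$cd[, i], plasma, mtac, pore_system())
    sum(fl$Jv) - 1.2
  }, numeric(1))
  expect_equal(sim$V[length(tt)] - sim$V[1], simpson(tt, net_jv),
               tolerance = 1e-6)
})

test_that("glucose falls monotonically and UF grows with bag strength", {
  solutes <- species_solutes("human")
  mtac <- c(urea = 20, creatinine = 10, sodium = 6, glucose = 15)
  plasma <- c(urea = 22, creatinine = 0.8, sodium = 140, glucose = 6)
  tt <- seq(0, 240, by = 2)
  ufs <- sapply(c("1.36%", "2.27%", "3.86%"), function(st) {
    bag <- fresh_bag_composition(solutes, st)
    cd0 <- (2000 * bag + 200 * plasma) / 2200
    sim <- tpm_simulate(mtac, L = 1, V0 = 2200, cd0, plasma, tt)
    expect_true(all(diff(sim$cd["glucose", ]) < 0))
    sim$uf
  })
  expect_true(all(diff(ufs) > 0))
})

test_that("aquaporin flux creates the early sodium dip and its removal abolishes it", {
  solutes <- species_solutes("human")
  mtac <- c(urea = 20, creatinine = 10, sodium = 6, glucose = 15)
  plasma <- c(urea = 22, creatinine = 0.8, sodium = 140, glucose = 6)
  bag <- fresh_bag_composition(solutes, "3.86%")
  cd0 <- (2000 * bag + 200 * plasma) / 2200
  tt <- seq(0, 240, by = 2)
  sim <- tpm_simulate(mtac, L = 1, V0 = 2200, cd0, plasma, tt)
  na <- sim$cd["sodium", ]
  i_min <- which.min(na)
  expect_lt(na[i_min], na[1] - 1)          # dip below the initial value
  expect_lt(tt[i_min], 239)                # interior minimum ...
  expect_gt(na[length(na)], na[i_min])     # ... followed by a rise
  # no ultrasmall pathway -> no solute-free water -> no dip
  p0 <- pore_system(alpha = list(ultrasmall = 0, small = 0.92, large = 0.08))
  na0 <- tpm_simulate(mtac, L = 1, V0 = 2200, cd0, plasma, tt, pores = p0)$cd["sodium", ]
  expect_gte(min(na0), na0[1] - 1e-9)
})

test_that("initial state mixes the fresh bag with residual fluid", {
  g <- generate_session("pig", seed = 3, noise = no_noise())
  ses <- g$session
  st <- tpm_initial_state(ses, "plasma")
  expect_equal(st$V0, ses$fill_volume + ses$residual_before)
  bag <- fresh_bag_composition(ses$solutes, ses$glucose_strength)
  cp0 <- sapply(ses$solutes, function(s) plasma_at(ses, s, 0))
  expect_equal(st$cd0, (ses$fill_volume * bag + ses$residual_before * cp0) / st$V0)
  # bag-composition residual: pure fresh fluid
  st2 <- tpm_initial_state(ses, "bag")
  expect_equal(st2$cd0, bag)
})
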
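test_that("residual volume reproduces the dilution mass balance", {
  expect_equal(residual_volume(30, 6, 1000), 250)
  expect_equal(residual_volume(10, 5, 1000), 1000)
  expect_equal(residual_volume(30, 0, 1000), 0)
  expect_error(residual_volume(5, 6, 1000), "non-physical dilution")
  expect_error(residual_volume(5, 5, 1000), "non-physical dilution")
})

test_that("residual volume round-trips a simulated flush", {
  set.seed(1)
  for (i in 1:25) {
    vres <- runif(1, 10, 600)
    flush <- runif(1, 500, 2000)
    c_pre <- runif(1, 0.5, 40)
    c_post <- c_pre * vres / (vres + flush)
    expect_equal(residual_volume(c_pre, c_post, flush), vres,
                 tolerance = 1e-9)
  }
})

test_that("linear volume profile anchors fill+residual endpoints", {
  cd <- matrix(10, 6, 8, dimnames = list(pig_solutes(), species_grid("pig")))
  ses <- make_pig_session(cd, fill = 2000, drain = 2400,
                          res_before = 200, res_after = 300)
  vp <- volume_profile_linear(ses)
  expect_equal(volume_at(vp, c(0, 120, 240)), c(2200, 2450, 2700))
  expect_equal(vp$provenance, "linear")

  ses0 <- make_pig_session(cd)
  expect_equal(volume_at(volume_profile_linear(ses0), c(0, 77, 240)),
               rep(2000, 3))

  ses_na <- ses
  ses_na$residual_after <- NA_real_
  expect_error(volume_profile_linear(ses_na), "residual_after")
})

test_that("human linear profile is anchored at the first measured time", {
  solutes <- species_solutes("human")
  tt <- species_grid("human")
  cd <- matrix(10, 4, 3, dimnames = list(solutes, tt))
  ses <- dwell_session("h", "human", "3.86%", 2000, 2500, 150, 250, tt, cd,
                       120, matrix(20, 4, 1, dimnames = list(solutes, 120)))
  vp <- volume_profile_linear(ses)
  expect_equal(volume_at(vp, 20), 2150)   # V0 at t = 20
  expect_equal(volume_at(vp, 240), 2750)
})

test_that("indicator profile inverts mass conservation", {
  cd <- matrix(10, 6, 8, dimnames = list(pig_solutes(), species_grid("pig")))
  tt <- species_grid("pig")
  # constant indicator -> constant volume
  ses <- make_pig_session(cd, fill = 2000, res_before = 200,
                          indicator = rep(0.45, 8))
  expect_equal(volume_profile_indicator(ses)$V, rep(2200, 8))
  # hand cases: c 0.5 -> 0.4 gives V 2000 -> 2500; 0.25 gives 4000
  ci <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.4, 0.3, 0.25)
  ses2 <- make_pig_session(cd, fill = 2000, res_before = 0, indicator = ci)
  vp <- volume_profile_indicator(ses2)
  expect_equal(volume_at(vp, c(120, 240)), c(2500, 4000))
  # round trip from a known volume trajectory
  Vt <- 2200 + 3 * tt - 0.008 * tt^2
  ses3 <- make_pig_session(cd, fill = 2000, res_before = 200,
                           indicator = 0.5 * 2200 / Vt)
  expect_equal(volume_profile_indicator(ses3)$V, Vt, tolerance = 1e-12)
  ses_bad <- make_pig_session(cd, indicator = c(rep(0.5, 7), 0))
  expect_error(volume_profile_indicator(ses_bad), "indicator")
})

test_that("plasma interpolation is linear for pigs, constant for humans", {
  cd <- matrix(10, 6, 8, dimnames = list(pig_solutes(), species_grid("pig")))
  cp <- matrix(20, 6, 3, dimnames = list(pig_solutes(), c(0, 120, 240)))
  cp["urea", ] <- c(20, 18, 18)
  ses <- make_pig_session(cd)
  ses$plasma_conc <- cp
  expect_equal(plasma_at(ses, "urea", 60), 19)
  expect_equal(plasma_at(ses, "urea", 180), 18)
  expect_equal(plasma_at(ses, "urea", -10), 20)  # clamped, not extrapolated
  expect_equal(plasma_at(ses, "urea", 400), 18)

  solutes <- species_solutes("human")
  tt <- species_grid("human")
  hs <- dwell_session("h", "human", "3.86%", 2000, 2500, 150, 250, tt,
                      matrix(10, 4, 3, dimnames = list(solutes, tt)),
                      120, matrix(22, 4, 1, dimnames = list(solutes, 120)))
  expect_equal(plasma_at(hs, "urea", c(0, 35, 240)), rep(22, 3))
})

test_that("normalization uses plasma for solutes and cd(0) for glucose", {
  tt <- species_grid("pig")
  cd <- matrix(10, 6, 8, dimnames = list(pig_solutes(), tt))
  cd["glucose", ] <- 214 * exp(-tt / 346.2)   # 214 -> ~107 at 240
  cd["sodium", ] <- 132
  ses <- make_pig_session(cd, cp = 20)
  expect_equal(unname(normalize_concentration(cd["urea", ], "urea", ses)),
               rep(0.5, 8))
  g <- unname(normalize_concentration(cd["glucose", ], "glucose", ses))
  expect_equal(g[1], 1.0)
  expect_equal(g[8], 0.5, tolerance = 1e-3)
  ses$plasma_conc["sodium", ] <- 132
  expect_equal(unname(normalize_concentration(cd["sodium", ], "sodium", ses)),
               rep(1, 8))
  # idempotent on unit-plasma normalized input
  ses$plasma_conc["urea", ] <- 1
  v <- normalize_concentration(cd["urea", ], "urea", ses)
  expect_equal(normalize_concentration(v, "urea", ses), v)
  ses$plasma_conc["urea", ] <- 0
  expect_error(norm_constant(ses, "urea"), "urea")
})

test_that("JSON and long-CSV round trips are lossless", {
  g <- generate_session("pig", seed = 31, noise = noise_model())
  ses <- g$session
  path <- withr::local_tempfile(fileext = ".json")
  write_session(ses, path)
  back <- read_session(path)
  expect_equal(back, ses)

  long <- session_to_long(ses)
  expect_setequal(unique(long$kind),
                  c("dialysate", "plasma", "indicator", "protein", "volume", "meta"))
  back2 <- session_from_long(long)
  expect_equal(back2$dialysate_conc, ses$dialysate_conc)
  expect_equal(back2$plasma_conc, ses$plasma_conc)
  expect_equal(back2$indicator_conc, ses$indicator_conc)
  expect_equal(back2$residual_before, ses$residual_before)
  expect_equal(back2$protein, lapply(ses$protein, lapply, unname),
               tolerance = 1e-12)

  # csv round trip through disk
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, csv, row.names = FALSE)
  back3 <- session_from_long(read.csv(csv, stringsAsFactors = FALSE,
                                      colClasses = c(value = "character")))
  expect_equal(back3$dialysate_conc, ses$dialysate_conc)
})

test_that("session validation flags structural violations", {
  g <- generate_session("human", seed = 8, noise = noise_model())
  expect_true(validate_dwell_session(g$session))
  bad <- g$session
  bad$dialysate_conc["urea", 2] <- -1
  expect_error(validate_dwell_session(bad), ">= 0")
  bad2 <- g$session
  bad2$dialysate_times <- rev(bad2$dialysate_times)
  expect_error(validate_dwell_session(bad2), "increasing")
  bad3 <- g$session
  bad3$fill_volume <- -5
  expect_error(validate_dwell_session(bad3), "volumes")
})
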
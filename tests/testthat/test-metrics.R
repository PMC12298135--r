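test_that("per-solute SSE is the normalized RMSE", {
  expect_equal(sse_solute(c(0.6, 0.7), c(0.5, 0.5)), sqrt((0.01 + 0.04) / 2))
  expect_equal(sse_solute(c(1, 1, 1) + 0.05, c(1, 1, 1)), 0.05)
  expect_equal(sse_solute(1:5 / 10, 1:5 / 10), 0)
  # RMSE never exceeds the largest residual
  set.seed(2)
  for (i in 1:10) {
    p <- runif(6); m <- runif(6)
    expect_lte(sse_solute(p, m), max(abs(p - m)))
  }
  expect_error(sse_solute(numeric(0), numeric(0)), "empty")
  expect_error(sse_solute(1:3, 1:4), "grids differ")
})

test_that("Cerror sums per-solute RMSEs and is permutation invariant", {
  pred <- rbind(urea = c(0.5, 0.6), glucose = c(0.9, 0.8))
  meas <- rbind(urea = c(0.4, 0.4), glucose = c(1.0, 0.6))
  expect_equal(cerror(pred, meas),
               sse_solute(pred[1, ], meas[1, ]) + sse_solute(pred[2, ], meas[2, ]))
  expect_equal(cerror(pred[2:1, ], meas), cerror(pred, meas))
  expect_equal(cerror(pred, pred), 0)
  # single solute: Cerror reduces to SSE
  expect_equal(cerror(pred[1, , drop = FALSE], meas[1, , drop = FALSE]),
               sse_solute(pred[1, ], meas[1, ]))
  # pooled single-root variant
  expect_equal(cerror(pred, meas, combined_root = TRUE),
               sqrt(sum((pred - meas)^2) / 2))
  expect_error(cerror(pred, meas[, 1, drop = FALSE]), "grids differ")
})

test_that("Verror matches hand arithmetic and is scale invariant", {
  expect_equal(verror(c(2100, 2400), c(2000, 2400)), sqrt((100 / 2400)^2 / 2))
  expect_equal(verror(c(2000, 2400), c(2000, 2400)), 0)
  set.seed(3)
  vm <- runif(5, 1800, 2800); vp <- vm + rnorm(5, 0, 60)
  expect_equal(verror(7 * vp, 7 * vm), verror(vp, vm))
  expect_error(verror(1:3, c(0, 0, 0)), "zero")
  expect_error(verror(1:3, 1:2), "grids differ")
})

test_that("measured UF is the volume balance of the dwell", {
  cd <- matrix(10, 6, 8, dimnames = list(pig_solutes(), species_grid("pig")))
  ses <- make_pig_session(cd, fill = 2000, drain = 2400,
                          res_before = 200, res_after = 300)
  expect_equal(uf_measured(ses), 500)
  ses2 <- make_pig_session(cd, fill = 2000, drain = 2000,
                           res_before = 250, res_after = 250)
  expect_equal(uf_measured(ses2), 0)
  ses3 <- make_pig_session(cd, fill = 2000, drain = 1800,
                           res_before = 200, res_after = 200)
  expect_equal(uf_measured(ses3), -200)
  ses3$residual_after <- NA_real_
  expect_error(uf_measured(ses3), "residual")
})

test_that("multistart minimization is deterministic and returns the best restart", {
  sphere <- function(p) sum((p - c(2, -1))^2) + 0.5
  a <- multistart_fit(sphere, c(-5, -5), c(5, 5), n_restarts = 6, seed = 42)
  b <- multistart_fit(sphere, c(-5, -5), c(5, 5), n_restarts = 6, seed = 42)
  expect_identical(a, b)
  expect_equal(a$par, c(2, -1), tolerance = 1e-5)
  expect_equal(a$value, 0.5, tolerance = 1e-8)
  expect_true(all(a$value <= a$restarts$value + 1e-12))
  # different seed draws different initializations
  seen <- new.env()
  recorder <- function(p) {
    if (is.null(seen$first)) seen$first <- p
    sum((p - c(2, -1))^2) + 0.5
  }
  multistart_fit(recorder, c(-5, -5), c(5, 5), n_restarts = 1, seed = 42)
  first42 <- seen$first; seen$first <- NULL
  multistart_fit(recorder, c(-5, -5), c(5, 5), n_restarts = 1, seed = 43)
  expect_false(identical(first42, seen$first))
  # ties break to the lowest restart index
  flat <- function(p) 1
  f <- multistart_fit(flat, 0, 1, n_restarts = 5, seed = 1)
  expect_identical(f$best_restart, 1L)
})

test_that("multistart honours bounds and recovers an ODE-embedded parameter", {
  tt <- species_grid("pig")
  vp <- volume_profile(tt, rep(2000, 8), "linear")
  target <- forward_lumped_ode(10, 0, 0.5, vp, 20, tt, 0)
  obj <- function(p) sse_solute(forward_lumped_ode(p[1], 0, 0.5, vp, 20, tt, 0) / 20,
                                target / 20)
  ms <- multistart_fit(obj, 0, 200, n_restarts = 5, seed = 7)
  expect_equal(ms$par, 10, tolerance = 0.01)
  expect_gte(ms$par, 0)
})
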
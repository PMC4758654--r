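p <- default_p

test_that("mirror-boundary Laplacian has the expected stencil action", {
  g <- sim_grid(64, 48)
  expect_equal(laplacian(matrix(3.7, g$nx, g$ny), g),
               matrix(0, g$nx, g$ny))
  X <- matrix(g$x^2, g$nx, g$ny)
  L <- laplacian(X, g)
  expect_equal(L[10:50, 10:40], matrix(2, 41, 31), tolerance = 1e-10)
  spike <- matrix(0, g$nx, g$ny)
  spike[30, 20] <- 1
  Ls <- laplacian(spike, g)
  expect_equal(Ls[30, 20], -(2 / g$dx^2 + 2 / g$dy^2))
  expect_error(laplacian(matrix(0, 3, 3), g), "congruent")
})

test_that("cosine-basis solves invert the discrete operators exactly", {
  g <- sim_grid(48, 40, width = 100, height = 80)
  u0 <- smooth_random_field(g, seed = 3)
  rhs <- u0 - 2.5 * laplacian(u0, g)
  expect_equal(angiophase:::solve_helmholtz(rhs, 2.5, g), u0,
               tolerance = 1e-12)
  rhs2 <- u0 + 1.3 * laplacian(laplacian(u0, g), g) - 0.4 * laplacian(u0, g)
  expect_equal(angiophase:::solve_biharmonic(rhs2, 0.4, 1.3, g), u0,
               tolerance = 1e-12)
})

test_that("tumor stepper preserves uniform bulk states", {
  g <- sim_grid(32, 24)
  for (ph in c(0, 1)) {
    st <- uniform_state(g, phi = ph, sigma = 0.3)
    expect_equal(step_tumor(st, g, 2, p), matrix(ph, g$nx, g$ny),
                 tolerance = 1e-12)
  }
})

test_that("a 1D tumor front under low nutrient recedes at the analytic speed", {
  # Oracle: traveling-wave speed of the tilted double-well equation,
  # v = M_phi * m(sigma) * 3 * sqrt(2) * lambda_phi (checked independently
  # against fine-grid explicit integration during development).
  g <- strip_grid()
  sigma0 <- 0.2
  st <- front_state(g, 512, sigma0, p)
  x_start <- front_position(st$phi, g)
  v_theory <- -p$M_phi * tilting_m(sigma0, p) * 3 * sqrt(2) * p$lambda_phi
  t_total <- 8
  nsteps <- 40
  for (k in seq_len(nsteps)) st$phi <- step_tumor(st, g, t_total / nsteps, p)
  x_end <- front_position(st$phi, g)
  v <- (x_end - x_start) / t_total
  expect_lt(v, 0)  # tumor shrinks: host is energetically preferred
  expect_equal(v, v_theory, tolerance = 0.05)
})

test_that("nutrient reaction is integrated exactly for uniform states", {
  g <- sim_grid(24, 20)
  st <- uniform_state(g, phi = 0, sigma = 0.8, cc = -1)
  for (dt in c(0.5, 2)) {
    out <- step_nutrient(st, g, dt, S = 1, p)
    expected <- 0.8 * exp(-p$V_uH * smoothed_heaviside_H(1, p) * dt)
    expect_equal(max(abs(out - expected)), 0, tolerance = 1e-6)
  }
  # inside a capillary at sigma = 1 the production term vanishes
  st2 <- uniform_state(g, phi = 0, sigma = 1, cc = 1)
  out2 <- step_nutrient(st2, g, 1, S = 1, p)
  expect_true(all(out2 < 1))
  expect_true(all(out2 > 1 - 2 * p$V_uH * 1.1))
})

test_that("host nutrient profile near a maintained capillary has the analytic
           decay length", {
  # steady state of D_sigma sigma'' = V_uH sigma: length sqrt(D/V) = 223.6
  g <- sim_grid(4, 256, width = 16, height = 1024)
  ymat <- matrix(g$y, g$nx, g$ny, byrow = TRUE)
  st <- uniform_state(g, phi = 0, sigma = 0.45, cc = -1)
  st$c <- tanh((20 - ymat) / p$lambda_c)
  for (k in 1:300) st$sigma <- step_nutrient(st, g, 50, S = 1, p)
  prof <- st$sigma[1, ]
  sel <- g$y > 100 & g$y < 500
  fit <- stats::lm(log(prof[sel]) ~ g$y[sel])
  expect_equal(-1 / coef(fit)[[2]], sqrt(p$D_sigma / p$V_uH),
               tolerance = 0.03)
})

test_that("capillary stepper preserves bulk states and conserves mass", {
  g <- sim_grid(48, 40, width = 100, height = 80)
  st1 <- uniform_state(g, cc = 1, f = 0)
  expect_equal(step_capillary(st1, g, 1, p), matrix(1, g$nx, g$ny),
               tolerance = 1e-12)
  st2 <- uniform_state(g, cc = -1, f = 0.7)
  expect_equal(step_capillary(st2, g, 1, p), matrix(-1, g$nx, g$ny),
               tolerance = 1e-8)
  # Cahn-Hilliard mass conservation with the proliferation term off (f = 0)
  st <- uniform_state(g)
  st$c <- smooth_random_field(g, seed = 11, lo = -1, hi = 1, alpha = 5)
  m0 <- mean(st$c)
  for (k in 1:100) st$c <- step_capillary(st, g, 0.5, p)
  expect_lt(abs(mean(st$c) - m0), 1e-8 * max(1, abs(m0)))
  expect_true(all(is.finite(st$c)))
})

test_that("TAF stepper sources only from tumor and respects saturation", {
  g <- sim_grid(24, 20)
  st0 <- uniform_state(g, phi = 0, f = 0)
  expect_equal(step_taf(st0, g, 1, p), matrix(0, g$nx, g$ny))
  st1 <- uniform_state(g, phi = 1, sigma = 0.3, cc = -1, f = 0)
  dt <- 1e-3
  expect_equal(step_taf(st1, g, dt, p), matrix(p$G_amp * dt, g$nx, g$ny),
               tolerance = 1e-3)
  st2 <- uniform_state(g, phi = 1, sigma = 0.3, cc = -1, f = 1)
  expect_equal(step_taf(st2, g, 1, p), matrix(1, g$nx, g$ny),
               tolerance = 1e-12)
})

test_that("adaptive controller follows the halve/grow rules and the TEC cap", {
  opts <- numerics_options()
  no_tec <- list(solver_failed = FALSE, max_change = 1e-3, tec_speed = 0)
  expect_equal(adapt_dt(1, no_tec, p, opts), 1.2)
  expect_equal(adapt_dt(1, modifyList(no_tec, list(max_change = 0.1)), p, opts),
               0.5)
  expect_equal(adapt_dt(1, modifyList(no_tec, list(solver_failed = TRUE)),
                        p, opts), 0.5)
  expect_equal(adapt_dt(10, no_tec, p, opts), opts$dt_max)
  # displacement cap: a TEC at full speed chi may move at most R/2 per step
  tec <- modifyList(no_tec, list(tec_speed = p$chi))
  expect_equal(adapt_dt(10, tec, p, opts), p$R / (2 * p$chi))
  expect_error(adapt_dt(1.5 * opts$dt_min,
                        modifyList(no_tec, list(solver_failed = TRUE)),
                        p, opts), "underflow")
})

test_that("tumor free energy decays with the nutrient frozen", {
  g <- sim_grid(64, 48)
  st <- uniform_state(g, sigma = 0.3)
  st$phi <- smooth_random_field(g, seed = 5, lo = -0.02, hi = 1.02)
  E <- numeric(121)
  E[1] <- tumor_free_energy(st$phi, st$sigma, g, p)
  for (k in 1:120) {
    st$phi <- step_tumor(st, g, 0.5, p)
    E[k + 1] <- tumor_free_energy(st$phi, st$sigma, g, p)
  }
  expect_true(all(diff(E) <= abs(E[1]) * 1e-10))
})

test_that("sigma and TAF remain in [0,1] from in-range initial data", {
  g <- sim_grid(48, 40)
  st <- uniform_state(g)
  st$sigma <- smooth_random_field(g, seed = 21)
  st$f <- smooth_random_field(g, seed = 22)
  st$phi <- smooth_random_field(g, seed = 23)
  st$c <- smooth_random_field(g, seed = 24, lo = -1, hi = 1)
  for (k in 1:50) {
    st$sigma <- step_nutrient(st, g, 1, S = 0.7, p)
    st$f <- step_taf(st, g, 1, p)
  }
  expect_gte(min(st$sigma), -1e-12)
  expect_lte(max(st$sigma), 1 + 1e-12)
  expect_gte(min(st$f), -1e-12)
  expect_lte(max(st$f), 1 + 1e-12)
})

test_that("deterministic steppers preserve mirror symmetry", {
  g <- sim_grid(48, 40)
  symmetrize <- function(M) (M + M[g$nx:1, ]) / 2
  st <- uniform_state(g)
  st$phi <- symmetrize(smooth_random_field(g, seed = 31, lo = 0, hi = 1))
  st$sigma <- symmetrize(smooth_random_field(g, seed = 32))
  st$c <- symmetrize(smooth_random_field(g, seed = 33, lo = -1, hi = 1))
  st$f <- symmetrize(smooth_random_field(g, seed = 34, lo = 0, hi = 0.5))
  st$sigma <- step_nutrient(st, g, 1, 1, p)
  st$phi <- step_tumor(st, g, 1, p)
  st$f <- step_taf(st, g, 1, p)
  st$c <- step_capillary(st, g, 1, p)
  for (fl in list(st$phi, st$sigma, st$f, st$c))
    expect_equal(fl, fl[g$nx:1, ], tolerance = 1e-12)
})

test_that("halving the grid spacing barely changes the day-5 tumor area", {
  area_at <- function(nx, ny) {
    cfg <- scenario_config("avascular", nx = nx, ny = ny, t_end_days = 5,
                           record_every = 50)
    run <- run_scenario(cfg)
    c(A0 = run$series$A_t[1], A5 = run$series$A_t[nrow(run$series)])
  }
  coarse <- area_at(64, 48)
  fine <- area_at(128, 96)
  expect_lt(abs(coarse[["A5"]] - fine[["A5"]]) / fine[["A0"]], 0.02)
})

test_that("field-state validation clips roundoff but rejects real violations", {
  g <- sim_grid(16, 12)
  st <- uniform_state(g, phi = 0.5, sigma = 0.5, cc = 0, f = 0.5)
  st$sigma[1, 1] <- 1 + 1e-12
  out <- validate_field_state(st)
  expect_lte(max(out$sigma), 1)
  st$sigma[1, 1] <- 1.01
  expect_error(validate_field_state(st), "out of")
  st <- uniform_state(g)
  st$c[2, 2] <- 1.2
  expect_error(validate_field_state(st), "capillary")
  st <- uniform_state(g)
  st$phi[1, 1] <- NaN
  expect_error(validate_field_state(st), "NaN")
})
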
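p <- default_p

test_that("the activation RNG stream is reproducible and leaves the global
           RNG untouched", {
  set.seed(999)
  before <- .Random.seed
  r1 <- rng_stream(42)
  r2 <- rng_stream(42)
  a <- replicate(20, angiophase:::rng_int(r1, 1000))
  b <- replicate(20, angiophase:::rng_int(r2, 1000))
  expect_identical(a, b)
  expect_identical(before, .Random.seed)
})

# grid fine enough (dx = 2.5) to resolve the R = 4 cell template, with a
# capillary strip at the bottom
tec_grid <- sim_grid(256, 192, width = 640, height = 480)
strip_state <- function(f_level = 0.01, grid = tec_grid) {
  st <- uniform_state(grid, f = f_level)
  ymat <- matrix(grid$y, grid$nx, grid$ny, byrow = TRUE)
  st$c <- ifelse(ymat < 20, 1, -1)
  st
}

test_that("TEC activation requires capillary, TAF, and Dll4 clearance", {
  st <- strip_state(f_level = 0.002)
  rng <- rng_stream(1)
  # far-away existing TEC (distance > delta4): a site is eligible
  tec_far <- tip_cell(1, c(320, 400), p)
  out <- scan_activation(st, list(tec_far), tec_grid, p, rng)
  expect_s3_class(out, "tip_cell")
  expect_lt(out$pos[2], 25)  # activated on the strip
  # f below f_act: nothing activates
  st_lowf <- strip_state(f_level = 5e-4)
  expect_null(scan_activation(st_lowf, list(), tec_grid, p, rng))
  # an active TEC on the strip blocks a delta4 disc around it
  tec_near <- tip_cell(1, c(320, 10), p)
  for (k in 1:25) {
    out <- scan_activation(st, list(tec_near), tec_grid, p, rng)
    d <- sqrt(sum((out$pos - tec_near$pos)^2))
    expect_gt(d, p$delta4)
  }
  # inactive TECs do not inhibit
  tec_off <- tip_cell(1, c(320, 10), p)
  tec_off$active <- FALSE
  hits <- replicate(40, {
    o <- scan_activation(st, list(tec_off), tec_grid, p, rng)
    sqrt(sum((o$pos - tec_off$pos)^2)) <= p$delta4
  })
  expect_true(any(hits))
})

test_that("mirror images across the symmetry edges also inhibit activation", {
  st <- strip_state()
  rng <- rng_stream(3)
  # TEC just across the x = 0 symmetry edge at x = 30: its own position only
  # blocks up to delta4, but its mirror (-30, y) blocks sites with x < 50
  tec <- tip_cell(1, c(30, 10), p)
  for (k in 1:40) {
    out <- scan_activation(st, list(tec), tec_grid, p, rng)
    d_real <- sqrt(sum((out$pos - c(30, 10))^2))
    d_mirror <- sqrt(sum((out$pos - c(-30, 10))^2))
    expect_gt(d_real, p$delta4)
    expect_gt(d_mirror, p$delta4)
  }
})

test_that("TEC migration follows the TAF gradient at the modulated speed", {
  g <- tec_grid
  st <- uniform_state(g, phi = 0)
  xmat <- matrix(g$x, g$nx, g$ny)
  st$f <- 0.001 + 1e-4 * xmat  # uniform gradient pointing +x
  dt <- 0.2
  tec <- tip_cell(1, c(300, 240), p)
  out <- update_tec(tec, st, g, dt, p)
  expect_equal(out$last_disp, p$chi * 1.0 * dt, tolerance = 1e-4)
  expect_gt(out$pos[1], 300)
  expect_equal(out$pos[2], 240, tolerance = 1e-9)
  expect_equal(out$path_length, out$last_disp)
  # deep inside the tumor the same cell crawls at about a tenth of the speed
  st$phi <- matrix(1, g$nx, g$ny)
  out2 <- update_tec(tec, st, g, dt, p)
  expect_equal(out2$last_disp, 0.1 * p$chi * dt, tolerance = 1e-4)
  # a deactivated TEC never moves
  tec$active <- FALSE
  out3 <- update_tec(tec, st, g, dt, p)
  expect_identical(out3$pos, tec$pos)
  expect_equal(out3$last_disp, 0)
})

test_that("filopodia are only consulted beyond 4R of migrated arc", {
  g <- tec_grid
  st <- uniform_state(g)
  st$c[, ] <- -1
  st$c[matrix(g$x, g$nx, g$ny) > 322] <- 1  # capillary wall within 4R reach
  st$f <- 0.001 + 1e-4 * matrix(g$x, g$nx, g$ny)
  tec <- tip_cell(1, c(310, 240), p)
  tec$path_length <- 3 * p$R
  out <- update_tec(tec, st, g, 0.1, p)
  expect_null(out$redirect_dir)  # threshold is 4R
  tec$path_length <- 4.5 * p$R
  tec$path <- rbind(c(300, 240), tec$pos)
  out2 <- update_tec(tec, st, g, 0.1, p)
  expect_false(is.null(out2$redirect_dir))
  expect_gt(out2$redirect_dir[1], 0.9)  # points towards the wall (+x)
})

test_that("filopodia ignore the cell's own trail", {
  g <- tec_grid
  st <- uniform_state(g)
  st$c[, ] <- -1
  # trail along y = 240 behind the cell, imprinted as its own sprout
  tec <- tip_cell(1, c(300, 240), p)
  path <- cbind(seq(240, 300, by = 2), 240)
  tec$path <- path
  tec$path_length <- 60
  for (i in seq_len(nrow(path))) {
    fake <- tec; fake$pos <- path[i, ]
    st$c <- imprint_template(st$c, fake, g, p)
  }
  expect_null(detect_filopodia(tec, st, g, p))
  # a foreign capillary ahead is detected
  st$c[matrix(g$x, g$nx, g$ny) > 312] <- 1
  dir <- detect_filopodia(tec, st, g, p)
  expect_false(is.null(dir))
  expect_gt(dir[1], 0.5)
})

test_that("anastomosis requires redirected homing onto foreign capillary", {
  g <- tec_grid
  st <- strip_state()
  # redirected TEC right next to the strip (foreign capillary): fuses
  tec <- tip_cell(1, c(320, 22), p)
  tec$redirect_dir <- c(0, -1)
  tec$path <- rbind(c(320, 60), c(320, 22))
  tec$path_length <- 38
  out <- try_anastomose(tec, st, g, p)
  expect_false(out$active)
  expect_identical(out$deactivation_reason, "anastomosis")
  # far from any capillary: stays active
  tec2 <- tip_cell(2, c(320, 300), p)
  tec2$redirect_dir <- c(0, -1)
  expect_true(try_anastomose(tec2, st, g, p)$active)
  # overlapping only its own trail: stays active
  st3 <- uniform_state(g)
  st3$c[, ] <- -1
  tec3 <- tip_cell(3, c(320, 240), p)
  tec3$redirect_dir <- c(1, 0)
  path <- cbind(seq(280, 320, by = 2), 240)
  tec3$path <- path
  tec3$path_length <- 40
  for (i in seq_len(nrow(path))) {
    fake <- tec3; fake$pos <- path[i, ]
    st3$c <- imprint_template(st3$c, fake, g, p)
  }
  expect_true(try_anastomose(tec3, st3, g, p)$active)
})

test_that("template imprinting raises c locally, never lowers it, and is
           idempotent", {
  g <- tec_grid
  cfld <- matrix(-1, g$nx, g$ny)
  tec <- tip_cell(1, c(320, 240), p)
  c1 <- imprint_template(cfld, tec, g, p)
  expect_gt(angiophase:::interp_field(c1, g, tec$pos), 0.95)
  far <- sqrt(outer((g$x - 320)^2, (g$y - 240)^2, `+`)) > 3 * p$R
  expect_equal(c1[far], rep(-1, sum(far)))
  expect_identical(imprint_template(c1, tec, g, p), c1)
  expect_gte(sum(c1), sum(cfld))  # total mass never decreases
  ones <- matrix(1, g$nx, g$ny)
  expect_identical(imprint_template(ones, tec, g, p), ones)
})

test_that("a TEC starved of TAF deactivates after ten consecutive steps", {
  g <- tec_grid
  st <- uniform_state(g, f = 0)
  tec <- tip_cell(1, c(320, 240), p)
  for (k in 1:9) tec <- update_tec(tec, st, g, 0.1, p)
  expect_true(tec$active)
  tec <- update_tec(tec, st, g, 0.1, p)
  expect_false(tec$active)
  expect_identical(tec$deactivation_reason, "starved")
})

test_that("smaller Dll4 distance admits more TECs on the same vessel", {
  # Exhaustive activation on a fixed capillary/TAF state: the lateral
  # inhibition radius directly limits how many tips fit.
  count_tecs <- function(delta4, seed) {
    pp <- model_parameters(delta4 = delta4)
    st <- strip_state()
    rng <- rng_stream(seed)
    tecs <- list()
    repeat {
      tec <- scan_activation(st, tecs, tec_grid, pp, rng,
                             id = length(tecs) + 1L)
      if (is.null(tec)) break
      tecs[[length(tecs) + 1L]] <- tec
      if (length(tecs) > 100) break
    }
    length(tecs)
  }
  n55 <- vapply(1:5, function(s) count_tecs(55, s), numeric(1))
  n80 <- vapply(1:5, function(s) count_tecs(80, s), numeric(1))
  expect_gte(mean(n55), mean(n80))
  expect_gt(mean(n55), 0)
})
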
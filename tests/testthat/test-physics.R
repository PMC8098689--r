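# Field physics: calibration, diffusion, evaporation, sampling.

test_that("evaporation calibration reproduces measured hourly losses", {
  for (r in c(0.1, 0.6, 0.75, 2.0)) {
    loss <- evaporationHourLoss(r, 40)
    expect_equal(loss, r, tolerance = 1e-3)  # round-trip within 0.1%
  }
  expect_identical(calibrateEvaporation(0, 40), 0)
  expect_equal(evaporationHourLoss(0, 40), 0)
  expect_error(calibrateEvaporation(0.75, 100), "uncalibratable")
  expect_error(calibrateEvaporation(0.75, 120), "uncalibratable")
})

test_that("a uniform-ambient field with dry substrate is a fixed point", {
  geo <- emptyGeometry(9, 9)
  ph <- physicsParams()
  f <- uniformField(9, 9, ph$ambient_rh)
  m <- dryMoisture(9, 9)
  for (cond in list(condition("still_wet"), condition("fan", "left"),
                    condition("dry"))) {
    st <- stepField(f, m, geo, ph, cond)
    expect_equal(st$field$values, f$values)
    expect_equal(st$moisture$mass, m$mass)
    expect_equal(st$ambient_loss, 0)
  }
})

test_that("diffusion of a pulse matches the explicit-scheme kernel oracle", {
  nx <- 25; ny <- 25; tsteps <- 10
  geo <- emptyGeometry(nx, ny)
  ph <- physicsParams(evap_rate = 0, lambda_open = 0, lambda_fan = 0)
  v0 <- matrix(0, nx, ny)
  v0[13, 13] <- 100
  f <- humidityField(v0, 1, 0.25)
  m <- dryMoisture(nx, ny)
  for (s in seq_len(tsteps)) f <- stepField(f, m, geo, ph)$field

  # independent oracle: repeated convolution with the 5-point kernel
  # (pulse support stays far from the boundary over tsteps steps)
  alpha <- ph$D * 0.25 / 1
  v <- v0
  for (s in seq_len(tsteps)) {
    w <- v * (1 - 4 * alpha)
    w[-1, ] <- w[-1, ] + alpha * v[-nx, ]
    w[-nx, ] <- w[-nx, ] + alpha * v[-1, ]
    w[, -1] <- w[, -1] + alpha * v[, -ny]
    w[, -ny] <- w[, -ny] + alpha * v[, -1]
    v <- w
  }
  expect_lt(sqrt(sum((f$values - v)^2)), 1e-6)
})

test_that("diffusion-only stepping conserves total humidity on a closed domain", {
  set.seed(7)
  geo <- defaultArena(nx = 15, ny = 21, wall_length = 8, wall_gap = 6,
                      block_size = 2)
  ph <- physicsParams(evap_rate = 0, lambda_open = 0, lambda_fan = 0)
  open <- geo$occupancy == OCC_EMPTY
  v0 <- matrix(runif(15 * 21, 40, 100), 15, 21)
  f <- humidityField(v0, 1, 0.25)
  m <- dryMoisture(15, 21)
  total0 <- sum(f$values[open])
  for (s in 1:200) f <- stepField(f, m, geo, ph)$field
  expect_equal(sum(f$values[open]), total0, tolerance = 1e-9)
})

test_that("water ledger closes: deposits = stored + airborne + lost to ambient", {
  set.seed(11)
  geo <- defaultArena(nx = 15, ny = 21, wall_length = 8, wall_gap = 6,
                      block_size = 2)
  nx <- 15; ny <- 21

  for (lam in c(0, 2e-3)) {
    ph <- physicsParams(lambda_open = lam, lambda_fan = max(lam, 0.05),
                        gamma = 3e4)
    f <- uniformField(nx, ny, ph$ambient_rh)
    m <- dryMoisture(nx, ny)
    rh_sum0 <- sum(f$values)
    added <- 0; ambient_loss <- 0
    open_cells <- which(geo$occupancy == OCC_EMPTY, arr.ind = TRUE)
    for (s in 1:500) {
      if (s %% 5 == 1) {
        cell <- open_cells[sample(nrow(open_cells), 1), ]
        amt <- runif(1, 0, 0.1)
        dw <- depositWater(m, cell, amt)
        m <- dw$moisture
        added <- added + amt - dw$runoff
      }
      st <- stepField(f, m, geo, ph)
      f <- st$field; m <- st$moisture
      ambient_loss <- ambient_loss + st$ambient_loss
    }
    held_air <- (sum(f$values) - rh_sum0) / ph$gamma
    expect_equal(added, sum(m$mass) + held_air + ambient_loss,
                 tolerance = 1e-6)
  }
})

test_that("the lid suppresses ambient exchange: covered wet cell stays moister air", {
  nx <- 21; ny <- 11
  occ <- matrix(OCC_EMPTY, nx, ny)
  # lid over columns 4-6 only (all y); identical wet cells at (5,5) and (15,5)
  geo <- arenaGeometry(occ, lid_extent_y = 11, lid_x_range = c(4L, 6L),
                       supply_cell = c(1L, 1L), block_size = 2L)
  ph <- physicsParams(lambda_open = 0.02, lambda_fan = 0.05)
  mass <- matrix(0, nx, ny); mass[5, 5] <- 1; mass[15, 5] <- 1
  m <- substrateMoisture(mass, 2)
  f <- uniformField(nx, ny, ph$ambient_rh)
  for (s in 1:400) {
    st <- stepField(f, m, geo, ph)
    f <- st$field; m <- st$moisture
  }
  covered_rh <- f$values[5, 5]
  uncovered_rh <- f$values[15, 5]
  expect_gt(covered_rh, ph$ambient_rh)
  expect_gt(uncovered_rh, ph$ambient_rh)
  # uncovered cell relaxes toward ambient strictly faster
  expect_lt(abs(uncovered_rh - ph$ambient_rh),
            abs(covered_rh - ph$ambient_rh))
})

test_that("exterior humidity is non-increasing in the fan exchange rate", {
  geo <- defaultArena(nx = 21, ny = 31, wall_length = 10, wall_gap = 10,
                      block_size = 2)
  wet <- humitect:::tunnelInteriorMask(geo)
  beyond <- col(geo$occupancy) > 10  # region beyond the tunnel mouth
  prev <- Inf
  for (lam_fan in c(0.001, 0.01, 0.1, 1)) {
    ph <- physicsParams(lambda_open = 0.001, lambda_fan = lam_fan)
    rh0 <- matrix(ph$ambient_rh, 21, 31); rh0[wet] <- 100
    f <- humidityField(rh0, 1, 0.25)
    m <- substrateMoisture(ifelse(wet, 2, 0), 2)
    for (s in 1:300) {
      st <- stepField(f, m, geo, ph, condition("fan", "left"))
      f <- st$field; m <- st$moisture
    }
    tot <- sum(f$values[beyond])
    expect_lte(tot, prev + 1e-9)
    prev <- tot
  }
})

test_that("step_field enforces dimension matching and stability", {
  geo <- emptyGeometry(5, 5)
  ph <- physicsParams()
  f_bad <- uniformField(4, 5)
  expect_error(stepField(f_bad, dryMoisture(5, 5), geo, ph), "dimensions")
  f_unstable <- uniformField(5, 5, dt = 5)  # alpha > 1/4 for D = 0.25
  expect_error(stepField(f_unstable, dryMoisture(5, 5), geo, ph), "stability")
  expect_error(humidityField(matrix(40, 3, 3), dt = 5, D = 0.25), "stability")
  expect_error(humidityField(matrix(c(40, 120, 40, 40), 2, 2)), "\\[0, 100\\]")
})

test_that("water deposition caps at capacity and reports runoff", {
  m <- dryMoisture(4, 4, capacity = 1)
  dw <- depositWater(m, c(2, 2), 0.1)
  expect_equal(dw$moisture$mass[2, 2], 0.1)
  expect_equal(dw$runoff, 0)
  dw2 <- depositWater(dw$moisture, c(2, 2), 2)
  expect_equal(dw2$moisture$mass[2, 2], 1)
  expect_equal(dw2$runoff, 1.1)
  dw3 <- depositWater(dw2$moisture, c(2, 2), 0.1)
  expect_equal(dw3$moisture$mass[2, 2], 1)
  expect_equal(dw3$runoff, 0.1)
  dw4 <- depositWater(m, c(3, 3), 0)
  expect_equal(dw4$moisture$mass, m$mass)
  expect_error(depositWater(m, c(9, 2), 0.1), "outside")
})

test_that("humidity sampling is bilinear in cell-centre values", {
  f <- uniformField(6, 6, 40)
  expect_equal(sampleHumidity(f, c(1.7, 4.2)), 40)
  v <- matrix(40, 6, 6)
  v[3, 3] <- 70; v[4, 3] <- 80
  v[3, 4] <- 70; v[4, 4] <- 80
  f2 <- humidityField(v, 1, 0.25)
  expect_equal(sampleHumidity(f2, c(2.5, 2.5)), 70)   # cell centre
  expect_equal(sampleHumidity(f2, c(3.0, 3.0)), 75)   # midpoint of 70/80
  expect_error(sampleHumidity(f2, c(-1, 3)), "outside")
  expect_error(sampleHumidity(f2, c(3, 6.5)), "outside")
})
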
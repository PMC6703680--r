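test_that("stand layout spacing follows density^(-1/2)", {
  expect_equal(stand_layout(100)$spacing, 0.1)
  expect_equal(stand_layout(6400)$spacing, 0.0125)
  expect_equal(stand_layout(711)$spacing, 711^(-0.5))
  expect_error(stand_layout(0))
  expect_error(stand_layout(100, rows = 4))
  pos <- grid_positions(stand_layout(400, 5, 5))
  expect_equal(nrow(pos), 25)
  f <- attr(pos, "focal")
  lay <- stand_layout(400, 5, 5)
  expect_equal(unname(pos[f, ]), c(lay$Lx / 2, lay$Ly / 2))
})

test_that("daily dose converts flux over the photoperiod", {
  expect_equal(daily_par_dose(220, 9), 7.128)
  expect_equal(daily_par_dose(0, 9), 0)
  expect_equal(daily_par_dose(220, 0), 0)
})

test_that("whole-plant R:FR sums before dividing", {
  expect_equal(mean_plant_rfr(c(1, 1), c(1, 1)), 1)
  expect_equal(mean_plant_rfr(c(2, 1), c(1, 2)), 1)
  expect_equal(mean_plant_rfr(2.3, 1), 2.3)
  expect_true(is.na(mean_plant_rfr(1, 0)))
})

test_that("LAI is non-senesced lamina area times density", {
  expect_equal(compute_lai(c(2e-3, 3e-3), c(FALSE, FALSE), 400), 2)
  expect_equal(compute_lai(c(1e-4), c(FALSE), 100), 0.01)
  expect_equal(compute_lai(c(2e-3, 3e-3), c(TRUE, TRUE), 400), 0)
})

test_that("an unshaded horizontal lamina sees the source spectrum", {
  layout <- stand_layout(100, 5, 5)
  pos <- grid_positions(layout)
  lv <- make_leaves(1, plant = attr(pos, "focal"), elevation_angle = 0,
                    lamina_area = 6e-4)
  g <- leaf_geometry(lv, pos)
  set.seed(1)
  L <- compute_light(g, layout, light_source(ray_count = 5000))
  expect_equal(L$lamina_rfr[1], 2.3, tolerance = 0.01)
  expect_equal(L$petiole_rfr[1], 2.3, tolerance = 0.01)
  expect_equal(L$lamina_par[1], 220, tolerance = 0.02)
})

test_that("energy is conserved per band and empty scenes absorb nothing", {
  layout <- stand_layout(400, 5, 5)
  pos <- grid_positions(layout)
  lv <- make_leaves(6, plant = rep(c(1L, 13L, 20L), 2),
                    azimuth = c(0, 60, 120, 180, 240, 300),
                    elevation_angle = c(0, 20, 40, 10, 30, 50),
                    lamina_area = 5e-4)
  g <- leaf_geometry(lv, pos)
  set.seed(2)
  L <- compute_light(g, layout, fast_source())
  closure <- with(L$audit, (absorbed + escaped) / emitted)
  expect_true(all(abs(closure - 1) < 0.01))
  expect_true(all(L$audit$absorbed > 0))
  # empty scene: no absorption, not a failure
  g0 <- leaf_geometry(make_leaves(1, lamina_area = 0, senesced = TRUE), pos)
  L0 <- compute_light(g0, layout, fast_source())
  expect_true(all(L0$audit$absorbed == 0))
})

test_that("perceived R:FR never exceeds the source ratio", {
  layout <- stand_layout(1600, 3, 3)
  pos <- grid_positions(layout)
  set.seed(3)
  n <- 12
  lv <- make_leaves(n, plant = sample(1:9, n, replace = TRUE),
                    azimuth = runif(n, 0, 360),
                    elevation_angle = runif(n, 0, 70),
                    petiole_length = runif(n, 0.005, 0.03),
                    lamina_area = runif(n, 1e-4, 8e-4))
  g <- leaf_geometry(lv, pos)
  L <- compute_light(g, layout, fast_source())
  expect_true(all(L$lamina_rfr <= 2.3 + 1e-6, na.rm = TRUE))
  expect_true(all(L$petiole_rfr <= 2.3 + 1e-6, na.rm = TRUE))
})

test_that("an opaque layer above a lamina dims it and lowers its R:FR", {
  layout <- stand_layout(400, 3, 3)
  pos <- grid_positions(layout)
  target <- make_leaves(1, plant = 5L, elevation_angle = 0,
                        lamina_area = 4e-4)
  # same target plus a large, gently inclined lamina held above it
  shaded <- rbind(target,
                  make_leaves(1, plant = 5L, rank = 2L,
                              elevation_angle = 30,
                              petiole_length = 0.04, lamina_area = 3e-3))
  par_open <- rfr_open <- par_shade <- rfr_shade <- numeric(10)
  for (i in 1:10) {
    set.seed(100 + i)
    Lo <- compute_light(leaf_geometry(target, pos), layout, fast_source())
    set.seed(100 + i)
    Ls <- compute_light(leaf_geometry(shaded, pos), layout, fast_source())
    par_open[i] <- Lo$lamina_par[1]; rfr_open[i] <- Lo$lamina_rfr[1]
    par_shade[i] <- Ls$lamina_par[1]; rfr_shade[i] <- Ls$lamina_rfr[1]
  }
  expect_lt(mean(par_shade), mean(par_open))
  expect_lt(mean(rfr_shade), mean(rfr_open))
})
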
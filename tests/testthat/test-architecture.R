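test_that("organ initiation follows the plastochron", {
  p <- default_params()  # plastochron 1.5 d, germination day 3
  plants <- data.frame(plant = 1L, base_azimuth = 0)
  empty <- make_leaves(1)[0, ]
  lv <- initiate_organs(empty, plants, 15, p)
  expect_equal(nrow(lv), 8)  # floor((15 - 3) / 1.5)
  expect_equal(lv$rank, 1:8)
  # nothing before germination
  expect_equal(nrow(initiate_organs(empty, plants, 2, p)), 0)
  # idempotent within a day
  lv2 <- initiate_organs(lv, plants, 15, p)
  expect_identical(lv, lv2)
  # existing leaves untouched when new ones appear
  lv$lamina_biomass <- 99
  lv3 <- initiate_organs(lv, plants, 18, p)
  expect_equal(nrow(lv3), 10)
  expect_equal(lv3$lamina_biomass[1:8], rep(99, 8))
})

test_that("phyllotaxis spirals at the divergence angle", {
  expect_equal(phyllotaxis_azimuth(1), 0)
  expect_equal(phyllotaxis_azimuth(2), 137.5)
  expect_equal(phyllotaxis_azimuth(9), 20)  # (8 * 137.5) mod 360
  expect_equal(phyllotaxis_azimuth(3, base = 10), (10 + 275) %% 360)
  expect_error(phyllotaxis_azimuth(0))
})

test_that("hyponasty triggers on touching or low R:FR and clamps", {
  p <- default_params()
  lv <- make_leaves(4, elevation_angle = c(20, 20, 20, 75))
  out <- update_leaf_angle(lv,
                           min_neighbour_distance = c(0.0015, 0.01, 0.01, 0.001),
                           lamina_rfr = c(1.2, 0.4, 1.0, 1.2), p)
  expect_equal(out$elevation_angle, c(36, 36, 20, 80))  # clamped at 80
  # senesced and post-growth leaves do not move
  lv2 <- make_leaves(2, senesced = c(TRUE, FALSE),
                     petiole_growing = c(TRUE, FALSE))
  out2 <- update_leaf_angle(lv2, c(0.001, 0.001), c(0.3, 0.3), p)
  expect_equal(out2$elevation_angle, c(20, 20))
  expect_error(update_leaf_angle(lv, rep(-1, 4), rep(1, 4), p))
})

test_that("senescence flags strictly after the threshold age and sticks", {
  p <- default_params()
  lv <- make_leaves(3, age = c(40, 41, 10))
  out <- senesce(lv, p)
  expect_equal(out$senesced, c(FALSE, TRUE, FALSE))
  expect_false(out$petiole_growing[2])
  expect_false(out$lamina_growing[2])
  # a 46-day run can only senesce leaves that emerged before day 6
  expect_true(46 - p$senescence_age < 6 + 1e-9)
})

test_that("leaf geometry places the lamina at the petiole tip", {
  pos <- one_plant_positions()
  lv <- make_leaves(1, petiole_length = 0.02, elevation_angle = 30)
  g <- leaf_geometry(lv, pos)
  expect_equal(g$attach_height, 0.02 * sin(30 * pi / 180))
  # doubling petiole length doubles the attachment height
  lv2 <- make_leaves(1, petiole_length = 0.04, elevation_angle = 30)
  expect_equal(leaf_geometry(lv2, pos)$attach_height, 2 * g$attach_height)
  # flat leaf attaches at height zero
  lv3 <- make_leaves(1, elevation_angle = 0)
  expect_equal(leaf_geometry(lv3, pos)$attach_height, 0)
  # zero-area lamina produces no patch
  lv4 <- make_leaves(1, lamina_area = 0)
  expect_equal(nrow(leaf_geometry(lv4, pos)$patches), 0)
  # patch area equals the lamina area
  a <- g$patches[1, "a"]; b <- g$patches[1, "b"]
  expect_equal(pi * a * b, lv$lamina_area[1])
  expect_equal(a / b, default_params()$lamina_aspect)
})
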
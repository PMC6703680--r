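test_that("beta growth mass hits its endpoints and midpoint value", {
  expect_equal(beta_growth_mass(0, 10, 20, 10), 0)
  expect_equal(beta_growth_mass(20, 10, 20, 10), 10)
  expect_equal(beta_growth_mass(25, 10, 20, 10), 10)  # flat after t_e
  # direct substitution at the inflection: 10 * (1 + 10/10) * 0.5^2
  expect_equal(beta_growth_mass(10, 10, 20, 10), 5)
  expect_error(beta_growth_mass(-1, 10, 20, 10))
  expect_error(beta_growth_mass(5, 10, 20, 25))  # t_m >= t_e
})

test_that("beta growth rate matches a numerical derivative and peaks at t_m", {
  w_max <- 12; t_e <- 18; t_m <- 7
  t <- seq(0.5, 17.5, by = 0.25)
  num <- (beta_growth_mass(t + 1e-5, w_max, t_e, t_m) -
            beta_growth_mass(t - 1e-5, w_max, t_e, t_m)) / 2e-5
  expect_equal(beta_growth_rate(t, w_max, t_e, t_m), num, tolerance = 1e-6)
  expect_equal(beta_growth_rate(0, w_max, t_e, t_m), 0)
  expect_equal(beta_growth_rate(t_e, w_max, t_e, t_m), 0)
  expect_equal(beta_growth_rate(t_e + 5, w_max, t_e, t_m), 0)
  # the rate is maximal at the inflection age (numeric scan)
  scan <- seq(0.01, t_e - 0.01, by = 0.01)
  expect_equal(scan[which.max(beta_growth_rate(scan, w_max, t_e, t_m))],
               t_m, tolerance = 0.02)
})

test_that("beta growth rate integrates to the final mass", {
  w_max <- 30; t_e <- 20; t_m <- 8
  q <- stats::integrate(beta_growth_rate, 0, t_e, w_max = w_max,
                        t_e = t_e, t_m = t_m, rel.tol = 1e-9)
  expect_equal(q$value, w_max, tolerance = 1e-3)  # within 0.1%
})

test_that("photosynthesis follows the negative-exponential light response", {
  p <- default_params()
  expect_equal(photosynthesis(0, 1e-3, p), 0)
  expect_equal(photosynthesis(100, 0, p), 0)
  # saturation at very high light
  sat <- p$p_max * 1e-3 * 9 * 3600 * p$carbon_conversion
  expect_equal(photosynthesis(1e7, 1e-3, p), sat, tolerance = 1e-6)
  # at I = p_max / phi the rate is p_max (1 - 1/e)
  a <- photosynthesis(p$p_max / p$phi, 1e-3, p)
  expect_equal(a, sat * (1 - exp(-1)))
})

test_that("allocation is proportional under shortage and exact overall", {
  expect_equal(allocate(6, c(4, 8)), c(2, 4))
  expect_equal(allocate(0, c(4, 8)), c(0, 0))
  # pool covers demand: demands met, surplus split root / laminas
  al <- allocate(20, c(4, 8, 2), is_lamina = c(TRUE, FALSE, FALSE),
                 root_index = 3, surplus_root_fraction = 0.5)
  expect_equal(al, c(4 + 3, 8, 2 + 3))
  expect_equal(sum(al), 20)
  # no demand at all: everything to the root
  expect_equal(allocate(5, c(0, 0, 0), root_index = 3), c(0, 0, 5))
  # scale equivariance
  a1 <- allocate(7, c(3, 9, 1), is_lamina = c(TRUE, TRUE, FALSE),
                 root_index = 3)
  a2 <- allocate(7 * 13, c(3, 9, 1) * 13, is_lamina = c(TRUE, TRUE, FALSE),
                 root_index = 3)
  expect_equal(a2, a1 * 13)
  expect_error(allocate(-1, c(1)))
})

test_that("petiole elongation multiplies length and queues its cost", {
  p <- default_params()
  lv <- make_leaves(3, petiole_length = 0.02,
                    petiole_growing = c(TRUE, TRUE, FALSE))
  out <- apply_petiole_plasticity(lv, c(1, 2, 2), p)
  expect_equal(out$petiole_length, c(0.02, 0.04, 0.02))
  expect_equal(out$petiole_extra_demand,
               c(0, 0.02 * p$petiole_density, 0))
})

test_that("dimension update converts mass to area and length linearly", {
  p <- default_params(sla = 3e-5, petiole_density = 100)
  lv <- make_leaves(1, lamina_area = 1e-4, petiole_length = 0.01)
  out <- dimension_update(lv, 1, 1, 1, p)
  expect_equal(out$lamina_area, 1e-4 + 3e-5)
  expect_equal(out$petiole_length, 0.01 + 0.01)
  expect_equal(out$lamina_biomass, lv$lamina_biomass + 1)
  expect_equal(out$petiole_biomass, lv$petiole_biomass + 1)
  out0 <- dimension_update(lv, 0, 0, 1, p)
  expect_equal(out0$lamina_area, lv$lamina_area)
})

test_that("compartment percentages partition whole-plant biomass", {
  expect_equal(percent_biomass_in("petiole", 2, 6, 2), 20)
  expect_equal(percent_biomass_in("petiole", 0, 0, 5), 0)
  shares <- c(percent_biomass_in("petiole", 2, 6, 2),
              percent_biomass_in("lamina", 2, 6, 2),
              percent_biomass_in("root", 2, 6, 2))
  expect_equal(sum(shares), 100)
  expect_true(is.na(percent_biomass_in("root", 0, 0, 0)))
})
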
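# Helpers: small performance matrices with known structure.
pm_from_means <- function(means, strategies, n = 2, cv = 0) {
  k <- length(strategies)
  reps <- array(rep(means, n), c(k, k, n))
  performance_matrix(reps, strategies)
}

test_that("invasion exponents are log mean ratios with a zero diagonal", {
  g <- c(0, 0.1)
  means <- matrix(c(1.0, 2.0,
                    0.5, 1.0), 2, 2, byrow = TRUE)  # rows mutant, cols resident
  im <- invasion_exponent(pm_from_means(means, g))
  expect_equal(im$exponent[1, 1], 0)
  expect_equal(im$exponent[2, 2], 0)
  # mutant mean 2 over resident mean 1: ln 2
  expect_equal(im$exponent[1, 2], log(2))
  # swapping the two means flips the sign
  expect_equal(im$exponent[2, 1], -log(2))
})

test_that("multiplying all performances by a constant leaves exponents unchanged", {
  set.seed(8)
  g <- seq(0, 0.7, by = 0.1)
  pm <- generate_matrix(landscape_spec(0.3, 1, 1, replicate_cv = 0.05,
                                       grid = g, replicates = 5))
  pm2 <- performance_matrix(pm$reps * 3.7, g)
  e1 <- invasion_exponent(pm)$exponent
  e2 <- invasion_exponent(pm2)$exponent
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("invasion CI follows the replicate formula and flags zero-inclusion", {
  # hand-computed: x = {0, 0.2}; mean 0.1, sd 0.14142; n - 1 = 1
  res_mean <- 100
  reps <- res_mean * exp(c(0, 0.2))
  ci <- invasion_ci(reps, res_mean)
  expect_equal(ci, c(0.1 - sd(c(0, 0.2)), 0.1 + sd(c(0, 0.2))))
  expect_true(ci[1] <= 0)  # inconclusive cell
  # all replicates equal to the resident mean: degenerate [0, 0]
  expect_equal(invasion_ci(c(100, 100, 100), 100), c(0, 0))
  expect_error(invasion_ci(100, 100))
})

test_that("the smoother reproduces structured surfaces and zeroes the diagonal", {
  g <- seq(0, 0.7, by = 0.1)
  # multiplicatively bilinear performance lies inside the basis span
  means <- outer(g, g, function(m, r) 500 * exp(0.5 * m - 0.3 * r))
  sm <- suppressWarnings(smooth_performance(pm_from_means(means, g)))
  probe <- expand.grid(m = seq(0.05, 0.65, by = 0.1),
                       r = seq(0.05, 0.65, by = 0.1))
  w_hat <- sm$surface(probe$m, probe$r)
  w_true <- 500 * exp(0.5 * probe$m - 0.3 * probe$r)
  expect_equal(w_hat, w_true, tolerance = 1e-3)
  expect_true(all(abs(sm$s(g, g)) < 1e-12))
  # constant matrix: flat surface, s identically zero
  smc <- suppressWarnings(smooth_performance(pm_from_means(
    matrix(42, 8, 8), g)))
  expect_true(all(abs(smc$s(probe$m, probe$r)) < 1e-8))
  expect_error(smooth_performance(pm_from_means(matrix(1, 2, 2), c(0, 1))))
})

test_that("singular strategies are found and classified analytically", {
  g <- seq(0, 0.7, by = 0.1)
  sp <- landscape_spec(0.35, k = 1, h = 1, replicate_cv = 0, grid = g,
                       replicates = 3)
  an <- suppressWarnings(analyse_pip(generate_matrix(sp)))
  expect_equal(length(an$singular), 1L)
  expect_equal(an$singular[[1]]$value, 0.35, tolerance = 0.01)
  expect_equal(an$singular[[1]]$classification, "cESS")
  # curvatures match the analytic -2h and -k
  expect_equal(an$singular[[1]]$ess_curvature, -2, tolerance = 0.05)
  expect_equal(an$singular[[1]]$convergence_slope, -1, tolerance = 0.05)
})

test_that("all four sign classes are recovered from noise-free landscapes", {
  g <- seq(0, 0.7, by = 0.1)
  cases <- list(c(1, 1, "cESS"), c(1, -1, "branching"),
                c(-1, 1, "ESS-not-convergent"), c(-1, -1, "repeller"))
  for (cs in cases) {
    sp <- landscape_spec(0.4, k = as.numeric(cs[1]), h = as.numeric(cs[2]),
                         replicate_cv = 0, grid = g, replicates = 3)
    an <- suppressWarnings(analyse_pip(generate_matrix(sp)))
    expect_equal(an$singular[[1]]$classification, cs[3])
  }
})

test_that("a gradient of constant sign yields a beyond-range verdict", {
  g <- seq(0, 0.7, by = 0.1)
  # singular strategy far above the grid: selection always upward
  sp <- landscape_spec(2.0, k = 1, h = 0.2, replicate_cv = 0, grid = g,
                       replicates = 3)
  an <- suppressWarnings(analyse_pip(generate_matrix(sp)))
  expect_equal(length(an$singular), 0L)
  expect_equal(an$verdict, "beyond-range-high")
  # degenerate flat landscape
  spf <- landscape_spec(0.3, k = 0, h = 0, replicate_cv = 0, grid = g,
                        replicates = 3)
  anf <- suppressWarnings(analyse_pip(generate_matrix(spf)))
  expect_equal(length(anf$singular), 0L)
})

test_that("classification refuses boundary roots and flags near-zero curvature", {
  g <- seq(0, 0.7, by = 0.1)
  sp <- landscape_spec(0.35, 1, 1, replicate_cv = 0, grid = g, replicates = 3)
  sm <- suppressWarnings(smooth_performance(generate_matrix(sp)))
  expect_error(classify_singular(sm, 0.7))
  # huge indeterminacy tolerance forces the indeterminate verdict
  cls <- classify_singular(sm, 0.35, tol = 10)
  expect_equal(cls$classification, "indeterminate")
})

test_that("pip export writes stable CSV artifacts", {
  g <- seq(0, 0.7, by = 0.1)
  set.seed(4)
  pm <- generate_matrix(landscape_spec(0.3, 1, 1, replicate_cv = 0.05,
                                       grid = g, replicates = 4))
  disc <- invasion_exponent(pm)
  sm <- suppressWarnings(smooth_performance(pm))
  dir <- withr::local_tempdir()
  paths <- pip_export(disc, sm, dir, prefix = "t")
  expect_true(all(file.exists(paths)))
  disc_csv <- read.csv(paths[1])
  expect_equal(nrow(disc_csv), 64)
  md5_1 <- unname(tools::md5sum(paths[1]))
  pip_export(disc, sm, dir, prefix = "t")
  expect_identical(md5_1, unname(tools::md5sum(paths[1])))
})
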
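test_that("noiseless generation equals the simulated truth exactly", {
  p <- base_params(a_T = 0)
  g <- synthesize_growth_data(p, sigma = 0, n_mice = 2, seed = 11,
                              horizon = 700)
  for (m in g$mice) expect_equal(m$value, g$truth$value)
  # observations stop at host death: no time exceeds the trajectory end
  tr <- simulate_model(p, dose_schedule(ef = p$ef), inoculum(), 700)
  expect_true(all(g$truth$t_hours <= max(tr$times)))
  expect_equal(g$truth$value,
               tumor_at(tr, g$truth$t_hours))
})

test_that("generation is reproducible from its seed", {
  p <- base_params(a_T = 0)
  g1 <- synthesize_growth_data(p, sigma = 0.2, n_mice = 3, seed = 42,
                               horizon = 700)
  g2 <- synthesize_growth_data(p, sigma = 0.2, n_mice = 3, seed = 42,
                               horizon = 700)
  expect_identical(lapply(g1$mice, `[[`, "value"),
                   lapply(g2$mice, `[[`, "value"))
  g3 <- synthesize_growth_data(p, sigma = 0.2, n_mice = 3, seed = 43,
                               horizon = 700)
  expect_false(identical(g1$mice[[1]]$value, g3$mice[[1]]$value))
  expect_error(synthesize_growth_data(p, sigma = 0.2, n_mice = 3,
                                      horizon = 700), "seed")
})

test_that("lognormal noise is median-unbiased on the log scale", {
  p <- base_params(a_T = 0)
  sigma <- 0.1
  g <- synthesize_growth_data(p, sigma = sigma, n_mice = 200, seed = 5,
                              horizon = 700)
  vals <- sapply(g$mice, `[[`, "value")       # times x mice
  med <- apply(vals, 1, stats::median)
  tol <- 2 * sigma / sqrt(200)                # ~2 SE of a median, log scale
  expect_true(all(abs(log(med) - log(g$truth$value)) < 3 * tol))
})

test_that("diameter conversion of datasets round-trips", {
  p <- base_params(a_T = 0)
  g <- synthesize_growth_data(p, sigma = 0, n_mice = 1, seed = 1,
                              horizon = 700)
  d_um <- to_diameters(g$truth)
  expect_identical(attr(d_um, "unit"), "diameter_um")
  back <- to_cells(d_um)
  expect_equal(back$value, g$truth$value, tolerance = 1e-9)
  # terminal burden of 1.6e10 cells is a ~4.4 cm tumor
  expect_equal(cells_to_diameter(1.6e10) / 1e4, 4.38, tolerance = 0.005)
})

test_that("synthetic cohorts write and read back with their manifest", {
  p <- base_params(a_T = 0)
  g <- synthesize_growth_data(p, sigma = 0.1, n_mice = 2, seed = 9,
                              horizon = 700)
  dir <- withr::local_tempdir()
  write_synthetic(g, dir)
  back <- read_growth_dataset(file.path(dir, "mouse-01.csv"))
  expect_equal(back$value, g$mice[[1]]$value)
  expect_identical(attr(back, "unit"), "cells")
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(man$seed, 9L)
  expect_identical(man$n_mice, 2L)
})
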
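test_that("diameter/cell conversion is exactly cubic and round-trips", {
  expect_equal(diameter_to_cells(17.4), 1)
  expect_equal(diameter_to_cells(34.8), 8)
  expect_equal(diameter_to_cells(43000), (43000 / 17.4)^3)  # ~1.51e10
  expect_equal(cells_to_diameter(1), 17.4)
  expect_equal(cells_to_diameter(8), 34.8)
  d <- c(10, 100, 5000, 43000)
  expect_equal(diameter_to_cells(2 * d), 8 * diameter_to_cells(d))
  expect_equal(cells_to_diameter(diameter_to_cells(d)), d, tolerance = 1e-9)
  expect_error(diameter_to_cells(-1), "diameter")
})

test_that("NRMSE matches hand arithmetic and is scale-free", {
  obs <- growth_dataset(c(0, 1), c(0, 100))
  expect_equal(nrmse(obs, c(10, 110)), 10)
  expect_equal(nrmse(obs, c(0, 80)), 100 * (20 / sqrt(2)) / 100)
  expect_equal(nrmse(obs, c(0, 100)), 0)
  # common rescaling of both series leaves range-normalized NRMSE unchanged
  obs2 <- growth_dataset(c(0, 1), 1e6 * c(0, 100))
  expect_equal(nrmse(obs2, 1e6 * c(10, 110)), nrmse(obs, c(10, 110)))
  expect_error(nrmse(growth_dataset(c(0, 1), c(5, 5)), c(5, 5)), "distinct")
})

test_that("Gompertz fit recovers noiseless generating parameters", {
  tm <- measurement_times(700)
  truth <- c(r = 0.00106, K = 6.754e15)
  d <- growth_dataset(tm, gompertz_curve(tm, truth["r"], truth["K"], 6e4))
  f <- fit_gompertz(d, T0 = 6e4)
  expect_lt(abs(f$par["r"] - truth["r"]) / truth["r"], 0.01)
  expect_lt(abs(f$par["K"] - truth["K"]) / truth["K"], 0.01)
  # optimality spot-check: no hand-picked pair beats the fit
  sse_log <- function(r, K) sum((log(gompertz_curve(tm, r, K, 6e4)) -
                                   log(d$value))^2)
  for (cand in list(c(0.001, 6e15), c(0.0011, 7e15), c(0.002, 1e14)))
    expect_lte(f$objective, sse_log(cand[1], cand[2]) + 1e-12)
})

test_that("Gompertz fit rejects degenerate inputs", {
  expect_error(fit_gompertz(growth_dataset(0, 6e4), T0 = 6e4),
               "under-determined")
  d <- growth_dataset(c(0, 100), c(6e4, 1e6))
  expect_error(fit_gompertz(d, T0 = 6e4, K_bounds = c(1e4, 1e5)),
               "K bound")
})

test_that("therapy-parameter grid search equals brute force and recovers truth", {
  p <- base_params()
  sp <- protocol_spec(3, 1e6, 168)
  synth <- synthesize_growth_data(p, protocol = sp, sigma = 0, n_mice = 1,
                                  seed = 1, horizon = 700)
  d <- synth$truth
  grids <- list(a_T = c(2e-8, p$a_T), r_a = c(0.02, p$r_a),
                r_e = c(p$r_e, 0.05), tau = c(p$tau, 144))
  f <- fit_therapy_params(d, p, sp, grids$a_T, grids$r_a, grids$r_e,
                          grids$tau, horizon = 700)
  expect_equal(unname(f$par), c(p$a_T, p$r_a, p$r_e, p$tau))
  expect_equal(f$objective, 0, tolerance = 1e-8)
  # independent re-evaluation of every scored combination
  recompute <- apply(f$grid, 1, function(row) {
    q <- p
    q$a_T <- row["a_T"]; q$r_a <- row["r_a"]
    q$r_e <- row["r_e"]; q$tau <- row["tau"]
    tr <- simulate_model(validate_model_parameters(unclass(q)),
                         protocol_schedule(sp), inoculum(), 700)
    nrmse(d, tr)
  })
  expect_equal(unname(f$grid$nrmse), unname(recompute))
  expect_equal(f$objective, min(recompute))
})

test_that("single-combination therapy grids pass through", {
  p <- base_params()
  sp <- protocol_spec(3, 1e6, 168)
  d <- synthesize_growth_data(p, protocol = sp, sigma = 0, n_mice = 1,
                              seed = 1, horizon = 700)$truth
  f <- fit_therapy_params(d, p, sp, 3e-8, 0.04, 0.02, 120, horizon = 700)
  expect_equal(unname(f$par), c(3e-8, 0.04, 0.02, 120))
  expect_error(fit_therapy_params(d, p, sp, numeric(0), 0.04, 0.02, 120),
               "non-empty")
})
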
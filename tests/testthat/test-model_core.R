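test_that("suppression factor hits its algebraic anchors and bounds", {
  expect_equal(suppression_factor(0, 0.69, 1e4), 1)
  # at F_beta = e_supp the factor sits at the midpoint of [supp_floor, 1]
  expect_equal(suppression_factor(1e4, 0.69, 1e4), (1 + 0.69) / 2)
  expect_equal(suppression_factor(1e300, 0.3, 50), 0.3, tolerance = 1e-12)
  # bounded and monotone non-increasing over a wide sweep
  for (floor_v in c(0.1, 0.69, 1)) {
    f <- suppression_factor(10^seq(-3, 12, length.out = 200), floor_v, 1e4)
    expect_true(all(f >= floor_v - 1e-12 & f <= 1 + 1e-12))
    expect_true(all(diff(f) <= 1e-15))
  }
  expect_error(suppression_factor(-1, 0.69, 1e4), "F_beta")
  expect_error(suppression_factor(1, 0.69, 0), "e_supp")
})

test_that("dendritic forcing matches the piecewise closed form", {
  sched <- weekly_schedule()
  mu_D <- 0.0096
  expect_identical(dendritic_forcing(100, sched, mu_D), 0)
  expect_identical(dendritic_forcing(-50, sched, mu_D), 0)
  expect_equal(dendritic_forcing(168, sched, mu_D), 5e5)
  expect_equal(dendritic_forcing(336, sched, mu_D),
               0.5 * 1e6 * (exp(-mu_D * 168) + 1))
  # between doses: pure exponential decay D(t + h) = D(t) e^(-mu_D h)
  for (t0 in c(170, 300, 400, 510, 900)) {
    h <- 20
    expect_equal(dendritic_forcing(t0 + h, sched, mu_D),
                 dendritic_forcing(t0, sched, mu_D) * exp(-mu_D * h))
  }
  # zero arrival fraction silences the forcing entirely
  expect_identical(
    dendritic_forcing(500, dose_schedule(c(168, 336), 1e6, ef = 0), mu_D), 0)
})

test_that("dose schedules reject malformed inputs", {
  expect_error(dose_schedule(c(336, 168), 1e6), "increasing")
  expect_error(dose_schedule(c(-10, 168), 1e6), ">= 0")
  expect_error(dose_schedule(168, 0), "n_DC")
  expect_error(dose_schedule(168, 1e6, ef = 1.5), "ef")
})

test_that("model derivatives honor their structural anchors", {
  p <- base_params()
  # at carrying capacity with no killers the tumor is stationary
  d <- model_derivatives(c(p$K, 0, 0, 0), c(p$K, 0, 0, 0), 0, p)
  expect_equal(unname(d["T"]), 0)
  # TGF-beta steady state under frozen tumor burden
  Tfix <- 1e8
  d <- model_derivatives(c(Tfix, 0, 1e5, p$p_beta * Tfix / p$mu_beta),
                         c(Tfix, 0, 1e5, p$p_beta * Tfix / p$mu_beta), 0, p)
  expect_equal(unname(d["F_beta"]), 0)
  # without DC forcing the naive pool purely decays
  d <- model_derivatives(c(1e6, 0, 2e5, 0), c(1e6, 0, 2e5, 0), 0, p)
  expect_equal(unname(d["C_i"]), -p$mu_Ci * 2e5)
  expect_equal(unname(d["C_a"]), 0)
  # the naive pool can only shrink, whatever the (non-negative) state
  set.seed(7)
  for (i in 1:50) {
    s <- c(runif(1, 0, 1e9), runif(1, 0, 1e7), runif(1, 0, 1e6),
           runif(1, 0, 1e5))
    d <- model_derivatives(s, s, runif(1, 0, 1e7), p)
    expect_lte(unname(d["C_i"]), 0)
  }
  expect_error(model_derivatives(c(p$K * 2, 0, 0, 0), c(0, 0, 0, 0), 0, p),
               "carrying capacity")
})

test_that("parameter validation names offending fields and bounds", {
  expect_error(base_params(ef = 1.5), "ef")
  expect_error(base_params(supp_floor = 0), "supp_floor")
  expect_error(base_params(mu_beta = -1), "mu_beta")
  expect_error(base_params(K = 1e9), "T_death")
  p <- unclass(base_params()); p$mu_beta <- NULL
  expect_error(validate_model_parameters(p), "mu_beta")
  p <- unclass(base_params()); p$extra <- 1
  expect_error(validate_model_parameters(p), "extra")
})

test_that("TGF-beta knockout silences the suppression pathway", {
  p <- tgfb_knockout(base_params())
  expect_identical(p$p_beta, 0)
  tr <- simulate_model(p, weekly_schedule(), inoculum(), 700)
  expect_true(all(tr$states[, "F_beta"] == 0))
  expect_equal(suppression_factor(max(tr$states[, "F_beta"]),
                                  p$supp_floor, p$e_supp), 1)
})
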
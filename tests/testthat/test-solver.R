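test_that("dose-free growth matches the Gompertz closed form", {
  # holds for any (r, K, T0) with T0 < K, not just the study values
  # growth rates span the biologically plausible murine range; the RK4
  # discretization error at dt = 1 h scales like r^5, so much faster
  # hypothetical tumors would need a finer step for this tolerance
  cases <- list(c(0.00106, 6.754e15, 6e4),
                c(0.002, 1e12, 1e3),
                c(0.0008, 1e9, 5e5))
  for (cs in cases) {
    p <- base_params(r = cs[1], K = cs[2], a_T = 0,
                     T_death = cs[2] * 0.99)
    tr <- simulate_model(p, dose_schedule(), c(cs[3], 0, 1e5, 0), 700)
    expect_equal(max(tr$times), 700)
    cf <- gompertz_curve(tr$times, cs[1], cs[2], cs[3])
    expect_lt(max(abs(tr$states[, "T"] - cf) / cf), 1e-6)
  }
})

test_that("immune states follow their exact linear solutions when inert", {
  p <- base_params(a_T = 0, T_death = 1e15)
  tr <- simulate_model(p, dose_schedule(), c(6e4, 0, 2e5, 0), 500)
  expect_true(all(tr$states[, "C_a"] == 0))
  expect_lt(max(abs(tr$states[, "C_i"] - 2e5 * exp(-p$mu_Ci * tr$times)) /
                  (2e5 * exp(-p$mu_Ci * tr$times))), 1e-6)
})

test_that("stop events are recorded at the right grid times", {
  p <- base_params()
  tr <- simulate_model(p, dose_schedule(), c(p$T_death, 0, 0, 0), 100)
  expect_identical(nrow(tr$states), 1L)
  expect_identical(tr$death_time, 0)
  # untreated control dies before the four-week horizon under study growth
  tr <- simulate_model(p, dose_schedule(), inoculum(), 1000)
  expect_false(is.na(tr$death_time))
  expect_identical(tr$death_time, max(tr$times))
  expect_gte(tr$states[nrow(tr$states), "T"], p$T_death)
  expect_true(all(tr$states[-nrow(tr$states), "T"] < p$T_death))
  # a large dose eradicates: T clamps to 0 and stays there
  sp <- protocol_spec(3, 1e8, 168)
  tr <- simulate_model(p, protocol_schedule(sp), inoculum(), 1000)
  expect_false(is.na(tr$eradication_time))
  i_erad <- which(tr$times == tr$eradication_time)
  expect_true(all(tr$states[i_erad:nrow(tr$states), "T"] == 0))
  expect_true(all(tr$states[seq_len(i_erad - 1L), "T"] > 0))
})

test_that("trajectories are non-negative, C_i monotone, and deterministic", {
  p <- base_params()
  tr1 <- simulate_model(p, weekly_schedule(), inoculum(), 1000)
  tr2 <- simulate_model(p, weekly_schedule(), inoculum(), 1000)
  expect_identical(tr1$states, tr2$states)
  expect_true(all(tr1$states >= 0))
  expect_true(all(diff(tr1$states[, "C_i"]) <= 1e-9))
})

test_that("RK4 shows fourth-order convergence on the smooth problem", {
  p <- base_params(a_T = 0, T_death = 1e15)
  err <- sapply(c(2, 1, 0.5), function(dt) {
    tr <- simulate_model(p, dose_schedule(), inoculum(), 96, dt = dt)
    cf <- gompertz_curve(96, p$r, p$K, 6e4)
    abs(tr$states[nrow(tr$states), "T"] - cf) / cf
  })
  # error ratio per halving should approach 2^4 = 16
  expect_gt(err[1] / err[2], 8)
  expect_gt(err[2] / err[3], 8)
})

test_that("solver rejects inconsistent configuration", {
  p <- base_params(tau = 0.5)
  expect_error(simulate_model(p, dose_schedule(), inoculum(), 100, dt = 1),
               "tau")
  expect_error(simulate_model(base_params(tau = 0), dose_schedule(),
                              inoculum(), 100), "ode_limit|ODE|tau")
  expect_error(simulate_model(base_params(), dose_schedule(168.5, 1e6),
                              inoculum(), 100), "grid")
  expect_error(simulate_model(base_params(), dose_schedule(), c(-1, 0, 0, 0),
                              100), "non-negative")
  expect_error(simulate_ode_limit(base_params(), dose_schedule(),
                                  inoculum(), 100), "tau = 0")
})

test_that("trajectory CSV and event sidecar round-trip", {
  p <- base_params()
  tr <- simulate_model(p, weekly_schedule(), inoculum(), 400)
  path <- file.path(withr::local_tempdir(), "traj.csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_named(back, c("t_hours", "T", "C_a", "C_i", "F_beta", "D"))
  expect_equal(back$T, unname(tr$states[, "T"]))
  ev <- jsonlite::read_json(paste0(path, ".events.json"))
  expect_identical(ev$clamp_count, tr$clamp_count)
})
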
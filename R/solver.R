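#' Integrate the tumor--immune delay model
#'
#' Fixed-step classic 4th-order Runge--Kutta integration of the four
#' integrated states (tumor `T`, activated CTLs `C_a`, naive CTLs `C_i`,
#' TGF-beta `F_beta`) driven by the closed-form DC forcing. Delayed states
#' `C_a(t - tau)`, `C_i(t - tau)` are read from the stored solution history
#' by linear interpolation between grid points, with a constant pre-history
#' equal to the initial condition for all lookup times before 0 (the mouse
#' has no immune response before therapy). The delayed forcing `D(t - tau)`
#' is evaluated exactly from its closed form. Within each step, forcing
#' evaluations only include doses given at or before the step's left
#' endpoint, so every step integrates a smooth piece of the dynamics;
#' requiring dose times to sit on the grid makes this exact.
#'
#' Integration halts at the first grid point where `T >= T_death`
#' (`death_time` recorded). Once `T` falls to or below `T_erad` it is
#' clamped to 0 and `eradication_time` recorded; integration continues for
#' the immune states. Any component driven slightly negative by a step is
#' clamped to 0 and counted (`clamp_count`; large counts indicate the step
#' size is too coarse).
#'
#' @param params A [model_parameters()] object. `tau` must be >= `dt`; use
#'   [simulate_ode_limit()] for the delay-free model.
#' @param schedule A [dose_schedule()]; dose times must be multiples of
#'   `dt`.
#' @param initial Named or positional numeric vector
#'   `c(T, C_a, C_i, F_beta)`, all >= 0.
#' @param t_end Final time, hours; a positive multiple of `dt`.
#' @param dt Integration step, hours (default 1).
#' @return A `trajectory` object: uniform `times`, a 4-column `states`
#'   matrix, the forcing `D` at each grid time, `death_time` /
#'   `eradication_time` (NA when the event did not occur), and
#'   `clamp_count`.
#' @examples
#' p <- model_parameters(
#'   r = 0.00106, K = 6.754e15, a_T = 0, supp_floor = 0.69, e_supp = 1e4,
#'   mu_D = 0.0096, r_a = 0.05, r_e = 0.01, tau = 96, theta_D = 2.5e5,
#'   theta_a = 2.5e6, mu_Ca = 0.007, mu_Ci = 0.0012, p_beta = 5.75e-6,
#'   mu_beta = 0.14, ef = 0.5, T_death = 1.6e10, T_erad = 1
#' )
#' tr <- simulate_model(p, dose_schedule(), c(6e4, 0, 1e5, 0), t_end = 240)
#' tail(as.data.frame(tr))
#' @export
simulate_model <- function(params, schedule, initial, t_end, dt = 1) {
  stopifnot(inherits(params, "model_parameters"))
  if (params$tau == 0)
    stop("tau = 0: use simulate_ode_limit() for the delay-free model")
  if (params$tau < dt)
    stop("tau (", params$tau, " h) must be >= the integration step dt (",
         dt, " h)")
  integrate_rk4(params, schedule, initial, t_end, dt, ode_limit = FALSE)
}

#' Integrate the delay-free (tau = 0) limit of the model
#'
#' Same contract as [simulate_model()] but with every delayed lookup taken
#' at the current time, turning the system into an ordinary ODE. Used for
#' validation against adaptive ODE solvers.
#'
#' @inheritParams simulate_model
#' @return A `trajectory` object.
#' @export
simulate_ode_limit <- function(params, schedule, initial, t_end, dt = 1) {
  stopifnot(inherits(params, "model_parameters"))
  if (params$tau != 0)
    stop("simulate_ode_limit() requires tau = 0 (got tau = ", params$tau, ")")
  integrate_rk4(params, schedule, initial, t_end, dt, ode_limit = TRUE)
}

integrate_rk4 <- function(params, schedule, initial, t_end, dt,
                          ode_limit) {
  stopifnot(inherits(schedule, "dose_schedule"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) stop("dt must be > 0")
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("t_end must be > 0")
  n_steps <- round(t_end / dt)
  if (abs(n_steps * dt - t_end) > 1e-9 * max(1, t_end))
    stop("t_end must be a multiple of dt")
  if (length(schedule$times) > 0L) {
    off <- abs(schedule$times / dt - round(schedule$times / dt))
    if (any(off > 1e-9))
      stop("dose times must lie on the integration grid (multiples of dt)")
  }
  initial <- as.numeric(initial)
  if (length(initial) != 4L || any(!is.finite(initial)) || any(initial < 0))
    stop("initial state must be 4 non-negative finite numbers")

  tau <- if (ode_limit) 0 else params$tau
  times <- seq(0, t_end, by = dt)
  n <- n_steps + 1L
  states <- matrix(NA_real_, nrow = n, ncol = 4L,
                   dimnames = list(NULL, c("T", "C_a", "C_i", "F_beta")))
  states[1L, ] <- initial
  clamp_count <- 0L
  death_time <- NA_real_
  erad_time <- NA_real_

  d_times <- schedule$times
  d_n <- schedule$n_DC
  d_ef <- schedule$ef
  forcing <- function(s, cutoff) {
    if (length(d_times) == 0L || d_ef == 0) return(0)
    keep <- d_times <= cutoff & d_times <= s
    if (!any(keep)) return(0)
    d_ef * sum(d_n[keep] * exp(-params$mu_D * (s - d_times[keep])))
  }
  # history lookup with constant pre-history and linear interpolation
  lookup <- function(s, filled) {
    if (s <= 0) return(initial)
    j <- s / dt
    j0 <- floor(j + 1e-9)
    frac <- j - j0
    if (frac < 1e-9) return(states[j0 + 1L, ])
    a <- states[j0 + 1L, ]
    b <- states[j0 + 2L, ]
    a + frac * (b - a)
  }

  if (initial[1L] >= params$T_death) {
    states <- states[1L, , drop = FALSE]
    return(new_trajectory(times[1L], states, forcing_grid(schedule, params,
                          times[1L]), 0, NA_real_, 0L, dt, params, schedule))
  }
  if (initial[1L] <= params$T_erad && initial[1L] > 0) {
    states[1L, 1L] <- 0
    erad_time <- 0
  } else if (initial[1L] == 0) {
    erad_time <- 0
  }

  last <- n
  for (i in seq_len(n_steps)) {
    t0 <- times[i]
    y0 <- states[i, ]
    step_rhs <- function(s, y) {
      del <- if (ode_limit) y else lookup(s - tau, i)
      Dd <- forcing(s - tau, cutoff = t0 - tau)
      model_rhs(y, del, Dd, params)
    }
    k1 <- step_rhs(t0, y0)
    k2 <- step_rhs(t0 + dt / 2, pmax(y0 + dt / 2 * k1, 0))
    k3 <- step_rhs(t0 + dt / 2, pmax(y0 + dt / 2 * k2, 0))
    k4 <- step_rhs(t0 + dt, pmax(y0 + dt * k3, 0))
    y1 <- y0 + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y1)))
      stop("non-finite state at t = ", t0 + dt, " h (component ",
           paste(which(!is.finite(y1)), collapse = ","), ")")
    neg <- y1 < 0
    if (any(neg)) {
      clamp_count <- clamp_count + sum(neg)
      y1[neg] <- 0
    }
    if (is.na(erad_time) && y1[1L] <= params$T_erad) {
      y1[1L] <- 0
      erad_time <- t0 + dt
    } else if (!is.na(erad_time)) {
      y1[1L] <- 0
    }
    states[i + 1L, ] <- y1
    if (y1[1L] >= params$T_death) {
      death_time <- t0 + dt
      last <- i + 1L
      break
    }
  }
  times <- times[seq_len(last)]
  states <- states[seq_len(last), , drop = FALSE]
  new_trajectory(times, states, forcing_grid(schedule, params, times),
                 death_time, erad_time, clamp_count, dt, params, schedule)
}

forcing_grid <- function(schedule, params, times) {
  dendritic_forcing(times, schedule, params$mu_D)
}

new_trajectory <- function(times, states, D, death_time, erad_time,
                           clamp_count, dt, params, schedule) {
  structure(list(times = times, states = states, D = D,
                 death_time = death_time, eradication_time = erad_time,
                 clamp_count = clamp_count, dt = dt,
                 params = params, schedule = schedule),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Tumor-immune model trajectory: ", length(x$times), " points, dt = ",
      x$dt, " h, t in [0, ", max(x$times), "] h\n", sep = "")
  cat("  final T = ", format(x$states[nrow(x$states), "T"], digits = 5),
      " cells\n", sep = "")
  if (!is.na(x$death_time))
    cat("  host death at t = ", x$death_time, " h\n", sep = "")
  if (!is.na(x$eradication_time))
    cat("  tumor eradicated at t = ", x$eradication_time, " h\n", sep = "")
  if (x$clamp_count > 0)
    cat("  negativity clamps: ", x$clamp_count, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(t_hours = x$times,
             T = x$states[, "T"], C_a = x$states[, "C_a"],
             C_i = x$states[, "C_i"], F_beta = x$states[, "F_beta"],
             D = x$D)
}

#' Write a trajectory to CSV with a JSON event sidecar
#'
#' The CSV holds columns `t_hours, T, C_a, C_i, F_beta, D`; the sidecar
#' (`<path>.events.json`) records `death_time`, `eradication_time` and
#' `clamp_count`.
#'
#' @param x A `trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "trajectory"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  ev <- list(death_time = if (is.na(x$death_time)) NULL else x$death_time,
             eradication_time =
               if (is.na(x$eradication_time)) NULL else x$eradication_time,
             clamp_count = x$clamp_count)
  jsonlite::write_json(ev, paste0(path, ".events.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Tumor burden at requested times, with event conventions
#'
#' Reads `T` off a trajectory at exact grid times. After host death the
#' tumor is held at `T_death` (the metric window is fixed; the animal is
#' not censored); after eradication `T` is 0. Times must lie on the
#' trajectory grid.
#'
#' @param x A `trajectory`.
#' @param times Times in hours.
#' @return Numeric vector of tumor cell counts.
#' @export
tumor_at <- function(x, times) {
  stopifnot(inherits(x, "trajectory"))
  idx <- match(round(times / x$dt), round(x$times / x$dt))
  out <- numeric(length(times))
  inside <- !is.na(idx)
  out[inside] <- x$states[idx[inside], "T"]
  if (any(!inside)) {
    beyond <- times > max(x$times)
    if (!is.na(x$death_time)) {
      out[!inside & beyond] <- x$params$T_death
    } else if (any(!inside)) {
      stop("requested time(s) not on the trajectory grid: ",
           paste(utils::head(times[!inside], 3), collapse = ", "))
    }
  }
  out
}
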
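#' Specify an infusion protocol
#'
#' A regular DC infusion protocol: `n_doses` doses of `dose_size` cells,
#' `interval` hours apart, starting at `first_dose_time` (default one week
#' after tumor inoculation, matching the validated clinical schedule), with
#' arrival fraction `ef`.
#'
#' @param n_doses Number of doses (>= 0; 0 means no treatment).
#' @param dose_size DCs per dose.
#' @param interval Hours between doses (> 0 when `n_doses` > 1).
#' @param first_dose_time Time of the first dose, hours (>= 0).
#' @param ef Arrival fraction in \[0, 1\]; overrides the parameter set's
#'   value for this protocol.
#' @param label Protocol label used in outputs.
#' @return A `protocol_spec` object.
#' @examples
#' # the validated murine protocol: 3 weekly doses of 1e6 DCs, 50% arrival
#' protocol_spec(3, 1e6, 168, label = "Protocol 1")
#' @export
protocol_spec <- function(n_doses, dose_size, interval = 168,
                          first_dose_time = 168, ef = 0.5,
                          label = NULL) {
  n_doses <- as.integer(n_doses)
  interval <- as.numeric(interval)
  dose_size <- as.numeric(dose_size)
  first_dose_time <- as.numeric(first_dose_time)
  ef <- as.numeric(ef)
  if (n_doses < 0) stop("n_doses must be >= 0")
  if (n_doses > 1 && (!is.numeric(interval) || interval <= 0))
    stop("interval must be > 0 when n_doses > 1")
  if (first_dose_time < 0) stop("first_dose_time must be >= 0")
  if (n_doses > 0 && dose_size <= 0) stop("dose_size must be > 0")
  if (ef < 0 || ef > 1) stop("ef must be in [0, 1]")
  if (is.null(label))
    label <- sprintf("%dx%.0e @ %gh, ef=%g", n_doses, dose_size, interval, ef)
  structure(list(n_doses = n_doses, dose_size = dose_size,
                 interval = interval, first_dose_time = first_dose_time,
                 ef = ef, label = label),
            class = "protocol_spec")
}

#' @rdname protocol_spec
#' @param spec A `protocol_spec`.
#' @return `protocol_schedule()`: the corresponding [dose_schedule()].
#' @export
protocol_schedule <- function(spec) {
  stopifnot(inherits(spec, "protocol_spec"))
  if (spec$n_doses == 0L) return(dose_schedule(ef = spec$ef))
  t <- spec$first_dose_time + (seq_len(spec$n_doses) - 1L) * spec$interval
  dose_schedule(times = t, n_DC = spec$dose_size, ef = spec$ef)
}

#' Tumor measurement schedule of the mouse study
#'
#' Tumor size is read on day 7 after inoculation and then every two days
#' from day 10, up to the simulation horizon: hours
#' `{168, 240, 288, 336, ...}`.
#'
#' @param horizon Simulation horizon in hours; must exceed 168 h.
#' @return Vector of measurement times, hours.
#' @examples
#' measurement_times(700)   # days 7, 10, 12, ..., 28
#' @export
measurement_times <- function(horizon) {
  if (!is.numeric(horizon) || horizon <= 168)
    stop("horizon must exceed 168 h (day 7, the first measurement)")
  c(168, seq(240, horizon, by = 48))
}

#' Mean percent decrease in tumor burden under treatment
#'
#' The efficacy metric: at each measurement time the percentage reduction
#' of the treated tumor relative to the untreated control,
#' `100 (T_control - T_treated) / T_control`, averaged over the
#' measurement times. A mouse that dies before a measurement time
#' contributes its terminal burden `T_death` thereafter; an eradicated
#' tumor contributes 0.
#'
#' @param control,treated `trajectory` objects simulated from identical
#'   initial conditions.
#' @param times Measurement times (hours) on both trajectories' grids.
#' @return Percent decrease (<= 100); negative if treatment worsens growth.
#' @export
percent_decrease <- function(control, treated, times) {
  Tc <- tumor_at(control, times)
  Tt <- tumor_at(treated, times)
  if (any(Tc <= 0))
    stop("control tumor is 0 at a measurement time; percent decrease undefined")
  mean(100 * (Tc - Tt) / Tc)
}

#' Simulate one infusion protocol against its untreated control
#'
#' Builds the dose schedule from `spec`, simulates treated and dose-free
#' control runs from identical initial conditions, and summarises efficacy:
#' the mean percent decrease over the study's measurement times, whether
#' the tumor was eradicated (reached the single-cell threshold) within the
#' horizon, and the host death time if the burden reached `T_death`.
#'
#' @param params A [model_parameters()] object.
#' @param spec A [protocol_spec()].
#' @param initial Initial state `c(T, C_a, C_i, F_beta)`; default tumor
#'   inoculum 6e4 cells, no activated CTLs, naive pool `C_i0`, no cytokine.
#' @param C_i0 Baseline naive CTL pool used when `initial` is NULL.
#' @param horizon Simulation horizon, hours (default 1000).
#' @param dt Integration step, hours.
#' @param control Optional pre-computed control `trajectory` (reused across
#'   a sweep); must match `params`, `initial`, `horizon` and `dt`.
#' @return A `protocol_outcome`: list with `label`, `percent_decrease`,
#'   `eradicated`, `death_time`, `eradication_time` and the two
#'   trajectories.
#' @export
run_protocol <- function(params, spec, initial = NULL, C_i0 = 1e5,
                         horizon = 1000, dt = 1, control = NULL) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(spec, "protocol_spec"))
  if (is.null(initial)) initial <- c(6e4, 0, C_i0, 0)
  if (is.null(control))
    control <- simulate_model(params, dose_schedule(ef = spec$ef), initial,
                              t_end = horizon, dt = dt)
  treated <- simulate_model(params, protocol_schedule(spec), initial,
                            t_end = horizon, dt = dt)
  times <- measurement_times(horizon)
  pd <- percent_decrease(control, treated, times)
  structure(list(label = spec$label,
                 percent_decrease = pd,
                 eradicated = !is.na(treated$eradication_time),
                 death_time = treated$death_time,
                 eradication_time = treated$eradication_time,
                 control = control, treated = treated),
            class = "protocol_outcome")
}

#' @export
print.protocol_outcome <- function(x, ...) {
  cat(x$label, ": ", sprintf("%.2f", x$percent_decrease),
      "% mean decrease; eradicated: ", if (x$eradicated) "yes" else "no",
      sep = "")
  if (!is.na(x$death_time)) cat("; host death at ", x$death_time, " h", sep = "")
  cat("\n")
  invisible(x)
}

#' Sweep infusion protocols over dose size, interval and arrival fraction
#'
#' Runs [run_protocol()] over the Cartesian product of the supplied grids
#' (all other protocol features fixed) and returns a tidy table, one row
#' per protocol, mirroring the columns of a dose/interval screening table.
#' The untreated control is computed once per arrival fraction and reused.
#'
#' @inheritParams run_protocol
#' @param dose_sizes DCs per dose to test.
#' @param intervals Injection intervals (hours) to test.
#' @param ef_values Arrival fractions to test.
#' @param n_doses Doses per protocol; by default every dose that fits in the
#'   three-week treatment window is given (doses at `168 + k * interval`
#'   with times up to 504 h, i.e. `floor(336 / interval) + 1` doses: 8 at a
#'   48-h interval, 5 at 72 h, 4 at 96 h, 3 at 120--168 h, 2 at 192--216 h);
#'   pass a single number to fix it instead.
#' @param first_dose_time First dose time, hours.
#' @return A data.frame with columns `label, dose_size, interval_h,
#'   n_doses, ef, percent_decrease, eradicated, death_time`.
#' @export
sweep_protocols <- function(params, dose_sizes, intervals,
                            ef_values = 0.5, n_doses = NULL,
                            first_dose_time = 168, initial = NULL,
                            C_i0 = 1e5, horizon = 1000, dt = 1) {
  if (length(dose_sizes) == 0L || length(intervals) == 0L ||
      length(ef_values) == 0L)
    stop("dose_sizes, intervals and ef_values must be non-empty")
  grid <- expand.grid(dose_size = dose_sizes, interval = intervals,
                      ef = ef_values, KEEP.OUT.ATTRS = FALSE)
  if (is.null(initial)) initial <- c(6e4, 0, C_i0, 0)
  controls <- lapply(unique(grid$ef), function(ef)
    simulate_model(params, dose_schedule(ef = ef), initial, horizon, dt))
  names(controls) <- as.character(unique(grid$ef))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    nd <- if (is.null(n_doses)) floor(336 / g$interval) + 1L else n_doses
    spec <- protocol_spec(nd, g$dose_size, g$interval, first_dose_time,
                          g$ef)
    out <- run_protocol(params, spec, initial = initial, horizon = horizon,
                        dt = dt, control = controls[[as.character(g$ef)]])
    data.frame(label = out$label, dose_size = g$dose_size,
               interval_h = g$interval, n_doses = nd, ef = g$ef,
               percent_decrease = out$percent_decrease,
               eradicated = out$eradicated,
               death_time = ifelse(is.na(out$death_time), NA_real_,
                                   out$death_time))
  })
  do.call(rbind, rows)
}
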
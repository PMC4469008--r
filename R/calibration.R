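#' Tumor growth datasets
#'
#' A `growth_dataset` holds one subject's tumor time course: observation
#' times (hours) and sizes, either as cell counts or as tumor diameters in
#' micrometres (unit tag `cells` or `diameter_um`).
#'
#' @param times Observation times, hours, non-decreasing.
#' @param values Tumor sizes, >= 0.
#' @param unit `"cells"` or `"diameter_um"`.
#' @param subject Subject label.
#' @return A `growth_dataset` (data.frame with attributes `unit`,
#'   `subject`).
#' @export
growth_dataset <- function(times, values, unit = c("cells", "diameter_um"),
                           subject = "subject-1") {
  unit <- match.arg(unit)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (is.unsorted(times)) stop("times must be non-decreasing")
  if (any(values < 0)) stop("values must be >= 0")
  structure(data.frame(t_hours = times, value = values),
            unit = unit, subject = subject,
            class = c("growth_dataset", "data.frame"))
}

#' Read a growth dataset from a two-column CSV
#'
#' Expects columns `t_hours, value`; an optional leading comment line
#' `# unit: cells` (or `diameter_um`) carries the unit tag, defaulting to
#' cells.
#'
#' @param path CSV path.
#' @param subject Subject label (default: file name).
#' @return A [growth_dataset()].
#' @export
read_growth_dataset <- function(path, subject = basename(path)) {
  first <- readLines(path, n = 1L)
  unit <- "cells"
  if (grepl("^#", first)) {
    m <- regmatches(first, regexpr("(cells|diameter_um)", first))
    if (length(m) == 1L) unit <- m
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("t_hours", "value") %in% names(df)))
    stop("growth CSV must have columns t_hours, value")
  growth_dataset(df$t_hours, df$value, unit = unit, subject = subject)
}

#' Convert tumor diameter to cell count (and back)
#'
#' Assumes a spherical tumor packed with spherical cells of diameter
#' `cell_diameter` (17.4 um for B16/F10 melanoma), so the count is the
#' ratio of volumes: `(diameter / cell_diameter)^3`.
#'
#' @param diameter Tumor diameter(s), micrometres, >= 0.
#' @param cells Tumor cell count(s), >= 0.
#' @param cell_diameter Single-cell diameter, micrometres (> 0).
#' @return Cell count(s) / diameter(s) in micrometres.
#' @examples
#' diameter_to_cells(34.8)       # doubling the diameter cubes the count: 8
#' cells_to_diameter(1.6e10) / 1e4  # terminal burden ~ 4.4 cm
#' @export
diameter_to_cells <- function(diameter, cell_diameter = 17.4) {
  if (any(diameter < 0)) stop("diameter must be >= 0")
  if (cell_diameter <= 0) stop("cell_diameter must be > 0")
  (diameter / cell_diameter)^3
}

#' @rdname diameter_to_cells
#' @export
cells_to_diameter <- function(cells, cell_diameter = 17.4) {
  if (any(cells < 0)) stop("cells must be >= 0")
  if (cell_diameter <= 0) stop("cell_diameter must be > 0")
  cell_diameter * cells^(1 / 3)
}

#' Normalized root-mean-square error between data and simulation
#'
#' RMSE of the simulated tumor burden against the observations at the
#' observation times, normalized by the spread of the observations and
#' expressed in percent. Range normalization (max - min) is the default;
#' mean normalization is available since the convention differs between
#' studies.
#'
#' @param observed A [growth_dataset()] in cells.
#' @param simulated A `trajectory` covering the observation times, or a
#'   numeric vector of simulated burdens at those times.
#' @param normalization `"range"` or `"mean"`.
#' @return NRMSE in percent.
#' @export
nrmse <- function(observed, simulated, normalization = c("range", "mean")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(observed, "growth_dataset"))
  if (attr(observed, "unit") != "cells")
    stop("observed data must be in cells (convert with diameter_to_cells)")
  if (length(unique(observed$value)) < 2L)
    stop("need >= 2 distinct observed values to normalize")
  sim <- if (inherits(simulated, "trajectory")) {
    tumor_at(simulated, observed$t_hours)
  } else {
    as.numeric(simulated)
  }
  if (length(sim) != nrow(observed))
    stop("simulated values do not cover the observation times")
  rmse <- sqrt(mean((sim - observed$value)^2))
  denom <- switch(normalization,
                  range = diff(range(observed$value)),
                  mean = mean(observed$value))
  if (denom == 0) stop("degenerate normalization (zero range/mean)")
  100 * rmse / denom
}

#' Gompertz growth curve (closed form)
#'
#' Solution of `dT/dt = r T ln(K / T)` from `T(0) = T0`:
#' `K (T0 / K)^(exp(-r t))`.
#'
#' @param t Time(s), hours.
#' @param r Maximal growth rate, 1/hour.
#' @param K Carrying capacity, cells.
#' @param T0 Initial burden, cells.
#' @return Tumor burden(s), cells.
#' @export
gompertz_curve <- function(t, r, K, T0) {
  K * (T0 / K)^exp(-r * t)
}

#' Fit Gompertz growth parameters (r, K) by least squares
#'
#' Minimizes the sum of squared residuals between the Gompertz closed form
#' and an untreated tumor time course, with the inoculum `T0` fixed. By
#' default the residuals are taken on the log scale: tumor counts span
#' five orders of magnitude and carry multiplicative measurement error, so
#' log-scale least squares is the natural objective (raw-scale SSE is
#' available but is dominated by the final observations). The fit is
#' deterministic: on the log scale the curve is linear in `log K` given
#' `r`, so `log K` is profiled out in closed form and `r` is found by a
#' grid scan over its bounds refined by 1-D optimization in the best
#' bracket; the raw-scale option polishes that initialisation with bounded
#' quasi-Newton iterations.
#'
#' @param data A [growth_dataset()] in cells with >= 2 distinct values.
#' @param T0 Initial tumor burden (fixed), cells.
#' @param r_bounds,K_bounds Length-2 search bounds for `r` (1/hour) and `K`
#'   (cells). All observed values must fall below the upper `K` bound.
#' @param n_profile Number of profile grid points over `r`.
#' @param scale `"log"` (default) or `"raw"`: the scale on which squared
#'   residuals are summed.
#' @return A `calibration_result`: fitted `par` (named `r`, `K`),
#'   `objective` (SSE on the chosen scale), and a search description.
#' @examples
#' d <- growth_dataset(c(168, seq(240, 672, 48)),
#'                     gompertz_curve(c(168, seq(240, 672, 48)),
#'                                    0.00106, 6.754e15, 6e4))
#' fit_gompertz(d, T0 = 6e4)$par
#' @export
fit_gompertz <- function(data, T0, r_bounds = c(1e-5, 1e-1),
                         K_bounds = c(1e10, 1e18), n_profile = 400,
                         scale = c("log", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(data, "growth_dataset"))
  if (attr(data, "unit") != "cells") stop("data must be in cells")
  keep <- data$value > 0
  t <- data$t_hours[keep]; y <- data$value[keep]
  if (length(unique(paste(t, y))) < 2L || length(t) < 2L)
    stop("under-determined: need >= 2 positive observations")
  if (T0 <= 0) stop("T0 must be > 0")
  if (any(y >= K_bounds[2]))
    stop("observed values must lie below the upper K bound")

  # log scale: log T = log K + exp(-r t)(log T0 - log K), linear in log K
  # given r, so log K is profiled out in closed form.
  ly <- log(y); lT0 <- log(T0)
  lK_bounds <- log(K_bounds)
  profile <- function(r) {
    w <- exp(-r * t)                       # ly ~ (1 - w) lK + w lT0
    x <- 1 - w
    lK <- sum(x * (ly - w * lT0)) / sum(x * x)
    lK <- min(max(lK, lK_bounds[1]), lK_bounds[2])
    list(lK = lK, sse = sum((lK * x + w * lT0 - ly)^2))
  }
  r_cand <- exp(seq(log(r_bounds[1]), log(r_bounds[2]),
                    length.out = n_profile))
  sse_cand <- vapply(r_cand, function(r) profile(r)$sse, 0)
  i <- which.min(sse_cand)
  bracket <- c(r_cand[max(i - 1L, 1L)], r_cand[min(i + 1L, n_profile)])
  opt1 <- stats::optimize(function(r) profile(r)$sse,
                          interval = bracket, tol = 1e-12)
  r_hat <- opt1$minimum
  lK_hat <- profile(r_hat)$lK
  if (scale == "log") {
    par <- c(r = r_hat, K = exp(lK_hat))
    objective <- opt1$objective
  } else {
    sse_raw <- function(p) sum((gompertz_curve(t, exp(p[1]), exp(p[2]),
                                               T0) - y)^2)
    fscale <- max(y)^2   # keeps the objective O(1) for the optimizer
    opt2 <- stats::optim(c(log(r_hat), lK_hat),
                         function(p) sse_raw(p) / fscale,
                         method = "L-BFGS-B",
                         lower = c(log(r_bounds[1]), lK_bounds[1]),
                         upper = c(log(r_bounds[2]), lK_bounds[2]),
                         control = list(maxit = 500, factr = 1e4))
    par <- c(r = exp(opt2$par[1]), K = exp(opt2$par[2]))
    objective <- opt2$value * fscale
  }
  structure(list(par = par, objective = objective,
                 objective_type = paste0("SSE (", scale, " scale)"),
                 search = sprintf(
                   "profiled log-K, %d log-spaced r in [%g, %g] + 1-D refinement; K in [%g, %g]; %s-scale residuals",
                   n_profile, r_bounds[1], r_bounds[2],
                   K_bounds[1], K_bounds[2], scale),
                 convergence = 0L),
            class = "calibration_result")
}

#' Fit therapy parameters by exhaustive grid search
#'
#' Simulates the treated arm of `spec` for every combination of the
#' candidate grids for the killing efficiency `a_T`, the activation rate
#' `r_a`, the expansion rate `r_e` and the delay `tau` (all other
#' parameters fixed at `params`), scores each by NRMSE against the treated
#' growth data, and returns the minimizer. Ties are broken by the first
#' minimum in row-major grid order (`a_T` fastest, then `r_a`, `r_e`,
#' `tau`).
#'
#' @param data A [growth_dataset()] in cells (treated arm observations).
#' @param params A [model_parameters()] object supplying the fixed
#'   parameters.
#' @param spec A [protocol_spec()] describing the therapy given.
#' @param a_T_grid,r_a_grid,r_e_grid,tau_grid Non-empty candidate vectors.
#' @param initial Initial state passed to the simulation (default inoculum
#'   6e4 cells, naive pool `C_i0`).
#' @param C_i0 Baseline naive CTL pool when `initial` is NULL.
#' @param horizon,dt Simulation horizon and step, hours.
#' @param normalization NRMSE normalization, `"range"` or `"mean"`.
#' @return A `calibration_result` with `par` (named `a_T, r_a, r_e, tau`),
#'   `objective` (NRMSE %), and the full scored `grid` data.frame.
#' @export
fit_therapy_params <- function(data, params, spec,
                               a_T_grid, r_a_grid, r_e_grid, tau_grid,
                               initial = NULL, C_i0 = 1e5,
                               horizon = 1000, dt = 1,
                               normalization = "range") {
  stopifnot(inherits(data, "growth_dataset"),
            inherits(params, "model_parameters"),
            inherits(spec, "protocol_spec"))
  grids <- list(a_T = a_T_grid, r_a = r_a_grid, r_e = r_e_grid,
                tau = tau_grid)
  if (any(vapply(grids, length, 1L) == 0L))
    stop("all four grids must be non-empty")
  if (is.null(initial)) initial <- c(6e4, 0, C_i0, 0)
  sched <- protocol_schedule(spec)
  grid <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)  # a_T varies fastest
  grid$nrmse <- NA_real_
  for (i in seq_len(nrow(grid))) {
    p <- params
    p$a_T <- grid$a_T[i]; p$r_a <- grid$r_a[i]
    p$r_e <- grid$r_e[i]; p$tau <- grid$tau[i]
    p <- validate_model_parameters(unclass(p))
    tr <- simulate_model(p, sched, initial, t_end = horizon, dt = dt)
    grid$nrmse[i] <- nrmse(data, tr, normalization = normalization)
  }
  ibest <- which.min(grid$nrmse)     # first minimum in row-major order
  structure(list(par = unlist(grid[ibest, c("a_T", "r_a", "r_e", "tau")]),
                 objective = grid$nrmse[ibest],
                 objective_type = paste0("NRMSE% (", normalization, ")"),
                 search = sprintf("exhaustive grid, %d combinations",
                                  nrow(grid)),
                 grid = grid),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result (", x$objective_type, " = ",
      format(x$objective, digits = 6), "):\n", sep = "")
  print(format(x$par, digits = 6))
  cat("  search: ", x$search, "\n", sep = "")
  invisible(x)
}

#' Write a calibration result to JSON
#'
#' @param x A `calibration_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(x, path) {
  stopifnot(inherits(x, "calibration_result"))
  jsonlite::write_json(list(par = as.list(x$par), objective = x$objective,
                            objective_type = x$objective_type,
                            search = x$search),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
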
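#' Generate synthetic mouse tumor-growth datasets
#'
#' Emulates the murine study design as a stand-in for unpublished animal
#' data: tumors are inoculated at 6e4 B16/F10 cells, the model is
#' simulated under the generating parameters (optionally under an infusion
#' protocol), the tumor burden is sampled at the study's measurement times
#' (day 7, then every two days from day 10), and per-observation
#' multiplicative lognormal noise is applied. As in the animal protocol,
#' measurement stops when the host dies: times after the simulated death
#' time yield no observations. The log-noise has mean 0, so
#' the noise is median-unbiased: the per-time median across many mice
#' converges to the noiseless truth. Fully reproducible from `seed`.
#'
#' @param params Generating [model_parameters()].
#' @param protocol A [protocol_spec()] for a treated arm, or NULL for
#'   untreated controls.
#' @param sigma Lognormal noise scale on the log of the cell count (>= 0;
#'   0 = noiseless).
#' @param n_mice Number of mice (datasets) to generate.
#' @param seed Integer random seed; mandatory, no implicit entropy.
#' @param horizon Simulation horizon, hours.
#' @param initial Initial state; default `c(6e4, 0, C_i0, 0)`.
#' @param C_i0 Baseline naive CTL pool when `initial` is NULL.
#' @param dt Integration step, hours.
#' @return A list with `mice` (list of [growth_dataset()] in cells, one
#'   per mouse), `truth` (the noiseless dataset), and `spec` (the
#'   generating settings, embeddable as manifest metadata).
#' @examples
#' p <- model_parameters(
#'   r = 0.00106, K = 6.754e15, a_T = 0, supp_floor = 0.69, e_supp = 1e4,
#'   mu_D = 0.0096, r_a = 0.05, r_e = 0.01, tau = 96, theta_D = 2.5e5,
#'   theta_a = 2.5e6, mu_Ca = 0.007, mu_Ci = 0.0012, p_beta = 5.75e-6,
#'   mu_beta = 0.14, ef = 0.5, T_death = 1.6e10, T_erad = 1
#' )
#' g <- synthesize_growth_data(p, sigma = 0.1, n_mice = 3, seed = 1,
#'                             horizon = 700)
#' g$mice[[1]]
#' @export
synthesize_growth_data <- function(params, protocol = NULL, sigma = 0.1,
                                   n_mice = 1, seed, horizon = 700,
                                   initial = NULL, C_i0 = 1e5, dt = 1) {
  stopifnot(inherits(params, "model_parameters"))
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an explicit integer seed is required")
  if (sigma < 0) stop("sigma must be >= 0")
  if (n_mice < 1) stop("n_mice must be >= 1")
  if (is.null(initial)) initial <- c(6e4, 0, C_i0, 0)
  sched <- if (is.null(protocol)) dose_schedule(ef = params$ef) else
    protocol_schedule(protocol)
  tr <- simulate_model(params, sched, initial, t_end = horizon, dt = dt)
  tm <- measurement_times(horizon)
  tm <- tm[tm <= max(tr$times)]          # no measurements after host death
  if (length(tm) == 0L)
    stop("host dies before the first measurement; nothing to observe")
  truth_vals <- tumor_at(tr, tm)
  truth <- growth_dataset(tm, truth_vals, unit = "cells",
                          subject = "truth")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  mice <- lapply(seq_len(n_mice), function(m) {
    noisy <- truth_vals * exp(stats::rnorm(length(tm), mean = 0,
                                           sd = sigma))
    growth_dataset(tm, noisy, unit = "cells",
                   subject = sprintf("mouse-%02d", m))
  })
  list(mice = mice, truth = truth,
       spec = list(protocol = if (is.null(protocol)) NULL else
                     protocol$label,
                   sigma = sigma, n_mice = n_mice, seed = seed,
                   horizon = horizon, dt = dt,
                   params = unclass(params)))
}

#' Convert a cell-count dataset to tumor diameters
#'
#' Inverse of [diameter_to_cells()] applied to a whole dataset:
#' `diameter = cell_diameter * cells^(1/3)` under the spherical-tumor
#' assumption. Round-trips with the forward conversion.
#'
#' @param dataset A [growth_dataset()] in cells.
#' @param cell_diameter Single-cell diameter, micrometres.
#' @return A [growth_dataset()] with unit `diameter_um`.
#' @export
to_diameters <- function(dataset, cell_diameter = 17.4) {
  stopifnot(inherits(dataset, "growth_dataset"))
  if (attr(dataset, "unit") != "cells") stop("dataset must be in cells")
  growth_dataset(dataset$t_hours,
                 cells_to_diameter(dataset$value, cell_diameter),
                 unit = "diameter_um", subject = attr(dataset, "subject"))
}

#' @rdname to_diameters
#' @export
to_cells <- function(dataset, cell_diameter = 17.4) {
  stopifnot(inherits(dataset, "growth_dataset"))
  if (attr(dataset, "unit") != "diameter_um")
    stop("dataset must be in diameter_um")
  growth_dataset(dataset$t_hours,
                 diameter_to_cells(dataset$value, cell_diameter),
                 unit = "cells", subject = attr(dataset, "subject"))
}

#' Write synthetic datasets as per-mouse CSVs plus a manifest
#'
#' Each mouse becomes `<dir>/<subject>.csv` (with a `# unit:` comment
#' header readable by [read_growth_dataset()]); the generating settings
#' and seed are written to `<dir>/manifest.json`.
#'
#' @param synth Output of [synthesize_growth_data()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c(synth$mice, list(synth$truth))) {
    path <- file.path(dir, paste0(attr(d, "subject"), ".csv"))
    con <- file(path, "w")
    writeLines(paste0("# unit: ", attr(d, "unit")), con)
    utils::write.table(as.data.frame(d)[c("t_hours", "value")], con,
                       sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
  }
  jsonlite::write_json(synth$spec, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
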
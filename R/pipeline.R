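#' Load protocol definitions from a config file
#'
#' Reads a YAML/JSON list of protocol entries, each with fields `label`,
#' `n_doses`, `dose_size`, `interval_h`, `first_dose_h`, `ef` (the last
#' two optional, defaulting to 168 h and 0.5).
#'
#' @param path Config file path.
#' @return Named list of [protocol_spec()] objects.
#' @export
load_protocols <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE) else
    yaml::read_yaml(path)
  if (!is.list(raw) || length(raw) == 0L)
    stop("protocol file must hold a non-empty list of protocols")
  specs <- lapply(raw, function(e) {
    need <- c("label", "n_doses", "dose_size")
    missing <- setdiff(need, names(e))
    if (length(missing) > 0L)
      stop("protocol entry missing field(s): ",
           paste(missing, collapse = ", "))
    protocol_spec(n_doses = e$n_doses, dose_size = e$dose_size,
                  interval = if (is.null(e$interval_h)) 168 else e$interval_h,
                  first_dose_time = if (is.null(e$first_dose_h)) 168 else
                    e$first_dose_h,
                  ef = if (is.null(e$ef)) 0.5 else e$ef,
                  label = e$label)
  })
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

#' Run a configured analysis pipeline
#'
#' Thin driver over the package stages, intended for scripted use. The
#' config is a named list (or a YAML/JSON file path) with:
#' \describe{
#'   \item{params}{path to the model-parameter file (required).}
#'   \item{stage}{one of `simulate`, `sweep`, `knockout`, `fit_growth`,
#'     `lpsa`, `synth`.}
#'   \item{protocols}{path to a protocol file; `protocol` selects a label
#'     (stages `simulate`, `knockout`, `lpsa`, `synth`).}
#'   \item{horizon, dt}{simulation window and step, hours (defaults 1000,
#'     1); `horizon` must be a multiple of `dt` and every dose time must
#'     sit on the grid.}
#'   \item{C_i0}{baseline naive CTL pool (default 1e5).}
#'   \item{out}{output directory (required); every artifact lands there.}
#'   \item{dose_sizes, intervals, ef_values}{grids for `sweep`.}
#'   \item{data}{growth CSV for `fit_growth`.}
#'   \item{sigma, n_mice, seed}{noise scale, cohort size and seed for
#'     `synth`.}
#' }
#' Artifacts: trajectory CSVs with event sidecars, sweep/LPSA tables as
#' CSV, calibration JSON, synthetic cohorts as per-mouse CSVs plus a
#' manifest. Every stage logs the settings it ran with.
#'
#' @param config Named list or path to a YAML/JSON config file.
#' @param quiet Suppress stage logging.
#' @return Invisible list of the artifact paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE) else
      yaml::read_yaml(config)
  }
  say <- function(...) if (!quiet) message("[dcimmune] ", ...)
  need <- function(nm) {
    if (is.null(config[[nm]])) stop("config is missing '", nm, "'")
    config[[nm]]
  }
  stage <- match.arg(need("stage"),
                     c("simulate", "sweep", "knockout", "fit_growth",
                       "lpsa", "synth"))
  params <- load_model_parameters(need("params"))
  out_dir <- need("out")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  horizon <- if (is.null(config$horizon)) 1000 else config$horizon
  dt <- if (is.null(config$dt)) 1 else config$dt
  C_i0 <- if (is.null(config$C_i0)) 1e5 else config$C_i0
  pick_protocol <- function() {
    specs <- load_protocols(need("protocols"))
    lab <- need("protocol")
    if (!lab %in% names(specs))
      stop("unknown protocol label '", lab, "'; available: ",
           paste(names(specs), collapse = ", "))
    specs[[lab]]
  }
  artifacts <- character(0)
  add <- function(p) artifacts <<- c(artifacts, p)

  if (stage %in% c("simulate", "knockout")) {
    spec <- pick_protocol()
    if (stage == "knockout") params <- tgfb_knockout(params)
    say(stage, ": ", spec$label, ", horizon ", horizon, " h, dt ", dt, " h")
    out <- run_protocol(params, spec, C_i0 = C_i0, horizon = horizon,
                        dt = dt)
    add(write_trajectory(out$treated, file.path(out_dir, "treated.csv")))
    add(write_trajectory(out$control, file.path(out_dir, "control.csv")))
    summary <- list(label = out$label,
                    percent_decrease = out$percent_decrease,
                    eradicated = out$eradicated,
                    death_time = if (is.na(out$death_time)) NULL else
                      out$death_time)
    jsonlite::write_json(summary, file.path(out_dir, "outcome.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    add(file.path(out_dir, "outcome.json"))
    say(sprintf("%s: %.2f%% mean decrease, eradicated: %s", out$label,
                out$percent_decrease, out$eradicated))
  } else if (stage == "sweep") {
    say("sweep: ", length(need("dose_sizes")), " dose sizes x ",
        length(need("intervals")), " intervals")
    tab <- sweep_protocols(params, config$dose_sizes, config$intervals,
                           ef_values = if (is.null(config$ef_values)) 0.5
                             else config$ef_values,
                           C_i0 = C_i0, horizon = horizon, dt = dt)
    p <- file.path(out_dir, "sweep.csv")
    utils::write.csv(tab, p, row.names = FALSE)
    add(p)
  } else if (stage == "fit_growth") {
    d <- read_growth_dataset(need("data"))
    if (attr(d, "unit") == "diameter_um") d <- to_cells(d)
    say("fit_growth: ", nrow(d), " observations")
    fit <- fit_gompertz(d, T0 = if (is.null(config$T0)) 6e4 else config$T0)
    add(write_calibration(fit, file.path(out_dir, "gompertz_fit.json")))
    say(sprintf("fitted r = %.3g /h, K = %.3g cells", fit$par["r"],
                fit$par["K"]))
  } else if (stage == "lpsa") {
    spec <- pick_protocol()
    say("lpsa: ", spec$label, ", +/-",
        100 * (if (is.null(config$delta)) 0.01 else config$delta), "%")
    rep <- lpsa(params, spec, C_i0 = C_i0, horizon = horizon,
                delta = if (is.null(config$delta)) 0.01 else config$delta,
                dt = dt)
    p <- file.path(out_dir, "lpsa.csv")
    utils::write.csv(as.data.frame(rep), p, row.names = FALSE)
    add(p)
  } else if (stage == "synth") {
    spec <- if (!is.null(config$protocols) && !is.null(config$protocol))
      pick_protocol() else NULL
    synth <- synthesize_growth_data(
      params, protocol = spec,
      sigma = if (is.null(config$sigma)) 0.1 else config$sigma,
      n_mice = if (is.null(config$n_mice)) 10 else config$n_mice,
      seed = need("seed"), horizon = horizon, C_i0 = C_i0, dt = dt)
    say("synth: ", length(synth$mice), " mice, sigma ",
        synth$spec$sigma, ", seed ", synth$spec$seed)
    add(write_synthetic(synth, out_dir))
  }
  invisible(artifacts)
}
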
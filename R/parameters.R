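#' Model parameters for the tumor--immune delay model
#'
#' Constructs and validates the full parameter set of the five-population
#' model: Gompertz tumor growth, pulsed dendritic-cell (DC) forcing,
#' activated/naive cytotoxic T lymphocytes (CTLs) with an activation delay,
#' and TGF-beta-mediated suppression of CTL killing. Units are cells and
#' hours throughout; TGF-beta is carried in arbitrary concentration units
#' consistent between `e_supp` and `p_beta`.
#'
#' @param r Maximal tumor growth rate, 1/hour.
#' @param K Tumor carrying capacity, cells.
#' @param a_T Maximal killing efficiency of activated CTLs, 1/(cell x hour).
#' @param supp_floor Maximal reduction effect of TGF-beta on CTL efficiency,
#'   dimensionless in (0, 1]. The suppression factor never falls below this.
#' @param e_supp Michaelis constant of TGF-beta suppression, concentration
#'   units.
#' @param mu_D Dendritic-cell decay rate, 1/hour.
#' @param r_a CTL activation rate, 1/hour.
#' @param r_e Activated-CTL expansion rate, 1/hour (scales the saturated
#'   DC-driven expansion term).
#' @param tau Activation/expansion time delay, hours. Must be >= the
#'   integration step (or exactly 0 for the ODE-limit path).
#' @param theta_D Michaelis constant for the DC effect on activation, cells.
#' @param theta_a Michaelis constant for activated-CTL expansion, cells.
#' @param mu_Ca Activated-CTL death rate, 1/hour.
#' @param mu_Ci Naive (inactivated) CTL death rate, 1/hour.
#' @param p_beta TGF-beta production rate per tumor cell,
#'   concentration/(cell x hour).
#' @param mu_beta TGF-beta degradation rate, 1/hour.
#' @param ef Fraction of injected DCs that reach the lymph nodes,
#'   dimensionless in \[0, 1\].
#' @param T_death Tumor burden at which the host dies, cells.
#' @param T_erad Eradication threshold, cells; a tumor at or below this is
#'   treated as extinct (default 1 cell).
#'
#' @return An object of class `model_parameters`: a validated named list.
#' @examples
#' p <- model_parameters(
#'   r = 0.00106, K = 6.754e15, a_T = 5e-8, supp_floor = 0.69,
#'   e_supp = 1e4, mu_D = 0.0096, r_a = 0.05, r_e = 0.01, tau = 96,
#'   theta_D = 2.5e5, theta_a = 2.5e6, mu_Ca = 0.007, mu_Ci = 0.0012,
#'   p_beta = 5.75e-6, mu_beta = 0.14, ef = 0.5,
#'   T_death = 1.6e10, T_erad = 1
#' )
#' @export
model_parameters <- function(r, K, a_T, supp_floor, e_supp, mu_D,
                             r_a, r_e, tau, theta_D, theta_a,
                             mu_Ca, mu_Ci, p_beta, mu_beta, ef,
                             T_death = 1.6e10, T_erad = 1) {
  p <- list(
    r = r, K = K, a_T = a_T, supp_floor = supp_floor, e_supp = e_supp,
    mu_D = mu_D, r_a = r_a, r_e = r_e, tau = tau,
    theta_D = theta_D, theta_a = theta_a, mu_Ca = mu_Ca, mu_Ci = mu_Ci,
    p_beta = p_beta, mu_beta = mu_beta, ef = ef,
    T_death = T_death, T_erad = T_erad
  )
  validate_model_parameters(p)
}

#' @rdname model_parameters
#' @param p A named list carrying every field of `model_parameters`.
#' @export
validate_model_parameters <- function(p) {
  required <- c("r", "K", "a_T", "supp_floor", "e_supp", "mu_D", "r_a",
                "r_e", "tau", "theta_D", "theta_a", "mu_Ca", "mu_Ci",
                "p_beta", "mu_beta", "ef", "T_death", "T_erad")
  missing <- setdiff(required, names(p))
  if (length(missing) > 0L)
    stop("missing parameter key(s): ", paste(missing, collapse = ", "))
  unknown <- setdiff(names(p), required)
  if (length(unknown) > 0L)
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  p <- p[required]
  for (nm in required) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  chk <- function(ok, nm, bound) {
    if (!ok) stop("parameter '", nm, "' out of bounds: must satisfy ", bound)
  }
  # a_T, r_a, r_e, p_beta may be 0 (knockouts and no-therapy limits)
  for (nm in c("r", "K", "e_supp", "mu_D", "theta_D", "theta_a",
               "mu_Ca", "mu_Ci", "mu_beta", "T_death", "T_erad"))
    chk(p[[nm]] > 0, nm, "> 0")
  for (nm in c("a_T", "r_a", "r_e", "p_beta"))
    chk(p[[nm]] >= 0, nm, ">= 0")
  chk(p$supp_floor > 0 && p$supp_floor <= 1, "supp_floor", "in (0, 1]")
  chk(p$ef >= 0 && p$ef <= 1, "ef", "in [0, 1]")
  chk(p$tau >= 0, "tau", ">= 0")
  chk(p$K > p$T_death, "K", "> T_death")
  chk(p$T_death > p$T_erad, "T_death", "> T_erad")
  structure(p, class = "model_parameters")
}

#' Load model parameters from a YAML or JSON config file
#'
#' Reads a flat key--value file whose keys match the fields of
#' [model_parameters()]. Every rate constant must be present: missing keys
#' and unknown keys are hard errors, as are invariant violations (no silent
#' defaults for rate constants; `T_death` and `T_erad` likewise must be
#' stated in the file).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `model_parameters` object.
#' @seealso [write_model_parameters()] for the round-trip writer.
#' @export
load_model_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stop("parameter file must be a flat key-value mapping")
  validate_model_parameters(lapply(raw, as.numeric))
}

#' @rdname load_model_parameters
#' @param params A `model_parameters` object.
#' @export
write_model_parameters <- function(params, path) {
  stopifnot(inherits(params, "model_parameters"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(lapply(unclass(params), as.numeric), path)
  }
  invisible(path)
}

#' Disable the TGF-beta suppression pathway (knockout experiment)
#'
#' Returns a parameter copy with TGF-beta production set to zero. Starting
#' from `F_beta(0) = 0` the cytokine then stays at zero, so the suppression
#' factor is identically 1 and CTL killing proceeds at full efficiency.
#'
#' @param params A `model_parameters` object.
#' @return A `model_parameters` object with `p_beta = 0`.
#' @export
tgfb_knockout <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  params$p_beta <- 0
  params
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Tumor-immune delay model parameters (cells, hours):\n")
  v <- unlist(unclass(x))
  print(format(v, digits = 6, scientific = TRUE), quote = FALSE)
  invisible(x)
}
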
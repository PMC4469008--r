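#' Dose schedule for pulsed dendritic-cell infusions
#'
#' An ordered set of DC infusions. Each dose of `n_DC` cells given at time
#' `t_i` contributes `ef * n_DC * exp(-mu_D * (t - t_i))` surviving cells to
#' the forcing for `t >= t_i`; `ef` is the fraction of injected cells that
#' reach the lymph nodes and trigger the immune response.
#'
#' @param times Infusion times in hours, strictly increasing, all >= 0.
#' @param n_DC Cells injected per dose; a scalar (recycled) or one value per
#'   dose, all > 0.
#' @param ef Arrival fraction in \[0, 1\].
#' @return A `dose_schedule` object (data.frame of doses plus `ef`).
#' @examples
#' # three weekly doses of 1e6 DCs starting one week after inoculation
#' dose_schedule(times = c(168, 336, 504), n_DC = 1e6, ef = 0.5)
#' @export
dose_schedule <- function(times = numeric(0), n_DC = numeric(0), ef = 0.5) {
  times <- as.numeric(times)
  if (length(times) > 0L) {
    n_DC <- rep_len(as.numeric(n_DC), length(times))
    if (any(!is.finite(times)) || any(times < 0))
      stop("dose times must be finite and >= 0")
    if (is.unsorted(times, strictly = TRUE))
      stop("dose times must be strictly increasing")
    if (any(n_DC <= 0)) stop("n_DC must be > 0 for every dose")
  } else {
    n_DC <- numeric(0)
  }
  if (!is.numeric(ef) || length(ef) != 1L || ef < 0 || ef > 1)
    stop("ef must be a single number in [0, 1]")
  structure(list(times = times, n_DC = n_DC, ef = ef),
            class = "dose_schedule")
}

#' TGF-beta suppression factor on CTL killing
#'
#' Michaelis--Menten reduction of cytotoxic efficiency by the TGF-beta
#' concentration: `supp_floor + e_supp * (1 - supp_floor) / (e_supp +
#' F_beta)`. Equals 1 when no cytokine is present, decreases monotonically
#' with `F_beta`, and saturates at `supp_floor`.
#'
#' @param F_beta TGF-beta concentration (>= 0); vectorized.
#' @param supp_floor Maximal reduction effect, in (0, 1].
#' @param e_supp Michaelis constant, > 0.
#' @return Dimensionless factor in \[`supp_floor`, 1\].
#' @export
suppression_factor <- function(F_beta, supp_floor, e_supp) {
  if (any(F_beta < 0)) stop("F_beta must be >= 0")
  if (e_supp <= 0) stop("e_supp must be > 0")
  if (supp_floor <= 0 || supp_floor > 1) stop("supp_floor must be in (0, 1]")
  supp_floor + e_supp * (1 - supp_floor) / (e_supp + F_beta)
}

#' Dendritic-cell forcing D(t)
#'
#' Closed-form number of lymph-node DCs at time `t`: the arrival-fraction-
#' scaled sum of exponentially decaying pulses from every dose already given,
#' `ef * sum_{t_i <= t} n_DC_i * exp(-mu_D (t - t_i))`. Zero before the
#' first dose (including all negative `t`, so delayed lookups are total).
#' Right-continuous at dose times; between doses it satisfies pure
#' exponential decay `dD/dt = -mu_D D`.
#'
#' @param t Time(s) in hours; any real values.
#' @param schedule A [dose_schedule()].
#' @param mu_D DC decay rate, 1/hour.
#' @param cutoff Only doses with `t_i <= cutoff` contribute (default `Inf`,
#'   i.e. all doses up to each `t`). The integrator uses this to evaluate
#'   stages against the smooth piece of the current step.
#' @return DC count(s), same length as `t`.
#' @export
dendritic_forcing <- function(t, schedule, mu_D, cutoff = Inf) {
  stopifnot(inherits(schedule, "dose_schedule"))
  out <- numeric(length(t))
  if (length(schedule$times) == 0L || schedule$ef == 0) return(out)
  keep <- schedule$times <= cutoff
  ti <- schedule$times[keep]
  ni <- schedule$n_DC[keep]
  for (k in seq_along(ti)) {
    on <- t >= ti[k]
    out[on] <- out[on] + ni[k] * exp(-mu_D * (t[on] - ti[k]))
  }
  schedule$ef * out
}

# Right-hand sides of the four integrated states, given current and delayed
# quantities. state / delayed are numeric c(T, C_a, C_i, F_beta). The
# Gompertz and kill terms are gated off below the eradication threshold
# (ln(K/T) diverges as T -> 0; a sub-single-cell tumor is extinct).
model_rhs <- function(state, delayed, D_delayed, params) {
  Tt <- state[1L]; Ca <- state[2L]; Ci <- state[3L]; Fb <- state[4L]
  if (Tt > params$K) stop("tumor burden exceeds carrying capacity K")
  if (Tt <= params$T_erad) {
    dT <- 0
  } else {
    supp <- params$supp_floor +
      params$e_supp * (1 - params$supp_floor) / (params$e_supp + max(Fb, 0))
    dT <- params$r * Tt * log(params$K / Tt) -
      params$a_T * Ca * Tt * supp
  }
  Dd <- D_delayed
  act <- params$r_a * exp(-params$mu_Ci * params$tau) * delayed[3L] *
    (Dd / (Dd + params$theta_D))
  expn <- params$r_e * exp(-params$mu_Ca * params$tau) * Dd *
    (delayed[2L] / (delayed[2L] + params$theta_a))
  dCa <- act + expn - params$mu_Ca * Ca
  dCi <- -act - params$mu_Ci * Ci
  dFb <- params$p_beta * Tt - params$mu_beta * Fb
  c(dT, dCa, dCi, dFb)
}

#' Evaluate the model right-hand sides at one time point
#'
#' Exposes the instantaneous derivatives of the four integrated states
#' (tumor `T`, activated CTLs `C_a`, naive CTLs `C_i`, TGF-beta `F_beta`)
#' given the current state, the state at `t - tau`, and the delayed DC
#' forcing. Mainly useful for inspection and testing; the integrator calls
#' the same kernel internally.
#'
#' @param state,delayed_state Numeric vectors `c(T, C_a, C_i, F_beta)`; the
#'   delayed state is the solution at `t - tau`.
#' @param D_delayed DC forcing evaluated at `t - tau`, cells.
#' @param params A [model_parameters()] object.
#' @return Named numeric vector of derivatives `c(T, C_a, C_i, F_beta)`.
#' @export
model_derivatives <- function(state, delayed_state, D_delayed, params) {
  stopifnot(inherits(params, "model_parameters"),
            length(state) == 4L, length(delayed_state) == 4L)
  if (any(state < 0) || any(delayed_state < 0))
    stop("state components must be >= 0")
  d <- model_rhs(as.numeric(state), as.numeric(delayed_state),
                 D_delayed, params)
  names(d) <- c("T", "C_a", "C_i", "F_beta")
  d
}
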
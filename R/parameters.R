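#' Physiological parameters of the density-dependence growth model
#'
#' Bundles the kinetic constants of the source-sink model: phloem conductance
#' for a single-individual population (`kappa`), the exponent linking
#' conductance to population size (`alpha`), the Michaelis-Menten unloading
#' constants (`Vm`, `Km`), the respiratory fraction (`r`) and the dry matter
#' content of the sink tissue (`DMC`).
#'
#' @param kappa Phloem conductance for a population of one individual,
#'   cm^6 g^-1 h^-1. Must be positive. Fitted values in fruit systems span
#'   roughly 1e-6 (single cell) to 1e3 (whole orchard plot).
#' @param alpha Dimensionless exponent of the conductance-population-size
#'   relationship `k = kappa * n^alpha`; `alpha = 0` makes conductance
#'   independent of population size, `alpha = 1` proportional to it.
#' @param Vm Maximal unloading rate per unit dry mass, g sugar (g DM)^-1
#'   h^-1. Must be positive.
#' @param Km Michaelis constant of sugar unloading, g cm^-3. Must be
#'   positive.
#' @param r Fraction of unloaded sugar consumed by sink respiration,
#'   dimensionless in `[0, 1)`. Default 0.16, the value estimated from fruit
#'   respiration data.
#' @param DMC Dry matter content of the sink tissue (dry mass / fresh mass),
#'   dimensionless in `(0, 1]`. Observed fruit values run from about 0.06
#'   (large tomato) to 0.24 (apple); default 0.16.
#'
#' @return An object of class `ddm_params` (a validated named list).
#' @examples
#' p <- ddm_params(kappa = 5, alpha = 0.2, Vm = 2e-3, Km = 0.01)
#' p$Vm
#' @export
ddm_params <- function(kappa, alpha, Vm, Km, r = 0.16, DMC = 0.16) {
  for (nm in c("kappa", "alpha", "Vm", "Km", "r", "DMC")) {
    stopifnot_scalar(get(nm), nm)
  }
  if (kappa <= 0) ddm_stop("'kappa' must be > 0", "ddm_invalid_parameter")
  if (Vm <= 0) ddm_stop("'Vm' must be > 0", "ddm_invalid_parameter")
  if (Km <= 0) ddm_stop("'Km' must be > 0", "ddm_invalid_parameter")
  if (alpha < 0) ddm_stop("'alpha' must be >= 0", "ddm_invalid_parameter")
  if (r < 0 || r >= 1) ddm_stop("'r' must be in [0, 1)", "ddm_invalid_parameter")
  if (DMC <= 0 || DMC > 1) ddm_stop("'DMC' must be in (0, 1]", "ddm_invalid_parameter")
  structure(list(kappa = kappa, alpha = alpha, Vm = Vm, Km = Km,
                 r = r, DMC = DMC),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Density-dependence model parameters\n")
  cat(sprintf("  kappa = %g cm^6 g^-1 h^-1   alpha = %g\n", x$kappa, x$alpha))
  cat(sprintf("  Vm    = %g g (g DM)^-1 h^-1  Km   = %g g cm^-3\n", x$Vm, x$Km))
  cat(sprintf("  r     = %g                   DMC  = %g\n", x$r, x$DMC))
  invisible(x)
}

#' Source phloem sugar concentration model
#'
#' The sugar concentration `C` of the source phloem either is constant
#' (sub-plant levels of organisation) or decreases logistically with
#' population size (plant-within-plot level, where mutual shading lowers
#' photosynthesis): `C(n) = C0 / (1 + exp(b * (n - d)))`.
#'
#' @param mode `"constant"` or `"logistic"`.
#' @param C0 Baseline concentration, g cm^-3; default 0.1, within the
#'   0.05-0.15 g cm^-3 range observed across species.
#' @param b Logistic steepness (per individual); required for `"logistic"`,
#'   proportional to the rate of decrease at `n = d`.
#' @param d Population size at the maximal rate of decrease; required for
#'   `"logistic"`. At `n = d` the model returns `C0 / 2`.
#' @return An object of class `ddm_source`.
#' @seealso [source_concentration()]
#' @examples
#' source_concentration(source_model("logistic", b = 0.01, d = 1200), 1200)
#' @export
source_model <- function(mode = c("constant", "logistic"), C0 = 0.1,
                         b = NULL, d = NULL) {
  mode <- match.arg(mode)
  stopifnot_scalar(C0, "C0")
  if (C0 <= 0) ddm_stop("'C0' must be > 0", "ddm_invalid_parameter")
  if (mode == "logistic") {
    if (is.null(b) || is.null(d)) {
      ddm_stop("logistic source requires 'b' and 'd'", "ddm_invalid_parameter")
    }
    stopifnot_scalar(b, "b")
    stopifnot_scalar(d, "d")
    if (b < 0) ddm_stop("'b' must be >= 0", "ddm_invalid_parameter")
  }
  structure(list(mode = mode, C0 = C0, b = b, d = d), class = "ddm_source")
}

#' @export
print.ddm_source <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("Source model: constant C = %g g cm^-3\n", x$C0))
  } else {
    cat(sprintf("Source model: logistic C(n) = %g / (1 + exp(%g (n - %g)))\n",
                x$C0, x$b, x$d))
  }
  invisible(x)
}

#' Simulation configuration
#'
#' Describes one growth simulation: the (fixed) population size `n`, the
#' individual dry mass `s0` at the time `t0` when the population size becomes
#' constant (end of cell division, anthesis, or thinning), the simulated
#' span and the integration step.
#'
#' @param n Population size, individuals. Positive real (mean counts such as
#'   5.7e6 cells are not integers); may exceed 1e8.
#' @param s0 Individual dry mass at `t0`, g.
#' @param t0 Start time, h. An offset label: dynamics depend on elapsed time
#'   only.
#' @param duration Simulated growth span, h. Must be a whole number of steps.
#' @param dt Integration step, h; default 1.
#' @return An object of class `ddm_config`.
#' @examples
#' sim_config(n = 20, s0 = 3, duration = 1200)
#' @export
sim_config <- function(n, s0, t0 = 0, duration, dt = 1) {
  for (nm in c("n", "s0", "t0", "duration", "dt")) stopifnot_scalar(get(nm), nm)
  if (n < 1) ddm_stop("'n' must be >= 1", "ddm_invalid_parameter")
  if (s0 <= 0) ddm_stop("'s0' must be > 0", "ddm_invalid_parameter")
  if (duration <= 0) ddm_stop("'duration' must be > 0", "ddm_invalid_parameter")
  if (dt <= 0) ddm_stop("'dt' must be > 0", "ddm_invalid_parameter")
  steps <- duration / dt
  if (abs(steps - round(steps)) > 1e-8) {
    ddm_stop("'duration' must be a whole number of steps of size 'dt'",
             "ddm_invalid_parameter")
  }
  structure(list(n = n, s0 = s0, t0 = t0, duration = duration, dt = dt,
                 steps = as.integer(round(steps))),
            class = "ddm_config")
}

#' Convert a duration in days to hours
#'
#' All internal time is in hours; observational protocols usually report
#' days.
#'
#' @param days Numeric vector of durations in days.
#' @return `days * 24`, hours.
#' @examples
#' days_to_hours(50)  # the 50-day reference growth span
#' @export
days_to_hours <- function(days) days * 24
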
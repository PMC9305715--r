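#' Phloem conductance of the transfer pathway
#'
#' `k = kappa * n^alpha`: total conductance feeding the `n` individuals of
#' the sink population. `alpha = 0` gives a conductance independent of
#' population size, `alpha = 1` one proportional to it. For `n > 1e6` the
#' power is evaluated in log space.
#'
#' @param kappa Conductance for a population of one individual,
#'   cm^6 g^-1 h^-1 (> 0).
#' @param alpha Dimensionless exponent (>= 0).
#' @param n Population size(s), individuals (>= 1); vectorised.
#' @return Conductance `k`, cm^6 g^-1 h^-1.
#' @examples
#' conductance(2, 1, 10)   # proportional: 20
#' conductance(5, 0, 1000) # independent of n: 5
#' @export
conductance <- function(kappa, alpha, n) {
  stopifnot_scalar(kappa, "kappa")
  stopifnot_scalar(alpha, "alpha")
  if (kappa <= 0) ddm_stop("'kappa' must be > 0", "ddm_invalid_parameter")
  if (alpha < 0) ddm_stop("'alpha' must be >= 0", "ddm_invalid_parameter")
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    ddm_stop("'n' must be finite and >= 1", "ddm_invalid_parameter")
  }
  ifelse(n > 1e6, kappa * exp(alpha * log(n)), kappa * n^alpha)
}

#' Source phloem concentration for a population size
#'
#' Evaluates a [source_model()]: constant sources return `C0` for any `n`;
#' logistic sources return `C0 / (1 + exp(b * (n - d)))`, which lies in
#' `(0, C0)` and equals `C0 / 2` at `n = d`.
#'
#' @param model A [source_model()].
#' @param n Population size(s), individuals (>= 1); vectorised.
#' @return Concentration `C`, g cm^-3.
#' @export
source_concentration <- function(model, n) {
  if (!inherits(model, "ddm_source")) {
    ddm_stop("'model' must be a ddm_source", "ddm_invalid_parameter")
  }
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    ddm_stop("'n' must be finite and >= 1", "ddm_invalid_parameter")
  }
  if (model$mode == "constant") {
    rep_len(model$C0, length(n))
  } else {
    model$C0 / (1 + exp(model$b * (n - model$d)))
  }
}

#' Flow of sugars from source to sink
#'
#' Muench mass flow with turgor pressures taken proportional to sugar
#' concentrations: `F = k * C * (C - Cf)`, g h^-1. Positive whenever the
#' sink concentration is below the source concentration.
#'
#' @param C Source phloem sugar concentration, g cm^-3.
#' @param Cf Sink phloem sugar concentration, g cm^-3.
#' @param k Pathway conductance, cm^6 g^-1 h^-1 (> 0).
#' @return Flow `F`, g h^-1; vectorised over its arguments.
#' @export
flow <- function(C, Cf, k) {
  if (any(k <= 0)) ddm_stop("'k' must be > 0", "ddm_invalid_parameter")
  k * C * (C - Cf)
}

#' Michaelis-Menten sugar unloading at the sink
#'
#' Total unloading of a population of `n` individuals of dry mass `s`:
#' `U = n * s * Vm * Cf / (Km + Cf)`, g h^-1. Non-negative, saturating at
#' `n * s * Vm` when `Cf >> Km`.
#'
#' @param n Population size, individuals (>= 1).
#' @param s Individual dry mass, g (> 0).
#' @param Cf Sink phloem sugar concentration, g cm^-3 (>= 0).
#' @param Vm Maximal unloading rate per unit dry mass, g (g DM)^-1 h^-1.
#' @param Km Michaelis constant, g cm^-3.
#' @return Unloading rate `U`, g h^-1; vectorised.
#' @export
unloading <- function(n, s, Cf, Vm, Km) {
  if (any(n < 1)) ddm_stop("'n' must be >= 1", "ddm_invalid_parameter")
  if (any(s <= 0)) ddm_stop("'s' must be > 0", "ddm_invalid_parameter")
  n * s * Vm * Cf / (Km + Cf)
}

#' Sink phloem concentration balancing flow and unloading
#'
#' With no storage in the sink phloem, the sink concentration `Cf` is set by
#' the steady-state balance `F = U`. Substituting the flow and unloading laws
#' gives the quadratic `A*Cf^2 + (A*(Km - C) + n*s*Vm)*Cf - A*C*Km = 0` with
#' `A = kappa * n^alpha * C`, whose unique positive root is returned. The
#' root is evaluated with the cancellation-stable q-formula: the two
#' competing terms (`A*C` and `n*s*Vm`) each span many orders of magnitude
#' across organisation levels, and the textbook root formula cancels
#' catastrophically when demand dominates supply.
#'
#' @param C Source phloem concentration, g cm^-3 (> 0).
#' @param n Population size, individuals (>= 1); vectorised with `s`.
#' @param s Individual dry mass, g (> 0).
#' @param params A [ddm_params()] object.
#' @return `Cf`, g cm^-3, guaranteed in `(0, C)`.
#' @examples
#' p <- ddm_params(kappa = 1, alpha = 0.5, Vm = 2e-3, Km = 0.01)
#' Cf <- sink_concentration(0.1, n = 4, s = 3, params = p)
#' k <- conductance(p$kappa, p$alpha, 4)
#' flow(0.1, Cf, k) - unloading(4, 3, Cf, p$Vm, p$Km)  # ~0: F = U
#' @export
sink_concentration <- function(C, n, s, params) {
  if (!inherits(params, "ddm_params")) {
    ddm_stop("'params' must be a ddm_params", "ddm_invalid_parameter")
  }
  if (any(C <= 0)) {
    ddm_stop("source concentration 'C' must be > 0 (degenerate A = 0)",
             "ddm_invalid_parameter")
  }
  if (any(s <= 0)) ddm_stop("'s' must be > 0", "ddm_invalid_parameter")
  k <- conductance(params$kappa, params$alpha, n)
  A <- k * C
  B <- A * (params$Km - C) + n * s * params$Vm
  sq <- sqrt(B^2 + 4 * A^2 * C * params$Km)
  ifelse(B >= 0, 2 * A * C * params$Km / (B + sq), (sq - B) / (2 * A))
}

#' Simulate individual growth of a sink population
#'
#' Integrates individual dry mass by explicit forward Euler at step `dt`
#' (default 1 h): at each step the source concentration `C` is taken from the
#' source model, the sink concentration `Cf` from the flow-unloading balance,
#' the unloading rate `U` from Michaelis-Menten kinetics, and the state is
#' advanced by `s <- s + dt * (1 - r) * U / n`. Population size is constant
#' after `t0`, and the source model depends on `n` only, so `C` is constant
#' in time.
#'
#' @param params A [ddm_params()].
#' @param source A [source_model()].
#' @param config A [sim_config()].
#' @return An object of class `ddm_trajectory`: a data frame with columns
#'   `time_h`, `s_g` (individual dry mass), `Cf_g_per_cm3`, `U_g_per_h`
#'   (population unloading), `M_g` (individual fresh mass `s / DMC`) and
#'   `TM_g` (population fresh mass `n * M`), one row per hourly node, with
#'   attributes `sugar_unloaded_g` (the accumulated `sum(U * dt)`), `params`,
#'   `source` and `config`. Signals a classed `ddm_integration_error`
#'   reporting the step if the state becomes non-finite.
#' @examples
#' tr <- simulate_growth(
#'   ddm_params(kappa = 5, alpha = 0.2, Vm = 2e-3, Km = 0.01),
#'   source_model("constant"),
#'   sim_config(n = 20, s0 = 3, duration = 240)
#' )
#' tail(tr, 2)
#' @export
simulate_growth <- function(params, source, config) {
  if (!inherits(params, "ddm_params")) {
    ddm_stop("'params' must be a ddm_params", "ddm_invalid_parameter")
  }
  if (!inherits(source, "ddm_source")) {
    ddm_stop("'source' must be a ddm_source", "ddm_invalid_parameter")
  }
  if (!inherits(config, "ddm_config")) {
    ddm_stop("'config' must be a sim_config", "ddm_invalid_parameter")
  }
  C <- source_concentration(source, config$n)
  res <- .ddm_euler_cpp(config$n, config$s0, C, params$kappa, params$alpha,
                        params$Vm, params$Km, params$r, config$steps,
                        config$dt)
  if (res$fail_step >= 0) {
    ddm_stop(sprintf(
      "integration failure: non-finite state at step %d (t = %g h)",
      res$fail_step, config$t0 + res$fail_step * config$dt),
      "ddm_integration_error", step = res$fail_step)
  }
  M <- res$s / params$DMC
  out <- data.frame(
    time_h = config$t0 + (0:config$steps) * config$dt,
    s_g = res$s,
    Cf_g_per_cm3 = res$Cf,
    U_g_per_h = res$U,
    M_g = M,
    TM_g = config$n * M
  )
  structure(out,
            class = c("ddm_trajectory", "data.frame"),
            sugar_unloaded_g = res$cum_unloaded,
            params = params, source = source, config = config)
}

#' @export
print.ddm_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Growth trajectory: n = %g, %g h at dt = %g h\n", cfg$n, cfg$duration,
    cfg$dt))
  cat(sprintf("  dry mass %.4g -> %.4g g; fresh mass %.4g -> %.4g g\n",
              x$s_g[1], x$s_g[nrow(x)], x$M_g[1], x$M_g[nrow(x)]))
  cat(sprintf("  total sugar unloaded: %.4g g\n",
              attr(x, "sugar_unloaded_g")))
  invisible(x)
}
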
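#' Density-dependence index
#'
#' A positive index quantifying how strongly individual mass at maturity
#' falls as population size grows from `n_min` to `n_max`:
#' `DD = -((M(n_min) - M(n_max)) / M_bar) * (n_bar / (n_min - n_max))`.
#' It is a normalised, elasticity-like endpoint slope: zero when individual
#' mass does not respond to population size, positive when it decreases,
#' negative (equal magnitude) when it increases.
#'
#' The reference masses `M_bar` and `n_bar` default to the endpoint means
#' `(M(n_min) + M(n_max)) / 2` and `(n_min + n_max) / 2`, which keeps the
#' index a function of the endpoints only; pass explicit grid means via
#' `M_bar` / `n_bar` to use the whole-grid convention instead.
#'
#' @param M_nmin Individual mass at `n_min`, g (> 0).
#' @param M_nmax Individual mass at `n_max`, g (> 0).
#' @param n_min,n_max Endpoint population sizes, `n_min < n_max`.
#' @param M_bar,n_bar Optional reference mass / population size; defaults to
#'   the endpoint means.
#' @return Dimensionless index.
#' @examples
#' dd_index(10, 5, 1, 20)  # mass halves over the grid: strong DD
#' dd_index(7, 7, 1, 20)   # no response: 0
#' @export
dd_index <- function(M_nmin, M_nmax, n_min, n_max,
                     M_bar = (M_nmin + M_nmax) / 2,
                     n_bar = (n_min + n_max) / 2) {
  for (nm in c("M_nmin", "M_nmax", "n_min", "n_max")) {
    stopifnot_scalar(get(nm), nm)
  }
  if (n_min == n_max) {
    ddm_stop("undefined index: n_min and n_max coincide", "ddm_undefined_index")
  }
  if (n_min > n_max) {
    ddm_stop("'n_min' must be smaller than 'n_max'", "ddm_invalid_parameter")
  }
  if (M_nmin <= 0 || M_nmax <= 0) {
    ddm_stop("masses must be positive", "ddm_invalid_parameter")
  }
  -((M_nmin - M_nmax) / M_bar) * (n_bar / (n_min - n_max))
}

#' Classify yield-density compensation
#'
#' Compares population mass at the smallest and largest population sizes:
#' undercompensation when the population mass still increases with size,
#' exact compensation when it is unchanged within a relative tolerance band,
#' overcompensation when competition makes it decrease.
#'
#' @param TM_min Population mass at the smallest population size, g (> 0).
#' @param TM_max Population mass at the largest population size, g (> 0).
#' @param rel_tol Relative half-width of the "exact" band, in `(0, 1)`;
#'   default 0.05.
#' @return One of `"under"`, `"exact"`, `"over"`.
#' @examples
#' classify_compensation(100, 180)  # "under"
#' classify_compensation(100, 60)   # "over"
#' @export
classify_compensation <- function(TM_min, TM_max, rel_tol = 0.05) {
  stopifnot_scalar(TM_min, "TM_min")
  stopifnot_scalar(TM_max, "TM_max")
  stopifnot_scalar(rel_tol, "rel_tol")
  if (TM_min <= 0 || TM_max <= 0) {
    ddm_stop("masses must be positive", "ddm_invalid_parameter")
  }
  if (rel_tol <= 0 || rel_tol >= 1) {
    ddm_stop("'rel_tol' must be in (0, 1)", "ddm_invalid_parameter")
  }
  if (TM_max > TM_min * (1 + rel_tol)) "under"
  else if (TM_max < TM_min * (1 - rel_tol)) "over"
  else "exact"
}

#' Density response over a grid of population sizes
#'
#' Runs one growth simulation per population size (same `s0`, `t0`,
#' `duration`), collects individual and population fresh mass at maturity
#' (the final integration node), and derives the density-dependence index
#' and the compensation class from the grid endpoints.
#'
#' @param params A [ddm_params()].
#' @param source A [source_model()]; the source concentration is
#'   re-evaluated for every `n`.
#' @param base_config A [sim_config()]; its `n` is ignored in favour of
#'   `n_grid`.
#' @param n_grid Ascending population sizes, length >= 2.
#' @param rel_tol Tolerance passed to [classify_compensation()].
#' @param mean_mode `"endpoint"` (default) or `"grid"`: which means enter
#'   the DD index denominator.
#' @return An object of class `ddm_density_response`: a data frame with
#'   columns `n`, `M_g`, `TM_g` and attributes `dd_index` and
#'   `compensation`.
#' @examples
#' resp <- density_response(
#'   ddm_params(kappa = 5, alpha = 0.2, Vm = 2e-3, Km = 0.01),
#'   source_model("constant"),
#'   sim_config(n = 1, s0 = 3, duration = 240),
#'   n_grid = c(1, 5, 10, 20)
#' )
#' attr(resp, "dd_index")
#' @export
density_response <- function(params, source, base_config, n_grid,
                             rel_tol = 0.05,
                             mean_mode = c("endpoint", "grid")) {
  mean_mode <- match.arg(mean_mode)
  if (!inherits(base_config, "ddm_config")) {
    ddm_stop("'base_config' must be a sim_config", "ddm_invalid_parameter")
  }
  if (!is.numeric(n_grid) || length(n_grid) < 2 || is.unsorted(n_grid) ||
      anyDuplicated(n_grid) || any(n_grid < 1)) {
    ddm_stop("'n_grid' must be >= 2 strictly ascending sizes >= 1",
             "ddm_invalid_parameter")
  }
  C <- source_concentration(source, n_grid)
  s_end <- .ddm_final_dry_mass_cpp(n_grid, C, base_config$s0, params$kappa,
                                   params$alpha, params$Vm, params$Km,
                                   params$r, base_config$steps,
                                   base_config$dt)
  if (anyNA(s_end)) {
    ddm_stop(sprintf("integration failure at n = %g",
                     n_grid[which(is.na(s_end))[1]]),
             "ddm_integration_error")
  }
  M <- s_end / params$DMC
  TM <- n_grid * M
  m <- length(n_grid)
  dd <- if (mean_mode == "endpoint") {
    dd_index(M[1], M[m], n_grid[1], n_grid[m])
  } else {
    dd_index(M[1], M[m], n_grid[1], n_grid[m],
             M_bar = mean(M), n_bar = mean(n_grid))
  }
  structure(data.frame(n = n_grid, M_g = M, TM_g = TM),
            class = c("ddm_density_response", "data.frame"),
            dd_index = dd,
            compensation = classify_compensation(TM[1], TM[m], rel_tol),
            params = params, source = source, base_config = base_config)
}

#' @export
print.ddm_density_response <- function(x, ...) {
  cat(sprintf(
    "Density response over n = %g..%g (%d sizes)\n", x$n[1], x$n[nrow(x)],
    nrow(x)))
  cat(sprintf("  individual mass %.4g -> %.4g g\n", x$M_g[1], x$M_g[nrow(x)]))
  cat(sprintf("  population mass %.4g -> %.4g g\n", x$TM_g[1], x$TM_g[nrow(x)]))
  cat(sprintf("  DD index = %.4g; compensation: %s\n",
              attr(x, "dd_index"), attr(x, "compensation")))
  invisible(x)
}

#' Reference density-response scenario
#'
#' The contour-plot evaluation scenario used to map how the
#' density-dependence index responds to the model parameters: population
#' sizes 1 to 20, a 50-day growth span, constant source concentration
#' 0.1 g cm^-3, `s0 = 3` g and `DMC = 0.16`.
#'
#' @param dt Integration step, h (default 1).
#' @return A list with elements `n_grid`, `config` (a [sim_config()] at
#'   `n = 1`) and `source`.
#' @export
reference_scenario <- function(dt = 1) {
  list(n_grid = 1:20,
       config = sim_config(n = 1, s0 = 3, t0 = 0,
                           duration = days_to_hours(50), dt = dt),
       source = source_model("constant", C0 = 0.1))
}

#' Density-dependence index over a parameter grid
#'
#' Evaluates the DD index on the full factorial grid of the supplied
#' parameter values under the reference scenario (only the endpoint
#' population sizes are simulated, since the endpoint-mean index needs no
#' interior points). Used to probe the monotone response of density
#' dependence to each parameter: DD rises with `kappa` and `Vm`, falls with
#' `alpha` and `Km`, and vanishes at `alpha = 1`.
#'
#' @param alpha,kappa,Vm,Km Numeric vectors of parameter values to cross.
#' @param scenario A list as returned by [reference_scenario()].
#' @param r Respiratory fraction used throughout; default 0.16.
#' @param DMC Dry matter content; default 0.16.
#' @return A data frame with columns `alpha`, `kappa`, `Vm`, `Km`, `dd`.
#' @examples
#' g <- dd_sensitivity_grid(alpha = c(0.2, 1), kappa = 5, Vm = 2e-3,
#'                          Km = 0.01)
#' g$dd[g$alpha == 1] # ~0
#' @export
dd_sensitivity_grid <- function(alpha, kappa, Vm, Km,
                                scenario = reference_scenario(),
                                r = 0.16, DMC = 0.16) {
  grid <- expand.grid(alpha = alpha, kappa = kappa, Vm = Vm, Km = Km,
                      KEEP.OUT.ATTRS = FALSE)
  n_ends <- range(scenario$n_grid)
  C <- source_concentration(scenario$source, n_ends)
  cfg <- scenario$config
  grid$dd <- vapply(seq_len(nrow(grid)), function(i) {
    s_end <- .ddm_final_dry_mass_cpp(n_ends, C, cfg$s0, grid$kappa[i],
                                     grid$alpha[i], grid$Vm[i], grid$Km[i],
                                     r, cfg$steps, cfg$dt)
    M <- s_end / DMC
    dd_index(M[1], M[2], n_ends[1], n_ends[2])
  }, numeric(1))
  grid
}
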
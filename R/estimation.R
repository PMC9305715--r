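#' Observation set for model fitting
#'
#' An observation set holds either a seasonal time series of individual mass
#' at one or more population sizes (`design = "time_series"`) or individual
#' (and optionally population) mass at maturity across a range of population
#' sizes (`design = "maturity_cross_section"`), together with the simulation
#' metadata the fit needs: the organisation level, initial dry mass `s0`,
#' start time `t0`, dry matter content `DMC` and growth span.
#'
#' @param records Data frame with columns `n` (population size),
#'   `individual_mass_g` (fresh mass, g), `time_h` (observation time, h,
#'   required for time series; `NA` for maturity designs) and optionally
#'   `population_mass_g`.
#' @param design `"time_series"` or `"maturity_cross_section"`.
#' @param level Organisation level: one of `"cell"`, `"seed"`,
#'   `"fruit_in_cluster"`, `"fruit_in_plant"`, `"plant"`.
#' @param species Free-text species/cultivar label.
#' @param s0 Individual dry mass at `t0`, g.
#' @param t0 Time at which population size becomes constant, h.
#' @param DMC Dry matter content of the sink tissue.
#' @param duration Growth span, h; observation times must lie in
#'   `[t0, t0 + duration]`.
#' @param dataset_id Short identifier written to serialized tables.
#' @return An object of class `ddm_observations`.
#' @export
observation_set <- function(records,
                            design = c("time_series",
                                       "maturity_cross_section"),
                            level = c("cell", "seed", "fruit_in_cluster",
                                      "fruit_in_plant", "plant"),
                            species = NA_character_, s0, t0 = 0, DMC,
                            duration, dataset_id = "obs") {
  design <- match.arg(design)
  level <- match.arg(level)
  if (!is.data.frame(records) ||
      !all(c("n", "individual_mass_g") %in% names(records))) {
    ddm_stop("'records' needs columns 'n' and 'individual_mass_g'",
             "ddm_invalid_configuration")
  }
  if (!"population_mass_g" %in% names(records)) {
    records$population_mass_g <- NA_real_
  }
  if (!"time_h" %in% names(records)) records$time_h <- NA_real_
  if (any(records$individual_mass_g <= 0) ||
      any(records$population_mass_g <= 0, na.rm = TRUE)) {
    ddm_stop("all masses must be positive", "ddm_invalid_configuration")
  }
  if (design == "time_series") {
    if (anyNA(records$time_h)) {
      ddm_stop("time series require 'time_h' on every record",
               "ddm_invalid_configuration")
    }
    if (any(records$time_h < t0 - 1e-9) ||
        any(records$time_h > t0 + duration + 1e-9)) {
      ddm_stop("observation times must lie within [t0, t0 + duration]",
               "ddm_invalid_configuration")
    }
  } else if (length(unique(records$n)) < 2) {
    ddm_stop("maturity cross-sections need at least 2 distinct n",
             "ddm_invalid_configuration")
  }
  for (nm in c("s0", "t0", "DMC", "duration")) stopifnot_scalar(get(nm), nm)
  structure(list(records = records[c("n", "time_h", "individual_mass_g",
                                     "population_mass_g")],
                 design = design, level = level, species = species,
                 s0 = s0, t0 = t0, DMC = DMC, duration = duration,
                 dataset_id = dataset_id),
            class = "ddm_observations")
}

#' @export
print.ddm_observations <- function(x, ...) {
  cat(sprintf("Observation set '%s' (%s, %s level): %d records, %d sizes\n",
              x$dataset_id, x$design, x$level, nrow(x$records),
              length(unique(x$records$n))))
  invisible(x)
}

#' Write / read observation tables
#'
#' Observation sets travel as a delimited-text pair: a CSV with columns
#' `level`, `dataset_id`, `n`, `time_h` (blank for maturity designs),
#' `individual_mass_g`, `population_mass_g`, plus a JSON sidecar
#' (`<stem>.json`) holding the metadata (`design`, `species`, `s0`, `t0`,
#' `DMC`, `duration`) and, for synthetic data, the generating truth.
#'
#' @param obs A [observation_set()].
#' @param path CSV file path.
#' @param truth Optional list (e.g. generating parameters) stored in the
#'   sidecar for audit.
#' @return `write_observations()` returns `path` invisibly;
#'   `read_observations()` returns a `ddm_observations` object (with the
#'   truth, if present, attached as attribute `"truth"`).
#' @export
write_observations <- function(obs, path, truth = NULL) {
  if (!inherits(obs, "ddm_observations")) {
    ddm_stop("'obs' must be a ddm_observations", "ddm_invalid_configuration")
  }
  tab <- cbind(data.frame(level = obs$level, dataset_id = obs$dataset_id),
               obs$records)
  write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  meta <- list(design = obs$design, level = obs$level,
               species = obs$species, s0 = obs$s0, t0 = obs$t0,
               DMC = obs$DMC, duration = obs$duration,
               dataset_id = obs$dataset_id)
  if (!is.null(truth)) meta$truth <- truth
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.[Cc][Ss][Vv]$", "", path), ".json")

#' @rdname write_observations
#' @param metadata Optional named list overriding / supplying metadata when
#'   no JSON sidecar exists (`design`, `level`, `species`, `s0`, `t0`,
#'   `DMC`, `duration`).
#' @export
read_observations <- function(path, metadata = NULL) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("level", "dataset_id", "n", "individual_mass_g")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    ddm_stop(sprintf("observation table is missing column(s): %s",
                     paste(missing, collapse = ", ")),
             "ddm_invalid_configuration")
  }
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!is.null(metadata)) meta <- modifyList(meta, metadata)
  if (is.null(meta$design)) {
    meta$design <- if (all(is.na(tab$time_h))) "maturity_cross_section"
                   else "time_series"
  }
  for (nm in c("s0", "DMC", "duration")) {
    if (is.null(meta[[nm]])) {
      ddm_stop(sprintf("metadata field '%s' missing (no sidecar; pass 'metadata')",
                       nm), "ddm_invalid_configuration")
    }
  }
  obs <- observation_set(tab[setdiff(names(tab), c("level", "dataset_id"))],
                         design = meta$design, level = tab$level[1],
                         species = if (is.null(meta$species)) NA_character_
                                   else meta$species,
                         s0 = meta$s0,
                         t0 = if (is.null(meta$t0)) 0 else meta$t0,
                         DMC = meta$DMC, duration = meta$duration,
                         dataset_id = tab$dataset_id[1])
  if (!is.null(meta$truth)) attr(obs, "truth") <- meta$truth
  obs
}

#' Relative root mean squared error
#'
#' `RRMSE = sqrt(mean((predicted - observed)^2)) / mean(observed)`: the root
#' mean squared prediction error expressed as a fraction of the observed
#' mean. Smaller values indicate a better fit; it is invariant to a common
#' rescaling of both series.
#'
#' @param predicted,observed Numeric vectors of equal length >= 1.
#' @return Dimensionless non-negative scalar.
#' @examples
#' rrmse(c(3, 3), c(2, 4))  # 1/3
#' @export
rrmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 1) {
    ddm_stop("'predicted' and 'observed' must have equal length >= 1",
             "ddm_invalid_configuration")
  }
  xbar <- mean(observed)
  if (!is.finite(xbar) || xbar <= 0) {
    ddm_stop("undefined RRMSE: observed mean must be positive",
             "ddm_undefined_index")
  }
  sqrt(mean((predicted - observed)^2)) / xbar
}

# Merge candidate parameters with fixed settings into one model
# specification. theta entries override fixed; r/DMC/C0/dt fall back to
# obs metadata and package defaults; a logistic source is used when b and d
# are available (plant-level fits).
resolve_fit_model <- function(theta, obs, fixed = list()) {
  th <- as.list(theta)
  full <- modifyList(list(r = 0.16, DMC = obs$DMC, C0 = 0.1, dt = 1), fixed)
  full <- modifyList(full, th[!vapply(th, is.null, logical(1))])
  full$source <- if (!is.null(full$b) && !is.null(full$d)) {
    source_model("logistic", C0 = full$C0, b = full$b, d = full$d)
  } else {
    source_model("constant", C0 = full$C0)
  }
  full
}

#' Model-predicted masses for an observation set
#'
#' Simulates the growth model at every distinct population size in the
#' observation set and returns the predicted individual fresh mass aligned
#' with the observation records: at the recorded times for time series, at
#' the final integration node for maturity cross-sections.
#'
#' @param theta Named list/vector of model parameters (`kappa`, `alpha`,
#'   `Vm`, `Km`, optionally `b`, `d`); anything not supplied is taken from
#'   `fixed` or defaults.
#' @param obs A [observation_set()].
#' @param fixed Named list of fixed settings (`r`, `DMC`, `C0`, `dt`, `b`,
#'   `d`).
#' @return Numeric vector of predicted `individual_mass_g`, one per record
#'   (may contain non-finite values if the integration diverges).
#' @export
predicted_masses <- function(theta, obs, fixed = list()) {
  mod <- resolve_fit_model(theta, obs, fixed)
  rec <- obs$records
  steps <- as.integer(round(obs$duration / mod$dt))
  n_distinct <- unique(rec$n)
  Cs <- source_concentration(mod$source, n_distinct)
  if (obs$design == "maturity_cross_section") {
    s_end <- .ddm_final_dry_mass_cpp(n_distinct, Cs, obs$s0, mod$kappa,
                                     mod$alpha, mod$Vm, mod$Km, mod$r,
                                     steps, mod$dt)
    (s_end / mod$DMC)[match(rec$n, n_distinct)]
  } else {
    pred <- numeric(nrow(rec))
    for (j in seq_along(n_distinct)) {
      res <- .ddm_euler_cpp(n_distinct[j], obs$s0, Cs[j], mod$kappa,
                            mod$alpha, mod$Vm, mod$Km, mod$r, steps, mod$dt)
      rows <- which(rec$n == n_distinct[j])
      idx <- round((rec$time_h[rows] - obs$t0) / mod$dt) + 1L
      pred[rows] <- res$s[idx] / mod$DMC
    }
    pred
  }
}

#' Sum-of-squared-errors objective for parameter estimation
#'
#' The genetic algorithm's performance index: squared deviations between
#' model-predicted and observed individual fresh masses, accumulated over
#' all records. Population-mass residuals (when recorded) can be included;
#' they are first divided by `n` so that they live on the individual-mass
#' scale and neither term dominates by units alone. A failed integration
#' returns the finite penalty `1e12` g^2 rather than an error, so the
#' optimiser can continue.
#'
#' @inheritParams predicted_masses
#' @param include_population Include population-mass residuals (scaled by
#'   `1/n`)? Default `FALSE`: the reference protocol fits individual masses.
#' @return SSE in g^2 (finite).
#' @export
sse_objective <- function(theta, obs, fixed = list(),
                          include_population = FALSE) {
  pred <- predicted_masses(theta, obs, fixed)
  sse <- sum((pred - obs$records$individual_mass_g)^2)
  if (include_population) {
    keep <- !is.na(obs$records$population_mass_g)
    if (any(keep)) {
      sse <- sse + sum(((obs$records$n[keep] * pred[keep] -
                           obs$records$population_mass_g[keep]) /
                          obs$records$n[keep])^2)
    }
  }
  if (!is.finite(sse)) 1e12 else sse
}

#' Default estimation bounds
#'
#' Box constraints mirroring the ranges estimated across fruit systems:
#' `alpha` in `[1e-4, 1]`, `kappa` in `[1e-7, 1e4]` cm^6 g^-1 h^-1, `Vm` in
#' `[1e-5, 1e-2]` h^-1, `Km` in `[1e-6, 0.1]` g cm^-3. Plant-level sets add
#' the source-decline parameters `b` in `[0, 1]` and `d` spanning the
#' observed population sizes.
#'
#' @param obs A [observation_set()].
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function(obs) {
  b <- list(kappa = c(1e-7, 1e4), alpha = c(1e-4, 1),
            Vm = c(1e-5, 1e-2), Km = c(1e-6, 0.1))
  if (obs$level == "plant") {
    b$b <- c(0, 1)
    b$d <- range(obs$records$n)
  }
  b
}

# kappa, Vm and Km each span >= 3 decades; the GA searches them in log10
# space so that mixing operators act scale-free. alpha, b and d stay linear.
LOG_SCALE_PARAMS <- c("kappa", "Vm", "Km")

#' Fit model parameters by genetic algorithm
#'
#' Minimises [sse_objective()] with the real-coded GA of [ga_minimize()].
#' `kappa`, `Vm` and `Km` are searched in log10 space; `alpha` (and, for
#' plant-level sets, `b` and `d`) in linear space. The result is fully
#' reproducible given `seed`.
#'
#' @param obs A [observation_set()].
#' @param bounds Named list of `c(lower, upper)` per fitted parameter;
#'   default [default_bounds()].
#' @param ga_settings Named list overriding [ga_minimize()] controls
#'   (`pop_size`, `generations`, `mutation_prob`, `mutation_sd`, `elitism`,
#'   `blx_alpha`).
#' @param seed Integer seed for this run.
#' @param fixed Fixed settings forwarded to the objective.
#' @param include_population Forwarded to [sse_objective()].
#' @param restart_index Bookkeeping label used by [multi_start_fit()].
#' @return An object of class `ddm_fit`: `params` (named list, natural
#'   scale), `sse` (g^2), `rrmse`, `seed`, `restart_index`,
#'   `n_evaluations`, `best_history`.
#' @export
fit_ga <- function(obs, bounds = default_bounds(obs), ga_settings = list(),
                   seed = NULL, fixed = list(), include_population = FALSE,
                   restart_index = 1L) {
  if (!inherits(obs, "ddm_observations")) {
    ddm_stop("'obs' must be a ddm_observations", "ddm_invalid_configuration")
  }
  if (length(bounds) == 0L || is.null(names(bounds)) ||
      any(!nzchar(names(bounds)))) {
    ddm_stop("'bounds' must be a non-empty named list",
             "ddm_invalid_configuration")
  }
  for (nm in names(bounds)) {
    bb <- bounds[[nm]]
    if (!is.numeric(bb) || length(bb) != 2 || any(!is.finite(bb)) ||
        bb[1] >= bb[2]) {
      ddm_stop(sprintf("bounds for '%s' must be finite with lower < upper",
                       nm), "ddm_invalid_configuration")
    }
    if (nm %in% LOG_SCALE_PARAMS && bb[1] <= 0) {
      ddm_stop(sprintf("bounds for '%s' must be positive", nm),
               "ddm_invalid_configuration")
    }
  }
  par_names <- names(bounds)
  log_mask <- par_names %in% LOG_SCALE_PARAMS
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  lower[log_mask] <- log10(lower[log_mask])
  upper[log_mask] <- log10(upper[log_mask])

  decode <- function(x) {
    x[log_mask] <- 10^x[log_mask]
    as.list(setNames(x, par_names))
  }
  objective <- function(x) {
    sse_objective(decode(x), obs, fixed, include_population)
  }
  ga_args <- c(list(fn = objective, lower = lower, upper = upper,
                    seed = seed), ga_settings)
  run <- do.call(ga_minimize, ga_args)
  best <- decode(run$par)
  pred <- predicted_masses(best, obs, fixed)
  structure(list(params = best, sse = run$value,
                 rrmse = rrmse(pred, obs$records$individual_mass_g),
                 seed = seed, restart_index = restart_index,
                 n_evaluations = run$n_evaluations,
                 best_history = run$best_history),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("GA fit (restart %s, seed %s): SSE = %.4g g^2, RRMSE = %.4g\n",
              x$restart_index, x$seed, x$sse, x$rrmse))
  cat("  ", paste(sprintf("%s = %.4g", names(x$params),
                          unlist(x$params)), collapse = ", "), "\n")
  invisible(x)
}

#' Multi-restart genetic-algorithm estimation
#'
#' Runs [fit_ga()] `n_restarts` times (the reference protocol uses at least
#' 15) with distinct seeds derived from `master_seed` by fixed offsets, so
#' that no two restarts share a random stream. All restarts are retained for
#' ensemble analysis; the fit with the smallest SSE is flagged as best.
#'
#' @inheritParams fit_ga
#' @param n_restarts Number of independent GA runs; default 15.
#' @param master_seed Integer; restart `i` uses seed `master_seed + i`
#'   (must stay below 2^31).
#' @return An object of class `ddm_multifit`: `fits` (list of `ddm_fit`),
#'   `best_index`, `best`, `seeds`.
#' @export
multi_start_fit <- function(obs, bounds = default_bounds(obs),
                            ga_settings = list(), n_restarts = 15,
                            master_seed = 1, fixed = list(),
                            include_population = FALSE) {
  if (n_restarts < 1) {
    ddm_stop("'n_restarts' must be >= 1", "ddm_invalid_configuration")
  }
  if (master_seed + n_restarts >= 2^31) {
    ddm_stop("'master_seed' too large: derived seeds must stay below 2^31",
             "ddm_invalid_configuration")
  }
  seeds <- master_seed + seq_len(n_restarts)
  fits <- lapply(seq_len(n_restarts), function(i) {
    fit_ga(obs, bounds = bounds, ga_settings = ga_settings, seed = seeds[i],
           fixed = fixed, include_population = include_population,
           restart_index = i)
  })
  sses <- vapply(fits, `[[`, numeric(1), "sse")
  best <- which.min(sses)
  structure(list(fits = fits, best_index = best, best = fits[[best]],
                 seeds = seeds),
            class = "ddm_multifit")
}

#' @export
print.ddm_multifit <- function(x, ...) {
  cat(sprintf("Multi-restart fit: %d restarts, best is restart %d\n",
              length(x$fits), x$best_index))
  print(x$best)
  invisible(x)
}

#' Parameter table of a multi-restart fit
#'
#' @param x A `ddm_multifit`.
#' @return Data frame with one row per restart: seed, fitted parameters,
#'   SSE, RRMSE and a `best` flag.
#' @export
parameter_table <- function(x) {
  if (!inherits(x, "ddm_multifit")) {
    ddm_stop("'x' must be a ddm_multifit", "ddm_invalid_configuration")
  }
  rows <- lapply(seq_along(x$fits), function(i) {
    f <- x$fits[[i]]
    cbind(data.frame(restart = i, seed = f$seed),
          as.data.frame(f$params),
          data.frame(sse = f$sse, rrmse = f$rrmse,
                     best = i == x$best_index))
  })
  do.call(rbind, rows)
}
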
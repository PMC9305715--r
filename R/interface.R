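# Pipeline entry points: each wraps one analysis stage, reads a plain-list
# or JSON config, writes CSV/JSON outputs, and logs version, config hash,
# seed and wall time. Outputs are deterministic functions of (config, seed).

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      ddm_stop(sprintf("config file not found: %s", config),
               "ddm_invalid_configuration")
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    ddm_stop("'config' must be a list or a JSON file path",
             "ddm_invalid_configuration")
  }
  config
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

ddm_log <- function(config, seed, started) {
  message(sprintf(
    "[ddmfruit %s] config %s | seed %s | %.2f s elapsed",
    as.character(packageVersion("ddmfruit")), config_hash(config),
    if (is.null(seed)) "none" else seed,
    as.numeric(proc.time()["elapsed"]) - started))
}

config_params <- function(config) {
  p <- config$params
  do.call(ddm_params, p[intersect(names(p),
                                  c("kappa", "alpha", "Vm", "Km", "r",
                                    "DMC"))])
}

config_source <- function(config) {
  s <- config$source
  if (is.null(s)) return(source_model("constant"))
  do.call(source_model, s[intersect(names(s), c("mode", "C0", "b", "d"))])
}

# Duration may be given in hours (duration_h) or, with an explicit field,
# in days (duration_days); all internal time is hourly.
config_sim <- function(config, n = NULL) {
  s <- config$sim
  duration <- if (!is.null(s$duration_days)) days_to_hours(s$duration_days)
              else s$duration_h
  sim_config(n = if (is.null(n)) s$n else n, s0 = s$s0,
             t0 = if (is.null(s$t0)) 0 else s$t0,
             duration = duration,
             dt = if (is.null(s$dt_h)) 1 else s$dt_h)
}

#' Run one growth simulation from a configuration
#'
#' Config blocks: `params` (kappa, alpha, Vm, Km, r, DMC), `source` (mode,
#' C0, b, d) and `sim` (n, s0, t0, duration_h or duration_days, dt_h).
#' Writes `trajectory.csv` with columns `time_h`, `s_g`, `Cf_g_per_cm3`,
#' `U_g_per_h`, `M_g`, `TM_g`.
#'
#' @param config List or JSON file path.
#' @param out_dir Output directory (created if missing).
#' @return Path of the written CSV, invisibly.
#' @export
run_simulate <- function(config, out_dir = ".") {
  started <- as.numeric(proc.time()["elapsed"])
  config <- read_run_config(config)
  tr <- simulate_growth(config_params(config), config_source(config),
                        config_sim(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "trajectory.csv")
  write.csv(as.data.frame(tr), path, row.names = FALSE, quote = FALSE)
  ddm_log(config, config$seed, started)
  invisible(path)
}

#' Run a density-response analysis from a configuration
#'
#' As [run_simulate()], plus an `n_grid` block (vector of population sizes,
#' or `list(from, to, length)` for an evenly spaced grid). Writes
#' `response.csv` (`n`, `M_g`, `TM_g`) and `response_summary.json` with the
#' density-dependence index and the compensation class.
#'
#' @inheritParams run_simulate
#' @return Named character vector of the two written paths, invisibly.
#' @export
run_respond <- function(config, out_dir = ".") {
  started <- as.numeric(proc.time()["elapsed"])
  config <- read_run_config(config)
  ng <- config$n_grid
  if (is.list(ng)) ng <- seq(ng$from, ng$to, length.out = ng$length)
  resp <- density_response(config_params(config), config_source(config),
                           config_sim(config, n = ng[1]), n_grid = ng,
                           rel_tol = if (is.null(config$rel_tol)) 0.05
                                     else config$rel_tol)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "response.csv")
  write.csv(as.data.frame(resp), csv, row.names = FALSE, quote = FALSE)
  js <- file.path(out_dir, "response_summary.json")
  jsonlite::write_json(
    list(dd_index = attr(resp, "dd_index"),
         compensation = attr(resp, "compensation"),
         n_min = resp$n[1], n_max = resp$n[nrow(resp)],
         M_at_n_min_g = resp$M_g[1], M_at_n_max_g = resp$M_g[nrow(resp)],
         TM_at_n_min_g = resp$TM_g[1], TM_at_n_max_g = resp$TM_g[nrow(resp)]),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ddm_log(config, config$seed, started)
  invisible(c(csv = csv, summary = js))
}

#' Summarise density dependence of an existing response table
#'
#' Reads a `response.csv` written by [run_respond()] (columns `n`, `M_g`,
#' `TM_g`) and writes `dd_summary.json` with the DD index and compensation
#' class of its endpoints.
#'
#' @param response_csv Path to the response table.
#' @param out_dir Output directory.
#' @param rel_tol Tolerance for [classify_compensation()].
#' @return Path of the written JSON, invisibly.
#' @export
run_dd <- function(response_csv, out_dir = ".", rel_tol = 0.05) {
  tab <- read.csv(response_csv)
  missing <- setdiff(c("n", "M_g", "TM_g"), names(tab))
  if (length(missing)) {
    ddm_stop(sprintf("response table is missing column(s): %s",
                     paste(missing, collapse = ", ")),
             "ddm_invalid_configuration")
  }
  m <- nrow(tab)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  js <- file.path(out_dir, "dd_summary.json")
  jsonlite::write_json(
    list(dd_index = dd_index(tab$M_g[1], tab$M_g[m], tab$n[1], tab$n[m]),
         compensation = classify_compensation(tab$TM_g[1], tab$TM_g[m],
                                              rel_tol)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(js)
}

#' Run a multi-restart fit from a configuration
#'
#' Config blocks: `fit` (`n_restarts`, default 15; `include_population`),
#' `bounds` (named lists of two-element lower/upper pairs), `ga` (GA
#' controls), `fixed` (fixed model settings) and `seed` (master seed;
#' required for this stochastic command, default 1 with a logged note).
#' Writes `fits.json` (all restarts plus the best) and
#' `parameter_table.csv`.
#'
#' @inheritParams run_simulate
#' @param observations_csv Path to an observation CSV (see
#'   [read_observations()]); schema violations are reported with the
#'   offending column names.
#' @return Named character vector of written paths, invisibly.
#' @export
run_fit <- function(config, observations_csv, out_dir = ".") {
  started <- as.numeric(proc.time()["elapsed"])
  config <- read_run_config(config)
  obs <- read_observations(observations_csv, metadata = config$metadata)
  seed <- if (is.null(config$seed)) 1 else config$seed
  bounds <- default_bounds(obs)
  if (!is.null(config$bounds)) {
    bounds <- modifyList(bounds, lapply(config$bounds, unlist))
  }
  fit_cfg <- config$fit
  ms <- multi_start_fit(
    obs, bounds = bounds,
    ga_settings = if (is.null(config$ga)) list() else config$ga,
    n_restarts = if (is.null(fit_cfg$n_restarts)) 15 else fit_cfg$n_restarts,
    master_seed = seed,
    fixed = if (is.null(config$fixed)) list() else config$fixed,
    include_population = isTRUE(fit_cfg$include_population))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- parameter_table(ms)
  csv <- file.path(out_dir, "parameter_table.csv")
  write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  js <- file.path(out_dir, "fits.json")
  jsonlite::write_json(
    list(dataset_id = obs$dataset_id, master_seed = seed,
         restarts = lapply(ms$fits, function(f) {
           f$best_history <- NULL
           unclass(f)
         }),
         best_restart = ms$best_index),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ddm_log(config, seed, started)
  invisible(c(table = csv, fits = js))
}

#' Generate and write the synthetic fixture suite
#'
#' Config fields: `seed` (master seed, default 1) and `noise`
#' (`list(kind, cv)`, default lognormal with cv 0.1). Writes one
#' observation CSV plus truth/metadata JSON sidecar per fixture into
#' `out_dir`.
#'
#' @inheritParams run_simulate
#' @return Character vector of the written CSV paths, invisibly.
#' @export
run_synth <- function(config = list(), out_dir = ".") {
  started <- as.numeric(proc.time()["elapsed"])
  config <- read_run_config(config)
  seed <- if (is.null(config$seed)) 1 else config$seed
  noise <- if (is.null(config$noise)) noise_model("lognormal", cv = 0.1)
           else do.call(noise_model, config$noise)
  suite <- make_fixture_suite(seed, noise)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(suite))
  for (i in seq_along(suite)) {
    paths[i] <- file.path(out_dir, paste0(names(suite)[i], ".csv"))
    write_observations(suite[[i]]$observations, paths[i],
                       truth = suite[[i]]$truth)
  }
  ddm_log(config, seed, started)
  invisible(paths)
}
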
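#' Observation noise model
#'
#' Synthetic observations perturb model masses with multiplicative
#' lognormal noise: masses are positive and their errors scale with size.
#' The lognormal factor has unit mean and coefficient of variation `cv`
#' (`sdlog = sqrt(log(1 + cv^2))`, `meanlog = -sdlog^2 / 2`), so noisy data
#' are unbiased on the natural scale.
#'
#' @param kind `"none"` (observations equal model output exactly) or
#'   `"lognormal"` (multiplicative lognormal).
#' @param cv Coefficient of variation of the noise factor (>= 0); default
#'   0.10, a typical replicate-level spread for fruit growth data.
#' @return An object of class `ddm_noise`.
#' @export
noise_model <- function(kind = c("none", "lognormal"), cv = 0.1) {
  kind <- match.arg(kind)
  stopifnot_scalar(cv, "cv")
  if (cv < 0) ddm_stop("'cv' must be >= 0", "ddm_invalid_parameter")
  structure(list(kind = kind, cv = cv), class = "ddm_noise")
}

apply_noise <- function(x, noise) {
  if (noise$kind == "none" || noise$cv == 0) return(x)
  sdlog <- sqrt(log1p(noise$cv^2))
  x * rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Typical study conditions per organisation level
#'
#' Reference presets for the five levels at which sink populations are
#' observed, with the population-size ranges reported for fruit systems:
#' 30-120 million cells per apple fruit, 100-1400 seeds per kiwifruit,
#' tens of fruits per cluster (grape, dogwood), 700-30000 fruits per plant
#' (St. Lucie's cherry) and 400-2000 trees per hectare (peach orchards).
#' `s0`, `DMC` and duration are plausible representative values for the
#' exemplar species.
#'
#' @return Data frame with one row per level: `level`, `species_example`,
#'   `n_min`, `n_max`, `design`, `s0_g`, `DMC`, `duration_h`.
#' @export
level_presets <- function() {
  data.frame(
    level = c("cell", "seed", "fruit_in_cluster", "fruit_in_plant",
              "plant"),
    species_example = c("apple", "kiwifruit", "grape",
                        "St. Lucie's cherry", "peach"),
    n_min = c(30e6, 100, 10, 700, 400),
    n_max = c(120e6, 1400, 100, 30000, 2000),
    design = c("time_series", "maturity_cross_section",
               "maturity_cross_section", "maturity_cross_section",
               "maturity_cross_section"),
    s0_g = c(5e-8, 5e-3, 0.05, 0.3, 100),
    DMC = c(0.15, 0.17, 0.2, 0.14, 0.13),
    duration_h = c(1200, 1440, 1200, 1800, 2400)
  )
}

#' Generate a synthetic observation set
#'
#' Simulates the growth model at every design point, applies the noise
#' model to the individual masses (population mass is `n` times the noisy
#' individual mass) and returns the observation set together with an audit
#' record of the generating truth and seed.
#'
#' @param params A [ddm_params()]: the generating truth.
#' @param source A [source_model()].
#' @param design A list: `type` (`"time_series"` or
#'   `"maturity_cross_section"`), `n` (population sizes), and for time
#'   series `times` (hours, within `[t0, t0 + duration]`, shared across
#'   sizes).
#' @param level,species,s0,t0,DMC,duration,dataset_id Metadata stored in
#'   the observation set (see [observation_set()]). `DMC` defaults to the
#'   truth's.
#' @param noise A [noise_model()].
#' @param seed Integer seed; two calls with the same seed return identical
#'   sets.
#' @return A list with elements `observations` (a `ddm_observations`) and
#'   `truth` (generating parameters, source, noise, seed).
#' @export
generate_observations <- function(params, source, design,
                                  noise = noise_model("none"), seed = NULL,
                                  level, species = NA_character_, s0,
                                  t0 = 0, DMC = params$DMC, duration,
                                  dataset_id = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  type <- match.arg(design$type, c("time_series", "maturity_cross_section"))
  n_values <- design$n
  rows <- list()
  for (n in n_values) {
    cfg <- sim_config(n = n, s0 = s0, t0 = t0, duration = duration, dt = 1)
    tr <- simulate_growth(params, source, cfg)
    if (type == "time_series") {
      idx <- round(design$times - t0) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, time_h = design$times, individual_mass_g = tr$s_g[idx] / DMC)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, time_h = NA_real_,
        individual_mass_g = tr$s_g[nrow(tr)] / DMC)
    }
  }
  rec <- do.call(rbind, rows)
  rec$individual_mass_g <- apply_noise(rec$individual_mass_g, noise)
  rec$population_mass_g <- rec$n * rec$individual_mass_g
  obs <- observation_set(rec, design = type, level = level,
                         species = species, s0 = s0, t0 = t0, DMC = DMC,
                         duration = duration, dataset_id = dataset_id)
  truth <- list(params = unclass(params),
                source = unclass(source),
                noise = unclass(noise), seed = seed)
  list(observations = obs, truth = truth)
}

# Study conditions of the 12-fixture suite: three tomato cell time series
# (truss-position and fruit-load designs), peach mesocarp cells at two
# fruit loads, seed cross-sections (two apple cultivars, sarsaparilla),
# cluster cross-sections (grape; dogwood with alpha = 1, hence no density
# dependence), fruit-per-plant cross-sections (peach, apple) and a
# peach-orchard plant-density cross-section with a logistic source. Truths
# sit inside the estimated per-level parameter ranges (alpha 3e-4..1,
# kappa 1.2e-6..3e3, Vm 1e-4..8.13e-3 h^-1, Km 1e-5..0.09 g cm^-3).
fixture_specs <- function() {
  season <- seq(120, 1200, by = 120)
  list(
    tomato_raissa_cells = list(
      level = "cell", species = "tomato Raissa",
      params = ddm_params(kappa = 1e-4, alpha = 0.55, Vm = 2e-3, Km = 0.01,
                          DMC = 0.06),
      source = source_model("constant"),
      design = list(type = "time_series", n = c(5.7e6, 6.4e6, 7.2e6),
                    times = season),
      s0 = 5e-8, duration = 1200),
    tomato_cervil_cells = list(
      level = "cell", species = "tomato Cervil",
      params = ddm_params(kappa = 1e-4, alpha = 0.55, Vm = 2.5e-3, Km = 0.012,
                          DMC = 0.08),
      source = source_model("constant"),
      design = list(type = "time_series", n = c(8e6, 30e6), times = season),
      s0 = 4e-8, duration = 1200),
    tomato_levovil_cells = list(
      level = "cell", species = "tomato Levovil",
      params = ddm_params(kappa = 2e-4, alpha = 0.5, Vm = 2e-3, Km = 0.01,
                          DMC = 0.06),
      source = source_model("constant"),
      design = list(type = "time_series", n = c(17e6, 43e6), times = season),
      s0 = 6e-8, duration = 1200),
    peach_mesocarp_cells = list(
      level = "cell", species = "peach Alexandra",
      params = ddm_params(kappa = 5e-4, alpha = 0.5, Vm = 2e-3, Km = 0.015,
                          DMC = 0.12),
      source = source_model("constant"),
      design = list(type = "maturity_cross_section",
                    n = c(1e6, 1.5e6, 2e6, 3e6, 4e6, 5e6)),
      s0 = 2e-7, duration = 2000),
    apple_seeds_royalgala = list(
      level = "seed", species = "apple Royal Gala",
      params = ddm_params(kappa = 1.5, alpha = 0.05, Vm = 6e-3, Km = 5e-3,
                          DMC = 0.15),
      source = source_model("constant"),
      design = list(type = "maturity_cross_section",
                    n = c(2, 4, 6, 8, 10, 12)),
      s0 = 0.2, duration = 2000),
    apple_seeds_grannysmith = list(
      level = "seed", species = "apple Granny Smith",
      params = ddm_params(kappa = 1.2, alpha = 0.05, Vm = 5e-3, Km = 5e-3,
                          DMC = 0.24),
      source = source_model("constant"),
      design = list(type = "maturity_cross_section",
                    n = c(2, 4, 6, 8, 10, 12)),
      s0 = 0.2, duration = 2000),
    sarsaparilla_seeds = list(
      level = "seed", species = "sarsaparilla",
      params = ddm_params(kappa = 5e-3, alpha = 0.05, Vm = 6e-3, Km = 5e-3,
                          DMC = 0.2),
      source = source_model("constant"),
      design = list(type = "maturity_cross_section", n = c(1, 2, 3)),
      s0 = 5e-3, duration = 1500),
    grape_cluster = list(
      level = "fruit_in_cluster", species = "grape Muscat",
      params = ddm_params(kappa = 0.1, alpha = 0.85, Vm = 4e-3, Km = 0.02,
                          DMC = 0.2),
      source = source_model("constant"),
      design = list(type = "maturity_cross_section",
                    n = c(10, 20, 40, 60, 80, 100)),
      s0 = 0.02, duration = 1200),
    dogwood_cluster = list(
      level = "fruit_in_cluster", species = "common dogwood",
      params = ddm_params(kappa = 0.05, alpha = 1, Vm = 3.5e-3, Km = 0.02,
                          DMC = 0.2),
      source = source_model("constant"),
      design = list(type = "maturity_cross_section",
                    n = c(10, 15, 20, 30, 40)),
      s0 = 5e-3, duration = 1200),
    peach_fruits_plant = list(
      level = "fruit_in_plant", species = "peach Suncrest",
      params = ddm_params(kappa = 50, alpha = 0.4, Vm = 2.5e-3, Km = 0.02,
                          DMC = 0.13),
      source = source_model("constant"),
      design = list(type = "maturity_cross_section",
                    n = c(100, 200, 400, 600, 800, 1000)),
      s0 = 1, duration = 2400),
    apple_fruits_plant = list(
      level = "fruit_in_plant", species = "apple Summerred",
      params = ddm_params(kappa = 60, alpha = 0.4, Vm = 2e-3, Km = 0.015,
                          DMC = 0.15),
      source = source_model("constant"),
      design = list(type = "maturity_cross_section",
                    n = c(200, 400, 700, 1000, 1300, 1500)),
      s0 = 1, duration = 2400),
    peach_orchard_plants = list(
      level = "plant", species = "peach Yanco Queen",
      params = ddm_params(kappa = 1000, alpha = 0.9, Vm = 5e-3, Km = 5e-3,
                          DMC = 0.13),
      source = source_model("logistic", C0 = 0.1, b = 0.0025, d = 1200),
      design = list(type = "maturity_cross_section",
                    n = c(400, 700, 1000, 1200, 1400, 1600, 1800, 2000)),
      s0 = 200, duration = 2400)
  )
}

#' Generate the 12-dataset synthetic fixture suite
#'
#' Builds one synthetic observation set per dataset of the reference study
#' design: tomato cell time series for three cultivars (truss-position and
#' fruit-load designs), a peach mesocarp-cell cross-section, seed
#' cross-sections for two apple cultivars and sarsaparilla, grape and
#' dogwood cluster cross-sections (the dogwood truth has `alpha = 1`, i.e.
#' no density dependence), peach and apple fruit-per-plant cross-sections,
#' and a peach-orchard plant-density cross-section driven by a logistic
#' source. Each fixture carries its generating truth for audit; all data
#' are synthetic.
#'
#' @param master_seed Integer; fixture `i` derives its seed as
#'   `master_seed + 1000 + i` (keep `master_seed` below 2^31 - 2000).
#' @param noise A [noise_model()]; default multiplicative lognormal with
#'   `cv = 0.1`. Use `noise_model("none")` for exact model output.
#' @return Named list of 12 elements, each a list with `observations` and
#'   `truth` (see [generate_observations()]).
#' @examples
#' suite <- make_fixture_suite(1, noise_model("none"))
#' names(suite)
#' @export
make_fixture_suite <- function(master_seed = 1,
                               noise = noise_model("lognormal", cv = 0.1)) {
  stopifnot_scalar(master_seed, "master_seed")
  if (master_seed + 2000 >= 2^31) {
    ddm_stop("'master_seed' too large: derived seeds must stay below 2^31",
             "ddm_invalid_configuration")
  }
  specs <- fixture_specs()
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    out[[i]] <- generate_observations(
      sp$params, sp$source, sp$design, noise = noise,
      seed = as.integer(master_seed + 1000 + i),
      level = sp$level, species = sp$species, s0 = sp$s0, t0 = 0,
      DMC = sp$params$DMC, duration = sp$duration,
      dataset_id = names(specs)[i])
  }
  out
}
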
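test_that("RRMSE definition and scale invariance", {
  expect_equal(rrmse(c(2, 4), c(2, 4)), 0)
  expect_equal(rrmse(c(3, 3), c(2, 4)), 1 / 3)
  x <- c(1.2, 3.4, 5.6)
  y <- c(1.5, 3.0, 6.0)
  expect_equal(rrmse(10 * x, 10 * y), rrmse(x, y))
  expect_error(rrmse(c(1, 2), c(-1, 1)), class = "ddm_undefined_index")
  expect_error(rrmse(1:3, 1:2), class = "ddm_invalid_configuration")
})

test_that("observation sets validate their records", {
  fx <- tiny_fixture()
  expect_s3_class(fx$observations, "ddm_observations")
  bad <- fx$observations$records
  bad$individual_mass_g[1] <- -1
  expect_error(observation_set(bad, design = "maturity_cross_section",
                               level = "seed", s0 = 5e-3, DMC = 0.2,
                               duration = 600),
               class = "ddm_invalid_configuration")
  one_n <- fx$observations$records[fx$observations$records$n == 1, ]
  expect_error(observation_set(one_n, design = "maturity_cross_section",
                               level = "seed", s0 = 5e-3, DMC = 0.2,
                               duration = 600),
               class = "ddm_invalid_configuration")
})

test_that("observation tables round-trip through CSV + JSON sidecar", {
  fx <- tiny_fixture()
  path <- file.path(tempdir(), "tiny.csv")
  write_observations(fx$observations, path, truth = fx$truth)
  back <- read_observations(path)
  expect_equal(back$records$individual_mass_g,
               fx$observations$records$individual_mass_g)
  expect_equal(back$DMC, 0.2)
  expect_equal(back$design, "maturity_cross_section")
  expect_equal(attr(back, "truth")$params$Vm, 6e-3)
  # schema violations name the missing column
  tab <- read.csv(path)
  tab$individual_mass_g <- NULL
  path2 <- file.path(tempdir(), "broken.csv")
  write.csv(tab, path2, row.names = FALSE)
  expect_error(read_observations(path2), "individual_mass_g",
               class = "ddm_invalid_configuration")
})

test_that("SSE objective is exact at the generating truth and grows away", {
  fx <- tiny_fixture()
  obs <- fx$observations
  truth <- fx$truth$params[c("kappa", "alpha", "Vm", "Km")]
  scale <- sum(obs$records$individual_mass_g^2)
  expect_lt(sse_objective(truth, obs), 1e-12 * scale)
  perturbed <- truth
  perturbed$kappa <- truth$kappa * 10
  expect_gt(sse_objective(perturbed, obs), sse_objective(truth, obs))
  perturbed2 <- truth
  perturbed2$Vm <- truth$Vm / 5
  expect_gt(sse_objective(perturbed2, obs), sse_objective(truth, obs))
})

test_that("SSE objective equals a record-by-record re-accumulation", {
  fx <- tiny_fixture()
  obs <- fx$observations
  theta <- list(kappa = 3e-3, alpha = 0.1, Vm = 4e-3, Km = 8e-3)
  # brute-force oracle: one full simulation per record
  sse_oracle <- 0
  for (i in seq_len(nrow(obs$records))) {
    tr <- simulate_growth(
      ddm_params(theta$kappa, theta$alpha, theta$Vm, theta$Km,
                 DMC = obs$DMC),
      source_model("constant"),
      sim_config(n = obs$records$n[i], s0 = obs$s0,
                 duration = obs$duration))
    pred <- tr$M_g[nrow(tr)]
    sse_oracle <- sse_oracle +
      (pred - obs$records$individual_mass_g[i])^2
  }
  expect_equal(sse_objective(theta, obs), sse_oracle, tolerance = 1e-12)
  # deterministic: repeated evaluation is bit-identical
  expect_identical(sse_objective(theta, obs), sse_objective(theta, obs))
})

test_that("SSE objective covers time series at the recorded times", {
  spec <- ddmfruit:::fixture_specs()$tomato_raissa_cells
  fx <- generate_observations(spec$params, spec$source, spec$design,
                              noise = noise_model("none"), seed = 3,
                              level = spec$level, s0 = spec$s0,
                              duration = spec$duration)
  truth <- as.list(spec$params)[c("kappa", "alpha", "Vm", "Km")]
  expect_lt(sse_objective(truth, fx$observations),
            1e-12 * sum(fx$observations$records$individual_mass_g^2))
})

test_that("integration blow-ups yield the finite GA penalty", {
  fx <- tiny_fixture()
  theta <- list(kappa = 1e300, alpha = 1, Vm = 1e-3, Km = 1e-3)
  expect_identical(sse_objective(theta, fx$observations), 1e12)
})

test_that("GA fit is reproducible and monotonically improving", {
  fx <- tiny_fixture()
  gs <- list(pop_size = 20, generations = 40)
  f1 <- fit_ga(fx$observations, ga_settings = gs, seed = 7)
  f2 <- fit_ga(fx$observations, ga_settings = gs, seed = 7)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$sse, f2$sse)
  expect_true(all(diff(f1$best_history) <= 0))
  expect_equal(f1$n_evaluations, 20 + 40 * 18)
  expect_error(fit_ga(fx$observations, bounds = list(kappa = c(2, 1))),
               class = "ddm_invalid_configuration")
  expect_error(fit_ga(fx$observations, bounds = list()),
               class = "ddm_invalid_configuration")
})

test_that("multi-restart fitting keeps all restarts and flags the best", {
  fx <- tiny_fixture()
  gs <- list(pop_size = 20, generations = 25)
  ms <- multi_start_fit(fx$observations, ga_settings = gs, n_restarts = 4,
                        master_seed = 5)
  expect_length(ms$fits, 4)
  sses <- vapply(ms$fits, `[[`, numeric(1), "sse")
  expect_equal(ms$best$sse, min(sses))
  expect_equal(length(unique(ms$seeds)), 4)
  # distinct seeds give distinct search trajectories
  expect_gt(length(unique(sses)), 1)
  tab <- parameter_table(ms)
  expect_equal(nrow(tab), 4)
  expect_equal(sum(tab$best), 1)
  expect_equal(tab$sse[tab$best], ms$best$sse)
})

test_that("plant-level fits expose the source-decline parameters", {
  spec <- ddmfruit:::fixture_specs()$peach_orchard_plants
  fx <- generate_observations(spec$params, spec$source, spec$design,
                              noise = noise_model("none"), seed = 9,
                              level = spec$level, s0 = spec$s0,
                              duration = spec$duration)
  b <- default_bounds(fx$observations)
  expect_true(all(c("b", "d") %in% names(b)))
  expect_equal(b$d, range(fx$observations$records$n))
  truth <- c(as.list(spec$params)[c("kappa", "alpha", "Vm", "Km")],
             list(b = 0.0025, d = 1200))
  expect_lt(sse_objective(truth, fx$observations),
            1e-12 * sum(fx$observations$records$individual_mass_g^2))
})
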
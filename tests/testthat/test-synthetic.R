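test_that("noise-free generation reproduces the simulator exactly", {
  p <- ddm_params(kappa = 0.1, alpha = 0.85, Vm = 4e-3, Km = 0.02,
                  DMC = 0.2)
  src <- source_model("constant")
  fx <- generate_observations(
    p, src, design = list(type = "maturity_cross_section", n = c(10, 40)),
    noise = noise_model("none"), seed = 1, level = "fruit_in_cluster",
    s0 = 0.02, duration = 1200)
  for (n in c(10, 40)) {
    tr <- simulate_growth(p, src, sim_config(n = n, s0 = 0.02,
                                             duration = 1200))
    expect_identical(
      fx$observations$records$individual_mass_g[
        fx$observations$records$n == n],
      tr$M_g[nrow(tr)])
  }
  expect_identical(fx$observations$records$population_mass_g,
                   fx$observations$records$n *
                     fx$observations$records$individual_mass_g)
})

test_that("lognormal noise has the requested coefficient of variation", {
  set.seed(123)
  x <- ddmfruit:::apply_noise(rep(5, 1e4), noise_model("lognormal", cv = 0.1))
  cv_hat <- sd(x) / mean(x)
  expect_lt(abs(cv_hat / 0.1 - 1), 0.05)
  expect_lt(abs(mean(x) / 5 - 1), 0.01)  # unbiased on the natural scale
  expect_true(all(x > 0))
})

test_that("generation is reproducible under a fixed seed", {
  p <- ddm_params(kappa = 5e-3, alpha = 0.05, Vm = 6e-3, Km = 5e-3,
                  DMC = 0.2)
  args <- list(p, source_model("constant"),
               design = list(type = "maturity_cross_section", n = c(1, 3)),
               noise = noise_model("lognormal", cv = 0.1), seed = 77,
               level = "seed", s0 = 5e-3, duration = 600)
  a <- do.call(generate_observations, args)
  b <- do.call(generate_observations, args)
  expect_identical(a$observations$records, b$observations$records)
  c2 <- args
  c2$seed <- 78
  d <- do.call(generate_observations, c2)
  expect_false(identical(a$observations$records$individual_mass_g,
                         d$observations$records$individual_mass_g))
})

test_that("the fixture suite mirrors the 12-dataset study design", {
  suite <- make_fixture_suite(1, noise_model("none"))
  expect_length(suite, 12)
  levels <- vapply(suite, function(f) f$observations$level, character(1))
  expect_equal(sum(levels == "cell"), 4)
  expect_equal(sum(levels == "seed"), 3)
  expect_equal(sum(levels == "fruit_in_cluster"), 2)
  expect_equal(sum(levels == "fruit_in_plant"), 2)
  expect_equal(sum(levels == "plant"), 1)
  for (f in suite) {
    m <- f$observations$records$individual_mass_g
    expect_true(all(is.finite(m) & m > 0))
  }
  # the dogwood truth carries no density dependence by construction
  expect_equal(suite$dogwood_cluster$truth$params$alpha, 1)
  # the plant-level fixture is driven by a logistic source with d in range
  pl <- suite$peach_orchard_plants
  expect_equal(pl$truth$source$mode, "logistic")
  expect_gt(pl$truth$source$d, 400)
  expect_lt(pl$truth$source$d, 2000)
  # same master seed reproduces the whole suite
  again <- make_fixture_suite(1, noise_model("none"))
  expect_identical(suite$grape_cluster$observations$records,
                   again$grape_cluster$observations$records)
})

test_that("level presets cover the published population-size ranges", {
  pr <- level_presets()
  expect_setequal(pr$level, c("cell", "seed", "fruit_in_cluster",
                              "fruit_in_plant", "plant"))
  expect_equal(pr$n_min[pr$level == "cell"], 30e6)
  expect_equal(pr$n_max[pr$level == "cell"], 120e6)
  expect_equal(pr$n_min[pr$level == "seed"], 100)
  expect_equal(pr$n_max[pr$level == "seed"], 1400)
  expect_equal(pr$n_min[pr$level == "fruit_in_plant"], 700)
  expect_equal(pr$n_max[pr$level == "fruit_in_plant"], 30000)
  expect_equal(pr$n_min[pr$level == "plant"], 400)
  expect_equal(pr$n_max[pr$level == "plant"], 2000)
})

test_that("noisy fixtures fit back to the truth family (round trip)", {
  # with 10% noise a short GA still lands near the generating curve
  suite <- make_fixture_suite(4, noise_model("lognormal", cv = 0.1))
  obs <- suite$sarsaparilla_seeds$observations
  truth <- suite$sarsaparilla_seeds$truth$params
  dec <- function(x) c(x / sqrt(10), x * sqrt(10))
  f <- fit_ga(obs,
              bounds = list(kappa = dec(truth$kappa),
                            alpha = c(1e-4, 0.3),
                            Vm = dec(truth$Vm), Km = dec(truth$Km)),
              ga_settings = list(pop_size = 30, generations = 60),
              seed = 21)
  expect_lt(f$rrmse, 0.25)
})
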
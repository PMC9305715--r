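test_that("conductance follows kappa * n^alpha", {
  expect_equal(conductance(5, 0, 1000), 5)
  expect_equal(conductance(2, 1, 10), 20)
  expect_equal(conductance(3, 0.5, 4), 6)
  # non-decreasing in n, including across the log-space switch at n = 1e6
  n <- c(1, 10, 1e4, 999999, 1e6 + 1, 1e8)
  expect_true(all(diff(conductance(2, 0.3, n)) >= 0))
  expect_error(conductance(-1, 0.5, 10), class = "ddm_invalid_parameter")
  expect_error(conductance(2, 0.5, 0.5), class = "ddm_invalid_parameter")
})

test_that("source concentration: constant and logistic modes", {
  expect_equal(source_concentration(source_model("constant"), 1e7), 0.1)
  logi <- source_model("logistic", b = 0.01, d = 1200)
  expect_equal(source_concentration(logi, 1200), 0.05)  # midpoint C0/2
  flat <- source_model("logistic", b = 0, d = 7)
  expect_equal(source_concentration(flat, c(1, 1e6)), c(0.05, 0.05))
  n <- seq(1, 3000, by = 50)
  Cs <- source_concentration(logi, n)
  expect_true(all(Cs > 0 & Cs < 0.1))
  expect_true(all(diff(Cs) < 0))
  expect_error(source_model("logistic"), class = "ddm_invalid_parameter")
})

test_that("flow and unloading laws", {
  expect_equal(flow(0.1, 0.1, 7), 0)        # no gradient, no flow
  expect_equal(flow(0.1, 0.05, 10), 0.05)
  expect_equal(flow(0.1, 0, 1), 0.01)       # maximal gradient
  expect_error(flow(0.1, 0.05, 0), class = "ddm_invalid_parameter")
  expect_equal(unloading(3, 2, 0, 1e-3, 0.01), 0)  # no substrate
  # half-saturation at Cf = Km
  expect_equal(unloading(3, 2, 0.01, 1e-3, 0.01), 3 * 2 * 1e-3 / 2)
  # Cf >> Km: per-individual unloading approaches s * Vm
  expect_equal(unloading(5, 2, 1, 1e-3, 1e-9) / 5, 2e-3, tolerance = 1e-8)
})

test_that("sink concentration balances flow and unloading", {
  p <- ddm_params(kappa = 1, alpha = 0.5, Vm = 0.002, Km = 0.01)
  Cf <- sink_concentration(0.1, 4, 3, p)
  k <- conductance(1, 0.5, 4)
  U <- unloading(4, 3, Cf, 0.002, 0.01)
  expect_lt(abs(flow(0.1, Cf, k) - U) / U, 1e-10)
  expect_equal(Cf, bisect_cf(0.1, 4, 3, p), tolerance = 1e-12)
  # alpha = 1: Cf independent of population size
  p1 <- ddm_params(kappa = 2, alpha = 1, Vm = 0.002, Km = 0.01)
  expect_equal(sink_concentration(0.1, 1, 3, p1),
               sink_concentration(0.1, 50, 3, p1), tolerance = 1e-12)
  expect_error(sink_concentration(0, 4, 3, p),
               class = "ddm_invalid_parameter")
})

test_that("closed-form sink concentration matches bisection across draws", {
  d <- random_cf_draws(250, seed = 42)
  cf <- vapply(seq_len(nrow(d)), function(i) {
    sink_concentration(0.1, d$n[i], d$s[i],
                       ddm_params(d$kappa[i], d$alpha[i], d$Vm[i], d$Km[i]))
  }, numeric(1))
  expect_true(all(cf > 0 & cf < 0.1))
  oracle <- vapply(seq_len(nrow(d)), function(i) {
    bisect_cf(0.1, d$n[i], d$s[i],
              ddm_params(d$kappa[i], d$alpha[i], d$Vm[i], d$Km[i]))
  }, numeric(1))
  expect_lt(max(abs(cf / oracle - 1)), 1e-8)
})

test_that("growth trajectory satisfies its bookkeeping identities", {
  p <- ref_params()
  src <- source_model("constant")
  tr <- simulate_growth(p, src, sim_config(n = 20, s0 = 3, duration = 240))
  expect_equal(nrow(tr), 241)
  expect_true(all(diff(tr$s_g) > 0))
  expect_true(all(tr$Cf_g_per_cm3 > 0 & tr$Cf_g_per_cm3 < 0.1))
  expect_identical(tr$M_g, tr$s_g / p$DMC)
  expect_identical(tr$TM_g, 20 * tr$M_g)
  s_end <- tr$s_g[nrow(tr)]
  expect_equal((s_end - 3) * 20 / (1 - p$r), attr(tr, "sugar_unloaded_g"),
               tolerance = 1e-10)
  # the per-step unloading column re-accumulates to the same total
  expect_equal(sum(tr$U_g_per_h[-nrow(tr)] * 1), attr(tr, "sugar_unloaded_g"),
               tolerance = 1e-12)
})

test_that("negligible unloading capacity leaves dry mass at s0", {
  p <- ddm_params(kappa = 5, alpha = 0.2, Vm = 1e-30, Km = 0.01)
  tr <- simulate_growth(p, source_model("constant"),
                        sim_config(n = 5, s0 = 3, duration = 100))
  expect_identical(unique(tr$s_g), 3)
})

test_that("alpha = 1 makes per-individual growth independent of n", {
  p <- ddm_params(kappa = 2, alpha = 1, Vm = 2e-3, Km = 0.01)
  src <- source_model("constant")
  tr2 <- simulate_growth(p, src, sim_config(n = 2, s0 = 3, duration = 480))
  tr20 <- simulate_growth(p, src, sim_config(n = 20, s0 = 3, duration = 480))
  expect_equal(tr2$s_g, tr20$s_g, tolerance = 1e-12)
})

test_that("saturated unloading approaches the exponential closed form", {
  # huge conductance, Km << Cf: U/n -> s*Vm, so s(t) ~ s0*exp((1-r)*Vm*t)
  p <- ddm_params(kappa = 1e3, alpha = 0, Vm = 2e-3, Km = 1e-12)
  src <- source_model("constant")
  closed <- 3 * exp((1 - p$r) * p$Vm * 1200)
  err <- vapply(c(1, 0.5), function(dt) {
    tr <- simulate_growth(p, src,
                          sim_config(n = 1, s0 = 3, duration = 1200, dt = dt))
    abs(tr$s_g[nrow(tr)] / closed - 1)
  }, numeric(1))
  expect_lt(err[1], 0.01)
  expect_lt(err[2], err[1])  # first-order: halving dt halves the bias
})

test_that("invalid configurations are rejected with classed conditions", {
  expect_error(sim_config(n = 0.5, s0 = 3, duration = 10),
               class = "ddm_invalid_parameter")
  expect_error(sim_config(n = 2, s0 = -1, duration = 10),
               class = "ddm_invalid_parameter")
  expect_error(sim_config(n = 2, s0 = 3, duration = 10, dt = 3),
               class = "ddm_invalid_parameter")
  expect_error(ddm_params(kappa = 1, alpha = 0.5, Vm = 1e-3, Km = 0.01,
                          r = 1), class = "ddm_invalid_parameter")
})
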
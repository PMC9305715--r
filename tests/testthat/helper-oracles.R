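# Independent bracketing-bisection oracle for the sink concentration: finds
# the root of F(Cf) - U(Cf) on (0, C) without using the closed form.
# F(0) = k*C^2 > 0 and F(C) - U(C) < 0 bracket the root; 200 halvings reach
# the last representable bit.
bisect_cf <- function(C, n, s, params, iters = 200) {
  k <- conductance(params$kappa, params$alpha, n)
  g <- function(Cf) {
    flow(C, Cf, k) - n * s * params$Vm * Cf / (params$Km + Cf)
  }
  lo <- 0
  hi <- C
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mid <= lo || mid >= hi) break
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Randomised parameter draws spanning the estimated ranges across all
# organisation levels (kappa and n over many orders of magnitude).
random_cf_draws <- function(m, seed) {
  set.seed(seed)
  data.frame(
    kappa = 10^runif(m, -6, 3),
    alpha = runif(m),
    n = sample(c(1, 10, 1e4, 1e7), m, replace = TRUE),
    Vm = 10^runif(m, -4, -2),
    Km = 10^runif(m, -5, -1),
    s = 10^runif(m, -7, 3)
  )
}

# Representative parameter set for the reference (contour-plot) scenario.
ref_params <- function(...) {
  ddm_params(kappa = 5, alpha = 0.2, Vm = 2e-3, Km = 0.01, ...)
}

# Small noiseless cross-section fixture for estimation tests (3 sizes,
# short season, so objective evaluations stay cheap).
tiny_fixture <- function() {
  make_tiny <- generate_observations(
    ddm_params(kappa = 5e-3, alpha = 0.05, Vm = 6e-3, Km = 5e-3, DMC = 0.2),
    source_model("constant"),
    design = list(type = "maturity_cross_section", n = c(1, 2, 3)),
    noise = noise_model("none"), seed = 1,
    level = "seed", s0 = 5e-3, duration = 600, dataset_id = "tiny")
  make_tiny
}
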
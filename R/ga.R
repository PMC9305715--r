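#' Real-coded genetic algorithm minimiser
#'
#' Minimises an objective over a box by a real-coded genetic algorithm:
#' uniform initialisation, binary tournament selection, blend (BLX-alpha)
#' crossover, per-gene Gaussian mutation scaled to the box width, and
#' elitism. Fully reproducible given `seed`. Elitism makes the best
#' objective value non-increasing across generations.
#'
#' @param fn Objective `function(x) -> scalar` to minimise; must be finite
#'   (use a large penalty for failed evaluations).
#' @param lower,upper Numeric bounds of equal length; `lower < upper`.
#' @param pop_size Population size; default 50.
#' @param generations Number of generations; default 300.
#' @param mutation_prob Per-gene mutation probability; default 0.05.
#' @param mutation_sd Mutation standard deviation as a fraction of each
#'   gene's box width; default 0.1.
#' @param elitism Number of elites copied unchanged; default 2.
#' @param blx_alpha Blend-crossover expansion factor; default 0.5.
#' @param seed Integer seed; if `NULL` the current RNG stream is used.
#' @return A list: `par` (best coordinates), `value` (best objective),
#'   `best_history` (best value after each generation), `n_evaluations`.
#' @export
ga_minimize <- function(fn, lower, upper, pop_size = 50, generations = 300,
                        mutation_prob = 0.05, mutation_sd = 0.1,
                        elitism = 2L, blx_alpha = 0.5, seed = NULL) {
  d <- length(lower)
  if (d == 0L || length(upper) != d || any(!is.finite(lower)) ||
      any(!is.finite(upper)) || any(lower >= upper)) {
    ddm_stop("bounds must be finite, equal-length, with lower < upper",
             "ddm_invalid_configuration")
  }
  if (elitism >= pop_size) {
    ddm_stop("'elitism' must be smaller than 'pop_size'",
             "ddm_invalid_configuration")
  }
  if (!is.null(seed)) set.seed(seed)

  clip <- function(m) {
    m <- pmax(m, matrix(lower, nrow(m), d, byrow = TRUE))
    pmin(m, matrix(upper, nrow(m), d, byrow = TRUE))
  }
  pop <- matrix(runif(pop_size * d, rep(lower, each = pop_size),
                      rep(upper, each = pop_size)),
                nrow = pop_size, ncol = d)
  fit <- apply(pop, 1, fn)
  n_eval <- pop_size
  history <- numeric(generations)

  n_child <- pop_size - elitism
  for (g in seq_len(generations)) {
    ord <- order(fit)
    elites <- pop[ord[seq_len(elitism)], , drop = FALSE]
    elite_fit <- fit[ord[seq_len(elitism)]]

    pick <- function() {
      a <- sample.int(pop_size, n_child, replace = TRUE)
      b <- sample.int(pop_size, n_child, replace = TRUE)
      ifelse(fit[a] <= fit[b], a, b)
    }
    p1 <- pop[pick(), , drop = FALSE]
    p2 <- pop[pick(), , drop = FALSE]
    lo <- pmin(p1, p2)
    hi <- pmax(p1, p2)
    span <- hi - lo
    children <- matrix(runif(n_child * d), n_child, d) *
      (span * (1 + 2 * blx_alpha)) + (lo - blx_alpha * span)
    mut <- matrix(runif(n_child * d) < mutation_prob, n_child, d)
    jump <- matrix(rnorm(n_child * d), n_child, d) *
      matrix(mutation_sd * (upper - lower), n_child, d, byrow = TRUE)
    children[mut] <- children[mut] + jump[mut]
    children <- clip(children)

    child_fit <- apply(children, 1, fn)
    n_eval <- n_eval + n_child
    pop <- rbind(elites, children)
    fit <- c(elite_fit, child_fit)
    history[g] <- min(fit)
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best], best_history = history,
       n_evaluations = n_eval)
}
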
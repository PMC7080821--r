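# Fixtures are generated in code; the heavier fits are memoized so several
# test files can share one trained model.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# random standardized matrix
std_gaussian <- function(n, g, seed = 1) {
  set.seed(seed)
  standardize_genes(expression_matrix(matrix(rnorm(n * g), n, g),
                                      scale = "log"))
}

# noiseless circle with equispaced pseudo-times: per-gene empirical means
# are exactly zero, so the bias-free cosine decoder can fit it exactly
equispaced_circle <- function(n = 100, g = 20, seed = 3) {
  set.seed(seed)
  t_n <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  phase <- runif(g, 0, 2 * pi)
  amp <- runif(g, 0.5, 2)
  Y <- sweep(cos(outer(t_n, phase, "-")), 2, amp, "*")
  list(std = standardize_genes(expression_matrix(Y, scale = "log")),
       pseudotime = t_n, phase = phase, amplitude = amp)
}

# small noiseless simulator fixture + fitted model (shared across files)
noiseless_fit <- function() memo("noiseless_fit", {
  sim <- simulate_circular(circular_sim_spec(
    n_cells = 100, n_genes = 20, n_periodic_genes = 20, noise_sd = 0,
    seed = 3))
  std <- standardize_genes(sim$matrix)
  fit <- fit_circular_ae(std, model_config(seed = 0, epochs = 800))
  list(sim = sim, std = std, fit = fit)
})

# the default-condition fixture + default fit used by the acceptance tests
acceptance_fit <- function() memo("acceptance_fit", {
  sim <- simulate_circular(circular_sim_spec(seed = 0))
  std <- standardize_genes(sim$matrix)
  fit <- fit_circular_ae(std, model_config(seed = 0))
  list(sim = sim, std = std, fit = fit)
})

# a tiny but genuinely trained model for identity/round-trip checks
tiny_fit <- function() memo("tiny_fit", {
  std <- std_gaussian(40, 12, seed = 9)
  fit <- fit_circular_ae(std, model_config(encoder_widths = c(6, 4),
                                           n_linear = 1, epochs = 40,
                                           seed = 2))
  list(std = std, fit = fit)
})
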
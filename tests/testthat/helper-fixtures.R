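# small shared fixtures, all built in code

# 3 age groups x 6 contiguous years; every cell observed
small_design <- function() {
  apc_design(age_lower = c(20L, 30L, 40L), age_upper = c(29L, 39L, 49L),
             years = 2001:2006)
}

small_grid <- function(seed = 101, sigma = 0.3, delta = 5) {
  d <- small_design()
  eff <- generate_effects(d, s_alpha = 0.5, s_beta = 0.3, s_gamma = 0.4,
                          sigma = sigma, delta = delta, seed = seed)
  list(design = d, effects = eff,
       grid = generate_grid(eff, d, seed = seed + 1))
}

random_state <- function(index, grid, seed = 1) {
  set.seed(seed)
  parameter_state(delta = rnorm(1, 0, 5),
                  alpha = rnorm(length(grid$age_lower)),
                  beta = rnorm(length(grid$years)),
                  gamma = rnorm(index$K),
                  sigma = runif(1, 0.2, 2),
                  s_alpha = runif(1, 0.2, 2),
                  s_beta = runif(1, 0.2, 2),
                  s_gamma = runif(1, 0.2, 2))
}

# quick small fit used by several suites
quick_fit <- function(grid, ..., chains = 2, iterations = 800, warmup = 400,
                      seed = 99) {
  suppressWarnings(fit_apc(grid, chains = chains, iterations = iterations,
                           warmup = warmup, seed = seed, ...))
}
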
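# shared fixtures and helpers, all generated in code

tiny_config <- function(...) {
  defaults <- list(K = 3, G = 4, n_up = 6, n_down = 30)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

tiny_dataset <- function(seed = 101, ...) {
  generate_qaop_data(tiny_config(...), seed = seed)
}

quiet_fit <- function(...) suppressWarnings(fit_qaop(...))

fast_mcmc <- function(seed = 1, chains = 2, warmup = 400, sampling = 800,
                      ...) {
  mcmc_config(chains = chains, warmup = warmup, sampling = sampling,
              seed = seed, ...)
}

# random valid dichotomous Hill parameter sets
random_theta2 <- function(n, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    v = stats::runif(n, 0.3, 1),
    q = stats::runif(n, 0, 0.5),
    h = stats::runif(n, -1, 2),
    r = stats::runif(n, 0.5, 4)
  ))
}
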
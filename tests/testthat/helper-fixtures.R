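# Shared fixtures: all data are built in code at test time.

# light MCMC settings for unit tests (acceptance tests set their own)
light_sampler <- function(seed = 1, chains = 2, warmup = 400, iter = 400) {
  sampler_settings(chains = chains, warmup = warmup, iter = iter, seed = seed)
}

# tiny deterministic dataset around x0 = 0.2
toy_rd <- function() {
  rd_data(x = c(0.10, 0.16, 0.19, 0.21, 0.24, 0.50),
          t = c(0, 0, 0, 1, 1, 1),
          y = c(4.0, 3.9, 3.8, 1.9, 2.0, 2.6),
          x0 = 0.2)
}

# random fuzzy fixture with a known jump, for oracle comparisons
random_rd <- function(n = 200, jump = -2, seed = 1, noise = 0.5) {
  set.seed(seed)
  x <- runif(n, 0, 0.4)
  z <- as.integer(x >= 0.2)
  y <- 3 + 1.5 * (x - 0.2) + jump * z + rnorm(n, 0, noise)
  t <- rbinom(n, 1, ifelse(z == 1, 0.9, 0.1))
  rd_data(x = x, t = t, y = y, x0 = 0.2)
}

# hand-built posterior pieces for compose_late unit tests
fake_numerator <- function(phi) {
  structure(list(draws = data.frame(phi = phi),
                 prior = prior_spec("sip")),
            class = "rd_numerator")
}
fake_denominator <- function(dpi) {
  structure(list(draws = data.frame(dpi = dpi),
                 prior = prior_spec("sip", "fdp")),
            class = "rd_denominator")
}
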
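# Expensive fixtures shared by several acceptance checks, computed once per
# test run. All problem sizes are scaled-down replicas of the built-in
# simulation designs (the full designs are documented in the package
# vignette).

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# scaled replica of design 1 (two separated cliques, 10 binary covariates)
# together with its clustering chain and edge-evidence matrix
fixture_sim1 <- function() {
  memo("sim1", function() {
    sim <- simulate_preset(1, n = 2000, seed = 11)
    chain <- dp_cluster(sim$data, burnin = 1500, iter = 2500, seed = 12)
    list(sim = sim, chain = chain, tgamma = build_tgamma(chain),
         medians = rho_medians(chain))
  })
}

# worked-example cluster population at n = 2000 with its clustering chain
fixture_population <- function() {
  memo("population", function() {
    pop <- illustration_population()
    data <- sample_population(pop, 2000, seed = 13)
    chain <- dp_cluster(data, burnin = 2000, iter = 4000, seed = 14)
    list(pop = pop, data = data, chain = chain)
  })
}
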
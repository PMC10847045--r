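# Shared fixture population, parameterized once per test run.
.pop_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .pop_cache)) {
    assign(key, force(expr), envir = .pop_cache)
  }
  get(key, envir = .pop_cache)
}

small_consumers <- function() {
  cached("small_consumers", {
    parameterize_consumers(fixture_isolates(6, seed = 11),
                           fixture_substrates(1, seed = 11))
  })
}

# population batch phenotypes: 16 isolates x one substrate per class
population_phenotypes <- function() {
  cached("population_phenotypes", {
    cons <- parameterize_consumers(fixture_isolates(16, seed = 21),
                                   fixture_substrates(1, seed = 21))
    simulate_batch(cons)
  })
}
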
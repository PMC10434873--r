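# Shared fixtures, all built in code.

# small deterministic population for unit tests
test_population <- function(n = 6, seed = 42) {
  sample_population(n, seed = seed)
}

# reduced protocol for tests that only need qualitative convergence
quick_protocol <- function(...) {
  protocol_params(warmup_duration = 20, n_stimuli = 200, ...)
}

# hand-built simulation record: frozen weights, noiseless tuning responses,
# output either supplied or the steady-state drive; lets analysis functions
# be tested independently of the protocol engine
fake_record <- function(population, weights, stimuli, output_rate = NULL,
                        neuron = output_neuron_params()) {
  rates <- population_rates(population, stimuli)
  if (length(stimuli) == 1) rates <- matrix(rates, nrow = 1)
  map <- rep(seq_len(population$n), population$contacts)
  if (is.null(output_rate)) {
    output_rate <- apply(rates, 1, function(r) drive(weights, r[map], neuron))
  }
  structure(
    list(
      population = population,
      stimuli = stimuli,
      input_rates = rates,
      output_rate = output_rate,
      weights = matrix(weights, nrow = length(stimuli),
                       ncol = length(weights), byrow = TRUE),
      initial_weights = weights,
      warmup_weights = weights,
      final_weights = weights,
      contact_map = map,
      seed = NULL,
      mode = "fast",
      plasticity = plasticity_params(),
      neuron = neuron,
      protocol = protocol_params(n_stimuli = length(stimuli))
    ),
    class = "plasticity_record"
  )
}

# circular mean of orientations (for sampling checks)
circ_mean_orientation <- function(theta) {
  wrap_orientation(Arg(mean(exp(2i * theta))) / 2)
}

skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
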
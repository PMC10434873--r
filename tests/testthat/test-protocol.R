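test_that("a frozen rule leaves the weights exactly at their initialization", {
  p <- test_population(10)
  rec <- run_simulation(p, plasticity_params("frozen"),
                        protocol = quick_protocol(initial_weight = c(0, 0.05)),
                        seed = 4)
  expect_identical(rec$final_weights, rec$initial_weights)
  expect_identical(rec$warmup_weights, rec$initial_weights)
})

test_that("records regenerate bit-identically from the same seed in each mode", {
  p <- test_population(8)
  for (mode in c("fast", "euler")) {
    proto <- protocol_params(warmup_duration = 2, n_stimuli = 20, mode = mode)
    r1 <- run_simulation(p, protocol = proto, seed = 99)
    r2 <- run_simulation(p, protocol = proto, seed = 99)
    expect_identical(r1, r2)
  }
})

test_that("warm-up drives every weight to the 20 Hz fixed point", {
  p <- test_population(10)
  rec <- run_simulation(p, protocol = protocol_params(n_stimuli = 1), seed = 1)
  w_fp <- stationary_weight_for_rate(20)
  # fast mode is exact for the variance rule: after 200 s the weights sit at
  # w_fp * (1 - exp(-eta0 * 200)) from a zero start
  expect_equal(rec$warmup_weights,
               rep(w_fp * (1 - exp(-0.03 * 200)), 10), tolerance = 1e-9)
})

test_that("converged weights are an increasing function of kappa alone", {
  p <- sample_population(50, seed = 21)
  rec <- run_simulation(p, seed = 22)
  expect_gt(cor(pair_weights(rec), p$kappa, method = "spearman"), 0.99)
})

test_that("weights never exceed the stationary weight at the peak rate", {
  p <- sample_population(20, seed = 31)
  rec <- run_simulation(p, protocol = quick_protocol(), seed = 32)
  peak_rate <- max(tuning_rate(p$po, p$po, p$kappa))
  expect_lte(max(rec$weights), stationary_weight_for_rate(peak_rate))
  expect_true(all(rec$weights >= 0))
})

test_that("fast and Euler modes agree on final weights", {
  p <- sample_population(15, seed = 41)
  for (rule in c("variance", "covariance")) {
    pp <- plasticity_params(rule)
    rf <- run_simulation(p, pp,
                         protocol = protocol_params(warmup_duration = 10,
                                                    n_stimuli = 100),
                         seed = 5)
    re <- run_simulation(p, pp,
                         protocol = protocol_params(warmup_duration = 10,
                                                    n_stimuli = 100,
                                                    mode = "euler"),
                         seed = 5)
    ref <- pmax(re$final_weights, 1e-8)
    expect_lt(max(abs(rf$final_weights - re$final_weights) / ref), 0.02)
  }
})

test_that("ensemble runs are independent, reproducible and order-independent", {
  proto <- quick_protocol()
  recs <- run_ensemble(2, base_seed = 77, protocol = proto)
  recs2 <- run_ensemble(2, base_seed = 77, protocol = proto)
  expect_identical(recs, recs2)
  # different runs use different populations and stimuli
  expect_false(identical(recs[[1]]$population, recs[[2]]$population))
  expect_false(identical(recs[[1]]$stimuli, recs[[2]]$stimuli))
  # a single run regenerated from its own seed matches the ensemble member
  seeds <- derive_run_seeds(77, 2)
  set.seed(seeds[2])
  pop <- sample_population(50)
  rec <- run_simulation(pop, protocol = proto)
  expect_equal(rec$final_weights, recs[[2]]$final_weights)
})

test_that("pooled converged weights are right-skewed", {
  recs <- run_ensemble(5, base_seed = 17, protocol = quick_protocol())
  w <- unlist(lapply(recs, pair_weights))
  expect_gt(skewness(w), 0)
})

test_that("the small-population variant keeps the weight-kappa collapse", {
  # N = 10 inputs with inhibition rescaled to 15 Hz
  neuron <- output_neuron_params(r_inh = 15)
  recs <- run_ensemble(3, base_seed = 55, population_args = list(n = 10),
                       neuron = neuron)
  pooled_w <- unlist(lapply(recs, pair_weights))
  pooled_k <- unlist(lapply(recs, function(r) r$population$kappa))
  expect_gt(cor(pooled_w, pooled_k, method = "spearman"), 0.95)
  eq <- equilibrium_weight(pooled_k)
  expect_equal(mean(pooled_w / eq), 1, tolerance = 0.15)
})

test_that("multi-contact synapses are independent copies under the variance rule", {
  pop <- multicontact_population(12, seed = 61)
  rec <- run_simulation(pop, protocol = quick_protocol(), seed = 62)
  expect_length(rec$final_weights, 12 + 4)
  # the variance rule is deterministic given the rates, so the 5 contacts of
  # neuron 1 carry identical weights and the pair weight is their sum
  w1 <- rec$final_weights[rec$contact_map == 1]
  expect_equal(w1, rep(w1[1], 5))
  expect_equal(pair_weights(rec)[1], 5 * w1[1])
})

test_that("records round-trip through the plain-text serialization", {
  p <- test_population(5)
  rec <- run_simulation(p, protocol = quick_protocol(), seed = 8)
  dir <- withr::local_tempdir()
  write_record(rec, dir)
  expect_true(all(file.exists(file.path(dir,
    c("metadata.json", "population.tsv", "stimuli.csv", "weights.csv",
      "input_rates.csv", "output_rate.csv", "final_weights.csv")))))
  back <- read_record(dir)
  expect_equal(back$final_weights, rec$final_weights, tolerance = 1e-12)
  expect_equal(back$stimuli, rec$stimuli, tolerance = 1e-12)
  expect_equal(back$population$kappa, rec$population$kappa, tolerance = 1e-12)
  expect_equal(back$plasticity, rec$plasticity)
  expect_equal(back$protocol, rec$protocol)
})

test_that("invalid protocol configurations fail before any compute", {
  expect_error(protocol_params(stimulus_duration = 0), "stimulus_duration")
  expect_error(protocol_params(stimulus_duration = 200, dt = 3), "multiple")
  expect_error(protocol_params(initial_weight = -1), "initial_weight")
})
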
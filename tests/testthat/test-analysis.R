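test_that("the circular resultant recovers PO and selectivity in closed-form cases", {
  centers <- seq(-pi / 2, pi / 2, length.out = 21)[-21] + pi / 40
  # flat curve: zero selectivity, undefined PO
  res <- circular_resultant(rep(3, 20), centers)
  expect_equal(res$selectivity, 0, tolerance = 1e-12)
  expect_true(is.na(res$po))
  # all mass in one bin: selectivity 1 at that orientation
  v <- rep(0, 20); v[7] <- 5
  res <- circular_resultant(v, centers)
  expect_equal(res$po, centers[7])
  expect_equal(res$selectivity, 1)
  # first circular harmonic: c = 1 + cos(2 theta) has PO 0, selectivity 1/2
  grid <- seq(-pi / 2, pi / 2, length.out = 1001)[-1001]
  res <- circular_resultant(1 + cos(2 * grid), grid)
  expect_equal(res$po, 0, tolerance = 1e-9)
  expect_equal(res$selectivity, 0.5, tolerance = 1e-9)
  # invariant under global scaling
  res2 <- circular_resultant(10 * (1 + cos(2 * grid)), grid)
  expect_equal(res2$selectivity, res$selectivity)
  expect_equal(res2$po, res$po)
  expect_error(circular_resultant(rep(0, 20), centers), "zero")
})

test_that("tuning estimation recovers input-neuron parameters from a record", {
  set.seed(9)
  pop <- input_population(po = c(0.4, -0.7, 0.1), kappa = c(1, 0.6, 1e-6))
  stimuli <- runif(600, -pi / 2, pi / 2)
  rec <- fake_record(pop, weights = rep(0.1, 3), stimuli = stimuli)
  # a kappa = 1 input: PO recovered within one bin width
  est <- estimate_tuning(rec, 1)
  expect_lt(abs(delta_po(est$po, 0.4)), pi / 20)
  # near-flat input: selectivity close to zero
  est0 <- estimate_tuning(rec, 3)
  expect_lt(est0$selectivity, 0.05)
  # estimated selectivity ranks with kappa
  sels <- sapply(1:3, function(i) estimate_tuning(rec, i)$selectivity)
  expect_equal(order(sels), order(pop$kappa))
  expect_error(estimate_tuning(rec, 1, last_k = 1000), "fewer")
})

test_that("empty orientation bins are excluded rather than zero-filled", {
  pop <- input_population(po = 0.2, kappa = 1)
  # stimuli confined to half the range leave half the bins empty
  set.seed(10)
  stimuli <- runif(500, -pi / 4, pi / 4)
  rec <- fake_record(pop, weights = 1, stimuli = stimuli)
  est <- estimate_tuning(rec, 1)
  expect_true(any(est$n_per_bin == 0))
  expect_lt(abs(delta_po(est$po, 0.2)), pi / 10)
})

test_that("weight-vs-dPO correlation flags a constructed dependence", {
  set.seed(12)
  pop <- sample_population(40, seed = 12)
  stimuli <- runif(600, -pi / 2, pi / 2)
  # output tuned to 0.3, weights manufactured to equal |dPO|
  y <- tuning_rate(stimuli, 0.3, 2)
  w <- abs(delta_po(pop$po, 0.3))
  rec <- fake_record(pop, weights = w, stimuli = stimuli, output_rate = y)
  res <- weight_vs_dpo_correlation(list(rec))
  expect_gt(res$correlation, 0.95)
  expect_equal(res$n, 40)
})

test_that("pre/post activity correlation behaves at its extremes", {
  set.seed(13)
  pop <- input_population(po = c(0.5, -0.5), kappa = c(1, 1))
  stimuli <- runif(400, -pi / 2, pi / 2)
  rates <- population_rates(pop, stimuli)
  # output a positive multiple of input 1
  rec <- fake_record(pop, weights = c(1, 1), stimuli = stimuli,
                     output_rate = 2 * rates[, 1])
  cc <- pre_post_activity_correlation(rec)
  expect_equal(cc[[1]], 1)
  # output statistically independent of the inputs
  rec2 <- fake_record(pop, weights = c(1, 1), stimuli = stimuli,
                      output_rate = tuning_rate(runif(400, -pi / 2, pi / 2),
                                                0, 1))
  cc2 <- pre_post_activity_correlation(rec2)
  expect_true(all(abs(cc2) < 3 / sqrt(400)))
})

test_that("the active-input threshold is strict and has the analytic half-width", {
  # kappa = 1 input is active iff |theta - PO| < arccos(log I0(1)) / 2;
  # kappa = 0 input sits exactly at threshold and is never active
  half_width <- acos(log(besselI(1, 0))) / 2
  pop <- input_population(po = c(0, 0.3), kappa = c(1, 0))
  stimuli <- seq(-pi / 2, pi / 2, length.out = 401)[-401]
  y <- tuning_rate(stimuli, 0, 1) # tuned output so the PO is defined
  rec <- fake_record(pop, weights = c(0.03, 0.01), stimuli = stimuli,
                     output_rate = y)
  dec <- active_input_decomposition(rec, last_k = 400, n_bins = 20)
  expect_equal(half_width, 0.6665, tolerance = 1e-3)
  inside <- abs(rec$stimuli) < half_width - 0.005
  outside <- abs(rec$stimuli) > half_width + 0.005
  expect_true(all(dec$per_stimulus$n_active[inside] == 1))
  expect_true(all(dec$per_stimulus$n_active[outside] == 0))
  # when only neuron 1 is active the mean active weight is its pair weight
  expect_true(all(dec$per_stimulus$mean_active_weight[inside] == 0.03))
  expect_true(all(is.na(dec$per_stimulus$mean_active_weight[outside])))
  # halving the threshold makes the kappa = 1 neuron active more often, and
  # the kappa = 0 neuron active always (its rate exceeds 0.5 beta)
  dec05 <- active_input_decomposition(rec, threshold_multiplier = 0.5,
                                      last_k = 400)
  expect_true(all(dec05$per_stimulus$n_active >=
                    dec$per_stimulus$n_active))
  expect_true(all(dec05$per_stimulus$n_active >= 1))
})

test_that("the weighted-sum PO estimate matches vector-sum arithmetic", {
  # single input: its own PO, for any positive weight
  pop1 <- input_population(po = 0.7, kappa = 0.8)
  expect_equal(estimate_po_from_weighted_sum(pop1, 2.5)$po, 0.7,
               tolerance = 1e-6)
  # two equal contributions at 0 and pi/4: resultant bisects at pi/8
  pop2 <- input_population(po = c(0, pi / 4), kappa = c(1, 1))
  expect_equal(estimate_po_from_weighted_sum(pop2, c(0.3, 0.3))$po, pi / 8,
               tolerance = 1e-6)
  # overrides
  est_u <- estimate_po_from_weighted_sum(pop2, c(0.3, 0.6),
                                         override = "unit_weights")
  expect_equal(est_u$po, pi / 8, tolerance = 1e-6)
  expect_error(estimate_po_from_weighted_sum(pop2, c(0, 0)), "zero")
})

test_that("full weights and widths predict the simulated postsynaptic PO best", {
  recs <- run_ensemble(5, base_seed = 23,
                       protocol = protocol_params(n_stimuli = 600))
  err <- sapply(recs, function(rec) {
    post <- postsynaptic_po(rec)
    w <- pair_weights(rec)
    sapply(c("none", "both"), function(ov) {
      abs(delta_po(estimate_po_from_weighted_sum(rec$population, w,
                                                 override = ov)$po, post))
    })
  })
  expect_lt(mean(err["none", ]), mean(err["both", ]))
})
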
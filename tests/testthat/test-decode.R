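test_that("response sampling matches each noise model's definition", {
  # zero rate gives zero Poisson counts
  expect_equal(sample_response(rep(0, 10), noise_model("poisson")),
               rep(0, 10))
  # Poisson moments at the peak rate of a kappa = 1 curve
  set.seed(14)
  r <- tuning_rate(0, 0, 1)
  draws <- sample_response(rep(r, 1e5), noise_model("poisson"))
  expect_equal(mean(draws), r, tolerance = 3 * sqrt(r / 1e5) / r)
  expect_equal(var(draws), r, tolerance = 0.05)
  # noiseless responses are the rates themselves
  expect_identical(sample_response(c(3, 7), noise_model("none")), c(3, 7))
  # gaussian noise has the configured sd
  set.seed(15)
  g <- sample_response(rep(20, 1e5), noise_model("gaussian_rate"))
  expect_equal(sd(g), 5, tolerance = 0.05)
  expect_error(sample_response(c(-1, 2), noise_model("poisson")), ">= 0")
})

test_that("the weighted decoder reduces to vector-sum geometry", {
  # single input: its own PO for any positive response and weight
  expect_equal(weighted_decode(5, 0.2, 0.9), 0.9)
  # two equal-mass inputs at 0 and pi/4: bisector pi/8
  expect_equal(weighted_decode(c(2, 2), c(1, 1), c(0, pi / 4)), pi / 8)
  # orthogonal equal masses cancel on the doubled circle: undefined
  expect_true(is.na(weighted_decode(c(2, 2), c(1, 1), c(0, pi / 2))))
  expect_error(weighted_decode(c(0, 0), c(1, 1), c(0, 0.4)), "zero")
  expect_error(weighted_decode(c(1, 1), 1, c(0, 0.4)), "length")
  # invariant under positive rescaling of the weights
  set.seed(16)
  p <- rpois(20, 30)
  pos <- runif(20, -pi / 2, pi / 2)
  w <- runif(20)
  expect_equal(weighted_decode(p, w, pos), weighted_decode(p, 13.7 * w, pos))
})

test_that("the ML decoder is exact for a homogeneous symmetric population", {
  n <- 20
  pos <- seq(-pi / 2, pi / 2, length.out = n + 1)[1:n]
  pop <- input_population(pos, rep(1, n))
  for (th in seq(-pi / 2, pi / 2, length.out = 17)[-17]) {
    est <- weighted_decode(population_rates(pop, th), pop$kappa, pop$po)
    expect_lt(abs(delta_po(est, th)), 1e-10)
  }
})

test_that("decoding is equivariant under joint rotation of stimulus and POs", {
  set.seed(18)
  pop <- sample_population(30, seed = 18)
  th <- 0.37
  for (delta in c(0.4, -1.1)) {
    pop_rot <- input_population(pop$po + delta, pop$kappa)
    set.seed(55)
    p1 <- sample_response(population_rates(pop, th), noise_model("poisson"))
    set.seed(55) # same rates after rotation, so the same Poisson draws
    p2 <- sample_response(population_rates(pop_rot, th + delta),
                          noise_model("poisson"))
    e1 <- weighted_decode(p1, pop$kappa, pop$po)
    e2 <- weighted_decode(p2, pop$kappa, pop_rot$po)
    expect_equal(delta_po(e2, e1), delta_po(delta, 0), tolerance = 1e-9)
  }
})

test_that("weight schemes resolve per their definitions", {
  pop <- input_population(c(0, 0.5), c(0.2, 0.9))
  expect_equal(resolve_weights("ml", pop), c(0.2, 0.9))
  expect_equal(resolve_weights("uniform", pop), c(1, 1))
  vw <- c(0.01, 0.04)
  expect_equal(resolve_weights("variance_rule", pop, variance_weights = vw),
               vw)
  s1 <- resolve_weights("shuffled", pop, variance_weights = vw,
                        shuffle_seed = 3)
  s2 <- resolve_weights("shuffled", pop, variance_weights = vw,
                        shuffle_seed = 3)
  expect_identical(s1, s2)
  expect_setequal(s1, vw)
  expect_error(resolve_weights("variance_rule", pop), "variance_weights")
  expect_error(resolve_weights("covariance", pop), "covariance_weights")
})

test_that("per-orientation error decomposes exactly into variance plus squared bias", {
  pop <- sample_population(50, seed = 19)
  perf <- evaluate_decoder(pop, pop$kappa, noise_model("poisson"),
                           n_trials = 50, seed = 20)
  per <- perf$per_orientation
  expect_equal(per$error, per$variance + per$bias^2)
  expect_equal(nrow(per), 20)
  expect_equal(perf$error, mean(per$error))
  expect_equal(perf$abs_bias, mean(abs(per$bias)))
})

test_that("a noiseless homogeneous population decodes with zero error", {
  n <- 20
  pos <- seq(-pi / 2, pi / 2, length.out = n + 1)[1:n]
  pop <- input_population(pos, rep(1, n))
  perf <- evaluate_decoder(pop, pop$kappa, noise_model("none"), n_trials = 2)
  expect_equal(perf$abs_bias, 0, tolerance = 1e-10)
  expect_equal(perf$variance, 0, tolerance = 1e-20)
  expect_equal(perf$error, 0, tolerance = 1e-10)
  expect_equal(perf$n_undefined, 0)
})

test_that("ML decoding sharpens with population size under Poisson noise", {
  res <- sapply(c(10, 50, 200), function(n) {
    pos <- seq(-pi / 2, pi / 2, length.out = n + 1)[1:n]
    pop <- input_population(pos, rep(1, n))
    perf <- evaluate_decoder(pop, pop$kappa, noise_model("poisson"),
                             n_trials = 200, seed = 100 + n)
    c(bias = perf$abs_bias, variance = perf$variance)
  })
  expect_true(all(diff(res["variance", ]) < 0))
  expect_true(all(diff(res["bias", ]) < 0))
  expect_lt(res["bias", 3], 0.02)
})

test_that("the po_jitter model perturbs tuning, not trial-to-trial draws", {
  pop <- sample_population(25, seed = 26)
  # with zero jitter sd the model reduces to plain Poisson sampling
  set.seed(27)
  perf0 <- evaluate_decoder(pop, pop$kappa, noise_model("po_jitter", sd = 0),
                            n_trials = 30, seed = 28)
  perf1 <- evaluate_decoder(pop, pop$kappa, noise_model("poisson"),
                            n_trials = 30, seed = 28)
  expect_equal(perf0$error, perf1$error)
  # jitter must be supplied to sample_response explicitly
  expect_error(sample_response(rep(1, 25), noise_model("po_jitter")),
               "jitter")
})
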
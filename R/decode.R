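#' Response-noise models for decoding
#'
#' Four models of the input responses \eqn{p_i} handed to a decoder:
#' * `"poisson"` — independent Poisson draws with mean \eqn{r_i(\theta)}
#'   (the default model of trial-to-trial variability);
#' * `"gaussian_rate"` — \eqn{r_i(\theta) + N(0, sd)} with sd 5 Hz by
#'   default; values may be negative and are used as-is (the decoder is
#'   defined for any reals), an optional floor at 0 is available;
#' * `"po_jitter"` — Poisson draws around rates evaluated at a jittered
#'   stimulus \eqn{\theta + \sigma_i}, where \eqn{\sigma_i \sim N(0, sd)}
#'   (sd \eqn{\pi/50}) is drawn once per input neuron and held fixed across
#'   trials (a model of miscalibrated tuning);
#' * `"none"` — \eqn{p_i = r_i(\theta)} exactly.
#'
#' @param kind One of `"poisson"`, `"gaussian_rate"`, `"po_jitter"`,
#'   `"none"`.
#' @param sd Noise scale; defaults to 5 (Hz) for `"gaussian_rate"` and
#'   \eqn{\pi/50} (rad) for `"po_jitter"`; ignored otherwise.
#' @param floor_at_zero For `"gaussian_rate"`: clamp negative responses at
#'   0 before decoding (default `FALSE`).
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(kind = c("poisson", "gaussian_rate", "po_jitter",
                                 "none"),
                        sd = NULL, floor_at_zero = FALSE) {
  kind <- match.arg(kind)
  if (is.null(sd)) {
    sd <- switch(kind, gaussian_rate = 5, po_jitter = pi / 50, 0)
  }
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  structure(list(kind = kind, sd = sd, floor_at_zero = floor_at_zero),
            class = "noise_model")
}

#' Sample noisy responses from mean rates
#'
#' Draws one response vector under a [noise_model()].  The `"po_jitter"`
#' model does not perturb rates but re-evaluates the tuning curves at a
#' per-neuron jittered orientation, so it requires `population`, `theta`
#' and a fixed `jitter` vector (see [evaluate_decoder()], which draws the
#' jitter once per run).
#'
#' @param rates Mean rates \eqn{r_i(\theta)}, Hz, all \eqn{\ge 0}.
#' @param noise A `"noise_model"`.
#' @param population,theta,jitter Required for `"po_jitter"` only.
#' @return Numeric response vector \eqn{p_i}.
#' @export
sample_response <- function(rates, noise = noise_model("poisson"),
                            population = NULL, theta = NULL, jitter = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(rates < 0)) stop("input rates must be >= 0", call. = FALSE)
  switch(noise$kind,
    poisson = stats::rpois(length(rates), rates),
    gaussian_rate = {
      p <- rates + stats::rnorm(length(rates), 0, noise$sd)
      if (noise$floor_at_zero) pmax(0, p) else p
    },
    none = rates,
    po_jitter = {
      if (is.null(population) || is.null(theta) || is.null(jitter)) {
        stop("po_jitter noise needs `population`, `theta` and `jitter`",
             call. = FALSE)
      }
      stats::rpois(population$n,
                   tuning_rate(theta + jitter, population$po,
                               population$kappa,
                               population$reference_rate))
    }
  )
}

#' Weighted population decoder
#'
#' Estimates the stimulus orientation from responses \eqn{p_i}, weights
#' \eqn{w_i} and preferred orientations \eqn{\theta_i^P}:
#' \deqn{\hat\theta = \tfrac{1}{2}\,\mathrm{atan2}\!\left(
#'   \sum_i p_i w_i \sin 2\theta_i^P,\;
#'   \sum_i p_i w_i \cos 2\theta_i^P\right),}
#' i.e. half the angle of the resultant of the doubled preferred
#' orientations weighted by \eqn{p_i w_i}.  The two-argument arctangent
#' resolves the quadrant ambiguity of the plain ratio form.  With
#' \eqn{w_i = \kappa_i} this is the maximum-likelihood estimator for
#' independent Poisson responses with von Mises tuning.  The estimate is
#' invariant under positive rescaling of the weights.
#'
#' @param responses Responses \eqn{p_i} (any reals).
#' @param weights Decoder weights \eqn{w_i}.
#' @param pos Preferred orientations \eqn{\theta_i^P}, radians.
#' @return Estimated orientation in \eqn{[-\pi/2, \pi/2)}, or `NA_real_`
#'   when the resultant is numerically zero (undefined estimate, e.g. two
#'   equal masses at orthogonal orientations).  Raises an error when all
#'   \eqn{p_i w_i} are exactly zero.
#' @export
weighted_decode <- function(responses, weights, pos) {
  if (length(responses) != length(weights) ||
      length(responses) != length(pos)) {
    stop("`responses`, `weights`, `pos` must have equal length", call. = FALSE)
  }
  m <- responses * weights
  if (all(m == 0)) stop("all p_i * w_i are zero: estimate undefined",
                        call. = FALSE)
  s <- sum(m * sin(2 * pos))
  cc <- sum(m * cos(2 * pos))
  if (sqrt(s^2 + cc^2) < 1e-10 * sum(abs(m))) return(NA_real_)
  wrap_orientation(atan2(s, cc) / 2)
}

#' Resolve decoder weights for a named scheme
#'
#' The five decoders differ only in their weights:
#' * `"variance_rule"` — final weights of the corresponding
#'   variance-rule plasticity simulation (pair weights);
#' * `"ml"` — \eqn{w_i = \kappa_i} (maximum likelihood);
#' * `"uniform"` — \eqn{w_i = 1};
#' * `"shuffled"` — the variance-rule weights, permuted (seeded), so they
#'   are decoupled from \eqn{\kappa};
#' * `"covariance"` — final weights of the covariance-rule simulation.
#'
#' @param scheme One of the five scheme names.
#' @param population The `"input_population"` being decoded.
#' @param variance_weights Per-neuron weights from a variance-rule run
#'   (required for `"variance_rule"` and `"shuffled"`).
#' @param covariance_weights Per-neuron weights from a covariance-rule run
#'   (required for `"covariance"`).
#' @param shuffle_seed Optional integer seed for the permutation; `NULL`
#'   uses the current RNG stream.
#' @return Numeric weight vector of length `population$n`.
#' @export
resolve_weights <- function(scheme = c("variance_rule", "ml", "uniform",
                                       "shuffled", "covariance"),
                            population,
                            variance_weights = NULL,
                            covariance_weights = NULL,
                            shuffle_seed = NULL) {
  scheme <- match.arg(scheme)
  n <- population$n
  need <- function(w, what) {
    if (is.null(w)) {
      stop(sprintf("scheme \"%s\" requires %s", scheme, what), call. = FALSE)
    }
    if (length(w) != n) stop("weight vector has wrong length", call. = FALSE)
    w
  }
  switch(scheme,
    variance_rule = need(variance_weights, "`variance_weights`"),
    ml = population$kappa,
    uniform = rep(1, n),
    shuffled = {
      w <- need(variance_weights, "`variance_weights`")
      if (!is.null(shuffle_seed)) set.seed(shuffle_seed)
      w[sample.int(n)]
    },
    covariance = need(covariance_weights, "`covariance_weights`")
  )
}

# vectorized decoding of a trials x N response matrix; NA rows = undefined
decode_matrix <- function(P, weights, pos) {
  s <- as.numeric(P %*% (weights * sin(2 * pos)))
  cc <- as.numeric(P %*% (weights * cos(2 * pos)))
  est <- wrap_orientation(atan2(s, cc) / 2)
  scale <- as.numeric(abs(P) %*% abs(weights))
  est[sqrt(s^2 + cc^2) < 1e-10 * pmax(scale, .Machine$double.eps)] <- NA_real_
  est
}

#' Evaluate a decoder's bias, variance and error
#'
#' Shows `n_orientations` test orientations, equally spaced over the
#' orientation period (the endpoint \eqn{+\pi/2} is excluded since it
#' duplicates \eqn{-\pi/2}), each for `n_trials` independent noisy trials,
#' and decodes every trial.  Per orientation, with wrapped deviations
#' \eqn{d_t = \hat\theta_t \ominus \theta} (period \eqn{\pi}):
#' bias \eqn{b = \langle d \rangle}, variance
#' \eqn{\sigma^2 = \langle (d - b)^2 \rangle}, and error
#' \eqn{e = \sigma^2 + b^2} (exactly).  Deviations are wrapped because
#' estimates near the range boundary would otherwise register spurious
#' \eqn{\approx\pi} errors.  The per-run summary averages \eqn{|b|},
#' \eqn{\sigma^2} and \eqn{e} across orientations.  Trials with an
#' undefined estimate (zero resultant) are excluded and counted.
#'
#' @param population An `"input_population"`.
#' @param weights Decoder weights, length N (see [resolve_weights()]).
#' @param noise A `"noise_model"`.
#' @param n_orientations Number of test orientations (default 20).
#' @param n_trials Trials per orientation (default 100; >= 2).
#' @param seed Optional integer seed (`NULL` continues the RNG stream).
#' @return An object of class `"decoder_performance"`: list with
#'   `per_orientation` (data frame: `theta`, `bias`, `variance`, `error`,
#'   `n_undefined`), and summary scalars `abs_bias`, `variance`, `error`,
#'   `n_undefined`.
#' @export
evaluate_decoder <- function(population, weights,
                             noise = noise_model("poisson"),
                             n_orientations = 20, n_trials = 100,
                             seed = NULL) {
  stopifnot(inherits(population, "input_population"),
            length(weights) == population$n, n_trials >= 2)
  if (!is.null(seed)) set.seed(seed)
  thetas <- seq(-pi / 2, pi / 2,
                length.out = n_orientations + 1)[seq_len(n_orientations)]
  n <- population$n
  jitter <- if (noise$kind == "po_jitter") {
    if (noise$sd > 0) stats::rnorm(n, 0, noise$sd) else rep(0, n)
  } else NULL

  rows <- lapply(thetas, function(th) {
    r <- population_rates(population, th)
    P <- switch(noise$kind,
      poisson = matrix(stats::rpois(n_trials * n, rep(r, each = n_trials)),
                       n_trials, n),
      gaussian_rate = {
        p <- matrix(r, n_trials, n, byrow = TRUE) +
          matrix(stats::rnorm(n_trials * n, 0, noise$sd), n_trials, n)
        if (noise$floor_at_zero) pmax(0, p) else p
      },
      po_jitter = {
        rj <- tuning_rate(th + jitter, population$po, population$kappa,
                          population$reference_rate)
        matrix(stats::rpois(n_trials * n, rep(rj, each = n_trials)),
               n_trials, n)
      },
      none = matrix(r, n_trials, n, byrow = TRUE)
    )
    est <- decode_matrix(P, weights, population$po)
    ok <- !is.na(est)
    d <- delta_po(est[ok], th)
    b <- mean(d)
    v <- mean((d - b)^2)
    data.frame(theta = th, bias = b, variance = v, error = v + b^2,
               n_undefined = sum(!ok))
  })
  per <- do.call(rbind, rows)
  structure(
    list(per_orientation = per,
         abs_bias = mean(abs(per$bias)),
         variance = mean(per$variance),
         error = mean(per$error),
         n_undefined = sum(per$n_undefined)),
    class = "decoder_performance"
  )
}

#' @export
print.decoder_performance <- function(x, ...) {
  cat(sprintf("Decoder performance over %d orientations:\n",
              nrow(x$per_orientation)))
  cat(sprintf("  |bias| = %.5f rad, variance = %.5f rad^2, error = %.5f rad^2\n",
              x$abs_bias, x$variance, x$error))
  if (x$n_undefined > 0) {
    cat(sprintf("  (%d undefined trials excluded)\n", x$n_undefined))
  }
  invisible(x)
}

#' Benchmark the five decoding schemes over an ensemble
#'
#' For each of `n_populations` independent populations, runs the
#' variance-rule (and, if needed, covariance-rule) plasticity simulation to
#' obtain learned weights, resolves each requested scheme's weights, and
#' evaluates the decoder under the given noise model.  All randomness is
#' derived from `base_seed`.
#'
#' @param n_populations Number of independent populations/runs.
#' @param base_seed Integer base seed.
#' @param schemes Character vector of scheme names (default all five).
#' @param noise A `"noise_model"` (default Poisson).
#' @param population_args Arguments to [sample_population()].
#' @param protocol A `"protocol_params"` for the plasticity runs.
#' @param neuron An `"output_neuron_params"`.
#' @param n_orientations,n_trials Decoding-protocol sizes.
#' @return A list with `per_run` (data frame: `run`, `scheme`, `abs_bias`,
#'   `variance`, `error`, `n_undefined`) and `summary` (per scheme: mean
#'   and standard error of each statistic across runs).
#' @export
decoder_benchmark <- function(n_populations = 20, base_seed = 1,
                              schemes = c("variance_rule", "ml", "uniform",
                                          "shuffled", "covariance"),
                              noise = noise_model("poisson"),
                              population_args = list(n = 50),
                              protocol = protocol_params(),
                              neuron = output_neuron_params(),
                              n_orientations = 20, n_trials = 100) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  seeds <- derive_run_seeds(base_seed, n_populations)
  per_run <- do.call(rbind, lapply(seq_len(n_populations), function(k) {
    set.seed(seeds[k])
    pop <- do.call(sample_population, c(population_args, list(seed = NULL)))
    var_w <- if (any(schemes %in% c("variance_rule", "shuffled"))) {
      pair_weights(run_simulation(pop, plasticity_params("variance"),
                                  neuron, protocol))
    } else NULL
    cov_w <- if ("covariance" %in% schemes) {
      pair_weights(run_simulation(pop, plasticity_params("covariance"),
                                  neuron, protocol))
    } else NULL
    do.call(rbind, lapply(schemes, function(sc) {
      w <- resolve_weights(sc, pop, variance_weights = var_w,
                           covariance_weights = cov_w)
      perf <- evaluate_decoder(pop, w, noise,
                               n_orientations = n_orientations,
                               n_trials = n_trials)
      data.frame(run = k, scheme = sc, abs_bias = perf$abs_bias,
                 variance = perf$variance, error = perf$error,
                 n_undefined = perf$n_undefined)
    }))
  }))
  agg <- function(x) c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
  summ <- do.call(rbind, lapply(split(per_run, per_run$scheme), function(d) {
    data.frame(
      scheme = d$scheme[1], n_runs = nrow(d),
      abs_bias = mean(d$abs_bias), abs_bias_sem = agg(d$abs_bias)["sem"],
      variance = mean(d$variance), variance_sem = agg(d$variance)["sem"],
      error = mean(d$error), error_sem = agg(d$error)["sem"],
      row.names = NULL
    )
  }))
  list(per_run = per_run, summary = summ)
}
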
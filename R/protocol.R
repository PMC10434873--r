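#' Stimulation-protocol parameters
#'
#' The full plasticity experiment: a warm-up phase in which every input
#' fires at a fixed untuned rate (plasticity active), followed by a stream
#' of randomly oriented stimuli, each shown to the whole population for
#' `stimulus_duration` ms.
#'
#' Two integration modes are available and must agree (see the package
#' vignette):
#' * `"fast"` — exploits \eqn{\tau_y \ll T}: the output rate is set to its
#'   steady state once per stimulus and each weight takes one exact
#'   exponential-relaxation step toward its per-stimulus fixed point.
#'   Warm-up is chunked into `stimulus_duration`-length segments so the
#'   covariance rule can track the evolving postsynaptic rate.
#' * `"euler"` — forward-Euler integration of both the rate and the weight
#'   equations at resolution `dt`.
#'
#' @param warmup_duration Warm-up length, s (default 200).
#' @param warmup_rate Untuned input rate during warm-up, Hz (default 20).
#' @param stimulus_duration Duration T of each stimulus, ms (default 200).
#' @param n_stimuli Number of stimuli (default 1000).
#' @param dt Euler time step, ms (default 1); `stimulus_duration` must be an
#'   integer multiple of `dt`.
#' @param initial_weight Either a single value (default 0) or a length-2
#'   range `c(lo, hi)` from which initial weights are drawn uniformly.
#' @param n_runs Default ensemble size (default 100).
#' @param mode `"fast"` or `"euler"`.
#' @return An object of class `"protocol_params"`.
#' @export
protocol_params <- function(warmup_duration = 200, warmup_rate = 20,
                            stimulus_duration = 200, n_stimuli = 1000,
                            dt = 1, initial_weight = 0, n_runs = 100,
                            mode = c("fast", "euler")) {
  mode <- match.arg(mode)
  if (warmup_duration < 0) stop("`warmup_duration` must be >= 0", call. = FALSE)
  if (warmup_rate < 0) stop("`warmup_rate` must be >= 0", call. = FALSE)
  if (stimulus_duration <= 0) stop("`stimulus_duration` must be > 0", call. = FALSE)
  if (n_stimuli < 1) stop("`n_stimuli` must be >= 1", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  steps <- stimulus_duration / dt
  if (abs(steps - round(steps)) > 1e-9) {
    stop("`stimulus_duration` must be an integer multiple of `dt`", call. = FALSE)
  }
  if (!length(initial_weight) %in% c(1, 2) || any(initial_weight < 0)) {
    stop("`initial_weight` must be a nonnegative value or range c(lo, hi)",
         call. = FALSE)
  }
  if (n_runs < 1) stop("`n_runs` must be >= 1", call. = FALSE)
  structure(
    list(warmup_duration = warmup_duration, warmup_rate = warmup_rate,
         stimulus_duration = stimulus_duration, n_stimuli = n_stimuli,
         dt = dt, initial_weight = initial_weight, n_runs = n_runs,
         mode = mode),
    class = "protocol_params"
  )
}

# one exact relaxation step of length t_s (seconds) toward the current
# fixed point of the selected rule; rates/weights are per synaptic contact
relax_weights_exact <- function(w, r_syn, y, t_s, plasticity) {
  if (plasticity$rule == "frozen") return(w)
  decay <- exp(-plasticity$eta0 * t_s)
  if (plasticity$rule == "variance") {
    wstar <- plasticity$eta1 / plasticity$eta0 *
      (r_syn / plasticity$reference_rate - plasticity$mu)^2
    wstar + (w - wstar) * decay
  } else {
    cc <- plasticity$eta1 *
      (r_syn / plasticity$reference_rate - plasticity$gamma) *
      (y / plasticity$reference_rate - plasticity$gamma)
    # weights cannot go negative: excitatory synapses are floored at 0
    pmax(0, cc / plasticity$eta0 + (w - cc / plasticity$eta0) * decay)
  }
}

weight_drift <- function(w, r_syn, y, plasticity) {
  switch(plasticity$rule,
    variance = variance_drift(w, r_syn, plasticity),
    covariance = covariance_drift(w, r_syn, y, plasticity),
    frozen = 0
  )
}

#' Run one plasticity simulation
#'
#' Executes the full protocol on a given input population: seeded draw of
#' initial weights and the stimulus sequence, warm-up at the untuned rate
#' with plasticity active, then the oriented-stimulus stream with
#' per-stimulus recording of input rates, output rate and weights.  The
#' output rate is integrated continuously across stimulus boundaries (in
#' fast mode it is the per-stimulus steady state, so the distinction is
#' immaterial).
#'
#' @param population An `"input_population"`.  Neurons with several
#'   synaptic contacts contribute one independent plastic weight per
#'   contact.
#' @param plasticity A `"plasticity_params"`.
#' @param neuron An `"output_neuron_params"`.
#' @param protocol A `"protocol_params"`.
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream.  Identical `(population, params, seed)` give a bit-identical
#'   record within each integration mode.
#' @return An object of class `"plasticity_record"`: a list with
#'   `population`, `stimuli` (length `n_stimuli`), `input_rates`
#'   (`n_stimuli` x N, per neuron), `output_rate` (per stimulus, end of
#'   stimulus), `weights` (`n_stimuli` x n_synapses, at stimulus end),
#'   `initial_weights`, `warmup_weights`, `final_weights`, `contact_map`
#'   (synapse -> neuron index), `seed`, `mode`, and the three parameter
#'   objects.
#' @export
run_simulation <- function(population,
                           plasticity = plasticity_params(),
                           neuron = output_neuron_params(),
                           protocol = protocol_params(),
                           seed = NULL) {
  stopifnot(inherits(population, "input_population"),
            inherits(plasticity, "plasticity_params"),
            inherits(neuron, "output_neuron_params"),
            inherits(protocol, "protocol_params"))
  if (!is.null(seed)) set.seed(seed)

  map <- rep(seq_len(population$n), population$contacts)
  n_syn <- length(map)
  w <- if (length(protocol$initial_weight) == 2) {
    stats::runif(n_syn, protocol$initial_weight[1], protocol$initial_weight[2])
  } else {
    rep(protocol$initial_weight, n_syn)
  }
  initial_weights <- w
  stimuli <- stats::runif(protocol$n_stimuli, -pi / 2, pi / 2)

  t_stim <- protocol$stimulus_duration / 1000 # seconds
  dt_s <- protocol$dt / 1000
  fast <- protocol$mode == "fast"
  y <- 0

  # ---- warm-up: all inputs at the untuned warm-up rate, plasticity on ----
  r_warm <- rep(protocol$warmup_rate, n_syn)
  if (protocol$warmup_duration > 0) {
    if (fast) {
      n_chunks <- floor(protocol$warmup_duration / t_stim)
      for (k in seq_len(n_chunks)) {
        y <- drive(w, r_warm, neuron)
        w <- relax_weights_exact(w, r_warm, y, t_stim, plasticity)
      }
      rem <- protocol$warmup_duration - n_chunks * t_stim
      if (rem > 1e-12) {
        y <- drive(w, r_warm, neuron)
        w <- relax_weights_exact(w, r_warm, y, rem, plasticity)
      }
    } else {
      n_steps <- round(protocol$warmup_duration * 1000 / protocol$dt)
      a <- neuron$alpha
      thr <- neuron$w_inh * neuron$r_inh
      for (s in seq_len(n_steps)) {
        target <- a * max(0, neuron$w_ref * sum(w * r_warm) + thr)
        y <- max(0, y + protocol$dt / neuron$tau_y * (target - y))
        w <- w + dt_s * weight_drift(w, r_warm, y, plasticity)
        if (plasticity$rule == "covariance") w <- pmax(0, w)
      }
    }
  }
  warmup_weights <- w

  # ---- oriented-stimulus stream ----
  n_stim <- protocol$n_stimuli
  rates_mat <- matrix(NA_real_, n_stim, population$n)
  w_traj <- matrix(NA_real_, n_stim, n_syn)
  y_rec <- numeric(n_stim)
  steps_per_stim <- round(protocol$stimulus_duration / protocol$dt)
  a <- neuron$alpha
  thr <- neuron$w_inh * neuron$r_inh

  for (t in seq_len(n_stim)) {
    r <- population_rates(population, stimuli[t])
    r_syn <- r[map]
    if (fast) {
      y <- drive(w, r_syn, neuron)
      w <- relax_weights_exact(w, r_syn, y, t_stim, plasticity)
    } else {
      for (s in seq_len(steps_per_stim)) {
        target <- a * max(0, neuron$w_ref * sum(w * r_syn) + thr)
        y <- max(0, y + protocol$dt / neuron$tau_y * (target - y))
        w <- w + dt_s * weight_drift(w, r_syn, y, plasticity)
        if (plasticity$rule == "covariance") w <- pmax(0, w)
      }
    }
    rates_mat[t, ] <- r
    w_traj[t, ] <- w
    y_rec[t] <- y
  }

  structure(
    list(
      population = population,
      stimuli = stimuli,
      input_rates = rates_mat,
      output_rate = y_rec,
      weights = w_traj,
      initial_weights = initial_weights,
      warmup_weights = warmup_weights,
      final_weights = w,
      contact_map = map,
      seed = seed,
      mode = protocol$mode,
      plasticity = plasticity,
      neuron = neuron,
      protocol = protocol
    ),
    class = "plasticity_record"
  )
}

#' @export
print.plasticity_record <- function(x, ...) {
  cat(sprintf("Plasticity simulation record (%s rule, %s mode)\n",
              x$plasticity$rule, x$mode))
  cat(sprintf("  %d input neurons, %d synaptic contacts, %d stimuli\n",
              x$population$n, length(x$final_weights),
              x$protocol$n_stimuli))
  cat(sprintf("  final weights: mean %.4g, max %.4g\n",
              mean(x$final_weights), max(x$final_weights)))
  invisible(x)
}

#' Per-neuron (pair) weights of a record
#'
#' Sums contact weights per presynaptic neuron, giving the total pre/post
#' pair weight; identical to `final_weights` when every neuron has a single
#' contact.
#'
#' @param record A `"plasticity_record"`.
#' @return Numeric vector of length `record$population$n`.
#' @export
pair_weights <- function(record) {
  as.numeric(tapply(record$final_weights, record$contact_map, sum))
}

#' Derive per-run seeds for an ensemble
#'
#' Deterministic function of the base seed: the base seed seeds R's RNG
#' once and `n_runs` integer seeds are drawn.  Runs are therefore fully
#' independent and can be executed in any order.
#'
#' @param base_seed Integer base seed.
#' @param n_runs Number of runs.
#' @return Integer vector of length `n_runs`.
#' @export
derive_run_seeds <- function(base_seed, n_runs) {
  set.seed(base_seed)
  sample.int(.Machine$integer.max - 1L, n_runs)
}

#' Run an ensemble of independent simulations
#'
#' Each run gets its own seed from [derive_run_seeds()] and, unless a fixed
#' population is supplied, samples its own input population before running
#' the protocol, so runs differ in population, initial weights and stimulus
#' stream but are individually reproducible.
#'
#' @param n_runs Number of independent runs.
#' @param base_seed Integer base seed.
#' @param population Optional fixed `"input_population"` shared by all
#'   runs; when `NULL` (default) each run samples one via
#'   `population_args`.
#' @param population_args List of arguments to [sample_population()]
#'   (default `list(n = 50)`).
#' @param plasticity,neuron,protocol Parameter objects shared by all runs.
#' @return A list of `"plasticity_record"` objects.
#' @export
run_ensemble <- function(n_runs, base_seed,
                         population = NULL,
                         population_args = list(n = 50),
                         plasticity = plasticity_params(),
                         neuron = output_neuron_params(),
                         protocol = protocol_params()) {
  seeds <- derive_run_seeds(base_seed, n_runs)
  lapply(seq_len(n_runs), function(k) {
    set.seed(seeds[k])
    pop <- if (is.null(population)) {
      do.call(sample_population, c(population_args, list(seed = NULL)))
    } else {
      population
    }
    rec <- run_simulation(pop, plasticity, neuron, protocol, seed = NULL)
    rec$seed <- seeds[k]
    rec
  })
}

#' Serialize a simulation record to plain-text files
#'
#' Writes a JSON metadata document (parameters, seed, mode) plus CSV/TSV
#' tables: the population, the stimulus sequence, per-stimulus input rates,
#' output rate, the weight trajectory, and the final weights.
#'
#' @param record A `"plasticity_record"`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_record <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    seed = record$seed,
    mode = record$mode,
    plasticity = unclass(record$plasticity),
    neuron = unclass(record$neuron),
    protocol = unclass(record$protocol),
    contact_map = record$contact_map
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_population(record$population, file.path(dir, "population.tsv"))
  utils::write.csv(data.frame(stimulus = record$stimuli),
                   file.path(dir, "stimuli.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(record$input_rates),
                   file.path(dir, "input_rates.csv"), row.names = FALSE)
  utils::write.csv(data.frame(output_rate = record$output_rate),
                   file.path(dir, "output_rate.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(record$weights),
                   file.path(dir, "weights.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(synapse = seq_along(record$final_weights),
               neuron = record$contact_map,
               initial = record$initial_weights,
               warmup = record$warmup_weights,
               final = record$final_weights),
    file.path(dir, "final_weights.csv"), row.names = FALSE
  )
  invisible(dir)
}

#' Read a simulation record written by [write_record()]
#'
#' @param dir Directory containing the serialized record.
#' @return A `"plasticity_record"`.
#' @export
read_record <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  pl <- do.call(plasticity_params, meta$plasticity)
  ne <- do.call(output_neuron_params, meta$neuron)
  pr <- do.call(protocol_params, meta$protocol)
  pop <- read_population(file.path(dir, "population.tsv"),
                         reference_rate = pl$reference_rate)
  fw <- utils::read.csv(file.path(dir, "final_weights.csv"))
  structure(
    list(
      population = pop,
      stimuli = utils::read.csv(file.path(dir, "stimuli.csv"))$stimulus,
      input_rates = as.matrix(utils::read.csv(file.path(dir, "input_rates.csv"))),
      output_rate = utils::read.csv(file.path(dir, "output_rate.csv"))$output_rate,
      weights = as.matrix(utils::read.csv(file.path(dir, "weights.csv"))),
      initial_weights = fw$initial,
      warmup_weights = fw$warmup,
      final_weights = fw$final,
      contact_map = as.integer(meta$contact_map),
      seed = meta$seed,
      mode = meta$mode,
      plasticity = pl,
      neuron = ne,
      protocol = pr
    ),
    class = "plasticity_record"
  )
}
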
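#' Experiment registry and configuration
#'
#' Every figure-level experiment of the model resolves to one validated
#' configuration: nested parameter blocks for the population, plasticity
#' rule, output neuron, stimulation protocol, analysis and decoding, plus
#' ensemble size and a base seed.  Defaults are layered: model defaults <
#' experiment preset < user overrides.
#'
#' Available experiment ids:
#' `fig1_3_main` (variance rule, all defaults), `fig2_covariance`
#' (covariance rule), `fig4_decoding` (five-scheme decoder benchmark,
#' Poisson noise), `s1_weak_inhibition` (inhibitory weight / 5),
#' `s4_s6_population_size` (N and inhibitory rate scaled together),
#' `s7_uniform_init` (weights initialized U(0, 0.05)), `s8_s9_normal_po`
#' (normal PO distribution), `s10_s11_thresholds` (active-input threshold
#' 0.5x / 1.5x), `s12_s13_decoder_noise` (PO-jitter and Gaussian-rate
#' decoder noise), `s14_multicontact` (5-contact co-tuned pair).
#'
#' @param experiment One of the experiment ids above.
#' @param overrides Named nested list of overrides, e.g.
#'   `list(protocol = list(n_stimuli = 600))`.  Unknown sections or keys
#'   are rejected with an error naming the offending key.
#' @param n_runs,base_seed Convenience overrides for the two most common
#'   fields.
#' @return An object of class `"experiment_config"`: nested named list
#'   with elements `experiment`, `n_runs`, `base_seed`, `population`,
#'   `plasticity`, `neuron`, `protocol`, `analysis`, `decode`.
#' @export
experiment_config <- function(experiment = c("fig1_3_main", "fig2_covariance",
                                             "fig4_decoding",
                                             "s1_weak_inhibition",
                                             "s4_s6_population_size",
                                             "s7_uniform_init",
                                             "s8_s9_normal_po",
                                             "s10_s11_thresholds",
                                             "s12_s13_decoder_noise",
                                             "s14_multicontact"),
                              overrides = list(),
                              n_runs = NULL, base_seed = NULL) {
  experiment <- match.arg(experiment)
  defaults <- list(
    experiment = experiment,
    n_runs = 100,
    base_seed = 1,
    population = list(n = 50, po_dist = "uniform", po_sd = pi / 8,
                      reference_rate = 125),
    plasticity = list(rule = "variance", eta1 = 0.1, eta0 = 0.03,
                      mu = 1 / (2 * pi), gamma = 0.24),
    neuron = list(tau_y = 1, alpha = 0.1, w_ref = 16, w_inh = -1.7,
                  r_inh = 100),
    protocol = list(warmup_duration = 200, warmup_rate = 20,
                    stimulus_duration = 200, n_stimuli = 1000, dt = 1,
                    initial_weight = 0, mode = "fast"),
    analysis = list(n_bins = 20, last_k = 500, threshold_multiplier = 1),
    decode = list(noise = "poisson", noise_sd = NULL, n_orientations = 20,
                  n_trials = 100,
                  schemes = c("variance_rule", "ml", "uniform", "shuffled",
                              "covariance"))
  )
  presets <- list(
    fig1_3_main = list(),
    fig2_covariance = list(plasticity = list(rule = "covariance")),
    fig4_decoding = list(),
    s1_weak_inhibition = list(neuron = list(w_inh = -1.7 / 5)),
    s4_s6_population_size = list(population = list(n = 100),
                                 neuron = list(r_inh = 200)),
    s7_uniform_init = list(protocol = list(initial_weight = c(0, 0.05))),
    s8_s9_normal_po = list(population = list(po_dist = "normal")),
    s10_s11_thresholds = list(analysis = list(threshold_multiplier = 1.5)),
    s12_s13_decoder_noise = list(decode = list(noise = "po_jitter")),
    s14_multicontact = list(population = list(po_dist = "normal"))
  )
  cfg <- merge_config(defaults, presets[[experiment]], path = experiment)
  cfg <- merge_config(cfg, overrides, path = "overrides")
  if (!is.null(n_runs)) cfg$n_runs <- n_runs
  if (!is.null(base_seed)) cfg$base_seed <- base_seed
  validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

# recursive merge rejecting keys absent from the base layer
merge_config <- function(base, new, path = "") {
  if (length(new) == 0) return(base)
  for (key in names(new)) {
    full <- if (nzchar(path)) paste(path, key, sep = ".") else key
    if (!key %in% names(base)) {
      stop(sprintf("unknown configuration key: `%s`", full), call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(new[[key]])) {
      base[[key]] <- merge_config(base[[key]], new[[key]], full)
    } else {
      # `[key] <- list(...)` keeps explicit NULLs instead of deleting the key
      base[key] <- list(new[[key]])
    }
  }
  base
}

validate_config <- function(cfg) {
  fail <- function(key, why) {
    stop(sprintf("invalid configuration: `%s` %s", key, why), call. = FALSE)
  }
  if (cfg$population$n < 1 || cfg$population$n != round(cfg$population$n)) {
    fail("population.n", "must be a positive integer")
  }
  if (!cfg$population$po_dist %in% c("uniform", "normal")) {
    fail("population.po_dist", "must be \"uniform\" or \"normal\"")
  }
  if (cfg$n_runs < 1) fail("n_runs", "must be >= 1")
  # constructors enforce the remaining invariants
  do.call(plasticity_params, cfg$plasticity)
  do.call(output_neuron_params, cfg$neuron)
  do.call(protocol_params, cfg$protocol)
  if (!cfg$decode$noise %in% c("poisson", "gaussian_rate", "po_jitter",
                               "none")) {
    fail("decode.noise", "is not a known noise model")
  }
  invisible(cfg)
}

#' Load and save experiment configurations as YAML
#'
#' `load_config()` reads a YAML file holding an `experiment` id and any
#' overrides, and resolves it through [experiment_config()] (so unknown or
#' ill-typed keys are rejected with the offending key path).
#' `dump_config()` writes a configuration back to YAML; a dumped
#' configuration reloads to an identical object.
#'
#' @param path YAML file path.
#' @return `load_config()` returns an `"experiment_config"`;
#'   `dump_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$experiment)) {
    stop("config must name an `experiment`", call. = FALSE)
  }
  experiment <- raw$experiment
  raw$experiment <- NULL
  n_runs <- raw$n_runs; raw$n_runs <- NULL
  base_seed <- raw$base_seed; raw$base_seed <- NULL
  experiment_config(experiment, overrides = raw,
                    n_runs = n_runs, base_seed = base_seed)
}

#' @rdname load_config
#' @param config An `"experiment_config"`.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

config_population_args <- function(cfg) {
  list(n = cfg$population$n, po_dist = cfg$population$po_dist,
       po_sd = cfg$population$po_sd,
       reference_rate = cfg$population$reference_rate)
}

config_protocol <- function(cfg) {
  do.call(protocol_params, c(cfg$protocol, list(n_runs = cfg$n_runs)))
}

#' Run a configured experiment and write its results
#'
#' Executes the pipeline selected by the configuration's experiment id and
#' writes plain-text results plus a `manifest.json` (full configuration and
#' per-run seeds) to `output_dir`.  Re-running with the same configuration
#' overwrites the outputs bit-identically.
#'
#' Plasticity experiments write `final_weights.csv` (one row per synapse
#' per run, with the presynaptic parameters and the run's postsynaptic PO)
#' and `postsynaptic.csv` (per-run PO and selectivity); the multi-contact
#' experiment adds `pair_weights.csv`; threshold experiments add
#' `active_inputs.csv` (per-bin curves per run).  Decoding experiments
#' write `decoder_per_run.csv` and `decoder_summary.csv`.
#'
#' @param config An `"experiment_config"` (see [experiment_config()] /
#'   [load_config()]).
#' @param output_dir Output directory (created if missing).
#' @return Invisibly, a list of the result data frames written.
#' @export
run_experiment <- function(config, output_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_run_seeds(config$base_seed, config$n_runs)
  manifest <- list(config = unclass(config), run_seeds = seeds,
                   package_version = as.character(utils::packageVersion("presynvar")))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  decoding <- config$experiment %in% c("fig4_decoding", "s12_s13_decoder_noise")
  out <- list()
  if (decoding) {
    noise <- noise_model(config$decode$noise, sd = config$decode$noise_sd)
    bench <- decoder_benchmark(
      n_populations = config$n_runs, base_seed = config$base_seed,
      schemes = config$decode$schemes, noise = noise,
      population_args = config_population_args(config),
      protocol = config_protocol(config),
      neuron = do.call(output_neuron_params, config$neuron),
      n_orientations = config$decode$n_orientations,
      n_trials = config$decode$n_trials
    )
    utils::write.csv(bench$per_run,
                     file.path(output_dir, "decoder_per_run.csv"),
                     row.names = FALSE)
    utils::write.csv(bench$summary,
                     file.path(output_dir, "decoder_summary.csv"),
                     row.names = FALSE)
    out <- bench
  } else {
    plast <- do.call(plasticity_params, config$plasticity)
    neuron <- do.call(output_neuron_params, config$neuron)
    protocol <- config_protocol(config)
    multicontact <- config$experiment == "s14_multicontact"
    records <- lapply(seq_len(config$n_runs), function(k) {
      set.seed(seeds[k])
      pop <- if (multicontact) {
        multicontact_population(config$population$n, seed = NULL)
      } else {
        do.call(sample_population,
                c(config_population_args(config), list(seed = NULL)))
      }
      run_simulation(pop, plast, neuron, protocol, seed = NULL)
    })

    post <- do.call(rbind, lapply(seq_along(records), function(k) {
      # a run whose output neuron stayed silent has no defined tuning
      est <- tryCatch(
        estimate_tuning(records[[k]], "output",
                        n_bins = config$analysis$n_bins,
                        last_k = min(config$analysis$last_k,
                                     protocol$n_stimuli)),
        error = function(e) list(po = NA_real_, selectivity = NA_real_)
      )
      data.frame(run = k, po = est$po, selectivity = est$selectivity)
    }))
    weights <- do.call(rbind, lapply(seq_along(records), function(k) {
      rec <- records[[k]]
      data.frame(run = k,
                 neuron = seq_len(rec$population$n),
                 po = rec$population$po,
                 kappa = rec$population$kappa,
                 contacts = rec$population$contacts,
                 weight = pair_weights(rec),
                 post_po = post$po[k])
    }))
    utils::write.csv(weights, file.path(output_dir, "final_weights.csv"),
                     row.names = FALSE)
    utils::write.csv(post, file.path(output_dir, "postsynaptic.csv"),
                     row.names = FALSE)
    out <- list(final_weights = weights, postsynaptic = post)

    if (multicontact) {
      pw <- do.call(rbind, lapply(seq_along(records), function(k) {
        w <- pair_weights(records[[k]])
        data.frame(run = k, multi_contact_pair = w[1], single_contact_pair = w[2])
      }))
      utils::write.csv(pw, file.path(output_dir, "pair_weights.csv"),
                       row.names = FALSE)
      out$pair_weights <- pw
    }
    if (config$experiment == "s10_s11_thresholds") {
      ai <- do.call(rbind, lapply(seq_along(records), function(k) {
        dec <- tryCatch(active_input_decomposition(
          records[[k]],
          threshold_multiplier = config$analysis$threshold_multiplier,
          n_bins = config$analysis$n_bins,
          last_k = min(config$analysis$last_k, protocol$n_stimuli)
        ), error = function(e) NULL)
        if (is.null(dec)) return(NULL)
        data.frame(run = k, dpo_bin = dec$bin_centers,
                   n_active = dec$n_active,
                   mean_active_weight = dec$mean_active_weight,
                   total_current = dec$total_current)
      }))
      utils::write.csv(ai, file.path(output_dir, "active_inputs.csv"),
                       row.names = FALSE)
      out$active_inputs <- ai
    }
  }
  invisible(out)
}
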
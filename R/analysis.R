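#' Circular resultant of a tuning curve
#'
#' Preferred orientation and selectivity are read off the circular mean of
#' the response on the doubled-angle circle:
#' \deqn{R = \frac{\sum_\theta c(\theta)\, e^{2i\theta}}
#'   {\sum_\theta c(\theta)} .}
#' The preferred orientation is half the argument of \eqn{R} (wrapped to
#' the canonical range) and the selectivity is its length \eqn{|R| \in
#' [0, 1]}: 0 for a flat curve, 1 when all mass sits at a single
#' orientation.  The statistic is invariant under global scaling of the
#' curve.
#'
#' @param values Nonnegative curve values, at least one strictly positive.
#' @param angles Orientations (radians) at which `values` were measured.
#' @return A list with `po` (radians; `NA` when the selectivity is
#'   numerically zero, in which case the PO is undefined) and `selectivity`
#'   in \eqn{[0, 1]}.
#' @export
circular_resultant <- function(values, angles) {
  if (length(values) != length(angles)) {
    stop("`values` and `angles` must have equal length", call. = FALSE)
  }
  if (any(values < 0)) stop("curve values must be nonnegative", call. = FALSE)
  tot <- sum(values)
  if (tot <= 0) {
    stop("all curve values are zero: selectivity undefined", call. = FALSE)
  }
  z <- sum(values * exp(2i * angles)) / tot
  sel <- Mod(z)
  po <- if (sel < 1e-12) NA_real_ else wrap_orientation(Arg(z) / 2)
  list(po = po, selectivity = sel)
}

#' Estimate a tuning curve from a simulation record
#'
#' Bins the last `last_k` (stimulus, response) pairs of a run by stimulus
#' orientation (`n_bins` equal bins over the orientation range), averages
#' the response within each bin, and extracts preferred orientation and
#' selectivity with [circular_resultant()].  Empty bins are excluded from
#' the resultant sums (zero-filling them would bias the resultant toward
#' the occupied bins' antipode); with 500 stimuli over 20 bins they are
#' rare.
#'
#' @param record A `"plasticity_record"`.
#' @param neuron `"output"` for the postsynaptic neuron, or an input-neuron
#'   index.
#' @param n_bins Number of orientation bins (default 20).
#' @param last_k Number of trailing stimuli to use (default 500).
#' @return An object of class `"tuning_estimate"`: list with
#'   `bin_centers`, `mean_rate`, `n_per_bin`, `po`, `selectivity`.
#' @export
estimate_tuning <- function(record, neuron = "output", n_bins = 20,
                            last_k = 500) {
  stopifnot(inherits(record, "plasticity_record"))
  n_stim <- length(record$stimuli)
  if (n_stim < last_k) {
    stop("record has fewer stimuli than `last_k`", call. = FALSE)
  }
  idx <- seq.int(n_stim - last_k + 1, n_stim)
  theta <- record$stimuli[idx]
  resp <- if (identical(neuron, "output")) {
    record$output_rate[idx]
  } else {
    record$input_rates[idx, neuron]
  }
  breaks <- seq(-pi / 2, pi / 2, length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  bin <- findInterval(theta, breaks, rightmost.closed = TRUE)
  mean_rate <- rep(NA_real_, n_bins)
  counts <- tabulate(bin, n_bins)
  occupied <- counts > 0
  mean_rate[occupied] <- as.numeric(
    tapply(resp, factor(bin, levels = seq_len(n_bins)), mean)[occupied]
  )
  res <- circular_resultant(mean_rate[occupied], centers[occupied])
  structure(
    list(bin_centers = centers, mean_rate = mean_rate, n_per_bin = counts,
         po = res$po, selectivity = res$selectivity),
    class = "tuning_estimate"
  )
}

#' @export
print.tuning_estimate <- function(x, ...) {
  cat(sprintf("Tuning estimate: PO = %s rad, selectivity = %.3f (%d bins)\n",
              ifelse(is.na(x$po), "undefined", sprintf("%.3f", x$po)),
              x$selectivity, length(x$bin_centers)))
  invisible(x)
}

#' Postsynaptic preferred orientation of a record
#'
#' Convenience wrapper: [estimate_tuning()] of the output neuron, returning
#' only the PO.
#'
#' @inheritParams estimate_tuning
#' @return Orientation in radians (possibly `NA`).
#' @export
postsynaptic_po <- function(record, n_bins = 20, last_k = 500) {
  estimate_tuning(record, "output", n_bins = n_bins, last_k = last_k)$po
}

#' Correlation between synaptic weight and |dPO| across an ensemble
#'
#' Pools all synapses across runs and computes the Pearson correlation
#' between the final pair weight and the absolute wrapped difference
#' between the presynaptic PO and the run's estimated postsynaptic PO.
#' Under the variance rule weights depend on presynaptic width only, so
#' this correlation is expected to be ~0; under the covariance rule it is
#' expected to be negative (stronger weights for co-tuned pairs).
#'
#' Runs whose postsynaptic PO is undefined (a silent or perfectly untuned
#' output neuron, possible when the rectified drive never crosses
#' threshold) are skipped and counted in `n_skipped`.
#'
#' @param records A list of `"plasticity_record"` objects (>= 1; at least 2
#'   pooled synapses with nondegenerate variance).
#' @param last_k Trailing stimuli used for the postsynaptic PO estimate.
#' @return A list with `correlation`, `n` (pooled synapses), `n_skipped`
#'   (runs without a defined postsynaptic PO) and `data` (data frame:
#'   `run`, `weight`, `abs_dpo`, `kappa`).
#' @export
weight_vs_dpo_correlation <- function(records, last_k = 500) {
  stopifnot(length(records) >= 1)
  rows <- lapply(seq_along(records), function(k) {
    rec <- records[[k]]
    post_po <- tryCatch(postsynaptic_po(rec, last_k = last_k),
                        error = function(e) NA_real_)
    if (is.na(post_po)) return(NULL)
    data.frame(
      run = k,
      weight = pair_weights(rec),
      abs_dpo = abs(delta_po(rec$population$po, post_po)),
      kappa = rec$population$kappa
    )
  })
  n_skipped <- sum(vapply(rows, is.null, logical(1)))
  pooled <- do.call(rbind, rows)
  if (is.null(pooled) || nrow(pooled) < 2 ||
      stats::sd(pooled$weight) == 0 || stats::sd(pooled$abs_dpo) == 0) {
    stop("degenerate variance: correlation undefined", call. = FALSE)
  }
  list(
    correlation = stats::cor(pooled$weight, pooled$abs_dpo),
    n = nrow(pooled),
    n_skipped = n_skipped,
    data = pooled
  )
}

#' Per-input correlation of pre- and postsynaptic activity
#'
#' Pearson correlation, across stimuli, between each input neuron's rate
#' and the postsynaptic rate.  Even when weights carry no information about
#' dPO, co-tuned inputs remain more correlated with the postsynaptic neuron
#' simply because they respond to the same stimuli.
#'
#' @param record A `"plasticity_record"`.
#' @param last_k Optional number of trailing stimuli to use (default: all).
#' @return Numeric vector of length N; `NA` for inputs with constant rate.
#' @export
pre_post_activity_correlation <- function(record, last_k = NULL) {
  stopifnot(inherits(record, "plasticity_record"))
  n_stim <- length(record$stimuli)
  idx <- if (is.null(last_k)) seq_len(n_stim) else
    seq.int(n_stim - last_k + 1, n_stim)
  y <- record$output_rate[idx]
  apply(record$input_rates[idx, , drop = FALSE], 2, function(r) {
    if (stats::sd(r) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(r, y)
  })
}

#' Active-input decomposition of the postsynaptic drive
#'
#' For each stimulus, an input neuron is *active* when its rate strictly
#' exceeds the threshold \eqn{\beta = r_{ref}/2\pi} (the
#' \eqn{\kappa}-independent mean rate; optionally scaled by a multiplier).
#' The total excitatory input current \eqn{w_{ref} \sum_i w_i r_i} is split
#' into the number of active inputs and the mean pair weight among them.
#' The three quantities are binned by the wrapped difference between the
#' stimulus and the run's estimated postsynaptic PO, so that curves from
#' runs with heterogeneous POs can be aligned (peak at 0) and averaged.
#'
#' A rate exactly at threshold counts as inactive (strict inequality);
#' this only matters for flat (\eqn{\kappa = 0}) inputs whose rate equals
#' \eqn{\beta} identically.
#'
#' @param record A `"plasticity_record"`.
#' @param threshold_multiplier Scale factor on \eqn{\beta} (1 by default;
#'   0.5 and 1.5 probe threshold robustness).
#' @param n_bins Number of dPO bins (default 20).
#' @param last_k Trailing stimuli analyzed (default 500; also used for the
#'   postsynaptic PO estimate).
#' @param include_inhibition If `TRUE`, add the (negative) inhibitory
#'   current \eqn{w_I r_I} to the total input current.
#' @return An object of class `"active_input_summary"`: list with
#'   `threshold` (Hz), `post_po`, `bin_centers` (dPO relative to the
#'   postsynaptic PO), per-bin means `n_active`, `mean_active_weight`,
#'   `total_current`, and the per-stimulus data frame `per_stimulus`.
#' @export
active_input_decomposition <- function(record, threshold_multiplier = 1,
                                       n_bins = 20, last_k = 500,
                                       include_inhibition = FALSE) {
  stopifnot(inherits(record, "plasticity_record"),
            threshold_multiplier > 0)
  beta <- record$population$reference_rate / (2 * pi)
  thr <- threshold_multiplier * beta
  post_po <- postsynaptic_po(record, last_k = last_k)
  if (is.na(post_po)) {
    stop("postsynaptic PO undefined: cannot align the decomposition",
         call. = FALSE)
  }
  n_stim <- length(record$stimuli)
  idx <- seq.int(n_stim - last_k + 1, n_stim)
  map <- record$contact_map

  per_stim <- lapply(idx, function(t) {
    r <- record$input_rates[t, ]
    w_syn <- record$weights[t, ]
    w_pair <- as.numeric(tapply(w_syn, map, sum))
    active <- r > thr
    cur <- record$neuron$w_ref * sum(w_syn * r[map])
    if (include_inhibition) cur <- cur + record$neuron$w_inh * record$neuron$r_inh
    c(
      dpo = delta_po(record$stimuli[t], post_po),
      n_active = sum(active),
      mean_active_weight = if (any(active)) mean(w_pair[active]) else NA_real_,
      total_current = cur
    )
  })
  per_stim <- as.data.frame(do.call(rbind, per_stim))

  breaks <- seq(-pi / 2, pi / 2, length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  bin <- findInterval(per_stim$dpo, breaks, rightmost.closed = TRUE)
  fbin <- factor(bin, levels = seq_len(n_bins))
  bin_mean <- function(x) as.numeric(tapply(x, fbin, mean, na.rm = TRUE))

  structure(
    list(
      threshold = thr,
      threshold_multiplier = threshold_multiplier,
      post_po = post_po,
      bin_centers = centers,
      n_active = bin_mean(per_stim$n_active),
      mean_active_weight = bin_mean(per_stim$mean_active_weight),
      total_current = bin_mean(per_stim$total_current),
      per_stimulus = per_stim
    ),
    class = "active_input_summary"
  )
}

#' Estimate the postsynaptic PO from the weighted sum of input tuning curves
#'
#' Builds the weighted sum \eqn{\sum_i w_i r_i(\theta)} of the presynaptic
#' tuning curves on a dense orientation grid and extracts its preferred
#' orientation with [circular_resultant()].  Overrides replace the weights
#' by 1 (`"unit_weights"`), the widths by 1 (`"unit_kappa"`), or both,
#' isolating the contributions of presynaptic PO, selectivity, and synaptic
#' weight to the postsynaptic preference.
#'
#' @param population An `"input_population"`.
#' @param weights Per-neuron weights (length N), or per-contact weights
#'   (length `sum(contacts)`), which are summed per neuron.
#' @param override One of `"none"`, `"unit_weights"`, `"unit_kappa"`,
#'   `"both"`.
#' @param n_grid Grid resolution (default 720).
#' @return A list with `po`, `selectivity`, and the grid curve (`theta`,
#'   `curve`).
#' @export
estimate_po_from_weighted_sum <- function(population, weights,
                                          override = c("none", "unit_weights",
                                                       "unit_kappa", "both"),
                                          n_grid = 720) {
  stopifnot(inherits(population, "input_population"))
  override <- match.arg(override)
  n_syn <- sum(population$contacts)
  if (length(weights) == n_syn && n_syn != population$n) {
    weights <- as.numeric(
      tapply(weights, rep(seq_len(population$n), population$contacts), sum)
    )
  }
  if (length(weights) != population$n) {
    stop("`weights` must have one entry per neuron or per contact",
         call. = FALSE)
  }
  w <- if (override %in% c("unit_weights", "both")) rep(1, population$n) else weights
  kap <- if (override %in% c("unit_kappa", "both")) rep(1, population$n) else
    population$kappa
  if (all(w == 0)) stop("all weights are zero: PO undefined", call. = FALSE)
  theta <- seq(-pi / 2, pi / 2, length.out = n_grid + 1)[seq_len(n_grid)]
  rates <- sapply(seq_len(population$n), function(i) {
    tuning_rate(theta, population$po[i], kap[i], population$reference_rate)
  })
  curve <- as.numeric(rates %*% w)
  res <- circular_resultant(curve, theta)
  list(po = res$po, selectivity = res$selectivity, theta = theta,
       curve = curve)
}
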
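#' Construct an input population of orientation-tuned neurons
#'
#' An input population is a set of `n` rate neurons whose responses to an
#' oriented stimulus follow von Mises tuning curves (see [tuning_rate()]).
#' Each neuron has a preferred orientation (PO) in the canonical range
#' \eqn{[-\pi/2, \pi/2)} and a tuning-width (concentration) parameter
#' \eqn{\kappa \ge 0}; larger \eqn{\kappa} means sharper tuning.  An optional
#' per-neuron contact count models pairs of neurons connected through several
#' independent synaptic contacts (multi-contact experiments); the default is
#' a single contact everywhere.
#'
#' @param po Numeric vector of preferred orientations (radians); wrapped into
#'   the canonical range.
#' @param kappa Numeric vector of von Mises widths, one per neuron, all
#'   \eqn{\ge 0} (0 gives a flat curve).
#' @param contacts Integer vector of synaptic contact counts per neuron
#'   (default all 1).
#' @param reference_rate Reference firing rate \eqn{r_{ref}} in Hz
#'   (default 125).
#' @return An object of class `"input_population"`: a list with elements
#'   `n`, `po`, `kappa`, `contacts`, `reference_rate`.
#' @seealso [sample_population()], [tuning_rate()]
#' @export
input_population <- function(po, kappa, contacts = NULL, reference_rate = 125) {
  n <- length(po)
  if (n < 1) stop("population must contain at least one neuron", call. = FALSE)
  if (length(kappa) != n) {
    stop("`po` and `kappa` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(kappa)) || any(kappa < 0)) {
    stop("all `kappa` must be finite and >= 0", call. = FALSE)
  }
  if (is.null(contacts)) contacts <- rep(1L, n)
  contacts <- as.integer(contacts)
  if (length(contacts) != n || any(contacts < 1)) {
    stop("`contacts` must be positive integers, one per neuron", call. = FALSE)
  }
  if (!is.numeric(reference_rate) || reference_rate <= 0) {
    stop("`reference_rate` must be positive", call. = FALSE)
  }
  structure(
    list(
      n = n,
      po = wrap_orientation(as.numeric(po)),
      kappa = as.numeric(kappa),
      contacts = contacts,
      reference_rate = reference_rate
    ),
    class = "input_population"
  )
}

#' @export
print.input_population <- function(x, ...) {
  cat("Input population of", x$n, "von Mises-tuned neurons\n")
  cat(sprintf("  kappa: [%.3f, %.3f]   PO: [%.3f, %.3f] rad\n",
              min(x$kappa), max(x$kappa), min(x$po), max(x$po)))
  cat(sprintf("  synaptic contacts: %d   reference rate: %g Hz\n",
              sum(x$contacts), x$reference_rate))
  invisible(x)
}

#' Sample a random input population
#'
#' Preferred orientations are drawn either uniformly over the full
#' orientation range or from a wrapped normal centred on 0 (sd
#' \eqn{\pi/8} by default), and widths \eqn{\kappa} from the uniform
#' distribution on \eqn{(0, 1]}.  Sampling is reproducible: the same seed
#' yields a bit-identical population.
#'
#' @param n Number of neurons (\eqn{\ge 1}).
#' @param po_dist `"uniform"` for PO ~ U\eqn{[-\pi/2, \pi/2)} or `"normal"`
#'   for PO ~ N(0, `po_sd`) wrapped into the canonical range.
#' @param kappa_dist Only `"uniform"` (on \eqn{(0, 1]}) is supported.
#' @param seed Optional integer seed.  When `NULL` the current RNG stream is
#'   used, so callers can embed sampling in a larger seeded computation.
#' @param po_sd Standard deviation of the normal PO variant (radians,
#'   default \eqn{\pi/8}).
#' @param contacts,reference_rate Passed to [input_population()].
#' @return An `"input_population"` object.
#' @export
sample_population <- function(n,
                              po_dist = c("uniform", "normal"),
                              kappa_dist = "uniform",
                              seed = NULL,
                              po_sd = pi / 8,
                              contacts = NULL,
                              reference_rate = 125) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  po_dist <- match.arg(po_dist)
  if (!identical(kappa_dist, "uniform")) {
    stop("unknown `kappa_dist`: only \"uniform\" on (0, 1] is supported",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  po <- switch(po_dist,
    uniform = stats::runif(n, -pi / 2, pi / 2),
    normal  = stats::rnorm(n, 0, po_sd)
  )
  # 1 - runif() maps the half-open (0, 1) support onto (0, 1]
  kappa <- 1 - stats::runif(n)
  input_population(po, kappa, contacts = contacts,
                   reference_rate = reference_rate)
}

#' von Mises tuning-curve firing rate
#'
#' Firing rate of an orientation-tuned neuron in response to stimulus
#' orientation \eqn{\theta}:
#' \deqn{r(\theta) = r_{ref}\, \frac{e^{\kappa \cos(2(\theta - \theta^P))}}
#'   {2\pi I_0(\kappa)},}
#' where \eqn{I_0} is the modified Bessel function of order 0.  The factor 2
#' in the argument makes the curve \eqn{\pi}-periodic (orientation, not
#' direction), and the normalization makes the mean rate over a uniform
#' stimulus distribution equal to \eqn{r_{ref}/2\pi} for every \eqn{\kappa}.
#' \eqn{\kappa = 0} gives a flat (untuned) curve at that mean rate.
#'
#' @param theta Stimulus orientation(s), radians.
#' @param po Preferred orientation(s), radians.
#' @param kappa Width parameter(s) \eqn{\ge 0}.
#' @param reference_rate \eqn{r_{ref}} in Hz (default 125).
#' @return Firing rate(s) in Hz (strictly positive).
#' @examples
#' tuning_rate(0, po = 0, kappa = 1)      # peak response, ~42.7 Hz
#' tuning_rate(pi / 2, po = 0, kappa = 1) # orthogonal, ~5.8 Hz
#' @export
tuning_rate <- function(theta, po = 0, kappa = 1, reference_rate = 125) {
  stopifnot(all(kappa >= 0))
  reference_rate * exp(kappa * cos(2 * (theta - po))) /
    (2 * pi * besselI(kappa, 0))
}

#' Population response to one or more stimuli
#'
#' Evaluates every neuron's tuning curve at the given stimulus
#' orientation(s).
#'
#' @param population An `"input_population"`.
#' @param theta A single orientation, or a vector of orientations.
#' @return For scalar `theta`, a numeric vector of length `population$n`;
#'   for vector `theta`, a matrix with one row per stimulus and one column
#'   per neuron.
#' @export
population_rates <- function(population, theta) {
  stopifnot(inherits(population, "input_population"))
  denom <- 2 * pi * besselI(population$kappa, 0)
  if (length(theta) == 1) {
    population$reference_rate *
      exp(population$kappa * cos(2 * (theta - population$po))) / denom
  } else {
    arg <- outer(theta, population$po, function(th, p) cos(2 * (th - p)))
    sweep(population$reference_rate *
            exp(sweep(arg, 2, population$kappa, `*`)), 2, denom, `/`)
  }
}

#' Read and write population parameter tables
#'
#' Populations serialize to a plain tab-separated table with one row per
#' neuron and columns `index`, `po`, `kappa`, `contacts`, so that the exact
#' input ensemble of a simulation can be archived alongside its results.
#'
#' @param population An `"input_population"`.
#' @param path File path.
#' @return `write_population()` returns `path` invisibly;
#'   `read_population()` returns an `"input_population"`.
#' @export
write_population <- function(population, path) {
  stopifnot(inherits(population, "input_population"))
  df <- data.frame(
    index = seq_len(population$n),
    po = population$po,
    kappa = population$kappa,
    contacts = population$contacts
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @param reference_rate Reference rate to attach on read (Hz).
#' @export
read_population <- function(path, reference_rate = 125) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  input_population(df$po, df$kappa, contacts = df$contacts,
                   reference_rate = reference_rate)
}

#' Population for the multi-contact experiment
#'
#' Builds the manipulated ensemble used to study multiple synaptic contacts
#' between a correlated pair: POs are drawn from the wrapped normal (mean 0,
#' sd \eqn{\pi/8}) variant, then neuron 1 is set co-tuned with the expected
#' postsynaptic PO (PO = 0) with low selectivity (\eqn{\kappa = 0.5}) and 5
#' contacts, and neuron 2 orthogonal (PO = \eqn{\pi/2}) with high selectivity
#' (\eqn{\kappa = 1}) and a single contact.  All other neurons keep one
#' contact and \eqn{\kappa \sim U(0, 1]}.
#'
#' @param n Population size (default 50).
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#' @return An `"input_population"` with a `contacts` vector of
#'   `c(5, 1, 1, ...)`.
#' @export
multicontact_population <- function(n = 50, seed = NULL) {
  pop <- sample_population(n, po_dist = "normal", seed = seed)
  pop$po[1] <- 0
  pop$kappa[1] <- 0.5
  pop$contacts[1] <- 5L
  pop$po[2] <- wrap_orientation(pi / 2)
  pop$kappa[2] <- 1
  pop$contacts[2] <- 1L
  pop
}
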
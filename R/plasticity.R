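#' Plasticity-rule parameters
#'
#' Two learning rules are available for the excitatory weights, plus a
#' frozen (no-op) rule for controls:
#'
#' * **variance** — potentiation depends on the squared deviation of the
#'   *presynaptic* normalized rate from its mean \eqn{\mu}, independent of
#'   postsynaptic activity:
#'   \deqn{dw_i/dt = \eta_1 (r_i/r_{ref} - \mu)^2 - \eta_0 w_i .}
#' * **covariance** — classic Hebbian-style product of pre- and postsynaptic
#'   normalized-rate deviations from an offset \eqn{\gamma}:
#'   \deqn{dw_i/dt = \eta_1 (r_i/r_{ref} - \gamma)(y/r_{ref} - \gamma)
#'     - \eta_0 w_i .}
#'
#' With a uniform stimulus ensemble the normalized von Mises rate has mean
#' \eqn{1/2\pi} for every width \eqn{\kappa}, which is the default \eqn{\mu}.
#' Rate constants are interpreted per second.
#'
#' @param rule One of `"variance"`, `"covariance"`, `"frozen"`.
#' @param eta1 Learning rate \eqn{\eta_1}, 1/s (default 0.1).
#' @param eta0 Weight decay rate \eqn{\eta_0}, 1/s (default 0.03).
#' @param mu Mean normalized presynaptic activity (default \eqn{1/2\pi}).
#' @param gamma Covariance-rule offset (default 0.24).
#' @param reference_rate \eqn{r_{ref}} in Hz (default 125).
#' @return An object of class `"plasticity_params"`.
#' @export
plasticity_params <- function(rule = c("variance", "covariance", "frozen"),
                              eta1 = 0.1, eta0 = 0.03,
                              mu = 1 / (2 * pi), gamma = 0.24,
                              reference_rate = 125) {
  rule <- match.arg(rule)
  if (eta1 <= 0 || eta0 <= 0) stop("`eta1` and `eta0` must be > 0", call. = FALSE)
  if (mu <= 0 || mu >= 1) stop("`mu` must lie in (0, 1)", call. = FALSE)
  if (gamma <= 0 || gamma >= 1) stop("`gamma` must lie in (0, 1)", call. = FALSE)
  if (reference_rate <= 0) stop("`reference_rate` must be > 0", call. = FALSE)
  structure(
    list(rule = rule, eta1 = eta1, eta0 = eta0, mu = mu, gamma = gamma,
         reference_rate = reference_rate),
    class = "plasticity_params"
  )
}

#' Weight drift under the presynaptic-variance rule
#'
#' \eqn{dw/dt = \eta_1 (r/r_{ref} - \mu)^2 - \eta_0 w}.  The drift depends
#' on the presynaptic rate only; at \eqn{w = 0} it is \eqn{\ge 0}, so
#' weights started non-negative stay non-negative.
#'
#' @param w Weight(s), dimensionless.
#' @param r Presynaptic rate(s), Hz (\eqn{\ge 0}).
#' @param params A `"plasticity_params"`.
#' @return Drift \eqn{dw/dt} in 1/s.
#' @export
variance_drift <- function(w, r, params = plasticity_params()) {
  stopifnot(all(r >= 0))
  params$eta1 * (r / params$reference_rate - params$mu)^2 - params$eta0 * w
}

#' Weight drift under the covariance (Hebbian) rule
#'
#' \eqn{dw/dt = \eta_1 (r_{pre}/r_{ref} - \gamma)(y/r_{ref} - \gamma)
#'  - \eta_0 w}: potentiation when pre- and postsynaptic normalized rates
#' deviate from \eqn{\gamma} on the same side, depression otherwise.
#'
#' @param w Weight(s).
#' @param r_pre Presynaptic rate(s), Hz.
#' @param y_post Postsynaptic rate, Hz.
#' @param params A `"plasticity_params"`.
#' @return Drift in 1/s.
#' @export
covariance_drift <- function(w, r_pre, y_post, params = plasticity_params()) {
  stopifnot(all(r_pre >= 0), all(y_post >= 0))
  params$eta1 * (r_pre / params$reference_rate - params$gamma) *
    (y_post / params$reference_rate - params$gamma) - params$eta0 * w
}

#' Per-stimulus fixed point of the variance rule
#'
#' For a constant presynaptic rate the variance rule relaxes exponentially
#' (rate \eqn{\eta_0}) toward
#' \eqn{w^\ast(r) = (\eta_1/\eta_0)(r/r_{ref} - \mu)^2}.
#'
#' @param r Presynaptic rate(s), Hz.
#' @param params A `"plasticity_params"`.
#' @return Stationary weight(s), dimensionless.
#' @export
stationary_weight_for_rate <- function(r, params = plasticity_params()) {
  stopifnot(all(r >= 0))
  params$eta1 / params$eta0 * (r / params$reference_rate - params$mu)^2
}

#' Closed-form equilibrium weight under the variance rule
#'
#' Averaging the per-stimulus fixed point over a uniform orientation
#' ensemble gives the expected converged weight of a synapse from a neuron
#' with tuning width \eqn{\kappa}:
#' \deqn{E[W] = \frac{\eta_1}{\eta_0}\,\frac{1}{4\pi^2}
#'   \left(\frac{I_0(2\kappa)}{I_0^2(\kappa)} - 1\right),}
#' i.e. \eqn{(\eta_1/\eta_0)} times the variance of the normalized von Mises
#' rate.  It is 0 at \eqn{\kappa = 0} and strictly increasing in
#' \eqn{\kappa}: sharper tuning means more presynaptic rate variance and a
#' stronger equilibrium weight.  Used throughout as the analytic oracle for
#' simulated weights.
#'
#' @param kappa Tuning width(s), \eqn{\ge 0}.
#' @param params A `"plasticity_params"`.
#' @return Expected equilibrium weight(s), dimensionless.
#' @examples
#' equilibrium_weight(1) # ~0.0356
#' @export
equilibrium_weight <- function(kappa, params = plasticity_params()) {
  stopifnot(all(kappa >= 0))
  params$eta1 / params$eta0 *
    (besselI(2 * kappa, 0) / besselI(kappa, 0)^2 - 1) / (4 * pi^2)
}
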
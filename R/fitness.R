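# Closed-form fitness families over binding energy: the Fermi-Dirac
# occupancy landscape F(E) = f0 + (1-f0) p(E) and the exponential family
# F^nu = exp(-rate * E); selection-strength analytics and regime labels.

#' Fermi-Dirac landscape parameters
#'
#' @param f0 fitness of an organism whose site never binds, in [0, 1].
#' @param beta effective inverse temperature > 0, (kcal/mol)^-1.
#' @param mu effective chemical potential (energy at half occupancy),
#'   kcal/mol.
#' @param nu scaling effective population size (exponent of F in the
#'   steady state), >= 0.
#' @return object of class \code{fd_params}; \code{$gamma} is the derived
#'   selection-strength combination \eqn{\gamma = \nu (1 - f_0)}.
#' @export
fd_params <- function(f0, beta, mu, nu = 1) {
  stopifnot(f0 >= 0, f0 <= 1, beta > 0, is.finite(mu), nu >= 0)
  structure(list(f0 = f0, beta = beta, mu = mu, nu = nu,
                 gamma = nu * (1 - f0)),
            class = "fd_params")
}

#' @export
print.fd_params <- function(x, ...) {
  cat(sprintf("Fermi-Dirac params: f0=%g beta=%g mu=%g nu=%g (gamma=%g)\n",
              x$f0, x$beta, x$mu, x$nu, x$gamma))
  invisible(x)
}

#' Exponential landscape parameters
#'
#' Only the product of the exponential steepness with the population-size
#' exponent is identifiable from steady-state data, so the family is
#' parameterized by that single combined \code{rate}:
#' \eqn{F(E)^\nu = e^{-\mathrm{rate}\, E}}.
#'
#' @param rate combined exponent per kcal/mol (finite).
#' @return object of class \code{exp_params}.
#' @export
exp_params <- function(rate) {
  stopifnot(is.finite(rate))
  structure(list(rate = rate), class = "exp_params")
}

#' TF occupancy (Fermi-Dirac binding probability)
#'
#' \eqn{p(E) = 1/(1 + e^{\beta (E - \mu)})}: the probability that a site of
#' energy E is bound.  Numerically stable over the full double range.
#'
#' @param E energy (kcal/mol), vectorized.
#' @param beta inverse temperature > 0.
#' @param mu chemical potential.
#' @return occupancy in (0, 1).
#' @export
occupancy <- function(E, beta, mu) {
  stopifnot(beta > 0)
  plogis(-beta * (E - mu))
}

#' Fermi-Dirac fitness \eqn{F(E) = f_0 + (1 - f_0) p(E)}
#' @param E energy (kcal/mol), vectorized.
#' @param params an \code{fd_params}.
#' @return fitness in [f0, 1].
#' @export
fd_fitness <- function(E, params) {
  params$f0 + (1 - params$f0) * occupancy(E, params$beta, params$mu)
}

#' Log Fermi-Dirac fitness, stable for deep tails
#' @inheritParams fd_fitness
#' @return \code{log(fd_fitness(E, params))}, finite wherever F > 0 (for
#'   f0 = 0 the stable log-occupancy branch is used).
#' @export
ln_fd_fitness <- function(E, params) {
  x <- params$beta * (E - params$mu)
  if (params$f0 == 0) {
    plogis(-x, log.p = TRUE)
  } else {
    log(params$f0 + (1 - params$f0) * plogis(-x))
  }
}

#' Exponential fitness (identifiable form \eqn{F^\nu})
#'
#' Returns \eqn{e^{-\mathrm{rate}\,E}}, i.e. the fitness raised to the
#' population-size exponent; the steady state only ever uses this product,
#' so the family is used everywhere with an implicit nu = 1.
#'
#' @param E energy (kcal/mol), vectorized.
#' @param params an \code{exp_params}.
#' @return \eqn{F^\nu = e^{-\mathrm{rate} E}} (1 at E = 0).
#' @export
exp_fitness <- function(E, params) exp(-params$rate * E)

# log F^nu for either family, dispatched internally
ln_fitness_nu <- function(E, fitness, nu) {
  if (inherits(fitness, "fd_params")) nu * ln_fd_fitness(E, fitness)
  else if (inherits(fitness, "exp_params")) -fitness$rate * E
  else if (is.function(fitness)) nu * fitness(E)  # fitness(E) must be ln F
  else stop("fitness must be fd_params, exp_params, or a ln-fitness function")
}

#' Local selection strength |s*| per unit energy
#'
#' Magnitude of the selection coefficient of a small energy change,
#' \eqn{|s^*| = |d \ln F / dE| = \beta (1 - f_0) p (1 - p) / F} for the
#' Fermi-Dirac landscape.
#'
#' @param E energy (kcal/mol), vectorized.
#' @param params an \code{fd_params}.
#' @return numeric vector, per kcal/mol.
#' @export
local_selection_strength <- function(E, params) {
  p <- occupancy(E, params$beta, params$mu)
  F <- params$f0 + (1 - params$f0) * p
  params$beta * (1 - params$f0) * p * (1 - p) / F
}

#' Derivative of local selection strength with respect to beta
#'
#' Partial derivative of \eqn{|s^*|} with respect to \eqn{\beta} at fixed
#' \eqn{E - \mu} and \eqn{f_0}.  Writing x = beta*(E - mu), u = p(1-p),
#' F = f0 + (1-f0) p:
#' \deqn{\partial_\beta |s^*| = (1-f_0)\left[g(x) + x\, g'(x)\right], \quad
#'       g = u/F,\; g' = u\frac{(1-f_0) u - (1-2p) F}{F^2}.}
#'
#' @inheritParams local_selection_strength
#' @return numeric vector (units: per kcal/mol per (kcal/mol)^-1).
#' @export
selection_beta_sensitivity <- function(E, params) {
  x <- params$beta * (E - params$mu)
  f0 <- params$f0
  p <- plogis(-x)
  u <- p * (1 - p)
  F <- f0 + (1 - f0) * p
  g <- u / F
  gp <- u * ((1 - f0) * u - (1 - 2 * p) * F) / F^2
  (1 - f0) * (g + x * gp)
}

# stationarity function whose roots in x = beta*(E - mu) give the
# boundaries where d|s*|/dbeta changes sign (the (1-f0) scale removed)
beta_sens_shape <- function(x, f0) {
  p <- plogis(-x)
  u <- p * (1 - p)
  F <- f0 + (1 - f0) * p
  g <- u / F
  gp <- u * ((1 - f0) * u - (1 - 2 * p) * F) / F^2
  g + x * gp
}

#' Boundaries of the beta-sensitivity sign regions
#'
#' Solves \eqn{\partial_\beta |s^*| = 0}; the solutions are constant values
#' of \eqn{x = \beta (E - \mu)}, i.e. curves \eqn{E - \mu = x^*/\beta} in
#' the \eqn{(\beta, E-\mu)} plane.  For f0 = 0 there is a single root at
#' \eqn{x = -(1 + W(e^{-1})) \approx -1.2785} (W the principal Lambert-W
#' branch); for 0 < f0 < 1 there are two roots bracketing the sign change;
#' for f0 = 1 the landscape is flat and there are none.
#'
#' @param f0 minimum fitness in [0, 1].
#' @param x_range search interval for roots of the stationarity condition.
#' @return numeric vector of roots x* (possibly empty), sorted.
#' @export
regime_boundaries <- function(f0, x_range = c(-50, 50)) {
  stopifnot(f0 >= 0, f0 <= 1)
  if (f0 >= 1) return(numeric(0))
  xs <- seq(x_range[1], x_range[2], length.out = 4001L)
  h <- beta_sens_shape(xs, f0)
  flips <- which(h[-1] * h[-length(h)] < 0)
  vapply(flips, function(i) {
    uniroot(beta_sens_shape, c(xs[i], xs[i + 1L]), f0 = f0,
            tol = 1e-12)$root
  }, numeric(1))
}

#' Classify the landscape regime of a site collection
#'
#' Sites on the high-energy side of the threshold (bulk of
#' \eqn{\beta(E-\mu)} above \code{threshold}) lie on the exponential tail;
#' sites on the low-energy side lie on the high-occupancy plateau;
#' otherwise they straddle the bound-unbound threshold.
#'
#' @param params an \code{fd_params}.
#' @param site_energies numeric vector of site energies.
#' @param threshold regime cutoff on \eqn{\beta(E-\mu)} (default 2).
#' @param bulk central fraction of sites that must clear the cutoff
#'   (default 0.8, i.e. the 10th/90th percentiles are tested).
#' @return one of "exponential_tail", "threshold", "plateau".
#' @export
classify_regime <- function(params, site_energies, threshold = 2,
                            bulk = 0.8) {
  if (!length(site_energies)) stop("no site energies given")
  x <- params$beta * (site_energies - params$mu)
  lo <- (1 - bulk) / 2
  q <- quantile(x, c(lo, 1 - lo), names = FALSE, type = 7)
  if (q[1] > threshold) "exponential_tail"
  else if (q[2] < -threshold) "plateau"
  else "threshold"
}
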
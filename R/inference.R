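# Steady-state landscape inference: P(E) = Q0(E) F(E)^nu / Z on a binned
# spectrum, grid-search maximum likelihood for three fitness models
# (UFD / CFD / EXP), AICc model selection, nonparametric inversion of the
# landscape, and fit diagnostics (profiles, Hessian, subsample refits).

#' Mutation-selection-drift steady-state density over energy bins
#'
#' \eqn{P(E) \propto Q_0(E) F(E)^\nu}, evaluated at bin centers and
#' normalized; all arithmetic in the log domain.  \code{nu = 0} returns the
#' neutral spectrum unchanged, and the result is invariant under an overall
#' rescaling of fitness.
#'
#' @param spectrum neutral \code{energy_spectrum} (Q0).
#' @param fitness an \code{fd_params}, an \code{exp_params}, or a function
#'   E -> ln F(E).
#' @param nu population-size exponent >= 0 (ignored for \code{exp_params},
#'   whose rate already includes it).
#' @return an \code{energy_spectrum} with the selected steady-state
#'   probabilities on the same bins.
#' @export
steady_state_density <- function(spectrum, fitness, nu = 1) {
  stopifnot(nu >= 0)
  lw <- log(spectrum$prob) + ln_fitness_nu(spectrum$centers, fitness, nu)
  m <- max(lw)
  if (!is.finite(m)) stop("steady state has zero total mass")
  w <- exp(lw - m)
  new_spectrum(spectrum$centers, w / sum(w), spectrum$width)
}

# map site energies to spectrum bin indices; error off-support
site_bins <- function(site_energies, spectrum) {
  k <- energy_bin(site_energies, spectrum$width)
  k0 <- energy_bin(spectrum$centers[1], spectrum$width)
  idx <- k - k0 + 1L
  bad <- idx < 1L | idx > length(spectrum$prob)
  bad <- bad | (!bad & spectrum$prob[pmax(pmin(idx, length(spectrum$prob)), 1L)] <= 0)
  if (any(bad))
    stop(sprintf("%d site energies fall outside the spectrum support",
                 sum(bad)))
  idx
}

#' Binned log-likelihood of site energies under a steady-state model
#'
#' \eqn{\ln L = \sum_i [\nu \ln F(E_i) - \ln Z]} with
#' \eqn{Z = \sum_b Q_0(b) F(E_b)^\nu}.  The constant \eqn{\pi_0(\sigma_i)}
#' terms are dropped: they are identical across fitness models and cancel
#' in all model comparisons.  Site energies are snapped to the spectrum
#' bin grid, making the likelihood exactly consistent with the discretized
#' spectrum (and with sequence-space enumeration when the matrix is
#' grid-aligned, see [snap_matrix()]).
#'
#' @param site_energies numeric vector of observed site energies.
#' @param spectrum neutral \code{energy_spectrum}.
#' @param fitness \code{fd_params} / \code{exp_params} / ln-fitness
#'   function.
#' @param nu exponent (as in [steady_state_density()]).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(site_energies, spectrum, fitness, nu = 1) {
  if (!length(site_energies)) stop("need at least one site")
  idx <- site_bins(site_energies, spectrum)
  lnFnu <- ln_fitness_nu(spectrum$centers, fitness, nu)
  lw <- log(spectrum$prob) + lnFnu
  m <- max(lw)
  lnZ <- m + log(sum(exp(lw - m)))
  sum(lnFnu[idx]) - length(site_energies) * lnZ
}

#' Default parameter mesh for grid-search fits
#'
#' beta and nu are log-spaced at 0.1 dex; f0 uses a two-branch grid
#' \eqn{\{e^{-x}\} \cup \{1 - e^{-x}\}} (x = 0.2..10 step 0.2, truncated at
#' 0.999) so that both near-lethal and near-neutral ends are resolved on a
#' log scale; mu spans the spectrum support plus a margin.  Fits whose f0
#' lands on the top (0.999) or bottom (e^-10) grid point are reported as
#' degenerate rather than as point estimates.  The EXP family uses a
#' log-spaced rate grid (plus 0).  All grids are ordinary numeric vectors
#' and can be replaced.
#'
#' @param spectrum neutral \code{energy_spectrum} (sets the mu range).
#' @param mu_margin margin beyond the spectrum support for mu (kcal/mol).
#' @param mu_step mu grid step (kcal/mol).
#' @return list with elements \code{f0}, \code{beta}, \code{mu}, \code{nu},
#'   \code{rate}.
#' @export
default_mesh <- function(spectrum, mu_margin = 5, mu_step = 0.1) {
  x <- seq(0.2, 10, by = 0.2)
  f0 <- sort(unique(c(exp(-x), 1 - exp(-x))))
  f0 <- f0[f0 <= 0.9991]
  er <- range(spectrum$centers)
  list(f0 = f0,
       beta = 10^seq(-1, 1, by = 0.1),
       mu = seq(er[1] - mu_margin, er[2] + mu_margin, by = mu_step),
       nu = 10^seq(0, 6, by = 0.1),
       rate = c(0, 10^seq(-3, 3, by = 0.05)))
}

#' Coarsen a mesh by keeping every k-th grid point
#' @param mesh a mesh list from [default_mesh()].
#' @param factor keep every \code{factor}-th point (default 2, i.e. double
#'   the grid spacing, the convention used for repeated refits).
#' @return coarsened mesh.
#' @export
mesh_coarsen <- function(mesh, factor = 2L) {
  lapply(mesh, function(g) g[seq(1L, length(g), by = factor)])
}

#' Grid-search maximum-likelihood fit of a fitness landscape
#'
#' Exhaustively evaluates the binned log-likelihood over the mesh and
#' returns the arg-max (ties broken toward smaller nu, then smaller beta,
#' then larger mu, so fits are deterministic).  Models:
#' \describe{
#'   \item{UFD}{unconstrained Fermi-Dirac, k = 4 parameters.}
#'   \item{CFD}{"non-lethal" Fermi-Dirac with f0 fixed at 0.99, k = 3.}
#'   \item{EXP}{exponential landscape, single combined rate, k = 1.}
#' }
#' Degeneracy flags are set from the fitted position: f0 on the top grid
#' point means only \eqn{\gamma = \nu(1-f_0)} is identified
#' (\code{gamma_degenerate}); f0 on the bottom grid point means f0 is
#' unresolved downward (\code{f0_floor}); mu more than 2/beta below (above)
#' all site energies means the tail (plateau) mu degeneracy
#' (\code{mu_left}, \code{mu_right}).
#'
#' @param site_energies numeric vector of site energies (>= 30 recommended;
#'   a warning is issued below that).
#' @param spectrum neutral \code{energy_spectrum}.
#' @param model "UFD", "CFD" or "EXP".
#' @param mesh parameter mesh (default [default_mesh()] on the spectrum).
#' @return object of class \code{fit_result}: params (an \code{fd_params}
#'   or \code{exp_params}), \code{lnL}, \code{k}, \code{n}, \code{aicc},
#'   \code{regime}, \code{flags}, and the mesh used.
#' @export
fit_gridsearch <- function(site_energies, spectrum,
                           model = c("UFD", "CFD", "EXP"),
                           mesh = default_mesh(spectrum)) {
  model <- match.arg(model)
  n <- length(site_energies)
  if (n < 1L) stop("need at least one site")
  if (n < 30L) warning("fewer than 30 sites; fits may be unstable")
  idx <- site_bins(site_energies, spectrum)
  nsite <- tabulate(idx, nbins = length(spectrum$prob))
  lnq <- log(spectrum$prob)

  if (model == "EXP") {
    rates <- mesh$rate
    if (!length(rates)) stop("empty rate mesh")
    Esites <- sum(spectrum$centers[idx])
    lnl <- vapply(rates, function(r) {
      lw <- lnq - r * spectrum$centers
      m <- max(lw)
      -r * Esites - n * (m + log(sum(exp(lw - m))))
    }, numeric(1))
    best <- which.max(lnl)
    params <- exp_params(rates[best])
    out <- list(model = model, params = params, lnL = lnl[best], k = 1L,
                n = n,
                regime = "exponential", flags = list(), mesh = mesh)
  } else {
    f0g <- if (model == "CFD") 0.99 else mesh$f0
    if (!length(f0g) || !length(mesh$beta) || !length(mesh$mu) ||
        !length(mesh$nu)) stop("empty mesh")
    sc <- fd_grid_scan(lnq, spectrum$centers, as.numeric(nsite), n,
                       f0g, mesh$beta, mesh$mu, mesh$nu)
    params <- fd_params(f0 = f0g[sc$i_f0], beta = mesh$beta[sc$i_beta],
                        mu = mesh$mu[sc$i_mu], nu = mesh$nu[sc$i_nu])
    flags <- list(
      gamma_degenerate = (model == "UFD" && sc$i_f0 == length(f0g)),
      f0_floor = (model == "UFD" && sc$i_f0 == 1L),
      mu_left = params$mu < min(site_energies),
      mu_right = params$mu > max(site_energies))
    out <- list(model = model, params = params, lnL = sc$lnL,
                k = if (model == "UFD") 4L else 3L, n = n,
                regime = classify_regime(params, site_energies),
                flags = flags, mesh = mesh)
  }
  out$aicc <- if (n > out$k + 1L) aicc(out$lnL, out$k, n) else NA_real_
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: lnL=%.4f AICc=%.4f (k=%d, n=%d)\n",
              x$model, x$lnL, x$aicc, x$k, x$n))
  print(x$params)
  if (!is.null(x$regime)) cat("regime:", x$regime, "\n")
  fl <- names(Filter(isTRUE, x$flags))
  if (length(fl)) cat("degeneracy flags:", paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' Finite-sample Akaike information criterion
#'
#' \eqn{AICc = 2k - 2\ln L + 2k(k+1)/(n-k-1)}.
#'
#' @param lnL maximized log-likelihood.
#' @param k number of fitted parameters.
#' @param n number of data points (must exceed k + 1).
#' @return AICc value.
#' @export
aicc <- function(lnL, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1")
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' \eqn{w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}},
#' \eqn{\Delta_i = AICc_i - \min_j AICc_j}: the relative likelihood that
#' each model is the best of the set.
#'
#' @param aicc_values numeric vector (>= 2 models), optionally named.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) < 2L) stop("need at least two models")
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Nonparametric landscape inversion
#'
#' Groups site energies into \code{n_bins} equal-width bins spanning the
#' spectrum's energy range and estimates, per bin,
#' \eqn{\frac{1}{\nu}[\ln \hat P_{obs} - \ln Q_0]}, which equals
#' \eqn{\ln F} up to an additive constant.  The per-bin standard error is
#' the binomial delta-method value \eqn{\sqrt{(1-\hat f)/(\hat f N)}/\nu}
#' on the observed fraction \eqn{\hat f}.  Bins with zero observed or zero
#' neutral mass are flagged undefined, never interpolated.
#'
#' @param site_energies numeric vector.
#' @param spectrum neutral \code{energy_spectrum}.
#' @param nu exponent used for the 1/nu scale (> 0).
#' @param n_bins number of equal-width bins (default 15).
#' @return data.frame (class \code{binned_landscape}) with bin_lo, bin_hi,
#'   center, n_sites, q0_mass, ln_fitness, se, defined.
#' @export
invert_landscape <- function(site_energies, spectrum, nu, n_bins = 15L) {
  stopifnot(nu > 0, n_bins >= 2L)
  er <- range(spectrum$centers) + c(-0.5, 0.5) * spectrum$width
  edges <- seq(er[1], er[2], length.out = n_bins + 1L)
  bin <- findInterval(site_energies, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  n <- length(site_energies)
  cnt <- tabulate(bin, nbins = n_bins)
  qbin <- findInterval(spectrum$centers, edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  q0 <- vapply(seq_len(n_bins), function(b) sum(spectrum$prob[qbin == b]),
               numeric(1))
  f <- cnt / n
  defined <- cnt > 0 & q0 > 0
  lnF <- ifelse(defined, (log(f) - log(q0)) / nu, NA_real_)
  se <- ifelse(defined, sqrt((1 - f) / (f * n)) / nu, NA_real_)
  out <- data.frame(bin_lo = edges[-(n_bins + 1L)], bin_hi = edges[-1L],
                    center = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                    n_sites = cnt, q0_mass = q0, ln_fitness = lnF, se = se,
                    defined = defined)
  class(out) <- c("binned_landscape", "data.frame")
  out
}

#' Profile likelihood along one parameter
#'
#' For each value in \code{grid}, pins that parameter and re-optimizes all
#' remaining parameters over the mesh.
#'
#' @param site_energies,spectrum,model,mesh as in [fit_gridsearch()].
#' @param param_name one of "f0", "beta", "mu", "nu" (or "rate" for EXP).
#' @param grid values to profile over (default: the mesh grid for that
#'   parameter).
#' @return data.frame with columns value, lnL.
#' @export
profile_likelihood <- function(site_energies, spectrum, model = "UFD",
                               param_name, grid = NULL,
                               mesh = default_mesh(spectrum)) {
  if (!param_name %in% names(mesh)) stop("unknown parameter: ", param_name)
  if (is.null(grid)) grid <- mesh[[param_name]]
  lnl <- vapply(grid, function(v) {
    m2 <- mesh
    m2[[param_name]] <- v
    fit_gridsearch(site_energies, spectrum, model, mesh = m2)$lnL
  }, numeric(1))
  data.frame(value = grid, lnL = lnl)
}

#' Log-likelihood heatmap over the (f0, nu) plane
#'
#' Re-optimizes (beta, mu) at each (f0, nu) pair.  In coordinates
#' \eqn{(\ln \nu, -\ln(1-f_0))} a constant \eqn{\gamma = \nu(1-f_0)} is a
#' straight line of slope 1, which makes the gamma degeneracy visible as a
#' flat ridge.
#'
#' @param site_energies,spectrum,mesh as in [fit_gridsearch()].
#' @param f0_grid,nu_grid axis grids (defaults: the mesh grids).
#' @return list with f0, nu, and matrix lnL (rows = nu, cols = f0).
#' @export
likelihood_heatmap <- function(site_energies, spectrum,
                               mesh = default_mesh(spectrum),
                               f0_grid = mesh$f0, nu_grid = mesh$nu) {
  n <- length(site_energies)
  idx <- site_bins(site_energies, spectrum)
  nsite <- tabulate(idx, nbins = length(spectrum$prob))
  lnq <- log(spectrum$prob)
  lnL <- matrix(NA_real_, length(nu_grid), length(f0_grid))
  for (i in seq_along(f0_grid)) {
    for (j in seq_along(nu_grid)) {
      sc <- fd_grid_scan(lnq, spectrum$centers, as.numeric(nsite), n,
                         f0_grid[i], mesh$beta, mesh$mu, nu_grid[j])
      lnL[j, i] <- sc$lnL
    }
  }
  list(f0 = f0_grid, nu = nu_grid, lnL = lnL)
}

# continuous lnL in transformed coordinates (ln nu, ln beta, ln(1-f0), mu)
lnl_transformed <- function(theta, site_energies, spectrum) {
  p <- fd_params(f0 = 1 - exp(theta[3]), beta = exp(theta[2]),
                 mu = theta[4], nu = exp(theta[1]))
  log_likelihood(site_energies, spectrum, p, p$nu)
}

#' Fit diagnostics: Hessian eigensystem and half-subsample refits
#'
#' The Hessian of the log-likelihood is evaluated by central finite
#' differences in the transformed coordinates
#' \eqn{(\ln\nu, \ln\beta, \ln(1-f_0), \mu)}, where the gamma degeneracy
#' is the straight direction \eqn{(1, 0, -1, 0)/\sqrt2}; its eigenvalues
#' should be negative at a well-identified interior maximum, with
#' near-zero eigenvalues marking degenerate directions.  Subsample refits
#' repeat the grid search on seeded random half-size subsets with the mesh
#' spacing doubled.
#'
#' @param site_energies,spectrum as in [fit_gridsearch()].
#' @param fit a \code{fit_result} for a Fermi-Dirac model.
#' @param n_subsamples number of half-subsample refits (default 64; 0
#'   skips them).
#' @param seed integer seed for the subsampling.
#' @param h finite-difference step.
#' @return list with \code{hessian}, \code{eigen} (values/vectors in the
#'   transformed coordinates, order ln nu, ln beta, ln(1-f0), mu),
#'   \code{boundary} (mesh-edge flags), and \code{subsamples} (data.frame
#'   of refitted parameters).
#' @export
fit_diagnostics <- function(site_energies, spectrum, fit,
                            n_subsamples = 64L, seed = 1L, h = 1e-3) {
  if (!inherits(fit$params, "fd_params"))
    stop("diagnostics are defined for Fermi-Dirac fits")
  p <- fit$params
  mesh <- fit$mesh
  on_edge <- c(nu = p$nu %in% range(mesh$nu),
               beta = p$beta %in% range(mesh$beta),
               mu = p$mu %in% range(mesh$mu))
  hess <- eig <- NULL
  if (any(on_edge)) {
    warning("optimum on the mesh boundary in: ",
            paste(names(on_edge)[on_edge], collapse = ", "),
            "; Hessian skipped")
  } else {
    th <- c(log(p$nu), log(p$beta), log(1 - p$f0), p$mu)
    f <- function(t) lnl_transformed(t, site_energies, spectrum)
    d <- length(th)
    hess <- matrix(NA_real_, d, d)
    f0v <- f(th)
    for (i in seq_len(d)) {
      for (j in i:d) {
        ei <- ej <- numeric(d); ei[i] <- h; ej[j] <- h
        if (i == j) {
          hess[i, i] <- (f(th + ei) - 2 * f0v + f(th - ei)) / h^2
        } else {
          hess[i, j] <- hess[j, i] <-
            (f(th + ei + ej) - f(th + ei - ej) -
             f(th - ei + ej) + f(th - ei - ej)) / (4 * h^2)
        }
      }
    }
    dimnames(hess) <- list(c("ln_nu", "ln_beta", "ln_1mf0", "mu"),
                           c("ln_nu", "ln_beta", "ln_1mf0", "mu"))
    eig <- eigen(hess, symmetric = TRUE)
  }
  # curvature restricted to the parameters the model actually fits
  # (CFD pins f0, so its optimum need not be a maximum along ln(1-f0))
  eig_free <- NULL
  if (!is.null(hess)) {
    free <- if (fit$model == "CFD")
      c("ln_nu", "ln_beta", "mu") else rownames(hess)
    eig_free <- eigen(hess[free, free, drop = FALSE], symmetric = TRUE)
  }
  subs <- NULL
  if (n_subsamples > 0L) {
    set.seed(seed)
    cmesh <- mesh_coarsen(mesh, 2L)
    n <- length(site_energies)
    rows <- lapply(seq_len(n_subsamples), function(s) {
      take <- sample.int(n, n %/% 2L)
      ft <- suppressWarnings(
        fit_gridsearch(site_energies[take], spectrum, fit$model,
                       mesh = cmesh))
      data.frame(subsample = s, f0 = ft$params$f0, beta = ft$params$beta,
                 mu = ft$params$mu, nu = ft$params$nu,
                 gamma = ft$params$gamma, lnL = ft$lnL)
    })
    subs <- do.call(rbind, rows)
  }
  list(hessian = hess, eigen = eig, eigen_free = eig_free,
       boundary = on_edge, subsamples = subs)
}

#' Continuous profile optimum over nu at fixed (f0, beta, mu)
#'
#' One-dimensional continuous maximization of the binned log-likelihood
#' over ln(nu), used to trace likelihood ridges (e.g. comparing the
#' gamma-degenerate parametrizations, where the compensating nu is not a
#' mesh point).
#'
#' @param site_energies,spectrum as in [log_likelihood()].
#' @param f0,beta,mu fixed Fermi-Dirac parameters.
#' @param log_nu_range search interval for ln(nu).
#' @return list with \code{nu} and \code{lnL} at the profile optimum.
#' @export
optimize_nu <- function(site_energies, spectrum, f0, beta, mu,
                        log_nu_range = c(0, log(1e8))) {
  f <- function(lnu)
    log_likelihood(site_energies, spectrum,
                   fd_params(f0, beta, mu, exp(lnu)), exp(lnu))
  o <- optimize(f, log_nu_range, maximum = TRUE, tol = 1e-10)
  list(nu = exp(o$maximum), lnL = o$objective)
}

#' Factorized steady state under exponential fitness
#'
#' With a mononucleotide (factorized) background and exponential fitness,
#' the steady state factorizes over positions:
#' \eqn{p_i(a) = b(a) e^{-\mathrm{rate}\,\epsilon_{ia}} / z_i} with
#' per-position partition functions \eqn{z_i}.
#'
#' @param mono per-base background probabilities.
#' @param matrix an \code{energy_matrix}.
#' @param rate combined exponent (as in [exp_params()]).
#' @return 4 x L matrix of per-position base probabilities (columns sum
#'   to 1).
#' @export
exp_factorized_steady_state <- function(mono, matrix, rate) {
  stopifnot(length(mono) == 4L, abs(sum(mono) - 1) < 1e-8,
            is.finite(rate))
  lw <- log(mono) - rate * unclass(matrix)
  lw <- sweep(lw, 2L, apply(lw, 2L, max))
  w <- exp(lw)
  sweep(w, 2L, colSums(w), "/")
}

#' Log-odds energy matrix from observed per-position frequencies
#'
#' Inverts the factorized steady state: the log-odds score
#' \eqn{\hat\epsilon_{ia} = -(1/\beta_{lo}) \ln(p_i(a)/b(a))} recovers the
#' energy matrix up to a per-position additive shift (and overall scale
#' \eqn{\mathrm{rate}/\beta_{lo}}), valid only under site independence.
#'
#' @param obs_freqs 4 x L matrix of observed base frequencies (columns sum
#'   to 1).
#' @param mono per-base background probabilities.
#' @param beta_lo effective inverse temperature for the score (default
#'   room temperature, 1.686).
#' @param pseudocount added to all frequencies before normalization when
#'   zeros are present (default 0: zero frequencies are an error unless a
#'   pseudocount is supplied).
#' @return an \code{energy_matrix} of log-odds energies.
#' @export
log_odds_matrix <- function(obs_freqs, mono, beta_lo = 1.686,
                            pseudocount = 0) {
  obs_freqs <- as.matrix(obs_freqs)
  stopifnot(nrow(obs_freqs) == 4L, length(mono) == 4L)
  if (any(obs_freqs <= 0)) {
    if (pseudocount <= 0)
      stop("zero observed frequencies; supply a positive pseudocount")
    obs_freqs <- obs_freqs + pseudocount
    obs_freqs <- sweep(obs_freqs, 2L, colSums(obs_freqs), "/")
  }
  energy_matrix(-log(obs_freqs / mono) / beta_lo, tf_name = "log_odds")
}
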
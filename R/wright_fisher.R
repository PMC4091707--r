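# Forward Wright-Fisher validation of the monomorphic steady-state theory:
# simulate binding-site evolution, compare observed energy distributions to
# the predicted steady state by total variation distance, and rerun the
# maximum-likelihood inference on simulated samples.

#' Wright-Fisher simulation configuration
#'
#' @param N population size (>= 2).
#' @param L site length, bp.
#' @param mu_rate per-base per-generation mutation probability in [0, 1];
#'   mutations go uniformly to one of the three other bases.
#' @param fitness an \code{fd_params} (used as the per-generation fitness
#'   F(E)) or an \code{exp_params} (per-generation F = exp(-rate E)).
#' @param matrix an \code{energy_matrix} mapping sequences to energies.
#' @param generations number of non-overlapping generations to run.
#' @param n_replicates independent replicate populations.
#' @param checkpoints generations at which to record (default: final
#'   generation only).  At each checkpoint one random individual's sequence
#'   and the number of unique sequences are recorded per replicate.
#' @param seed optional integer seed.
#' @param start_seq optional fixed starting sequence (string); default is
#'   a random monomorphic start per replicate.
#' @return object of class \code{wf_config}.
#' @export
wf_config <- function(N, L, mu_rate, fitness, matrix, generations,
                      n_replicates = 500L, checkpoints = NULL, seed = NULL,
                      start_seq = NULL) {
  stopifnot(N >= 2, mu_rate >= 0, mu_rate <= 1, generations >= 0,
            n_replicates >= 1, em_length(matrix) == L)
  if (is.null(checkpoints)) checkpoints <- generations
  checkpoints <- sort(unique(as.integer(checkpoints)))
  stopifnot(all(checkpoints >= 0), all(checkpoints <= generations))
  structure(list(N = as.integer(N), L = as.integer(L), mu_rate = mu_rate,
                 fitness = fitness, matrix = matrix,
                 generations = as.integer(generations),
                 n_replicates = as.integer(n_replicates),
                 checkpoints = checkpoints, seed = seed,
                 start_seq = start_seq),
            class = "wf_config")
}

#' Geometric checkpoint schedule
#' @param generations final generation.
#' @param n number of checkpoints.
#' @return increasing integer vector ending at \code{generations}.
#' @export
checkpoint_schedule <- function(generations, n = 12L) {
  g <- unique(pmax(1L, round(exp(seq(0, log(generations), length.out = n)))))
  sort(unique(c(g, generations)))
}

#' Run a Wright-Fisher simulation
#'
#' Each generation applies a selection step (fitness-weighted multinomial
#' resampling to size N) then a mutation step (each base mutates with
#' probability \code{mu_rate}).  Each replicate starts from a monomorphic
#' random sequence.  Deterministic given \code{seed}.
#'
#' @param config a \code{wf_config}.
#' @return object of class \code{sim_result}: \code{sequences} (replicates
#'   x checkpoints character matrix; one randomly sampled sequence per
#'   replicate per checkpoint), \code{unique_counts} (same shape),
#'   \code{energies} (numeric, same shape), \code{checkpoints},
#'   \code{config}.
#' @export
wf_simulate <- function(config) {
  stopifnot(inherits(config, "wf_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  fit <- config$fitness
  if (inherits(fit, "fd_params")) {
    type <- 0L; p1 <- fit$f0; p2 <- fit$beta; p3 <- fit$mu
  } else if (inherits(fit, "exp_params")) {
    type <- 1L; p1 <- fit$rate; p2 <- 0; p3 <- 0
  } else stop("fitness must be fd_params or exp_params")
  start <- NULL
  if (!is.null(config$start_seq))
    start <- as.integer(encode_sites(config$start_seq)[1, ])
  raw <- wf_simulate_cpp(config$N, config$L, config$mu_rate,
                         unclass(config$matrix), type, p1, p2, p3,
                         config$checkpoints, config$n_replicates, start)
  seqs <- raw$sequences
  en <- matrix(NA_real_, nrow(seqs), ncol(seqs))
  for (j in seq_len(ncol(seqs)))
    en[, j] <- site_energy(config$matrix, seqs[, j])
  structure(list(sequences = seqs, unique_counts = raw$unique_counts,
                 energies = en, checkpoints = config$checkpoints,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("WF simulation: %d replicates, %d checkpoints (final gen %d)\n",
              nrow(x$sequences), length(x$checkpoints),
              max(x$checkpoints)))
  cat(sprintf("final mean unique sequences: %.3f\n",
              mean(x$unique_counts[, ncol(x$unique_counts)])))
  invisible(x)
}

#' Bin energies on the matrix's full range (100 equal bins by convention)
#' @param energies numeric vector.
#' @param matrix the \code{energy_matrix} whose realizable range defines
#'   the bins.
#' @param n_bins number of equal-size bins (default 100).
#' @return list with \code{edges} (length n_bins + 1) and \code{prob}.
#' @export
wf_energy_distribution <- function(energies, matrix, n_bins = 100L) {
  er <- em_energy_range(matrix)
  edges <- seq(er[1] - 1e-9, er[2] + 1e-9, length.out = n_bins + 1L)
  b <- findInterval(energies, edges, rightmost.closed = TRUE,
                    all.inside = TRUE)
  list(edges = edges, prob = tabulate(b, nbins = n_bins) / length(energies))
}

#' Predicted monomorphic steady-state energy distribution for a WF run
#'
#' \eqn{P(\sigma) \propto \pi_0(\sigma) F(\sigma)^\nu} with the uniform
#' neutral distribution implied by the symmetric mutation model, projected
#' to energies and binned like [wf_energy_distribution()].  Exact
#' enumeration for L <= 12.
#'
#' @param matrix an \code{energy_matrix} (L <= 12).
#' @param fitness \code{fd_params} or \code{exp_params}.
#' @param nu exponent; the Wright-Fisher correspondence is nu = 2N - 2.
#' @param n_bins number of bins (default 100).
#' @return list with \code{edges} and \code{prob}.
#' @export
wf_predicted_distribution <- function(matrix, fitness, nu, n_bins = 100L) {
  E <- enumerate_energies(matrix)
  lw <- ln_fitness_nu(E, fitness, nu)  # uniform pi0 cancels
  w <- exp(lw - max(lw))
  er <- em_energy_range(matrix)
  edges <- seq(er[1] - 1e-9, er[2] + 1e-9, length.out = n_bins + 1L)
  b <- findInterval(E, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pr <- vapply(seq_len(n_bins), function(k) sum(w[b == k]), numeric(1))
  list(edges = edges, prob = pr / sum(pr))
}

#' Total variation distance between two distributions on shared bins
#' @param P,Q probability vectors on the same bins.
#' @return \eqn{\frac{1}{2}\sum_i |P_i - Q_i|} in [0, 1].
#' @export
tvd <- function(P, Q) {
  if (length(P) != length(Q)) stop("distributions must share the same bins")
  sum(abs(P - Q)) / 2
}

#' Mean number of unique sequences per population (degree of polymorphism)
#' @param sim a \code{sim_result}.
#' @param checkpoint column index (default: final checkpoint).
#' @return mean over replicates of the unique-sequence count.
#' @export
polymorphism_stats <- function(sim, checkpoint = NULL) {
  u <- sim$unique_counts
  if (is.null(checkpoint)) checkpoint <- ncol(u)
  mean(u[, checkpoint])
}

#' Expected polymorphism from a per-site polymorphic proportion
#'
#' With probability \code{p_site} per base of segregating (at most two
#' alleles), a locus of L bases carries on average
#' \eqn{1 + (1 - (1 - p)^L)} distinct sequences.
#'
#' @param p_site per-base polymorphic proportion.
#' @param L locus length, bp.
#' @return expected mean unique-sequence count.
#' @export
expected_polymorphism <- function(p_site = 0.001, L = 10L) {
  1 + (1 - (1 - p_site)^L)
}

#' Mutation-rate threshold for the monomorphic limit
#'
#' Monomorphism requires the mutation supply \eqn{\mu N L} to be small;
#' two standard forms of the threshold are provided: \code{basic}
#' \eqn{1/(NL)} and \code{log_corrected} \eqn{1/(NL \ln N)} (default; the
#' extra \eqn{\ln N} accounts for the drift time of segregating neutral
#' mutations).
#'
#' @param N population size.
#' @param L locus length.
#' @param form "log_corrected" (default) or "basic".
#' @return mutation-rate threshold.
#' @export
monomorphism_bound <- function(N, L, form = c("log_corrected", "basic")) {
  form <- match.arg(form)
  stopifnot(N >= 2, L >= 1)
  switch(form,
         basic = 1 / (N * L),
         log_corrected = 1 / (N * L * log(N)))
}

#' Standard Wright-Fisher validation study
#'
#' The packaged validation design: a unit-SD random L = 10 matrix
#' (grid-aligned at 0.05 kcal/mol), uniform neutral background, the
#' "non-lethal" Fermi-Dirac landscape (f0 = 0.99, beta = 1, mu one SD
#' below the neutral mean) evolving in N = 1000 haploids (nu = 2N - 2,
#' so gamma just under 20).  Three conditions are simulated and refitted
#' (CFD, 3 parameters, resampled as \code{n_samples} draws of
#' \code{sample_size} sequences each):
#' \describe{
#'   \item{below_bound}{mutation rate 1e-5 (under the monomorphism
#'     bound), run to steady state (6e5 generations).}
#'   \item{above_bound}{mutation rate 3e-4 (polymorphic), at its own
#'     steady state.}
#'   \item{pre_steady}{mutation rate 1e-5 stopped at 1.2e5 generations,
#'     about a fifth of the equilibration time, started from the
#'     consensus (minimum-energy) sequence: populations are still
#'     relaxing upward from a strong binder and have not yet populated
#'     the high-energy side of the steady state.}
#' }
#'
#' @param seed integer seed for simulations and resampling.
#' @param n_replicates WF replicates per condition (default 500).
#' @param n_samples,sample_size resampling scheme (default 200 x 500).
#' @return list with \code{summary} (one row per condition: mean and SD
#'   of fitted gamma, nu, beta, mu), \code{fits} (all refits),
#'   \code{truth}, and the study \code{matrix}/\code{spectrum}.
#' @export
wf_validation_study <- function(seed = 1, n_replicates = 500L,
                                n_samples = 200L, sample_size = 500L) {
  em <- snap_matrix(random_energy_matrix(10, seed = 3), 0.05)
  bg <- markov_background(rep(0.25, 4))
  sp <- neutral_energy_spectrum(bg, em, 0.05)
  m <- sum(sp$centers * sp$prob)
  truth <- fd_params(0.99, 1, m - 1, 1998)
  mesh <- default_mesh(sp, mu_margin = 3)
  mesh$nu <- 10^seq(0, 6, by = 0.2)
  conds <- list(below_bound = list(mu_rate = 1e-5, generations = 6e5),
                above_bound = list(mu_rate = 3e-4, generations = 2e4),
                pre_steady = list(mu_rate = 1e-5, generations = 1.2e5,
                                  start = consensus_site(em)$seq))
  fits <- list()
  for (nm in names(conds)) {
    rec <- recovery_experiment(em, truth, nu_true = 1998,
                               mu_rates = conds[[nm]]$mu_rate,
                               N = 1000L, n_replicates = n_replicates,
                               generations = conds[[nm]]$generations,
                               spectrum = sp, model = "CFD", mesh = mesh,
                               n_samples = n_samples,
                               sample_size = sample_size, seed = seed,
                               start_seq = conds[[nm]]$start)
    f <- rec$fits
    f$condition <- nm
    fits[[nm]] <- f
  }
  fits <- do.call(rbind, fits)
  agg <- do.call(rbind, lapply(split(fits, fits$condition), function(d)
    data.frame(condition = d$condition[1],
               gamma_mean = mean(d$gamma), gamma_sd = sd(d$gamma),
               nu_mean = mean(d$nu), beta_mean = mean(d$beta),
               mu_mean = mean(d$mu), mu_sd = sd(d$mu))))
  rownames(agg) <- NULL
  list(summary = agg, fits = fits,
       truth = list(params = truth, nu = 1998, gamma = 1998 * 0.01),
       matrix = em, spectrum = sp)
}

#' Parameter-recovery experiment over a sweep of mutation rates
#'
#' For each mutation rate: run a WF ensemble to the requested generation,
#' pool one final sequence per replicate, then repeatedly resample
#' \code{sample_size} sequences and refit the fitness parameters by grid
#' search, reporting the fitted values against the generating truth.
#'
#' @param matrix grid-aligned \code{energy_matrix}.
#' @param fitness generating \code{fd_params}.
#' @param nu_true generating exponent (2N - 2 for WF).
#' @param mu_rates mutation rates to sweep.
#' @param N,n_replicates WF scale.
#' @param generations vector (recycled) of generations per rate; default
#'   10/(L*mu), the expected relaxation scale times ten.
#' @param spectrum neutral spectrum for the fits (uniform background).
#' @param model fit model (default "CFD": f0 pinned, 3 parameters).
#' @param mesh fit mesh (default: [default_mesh()] coarsened once, the
#'   doubled-spacing convention for repeated refits).
#' @param n_samples,sample_size resampling scheme (default 200 x 500).
#' @param seed integer seed.
#' @return list with \code{fits} (data.frame: mu_rate, sample, fitted
#'   params), \code{pools} (list of pooled energies per rate), and
#'   \code{truth}.
#' @export
recovery_experiment <- function(matrix, fitness, nu_true, mu_rates,
                                N = 1000L, n_replicates = 500L,
                                generations = NULL, spectrum,
                                model = "CFD",
                                mesh = mesh_coarsen(default_mesh(spectrum)),
                                n_samples = 200L, sample_size = 500L,
                                seed = 1L, start_seq = NULL) {
  L <- em_length(matrix)
  if (is.null(generations))
    generations <- pmin(ceiling(10 / (L * mu_rates)), 2e6)
  generations <- rep_len(generations, length(mu_rates))
  set.seed(seed)
  rows <- list(); pools <- list()
  for (i in seq_along(mu_rates)) {
    cfg <- wf_config(N = N, L = L, mu_rate = mu_rates[i], fitness = fitness,
                     matrix = matrix, generations = generations[i],
                     n_replicates = n_replicates, start_seq = start_seq)
    sim <- wf_simulate(cfg)
    pool <- sim$energies[, ncol(sim$energies)]
    pools[[i]] <- pool
    for (s in seq_len(n_samples)) {
      e <- pool[sample.int(length(pool), sample_size, replace = TRUE)]
      ft <- suppressWarnings(fit_gridsearch(e, spectrum, model, mesh = mesh))
      rows[[length(rows) + 1L]] <-
        data.frame(mu_rate = mu_rates[i], sample = s, f0 = ft$params$f0,
                   beta = ft$params$beta, mu = ft$params$mu,
                   nu = ft$params$nu, gamma = ft$params$gamma, lnL = ft$lnL)
    }
  }
  list(fits = do.call(rbind, rows), pools = pools,
       truth = list(fitness = fitness, nu = nu_true,
                    gamma = nu_true * (1 - fitness$f0)))
}
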
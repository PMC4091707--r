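# Seeded synthetic-data generator: emulates every input the pipeline
# needs (energy matrix, intergenic background, steady-state site
# collections, gene annotations, ortholog pairs) with a truth record, so
# the full analysis runs and is validated with no external data.

#' Yeast-like default background (AT-rich, mild dinucleotide structure)
#'
#' Illustrative composition for an AT-rich intergenic background: mono
#' A = T = 0.31, C = G = 0.19, with a small same-base dinucleotide excess.
#' Not estimated from any genome; a stand-in with realistic gross
#' composition.
#'
#' @param at AT mono probability per base (default 0.31).
#' @param self_excess extra weight on same-base dinucleotides (default
#'   0.04) before renormalization.
#' @return a \code{markov_background}.
#' @export
yeastlike_background <- function(at = 0.31, self_excess = 0.04) {
  mono <- c(A = at, C = 0.5 - at, G = 0.5 - at, T = at)
  di <- outer(mono, mono)
  diag(di) <- diag(di) + self_excess * mono
  di <- di / sum(di)
  # keep the stated mono composition as the chain's initial distribution
  markov_background(mono, di)
}

#' Sample a sequence from the background Markov chain
#' @param bg a \code{markov_background}.
#' @param length number of bases.
#' @param seed optional integer seed.
#' @return a single DNA string.
#' @export
sample_background_sequence <- function(bg, length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length >= 1)
  code <- integer(length)
  code[1] <- sample.int(4L, 1L, prob = bg$mono)
  if (length >= 2L)
    for (i in 2:length)
      code[i] <- sample.int(4L, 1L, prob = bg$trans[code[i - 1L], ])
  paste(DNA_BASES[code], collapse = "")
}

#' Sample binding sites from the mutation-selection-drift steady state
#'
#' Draws sequences with probability
#' \eqn{P(\sigma) \propto \pi_0(\sigma) F(E(\sigma))^\nu}.  For L <= 10
#' the 4^L weights are enumerated and sampled exactly; for larger L a
#' seeded single-site Metropolis sampler over sequence space is used
#' (burn-in 200 L sweeps-equivalent, thinning 20 L proposals, documented
#' in the methods vignette).
#'
#' @param matrix an \code{energy_matrix}.
#' @param background a \code{markov_background} (neutral distribution).
#' @param fitness \code{fd_params} or \code{exp_params}.
#' @param nu population-size exponent.
#' @param n number of sites to draw (>= 1).
#' @param seed optional integer seed.
#' @param burn_in,thin Metropolis schedule (proposals), used only for
#'   L > 10.
#' @return character vector of n sequences.
#' @export
sample_steady_state_sites <- function(matrix, background, fitness, nu, n,
                                      seed = NULL, burn_in = NULL,
                                      thin = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- em_length(matrix)
  if (L <= 10L) {
    lw <- enumerate_log_pi0(background, L) +
      ln_fitness_nu(enumerate_energies(matrix), fitness, nu)
    w <- exp(lw - max(lw))
    idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    return(index_to_seq(idx, L))
  }
  metropolis_sites(matrix, background, fitness, nu, n,
                   burn_in = burn_in %||% 200L * L,
                   thin = thin %||% 20L * L)
}

# single-site Metropolis over sequence space; target pi0 * F^nu
metropolis_sites <- function(matrix, background, fitness, nu, n, burn_in,
                             thin) {
  L <- em_length(matrix)
  m <- unclass(matrix)
  lt <- log(background$trans)
  lmono <- log(background$mono)
  code <- encode_sites(sample_background_sequence(background, L))[1, ]
  cur_lpi <- lmono[code[1]] +
    (if (L > 1) sum(lt[cbind(code[-L], code[-1])]) else 0)
  cur_E <- sum(m[cbind(code, seq_len(L))])
  cur_lw <- cur_lpi + ln_fitness_nu(cur_E, fitness, nu)
  out <- character(n)
  total <- burn_in + n * thin
  got <- 0L
  for (step in seq_len(total)) {
    i <- sample.int(L, 1L)
    newb <- sample((1:4)[-code[i]], 1L)
    old <- code[i]
    code[i] <- newb
    lpi <- lmono[code[1]] +
      (if (L > 1) sum(lt[cbind(code[-L], code[-1])]) else 0)
    E <- sum(m[cbind(code, seq_len(L))])
    lw <- lpi + ln_fitness_nu(E, fitness, nu)
    if (log(runif(1)) < lw - cur_lw) {
      cur_lw <- lw
    } else {
      code[i] <- old
    }
    if (step > burn_in && (step - burn_in) %% thin == 0L) {
      got <- got + 1L
      out[got] <- paste(DNA_BASES[code], collapse = "")
    }
  }
  out[seq_len(got)]
}

#' Fixture configuration for the synthetic pipeline
#'
#' Defaults define the standing study conditions: an enumerable L = 8
#' site, 500 sites sampled from a threshold-regime "non-lethal"
#' Fermi-Dirac steady state (f0 = 0.99, beta = 1, mu = -1.5, nu = 2000,
#' so gamma = 20), AT-rich background, a 20 kb intergenic record, a null
#' gene table and 10% ortholog divergence.
#'
#' @param L site length.
#' @param regime target regime: "threshold", "tail" or "plateau".
#' @param params generating \code{fd_params} (or \code{exp_params});
#'   NULL picks a default consistent with \code{regime}.
#' @param nu exponent (ignored when params is \code{exp_params}).
#' @param n_sites number of sites.
#' @param background a \code{markov_background}.
#' @param genome_length background FASTA length (bases).
#' @param effect NULL for a null gene table, or a list such as
#'   \code{list(essential_energy_shift = -1)} for planted site-specific
#'   selection.
#' @param divergence per-base ortholog substitution probability.
#' @param bin_width spectrum bin width; the fixture matrix is snapped to
#'   this grid so enumeration, spectrum and likelihood agree exactly.
#' @param seed integer seed (fixtures are byte-identical given the seed).
#' @return object of class \code{fixture_config}.
#' @export
fixture_config <- function(L = 8L, regime = c("threshold", "tail", "plateau"),
                           params = NULL, nu = 2000, n_sites = 500L,
                           background = yeastlike_background(),
                           genome_length = 20000L, effect = NULL,
                           divergence = 0.1, bin_width = 0.02, seed = 1L) {
  regime <- match.arg(regime)
  structure(list(L = as.integer(L), regime = regime, params = params,
                 nu = nu, n_sites = as.integer(n_sites),
                 background = background,
                 genome_length = as.integer(genome_length), effect = effect,
                 divergence = divergence, bin_width = bin_width,
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# default generating parameters per regime, placed relative to the
# neutral spectrum (mean m, unit SD): threshold puts mu in the lower tail
# so sampled sites straddle it; tail puts mu below the whole support;
# plateau puts mu well above the neutral bulk so sites sit below it.
default_regime_params <- function(regime, nu, spectrum) {
  m <- sum(spectrum$centers * spectrum$prob)
  lo <- min(spectrum$centers)
  switch(regime,
         threshold = fd_params(f0 = 0.99, beta = 1, mu = m - 2, nu = nu),
         # tail TFs show gamma in the hundreds; mu below the support keeps
         # every site on the exponential flank while gamma*exp(-beta(E-mu))
         # stays O(10) at the low-energy end, i.e. real selection
         tail = fd_params(f0 = 0.99, beta = 1, mu = lo - 2.5, nu = 6 * nu),
         plateau = fd_params(f0 = 0.99, beta = 1, mu = m + 3, nu = nu))
}

#' Generate a complete synthetic fixture
#'
#' Produces every input the pipeline consumes: a grid-aligned random
#' unit-SD energy matrix, a background "intergenic" sequence from the
#' Markov chain, sites sampled from the exact steady state, a gene table
#' (null or with planted effects), ortholog pairs, and a truth record
#' carrying all generating parameters.
#'
#' @param config a \code{fixture_config}.
#' @return list with \code{matrix}, \code{background} (the generating
#'   \code{markov_background}), \code{intergenic} (one long DNA string),
#'   \code{sites} (an \code{aligned_site_set}), \code{spectrum}
#'   (neutral Q0 on the fixture grid), \code{annotated} (site/gene
#'   data.frame), \code{gene_table}, \code{ortholog_pairs}, \code{truth}.
#' @export
make_fixture <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  mono <- config$background$mono
  em <- snap_matrix(random_energy_matrix(config$L, background = mono),
                    config$bin_width)
  spectrum <- neutral_energy_spectrum(config$background, em,
                                      config$bin_width)
  er <- range(spectrum$centers)
  params <- config$params %||%
    default_regime_params(config$regime, config$nu, spectrum)
  nu <- if (inherits(params, "fd_params")) params$nu else 1
  if (inherits(params, "fd_params") &&
      (params$mu < er[1] - 10 || params$mu > er[2] + 10))
    stop("infeasible regime: mu lies far outside the matrix energy range ",
         sprintf("[%.2f, %.2f]", er[1], er[2]))
  seqs <- sample_steady_state_sites(em, config$background, params, nu,
                                    config$n_sites)
  e <- site_energy(em, seqs)
  if (inherits(params, "fd_params")) {
    got <- classify_regime(params, e)
    want <- if (config$regime == "tail") "exponential_tail" else config$regime
    if (got != want)
      stop(sprintf(paste0("infeasible regime: requested '%s' but sampled ",
                          "sites classify as '%s' for these parameters ",
                          "and matrix range [%.2f, %.2f]"),
                   want, got, er[1], er[2]))
  }
  sites <- structure(list(tf_name = attr(em, "tf_name"), sites = seqs,
                          energies = e, offset = 1L, strand = "+"),
                     class = "aligned_site_set")
  intergenic <- sample_background_sequence(config$background,
                                           config$genome_length)
  ann <- synth_gene_annotations(sites, effect = config$effect)
  pairs <- synth_ortholog_pairs(seqs, config$divergence)
  pairs$group <- ann$annotated$essential[match(seq_along(seqs),
                                               ann$annotated$site_id)]
  list(matrix = em, background = config$background,
       intergenic = intergenic, sites = sites, spectrum = spectrum,
       annotated = ann$annotated, gene_table = ann$gene_table,
       ortholog_pairs = pairs,
       truth = list(config = config, params = params, nu = nu,
                    gamma = if (inherits(params, "fd_params"))
                      params$gamma else NA_real_))
}

#' Synthetic gene annotations for a site collection
#'
#' Places each site on a synthetic chromosome with a gene TSS within the
#' upstream window (so the site-to-gene assignment rule applies), draws
#' essentiality labels and gene attributes, and optionally plants a
#' site-specific effect (e.g. an energy shift for sites regulating
#' essential genes) after sampling.
#'
#' @param sites an \code{aligned_site_set} (or list with \code{sites} and
#'   \code{energies}).
#' @param effect NULL (null table: attributes independent of energy) or a
#'   list with any of \code{essential_energy_shift} (added to the energy
#'   column of essential-gene sites) and \code{p_essential}.
#' @param window upstream window (default 700).
#' @param spacing chromosome spacing between sites (default 2000 bp).
#' @return list with \code{annotated} (per-site data.frame: site_id, tf,
#'   energy, gene_id, essential, growth_min, expression, dnds,
#'   tss_distance) and \code{gene_table}.
#' @export
synth_gene_annotations <- function(sites, effect = NULL, window = 700,
                                   spacing = 2000L) {
  n <- length(sites$sites)
  L <- nchar(sites$sites[1])
  p_ess <- (effect$p_essential %||% 0.2)
  start <- spacing * seq_len(n)
  mid <- start + L / 2
  gstrand <- sample(c("+", "-"), n, replace = TRUE)
  d <- sample.int(window - L - 10L, n, replace = TRUE) + L + 5L
  tss <- ifelse(gstrand == "+", mid + d, mid - d)
  essential <- ifelse(runif(n) < p_ess, "essential", "nonessential")
  growth <- matrix(runif(3L * n, 0.6, 1.0), n, 3L)
  growth[essential == "essential", ] <- NA_real_
  gene_table <- data.frame(gene_id = sprintf("gene%04d", seq_len(n)),
                           tss = tss, strand = gstrand, chrom = "chrS",
                           essential = essential,
                           growth_1 = growth[, 1], growth_2 = growth[, 2],
                           growth_3 = growth[, 3],
                           expression = stats::rlnorm(n, 0, 1),
                           dnds = runif(n, 0.01, 0.5))
  gene_table$growth_min <- pmin(gene_table$growth_1, gene_table$growth_2,
                                gene_table$growth_3)
  energy <- sites$energies
  shift <- effect$essential_energy_shift %||% 0
  if (shift != 0)
    energy[essential == "essential"] <-
      energy[essential == "essential"] + shift
  annotated <- data.frame(site_id = seq_len(n), tf = sites$tf_name,
                          chrom = "chrS", start = start, end = start + L,
                          energy = energy,
                          gene_id = gene_table$gene_id,
                          essential = essential,
                          growth_min = gene_table$growth_min,
                          expression = gene_table$expression,
                          dnds = gene_table$dnds, tss_distance = d)
  list(annotated = annotated, gene_table = gene_table)
}

#' Synthetic ortholog pairs at a set divergence
#'
#' Each base of each site is substituted with probability \code{d},
#' uniformly among the three alternative bases.
#'
#' @param sites character vector of sequences.
#' @param d per-base substitution probability in [0, 1].
#' @param seed optional integer seed.
#' @return data.frame with seq1 (input) and seq2 (diverged partner).
#' @export
synth_ortholog_pairs <- function(sites, d, seed = NULL) {
  stopifnot(d >= 0, d <= 1)
  if (!is.null(seed)) set.seed(seed)
  code <- encode_sites(sites)
  hit <- matrix(runif(length(code)) < d, nrow = nrow(code))
  shift <- matrix(sample.int(3L, length(code), replace = TRUE),
                  nrow = nrow(code))
  newc <- ifelse(hit, (code - 1L + shift) %% 4L + 1L, code)
  seq2 <- apply(matrix(DNA_BASES[newc], nrow = nrow(code)), 1L, paste,
                collapse = "")
  data.frame(seq1 = as.character(sites), seq2 = seq2,
             stringsAsFactors = FALSE)
}
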
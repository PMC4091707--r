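# Shared small fixtures, built once per test run.

uniform_bg <- markov_background(rep(0.25, 4))

# small random backgrounds/matrices with fixed seeds for oracle tests
toy_matrix <- function(L, seed, width = NULL) {
  em <- random_energy_matrix(L, seed = seed)
  if (!is.null(width)) em <- snap_matrix(em, width)
  em
}

random_bg <- function(seed) {
  set.seed(seed)
  mono <- runif(4, 0.5, 1.5); mono <- mono / sum(mono)
  di <- matrix(runif(16, 0.5, 1.5), 4) * outer(mono, mono)
  markov_background(mono, di / sum(di))
}

random_seqs <- function(n, L, seed, prob = rep(0.25, 4)) {
  set.seed(seed)
  apply(matrix(sample(c("A", "C", "G", "T"), n * L, TRUE, prob = prob),
               n, L), 1, paste, collapse = "")
}

# default threshold fixture reused across files (cached)
.fx_cache <- new.env()
threshold_fixture <- function(seed = 7, n_sites = 500) {
  key <- sprintf("fx_%d_%d", seed, n_sites)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- make_fixture(
      fixture_config(regime = "threshold", n_sites = n_sites, seed = seed))
  .fx_cache[[key]]
}

# exhaustive-enumeration steady state binned on the spectrum grid:
# the independent oracle for spectrum-based quantities (grid-aligned
# matrices make both routes exact)
enum_steady_probs <- function(em, bg, fitness, nu, width) {
  E <- enumerate_energies(em)
  lw <- enumerate_log_pi0(bg, em_length(em)) +
    tfscape:::ln_fitness_nu(E, fitness, nu)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  k <- as.integer(round(E / width))
  lo <- min(k); hi <- max(k)
  p <- vapply(lo:hi, function(kk) sum(w[k == kk]), numeric(1))
  list(centers = (lo:hi) * width, prob = p)
}
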
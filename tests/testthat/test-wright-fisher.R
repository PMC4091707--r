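# Forward Wright-Fisher simulation: determinism, fixation, stationarity
# against the monomorphic steady-state prediction, polymorphism counts,
# the monomorphism bound, and relaxation-time scaling.

test_that("tvd satisfies its defining identities", {
  expect_equal(tvd(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(tvd(c(1, 0), c(0, 1)), 1)
  expect_equal(tvd(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(tvd(c(1), c(0.5, 0.5)), "same bins")
})

test_that("monomorphism bound forms and monotonicity", {
  expect_equal(monomorphism_bound(1000, 10, "basic"), 1e-4)
  expect_equal(monomorphism_bound(1000, 10, "log_corrected"),
               1 / (1e4 * log(1000)), tolerance = 1e-12)
  expect_equal(monomorphism_bound(1000, 10), 1.45e-5, tolerance = 1e-2)
  for (form in c("basic", "log_corrected")) {
    expect_gt(monomorphism_bound(500, 10, form),
              monomorphism_bound(1000, 10, form))
    expect_gt(monomorphism_bound(1000, 5, form),
              monomorphism_bound(1000, 10, form))
  }
})

test_that("expected polymorphism from the per-site proportion", {
  expect_equal(expected_polymorphism(0.001, 10), 1 + (1 - 0.999^10))
  expect_equal(expected_polymorphism(0, 10), 1)
})

test_that("WF simulation is deterministic under seed and fixes without mutation", {
  em <- toy_matrix(6, seed = 301)
  flat <- fd_params(1, 1, 0, 0)
  cfg <- wf_config(N = 50, L = 6, mu_rate = 0, fitness = flat, matrix = em,
                   generations = 300, n_replicates = 10,
                   checkpoints = c(100, 200, 300), seed = 11)
  s1 <- wf_simulate(cfg)
  s2 <- wf_simulate(cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$unique_counts, s2$unique_counts)
  # without mutation the monomorphic start never changes
  expect_true(all(s1$unique_counts == 1))
  expect_true(all(s1$sequences[, 1] == s1$sequences[, 2]))
  expect_true(all(s1$sequences[, 2] == s1$sequences[, 3]))
  # monomorphic replicates have polymorphism exactly 1
  expect_equal(polymorphism_stats(s1), 1)
})

test_that("neutral fitness relaxes to the uniform neutral distribution", {
  em <- toy_matrix(10, seed = 311, width = 0.05)
  flat <- fd_params(1, 1, 0, 0)
  cfg <- wf_config(N = 100, L = 10, mu_rate = 1e-3, fitness = flat,
                   matrix = em, generations = 2500, n_replicates = 4000,
                   seed = 12)
  sim <- wf_simulate(cfg)
  obs <- wf_energy_distribution(sim$energies[, 1], em)
  pred <- wf_predicted_distribution(em, flat, 0)
  expect_lt(tvd(obs$prob, pred$prob), 0.05)
})

test_that("very high mutation rates drive P_obs to the neutral distribution", {
  em <- toy_matrix(10, seed = 311, width = 0.05)
  # strong selection, but mutation dominates at NL mu >> 1
  sel <- fd_params(0.99, 1, 4, 0)
  cfg <- wf_config(N = 100, L = 10, mu_rate = 1e-2, fitness = sel,
                   matrix = em, generations = 300, n_replicates = 4000,
                   seed = 13)
  sim <- wf_simulate(cfg)
  obs <- wf_energy_distribution(sim$energies[, 1], em)
  q0 <- wf_predicted_distribution(em, fd_params(1, 1, 0, 0), 0)
  expect_lt(tvd(obs$prob, q0$prob), 0.05)
})

test_that("populations started at the steady state stay there", {
  em <- toy_matrix(10, seed = 3, width = 0.05)
  bgu <- markov_background(rep(0.25, 4))
  sp <- neutral_energy_spectrum(bgu, em, 0.05)
  m <- sum(sp$centers * sp$prob)
  fit <- fd_params(0.99, 1, m - 1, 1998)
  pred <- wf_predicted_distribution(em, fit, 1998)
  pm <- sum(pred$prob * (pred$edges[-1] + pred$edges[-101]) / 2)
  E <- enumerate_energies(em)
  s0 <- index_to_seq(which.min(abs(E - pm)), 10)
  cfg <- wf_config(N = 1000, L = 10, mu_rate = 1e-5, fitness = fit,
                   matrix = em, generations = 5e4, n_replicates = 400,
                   seed = 8, start_seq = s0)
  sim <- wf_simulate(cfg)
  obs <- wf_energy_distribution(sim$energies[, 1], em)
  # TVD within ~2x of the pure sampling floor at 400 draws, and no
  # systematic drift of the mean
  expect_lt(tvd(obs$prob, pred$prob), 0.2)
  expect_lt(abs(mean(sim$energies[, 1]) - pm), 0.15)
})

test_that("relaxation time scales inversely with the mutation rate", {
  em <- toy_matrix(10, seed = 3, width = 0.05)
  bgu <- markov_background(rep(0.25, 4))
  sp <- neutral_energy_spectrum(bgu, em, 0.05)
  m <- sum(sp$centers * sp$prob)
  fit <- fd_params(0.99, 1, m - 1, 1998)
  pred <- wf_predicted_distribution(em, fit, 1998)
  pm <- sum(pred$prob * (pred$edges[-1] + pred$edges[-101]) / 2)
  tau_of <- function(mu, gmax) {
    cks <- unique(round(seq(gmax / 12, gmax, length.out = 12)))
    cfg <- wf_config(N = 1000, L = 10, mu_rate = mu, fitness = fit,
                     matrix = em, generations = max(cks),
                     n_replicates = 250, checkpoints = cks, seed = 9)
    sim <- wf_simulate(cfg)
    dev <- colMeans(sim$energies) - pm
    # exponential decay fit of the mean-energy excess
    ok <- dev > 0.05
    if (sum(ok) < 4) return(NA_real_)
    -1 / coef(lm(log(dev[ok]) ~ cks[ok]))[2]
  }
  t1 <- tau_of(1e-4, 4e4)
  t2 <- tau_of(4e-4, 1e4)
  expect_false(is.na(t1) || is.na(t2))
  ratio <- (t1 / t2) / 4  # expected tau ratio = mu2/mu1 = 4
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)
})

test_that("recovery_experiment returns seeded fit tables against truth", {
  em <- toy_matrix(8, seed = 321, width = 0.05)
  bgu <- markov_background(rep(0.25, 4))
  sp <- neutral_energy_spectrum(bgu, em, 0.05)
  m <- sum(sp$centers * sp$prob)
  fit <- fd_params(0.99, 1, m - 1, 398)
  mesh <- mesh_coarsen(default_mesh(sp))
  rec <- recovery_experiment(em, fit, nu_true = 398, mu_rates = 1e-4,
                             N = 200, n_replicates = 60,
                             generations = 2e4, spectrum = sp,
                             mesh = mesh, n_samples = 5, sample_size = 50,
                             seed = 31)
  expect_equal(nrow(rec$fits), 5L)
  expect_true(all(is.finite(rec$fits$gamma)))
  expect_equal(rec$truth$gamma, 398 * 0.01)
  rec2 <- recovery_experiment(em, fit, nu_true = 398, mu_rates = 1e-4,
                              N = 200, n_replicates = 60,
                              generations = 2e4, spectrum = sp,
                              mesh = mesh, n_samples = 5, sample_size = 50,
                              seed = 31)
  expect_identical(rec$fits, rec2$fits)
})
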
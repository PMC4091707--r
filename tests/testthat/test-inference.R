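# Landscape inference: steady-state density and likelihood vs exhaustive
# enumeration, grid-search fits, AICc/weights, nonparametric inversion,
# profiles, diagnostics, and the factorized exponential steady state.

test_that("steady_state_density: nu = 0 returns Q0; rescale invariance", {
  em <- toy_matrix(5, seed = 161, width = 0.02)
  bg <- random_bg(162)
  sp <- neutral_energy_spectrum(bg, em, 0.02)
  p0 <- steady_state_density(sp, fd_params(0.5, 1, 3, 0), 0)
  expect_equal(p0$prob, sp$prob, tolerance = 1e-12)

  # invariant under F -> c F: exp landscape with an additive ln-shift
  lnF <- function(E) -0.8 * E
  lnFc <- function(E) -0.8 * E + 3.7
  expect_equal(steady_state_density(sp, lnF, 2)$prob,
               steady_state_density(sp, lnFc, 2)$prob, tolerance = 1e-12)
})

test_that("steady_state_density equals 4^L enumeration on toy matrices", {
  em <- toy_matrix(5, seed = 171, width = 0.02)
  bg <- random_bg(172)
  sp <- neutral_energy_spectrum(bg, em, 0.02)
  for (fit in list(fd_params(0.4, 1.3, 4.0, 60), exp_params(1.7))) {
    nu <- if (inherits(fit, "fd_params")) fit$nu else 1
    ss <- steady_state_density(sp, fit, nu)
    oracle <- enum_steady_probs(em, bg, fit, nu, 0.02)
    keep <- ss$centers >= min(oracle$centers) - 1e-9 &
      ss$centers <= max(oracle$centers) + 1e-9
    expect_lt(max(abs(ss$prob[keep] - oracle$prob)), 1e-10)
  }
})

test_that("log_likelihood matches exhaustive sequence-space likelihood", {
  em <- toy_matrix(4, seed = 181, width = 0.02)
  bg <- random_bg(182)
  sp <- neutral_energy_spectrum(bg, em, 0.02)
  seqs <- sample_steady_state_sites(em, bg, fd_params(0.3, 1, 4, 50), 50,
                                    200, seed = 183)
  e <- site_energy(em, seqs)
  for (fit in list(fd_params(0.3, 1, 4, 50), fd_params(0.9, 0.5, 5, 500))) {
    # enumeration oracle: Z over all 4^4 sequences, site term at exact E
    E <- enumerate_energies(em)
    lw <- enumerate_log_pi0(bg, 4) + tfscape:::ln_fitness_nu(E, fit, fit$nu)
    m <- max(lw)
    lnZ <- m + log(sum(exp(lw - m)))
    oracle <- sum(tfscape:::ln_fitness_nu(e, fit, fit$nu)) - length(e) * lnZ
    expect_equal(log_likelihood(e, sp, fit, fit$nu), oracle,
                 tolerance = 1e-8)
  }
  # identical parameter sets give identical lnL
  expect_identical(log_likelihood(e, sp, fd_params(0.3, 1, 4, 50), 50),
                   log_likelihood(e, sp, fd_params(0.3, 1, 4, 50), 50))
  expect_error(log_likelihood(min(sp$centers) - 1, sp,
                              fd_params(0.3, 1, 4, 50), 50), "support")
})

test_that("model ranking is invariant to the dropped pi0 site terms", {
  em <- toy_matrix(4, seed = 191, width = 0.02)
  bg <- random_bg(192)
  sp <- neutral_energy_spectrum(bg, em, 0.02)
  seqs <- sample_steady_state_sites(em, bg, fd_params(0.99, 1, 4, 2000),
                                    2000, 300, seed = 193)
  e <- site_energy(em, seqs)
  const <- sum(log(sp$prob[tfscape:::site_bins(e, sp)]))
  models <- list(fd_params(0.99, 1, 4, 2000), fd_params(0.5, 2, 5, 100),
                 exp_params(2))
  lnl <- vapply(models, function(m)
    log_likelihood(e, sp, m, if (inherits(m, "fd_params")) m$nu else 1),
    numeric(1))
  expect_identical(order(lnl), order(lnl + const))
})

test_that("gamma degeneracy: equivalent ridge maxima on tail data", {
  # on tail-only data the likelihood depends on (f0, nu) only through the
  # ridge combination: profiling out nu at f0 = 0.99 vs 0.999 gives
  # indistinguishable maxima (the compensating nu is found continuously)
  em <- toy_matrix(6, seed = 201, width = 0.02)
  bg <- yeastlike_background()
  sp <- neutral_energy_spectrum(bg, em, 0.02)
  mu <- min(sp$centers) - 3
  gamma <- 50
  seqs <- sample_steady_state_sites(em, bg,
                                    fd_params(0.99, 1, mu, gamma / 0.01),
                                    gamma / 0.01, 400, seed = 202)
  e <- site_energy(em, seqs)
  o1 <- optimize_nu(e, sp, f0 = 0.99, beta = 1, mu = mu)
  o2 <- optimize_nu(e, sp, f0 = 0.999, beta = 1, mu = mu)
  expect_lt(abs(o1$lnL - o2$lnL), 0.01)
  # the profiled optima share gamma = nu (1 - f0) to first order
  expect_equal(o2$nu * 0.001, o1$nu * 0.01, tolerance = 0.02)
})

test_that("grid-search fits recover generating parameters", {
  # threshold fixture, CFD (the generating f0 equals the constraint):
  # gamma within 25%, mu within 0.3, regime recovered (n = 2000 so the
  # sampling error is below the stated tolerances)
  for (seed in c(2, 4)) {
    fx <- make_fixture(fixture_config(regime = "threshold",
                                      n_sites = 2000, seed = seed))
    ft <- fit_gridsearch(fx$sites$energies, fx$spectrum, "CFD")
    expect_lt(abs(ft$params$gamma - fx$truth$gamma) / fx$truth$gamma, 0.25)
    expect_lt(abs(ft$params$mu - fx$truth$params$mu), 0.3)
    expect_equal(ft$regime, "threshold")
    expect_false(ft$flags$mu_left || ft$flags$mu_right)
  }

  # EXP rate recovered within 10% at n = 1000
  em <- toy_matrix(8, seed = 211, width = 0.02)
  bg <- yeastlike_background()
  sp <- neutral_energy_spectrum(bg, em, 0.02)
  seqs <- sample_steady_state_sites(em, bg, exp_params(2.5), 1, 1000,
                                    seed = 212)
  fe <- fit_gridsearch(site_energy(em, seqs), sp, "EXP")
  expect_lt(abs(fe$params$rate - 2.5) / 2.5, 0.10)
  expect_equal(fe$k, 1L)

  # tail data: CFD lnL within 0.5 of UFD (their likelihoods are
  # essentially equivalent under the gamma degeneracy)
  fxt <- make_fixture(fixture_config(regime = "tail", seed = 7))
  mesh <- mesh_coarsen(default_mesh(fxt$spectrum))
  fu <- suppressWarnings(fit_gridsearch(fxt$sites$energies, fxt$spectrum,
                                        "UFD", mesh = mesh))
  fc <- suppressWarnings(fit_gridsearch(fxt$sites$energies, fxt$spectrum,
                                        "CFD", mesh = mesh))
  expect_lt(abs(fu$lnL - fc$lnL), 0.5)
  expect_true(fc$flags$mu_left)
  expect_error(fit_gridsearch(fxt$sites$energies, fxt$spectrum, "CFD",
                              mesh = list(f0 = 1, beta = numeric(0),
                                          mu = 1, nu = 1)), "empty mesh")
})

test_that("fitted mu-degeneracy flags track the generating regime", {
  # n = 2000 sites per replicate: at this sampling depth the fitted mu
  # lands on the correct side of the data for >= 90% of seeds
  hits <- 0L; total <- 0L
  for (seed in 1:8) {
    for (rg in c("tail", "threshold", "plateau")) {
      fx <- make_fixture(fixture_config(regime = rg, n_sites = 2000,
                                        seed = 20 + seed))
      ft <- fit_gridsearch(fx$sites$energies, fx$spectrum, "CFD")
      ok <- switch(rg,
                   tail = ft$flags$mu_left,
                   plateau = ft$flags$mu_right,
                   threshold = !ft$flags$mu_left && !ft$flags$mu_right)
      hits <- hits + ok; total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("AICc and Akaike weights follow the finite-sample formulas", {
  expect_equal(aicc(-100, 4, 50), 8 + 200 + 40 / 45, tolerance = 1e-12)
  expect_equal(aicc(-100, 4, 50), 208.8889, tolerance = 1e-4)
  expect_error(aicc(-10, 4, 5), "n > k")
  # n -> infinity reduces to 2k - 2 lnL; penalty difference -> -2
  expect_equal(aicc(-100, 3, 1e9) - aicc(-100, 4, 1e9), -2,
               tolerance = 1e-5)
  expect_equal(akaike_weights(c(10, 10, 10)), rep(1 / 3, 3))
  w <- akaike_weights(c(0, 2))
  expect_equal(w[1] / w[2], exp(1), tolerance = 1e-12)
  expect_error(akaike_weights(5), "two models")
})

test_that("landscape inversion round-trips a known Fermi-Dirac landscape", {
  fx <- threshold_fixture(seed = 7, n_sites = 500)
  em <- fx$matrix; bg <- fx$background; sp <- fx$spectrum
  truth <- fx$truth$params
  seqs <- sample_steady_state_sites(em, bg, truth, truth$nu, 1e4,
                                    seed = 221)
  e <- site_energy(em, seqs)
  bl <- invert_landscape(e, sp, nu = truth$nu, n_bins = 15)
  ok <- bl$defined
  expect_gt(sum(ok), 4)
  truth_lnF <- ln_fd_fitness(bl$center[ok], truth)
  r2 <- summary(lm(bl$ln_fitness[ok] ~ truth_lnF))$r.squared
  expect_gt(r2, 0.95)

  # null case: sites drawn from Q0 give a flat landscape within errors
  seqs0 <- sample_steady_state_sites(em, bg, fd_params(1, 1, 0, 0), 0,
                                     5000, seed = 222)
  bl0 <- invert_landscape(site_energy(em, seqs0), sp, nu = truth$nu,
                          n_bins = 15)
  ok0 <- bl0$defined & bl0$n_sites >= 5
  # flat within error bars: most bins near the common level, no trend
  dev <- (bl0$ln_fitness[ok0] - mean(bl0$ln_fitness[ok0])) / bl0$se[ok0]
  expect_gte(mean(abs(dev) < 2.5), 0.8)
  trend <- cor.test(bl0$center[ok0], bl0$ln_fitness[ok0])
  expect_gt(trend$p.value, 0.001)

  # empty bins are flagged, never interpolated
  expect_true(any(!bl$defined))
  expect_true(all(is.na(bl$ln_fitness[!bl$defined])))
})

test_that("profile likelihood re-optimizes and peaks at the joint optimum", {
  fx <- threshold_fixture(seed = 7, n_sites = 500)
  e <- fx$sites$energies; sp <- fx$spectrum
  mesh <- mesh_coarsen(default_mesh(sp))
  ft <- fit_gridsearch(e, sp, "CFD", mesh = mesh)
  pr <- profile_likelihood(e, sp, "CFD", "mu", grid = mesh$mu, mesh = mesh)
  expect_equal(max(pr$lnL), ft$lnL, tolerance = 1e-9)
  expect_equal(pr$value[which.max(pr$lnL)], ft$params$mu)
  # threshold data: on the full mesh the profile peaks inside the data
  # range and falls off sharply below it (mu is identified, unlike on
  # the tail)
  meshF <- default_mesh(sp)
  prF <- profile_likelihood(e, sp, "CFD", "mu",
                            grid = meshF$mu[seq(1, length(meshF$mu), 2)],
                            mesh = meshF)
  expect_gt(prF$value[which.max(prF$lnL)], min(e) - 0.5)
  expect_lt(prF$value[which.max(prF$lnL)], max(e) + 0.5)
  below <- prF$value < min(e) - 2
  expect_gt(max(prF$lnL) - max(prF$lnL[below]), 2)

  # tail data: mu profile flat (dlnL < 0.5) for mu below all site
  # energies, tracing the ridge with the compensating nu optimized
  # continuously (a discrete nu grid cannot follow nu e^{beta mu} = const)
  fxt <- make_fixture(fixture_config(regime = "tail", seed = 7))
  fc0 <- fit_gridsearch(fxt$sites$energies, fxt$spectrum, "CFD",
                        mesh = mesh_coarsen(default_mesh(fxt$spectrum)))
  hi <- min(fxt$sites$energies) - 3.5
  grid_lo <- seq(hi - 2.5, hi, by = 0.25)
  lnl <- vapply(grid_lo, function(mu)
    optimize_nu(fxt$sites$energies, fxt$spectrum, f0 = 0.99,
                beta = fc0$params$beta, mu = mu)$lnL, numeric(1))
  expect_lt(max(lnl) - min(lnl), 0.5)
})

test_that("diagnostics: eigen spectrum and subsample refits", {
  # tail data: near-zero Hessian eigenvalue along the constant-gamma
  # direction (1, 0, -1, 0) in (ln nu, ln beta, ln(1-f0), mu)
  fxt <- make_fixture(fixture_config(regime = "tail", seed = 7))
  meshT <- mesh_coarsen(default_mesh(fxt$spectrum))
  fc <- fit_gridsearch(fxt$sites$energies, fxt$spectrum, "CFD",
                       mesh = meshT)
  dg <- fit_diagnostics(fxt$sites$energies, fxt$spectrum, fc,
                        n_subsamples = 0)
  iv <- which.min(abs(dg$eigen$values))
  expect_lt(abs(dg$eigen$values[iv]) / max(abs(dg$eigen$values)), 1e-3)
  u <- c(1, 0, -1, 0) / sqrt(2)
  expect_gt(abs(sum(dg$eigen$vectors[, iv] * u)), 0.9)

  # well-identified threshold fit: negative curvature along every fitted
  # direction, and half-subsample refits concentrate near the full-data
  # optimum
  fx <- threshold_fixture(seed = 4, n_sites = 2000)
  ft <- fit_gridsearch(fx$sites$energies, fx$spectrum, "CFD")
  dg2 <- fit_diagnostics(fx$sites$energies, fx$spectrum, ft,
                         n_subsamples = 8, seed = 3)
  expect_true(all(dg2$eigen_free$values < 0))
  gam <- dg2$subsamples$gamma
  expect_lt(abs(median(log(gam)) - log(ft$params$gamma)), log(2))
  mus <- dg2$subsamples$mu
  expect_lt(abs(median(mus) - ft$params$mu), 1.5)
})

test_that("exponential steady state factorizes and log-odds inverts it", {
  em <- toy_matrix(4, seed = 231)
  mono <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  rate <- 1.4
  pf <- exp_factorized_steady_state(mono, em, rate)
  expect_equal(colSums(pf), rep(1, 4), tolerance = 1e-12)

  # full-form enumeration (factorized background) gives the same P(sigma)
  bgm <- markov_background(mono)
  E <- enumerate_energies(em)
  lw <- enumerate_log_pi0(bgm, 4) - rate * E
  w <- exp(lw); w <- w / sum(w)
  code <- encode_sites(index_to_seq(1:256, 4))
  pprod <- rep(1, 256)
  for (i in 1:4) pprod <- pprod * pf[cbind(code[, i], i)]
  expect_lt(max(abs(w - pprod)), 1e-12)

  # rate = 0 reproduces the background at every position
  p0 <- exp_factorized_steady_state(mono, em, 0)
  expect_true(all(abs(p0 - mono) < 1e-12))

  # round trip: log-odds of the factorized frequencies recovers the
  # matrix up to a per-position additive shift
  beta_lo <- 1.686
  lo <- log_odds_matrix(pf, mono, beta_lo = beta_lo)
  resid <- (unclass(lo) * beta_lo / rate) - unclass(em)
  resid <- sweep(resid, 2, colMeans(resid))
  expect_lt(max(abs(resid)), 1e-9)

  expect_error(log_odds_matrix(matrix(c(0, .5, .25, .25), 4, 1), mono),
               "pseudocount")
})

test_that("fit serialization writes valid JSON and TSV spectra", {
  fx <- threshold_fixture(seed = 7, n_sites = 500)
  mesh <- mesh_coarsen(default_mesh(fx$spectrum))
  ft <- fit_gridsearch(fx$sites$energies, fx$spectrum, "CFD", mesh = mesh)
  fj <- tempfile(fileext = ".json")
  write_fit_json(ft, fj)
  back <- jsonlite::read_json(fj)
  expect_equal(back$model, "CFD")
  expect_equal(back$params$gamma, ft$params$gamma, tolerance = 1e-12)
  fs <- tempfile(fileext = ".tsv")
  write_spectrum_tsv(fx$spectrum, fs)
  tab <- read.table(fs, header = TRUE, sep = "\t")
  expect_equal(sum(tab$prob), 1, tolerance = 1e-9)
  unlink(c(fj, fs))
})
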
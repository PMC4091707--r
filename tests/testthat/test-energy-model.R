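# Energy matrices: sequence energies, PSAM conversion, rescaling,
# alignment, Boltzmann logos, text IO.

test_that("site_energy sums per-position contributions", {
  zero <- energy_matrix(matrix(0, 4, 3))
  expect_identical(site_energy(zero, "ACG"), 0)

  single <- energy_matrix(matrix(c(0, 1, 2, 3), 4, 1))
  expect_equal(site_energy(single, "T"), 3)

  # brute-force per-position oracle on random sequences
  em <- toy_matrix(5, seed = 11)
  seqs <- random_seqs(100, 5, seed = 12)
  oracle <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(vapply(1:5, function(i) unclass(em)[ch[i], i], numeric(1)))
  }, numeric(1))
  expect_equal(site_energy(em, seqs), unname(oracle), tolerance = 1e-12)
})

test_that("site_energy rejects bad input explicitly", {
  em <- toy_matrix(4, seed = 1)
  expect_error(site_energy(em, "ACG"), "length")
  expect_error(site_energy(em, "ACGN"), "outside")
})

test_that("energy is additive over concatenated half-sites", {
  a <- toy_matrix(3, seed = 21)
  b <- toy_matrix(4, seed = 22)
  block <- energy_matrix(cbind(unclass(a), unclass(b)))
  s1 <- random_seqs(20, 3, seed = 23)
  s2 <- random_seqs(20, 4, seed = 24)
  expect_equal(site_energy(block, paste0(s1, s2)),
               site_energy(a, s1) + site_energy(b, s2), tolerance = 1e-12)
})

test_that("PSAM conversion: -ln(w)/beta, unit weights map to zero", {
  w <- matrix(1, 4, 2)
  expect_true(all(unclass(psam_to_energy_matrix(w)) == 0))
  w[2, 1] <- 0.5
  em <- psam_to_energy_matrix(w, beta_room = 1.686)
  expect_equal(unname(unclass(em)[2, 1]), log(2) / 1.686, tolerance = 1e-10)
  expect_equal(unname(unclass(em)[2, 1]), 0.4112, tolerance = 1e-3)
  # consensus (largest affinity) base gets the minimal energy 0
  col <- psam_to_energy_matrix(matrix(c(1, .1, .1, .1), 4, 1))
  expect_equal(unname(which.min(unclass(col)[, 1])), 1L)
  expect_equal(min(unclass(col)[, 1]), 0)
  expect_error(psam_to_energy_matrix(matrix(c(1, 0, 1, 1), 4, 1)), "positive")
})

test_that("PSAM conversion round-trips through its inverse", {
  set.seed(31)
  w <- matrix(runif(4 * 6, 0.05, 2), 4, 6)
  em <- psam_to_energy_matrix(w, beta_room = 1.686)
  expect_equal(energy_matrix_to_psam(em, beta_room = 1.686), w,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rescale_to_unit_sd gives exact analytic lambda and unit variance", {
  one <- energy_matrix(matrix(c(0, 0, 0, 2), 4, 1))
  r <- rescale_to_unit_sd(one)
  expect_equal(r$lambda, sqrt(0.75), tolerance = 1e-12)

  # idempotence: already unit-SD matrix has lambda 1
  r2 <- rescale_to_unit_sd(r$matrix)
  expect_equal(r2$lambda, 1, tolerance = 1e-12)

  # analytic variance of the rescaled matrix is exactly 1
  em <- toy_matrix(7, seed = 41)
  m <- unclass(em)
  b <- rep(0.25, 4)
  v <- sum(colSums((m - rep(colSums(m * b), each = 4))^2 * b))
  expect_equal(v, 1, tolerance = 1e-10)

  expect_error(rescale_to_unit_sd(energy_matrix(matrix(1, 4, 2))),
               "degenerate")
})

test_that("random matrices are seeded and give unit-SD background energies", {
  expect_identical(unclass(random_energy_matrix(10, seed = 5)),
                   unclass(random_energy_matrix(10, seed = 5)))
  em <- random_energy_matrix(10, seed = 5)
  expect_equal(dim(unclass(em)), c(4L, 10L))
  # Monte-Carlo: background-sampled energies have SD ~ 1, roughly Gaussian
  seqs <- random_seqs(20000, 10, seed = 6)
  e <- site_energy(em, seqs)
  expect_equal(sd(e), 1, tolerance = 0.02)
  expect_lt(abs(mean((e - mean(e))^3)), 0.3)  # near-zero skew
})

test_that("collection alignment recovers offsets and strands", {
  em <- toy_matrix(6, seed = 51)
  cons <- consensus_site(em)$seq
  set.seed(52)
  pre <- random_seqs(25, 2, seed = 52)
  post <- random_seqs(25, 3, seed = 53)

  # identity when sites already have the matrix length and favor the
  # forward strand (sampled under selection on the forward matrix)
  sites0 <- sample_steady_state_sites(em, uniform_bg,
                                      exp_params(3), 1, 25, seed = 54)
  al0 <- align_sites_to_matrix(em, sites0)
  expect_equal(al0$offset, 1L)
  expect_equal(al0$strand, "+")
  expect_equal(al0$energies, site_energy(em, sites0))

  # consensus embedded at offset 3 (2 bp of padding)
  embedded <- paste0(pre, cons, post)
  al <- align_sites_to_matrix(em, embedded)
  expect_equal(al$offset, 3L)
  expect_equal(al$strand, "+")
  expect_true(all(al$sites == cons))

  # reverse-complemented consensus recovered on the minus strand
  alrc <- align_sites_to_matrix(em, revcomp(embedded))
  expect_equal(alrc$strand, "-")
  expect_true(all(alrc$sites == cons))

  # never worse than any other single (offset, strand): exhaustive scan
  raw <- random_seqs(30, 9, seed = 55)
  alr <- align_sites_to_matrix(em, raw)
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") raw else revcomp(raw)
    for (off in 1:4) {
      alt <- mean(site_energy(em, substr(ss, off, off + 5)))
      expect_gte(alt, mean(alr$energies) - 1e-10)
    }
  }
  expect_error(align_sites_to_matrix(em, c("ACGT")), "long")
})

test_that("Boltzmann logo is the per-position softmax", {
  em <- energy_matrix(matrix(0, 4, 3))
  expect_true(all(abs(boltzmann_logo(em) - 0.25) < 1e-12))
  em2 <- toy_matrix(5, seed = 61)
  expect_true(all(abs(boltzmann_logo(em2, beta = 0) - 0.25) < 1e-12))
  lg <- boltzmann_logo(em2, beta = 1.686)
  expect_equal(colSums(lg), rep(1, 5), tolerance = 1e-12)
  col <- energy_matrix(matrix(c(0, 5, 5, 5), 4, 1))
  expect_equal(unname(boltzmann_logo(col, beta = 1.686)[1, 1]),
               1 / (1 + 3 * exp(-1.686 * 5)), tolerance = 1e-10)
  expect_equal(unname(boltzmann_logo(col, beta = 1.686)[1, 1]), 0.99934,
               tolerance = 1e-4)
})

test_that("matrix text format round-trips, including PSAM variant", {
  em <- toy_matrix(6, seed = 71)
  f <- tempfile(fileext = ".txt")
  write_energy_matrix(em, f)
  back <- read_energy_matrix(f)
  expect_equal(unclass(back), unclass(em), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "tf_name"), attr(em, "tf_name"))

  w <- energy_matrix_to_psam(em)
  fp <- tempfile(fileext = ".txt")
  write_energy_matrix(energy_matrix(w, tf_name = "psamTF"), fp,
                      type = "psam")
  back2 <- read_energy_matrix(fp, beta_room = 1.686)
  expect_equal(unclass(back2), unclass(em), tolerance = 1e-10,
               ignore_attr = TRUE)
  unlink(c(f, fp))
})

test_that("BED-like site reader filters on posterior and extracts strands", {
  genome <- c(chr1 = "AAACGTACGTACGTTT")
  d <- data.frame(chrom = "chr1", start = c(3L, 7L), end = c(7L, 11L),
                  strand = c("+", "-"), posterior = c(0.95, 0.5))
  f <- tempfile(fileext = ".tsv")
  write.table(d, f, sep = "\t", row.names = FALSE, quote = FALSE)
  sites <- read_sites_bed(f)
  expect_equal(nrow(sites), 1L)  # posterior 0.5 dropped
  expect_equal(extract_site_seqs(sites, genome), "CGTA")
  # minus strand reverse-complemented
  d$posterior <- 0.99
  write.table(d, f, sep = "\t", row.names = FALSE, quote = FALSE)
  sites <- read_sites_bed(f)
  expect_equal(extract_site_seqs(sites, genome),
               unname(c("CGTA", revcomp(substr(genome, 8, 11)))))
  unlink(f)
})
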
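# Additive TF-DNA energy matrices: construction, sequence energies, PSAM
# conversion, unit-SD rescaling, collection alignment, Boltzmann logos.

#' Construct an energy matrix
#'
#' An energy matrix parameterizes additive TF-DNA binding energetics: entry
#' \code{entries[a, i]} is the contribution (kcal/mol) of base \code{a} at
#' position \code{i}, and the energy of a site is the sum over positions.
#'
#' @param entries numeric 4 x L matrix; rows in order A, C, G, T (row names,
#'   if present, must match).
#' @param tf_name label for the factor the matrix describes.
#' @param units energy units label (informational), default kcal/mol.
#' @return An object of class \code{energy_matrix} (a 4 x L matrix with
#'   attributes \code{tf_name} and \code{units}).
#' @export
energy_matrix <- function(entries, tf_name = "TF", units = "kcal/mol") {
  entries <- as.matrix(entries)
  if (nrow(entries) != 4L)
    stop("energy matrix must have 4 rows (A, C, G, T)")
  if (ncol(entries) < 1L)
    stop("energy matrix must have at least one position")
  if (!all(is.finite(entries)))
    stop("energy matrix entries must all be finite")
  if (!is.null(rownames(entries)) && !identical(rownames(entries), DNA_BASES))
    stop("row names, if given, must be A, C, G, T in that order")
  dimnames(entries) <- list(DNA_BASES, NULL)
  structure(entries, class = "energy_matrix",
            tf_name = tf_name, units = units)
}

#' @export
print.energy_matrix <- function(x, ...) {
  cat(sprintf("energy matrix '%s': %d bp, units %s\n",
              attr(x, "tf_name"), ncol(x), attr(x, "units")))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Number of positions in an energy matrix
#' @param matrix an \code{energy_matrix}.
#' @return integer site length L.
#' @export
em_length <- function(matrix) ncol(matrix)

#' Minimum-energy (consensus) sequence and energy
#' @param matrix an \code{energy_matrix}.
#' @return list with \code{seq} (consensus string, ties to the first base in
#'   A,C,G,T order) and \code{energy} (sum of per-position minima).
#' @export
consensus_site <- function(matrix) {
  idx <- apply(unclass(matrix), 2L, which.min)
  list(seq = paste(DNA_BASES[idx], collapse = ""),
       energy = sum(apply(unclass(matrix), 2L, min)))
}

#' Range of energies realizable under an energy matrix
#' @param matrix an \code{energy_matrix}.
#' @return numeric c(min, max): column-wise minimum and maximum sums.
#' @export
em_energy_range <- function(matrix) {
  m <- unclass(matrix)
  c(sum(apply(m, 2L, min)), sum(apply(m, 2L, max)))
}

# Encode DNA strings (equal length) as an integer matrix, one row per site,
# values 1..4 for A,C,G,T.  Errors on any other character unless allow_n.
encode_sites <- function(seqs, allow_other = FALSE) {
  seqs <- toupper(as.character(seqs))
  n <- length(seqs)
  if (n == 0L) stop("no sequences given")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences must all have the same length")
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  code <- match(chars, DNA_BASES)
  if (!allow_other && anyNA(code))
    stop("sequences contain characters outside A, C, G, T")
  matrix(code, nrow = n)
}

#' Binding energy of sites under an energy matrix
#'
#' Sums the per-position contributions \code{matrix[base_i, i]} over the
#' site.  Strictly additive; non-ACGT characters and length mismatches are
#' errors (no silent handling of ambiguity codes).
#'
#' @param matrix an \code{energy_matrix}.
#' @param seq character vector of DNA strings, each of length
#'   \code{em_length(matrix)}.
#' @return numeric vector of energies (same units as the matrix).
#' @export
site_energy <- function(matrix, seq) {
  L <- em_length(matrix)
  code <- encode_sites(seq)
  if (ncol(code) != L)
    stop(sprintf("site length %d does not match matrix length %d",
                 ncol(code), L))
  m <- unclass(matrix)
  e <- numeric(nrow(code))
  for (i in seq_len(L)) e <- e + m[code[, i], i]
  unname(e)
}

#' Convert a position-specific affinity matrix (PSAM) to an energy matrix
#'
#' PSAM entries w are relative affinities; the corresponding energies are
#' \eqn{\epsilon = -\ln(w)/\beta}.  An entry w = 1 (the reference base) maps
#' to energy 0, and larger affinities map to lower energies.
#'
#' @param psam 4 x L matrix of positive affinity weights (rows A,C,G,T).
#' @param beta_room inverse temperature in (kcal/mol)^-1; the default 1.686
#'   corresponds to kB*T = 0.593 kcal/mol at 298 K.
#' @param tf_name label for the resulting matrix.
#' @return an \code{energy_matrix} in kcal/mol.
#' @export
psam_to_energy_matrix <- function(psam, beta_room = 1.686, tf_name = "TF") {
  psam <- as.matrix(psam)
  if (any(!is.finite(psam)) || any(psam <= 0))
    stop("PSAM entries must be positive and finite")
  if (beta_room <= 0) stop("beta_room must be positive")
  energy_matrix(-log(psam) / beta_room, tf_name = tf_name)
}

#' Inverse of \code{psam_to_energy_matrix} (affinity weights from energies)
#' @param matrix an \code{energy_matrix}.
#' @param beta_room inverse temperature, (kcal/mol)^-1.
#' @return 4 x L matrix of positive weights.
#' @export
energy_matrix_to_psam <- function(matrix, beta_room = 1.686) {
  exp(-beta_room * unclass(matrix))
}

#' Rescale an energy matrix to unit background standard deviation
#'
#' Divides all entries by
#' \eqn{\lambda = \sqrt{\sum_i \sum_a b(a) (\epsilon_{ia} - \bar\epsilon_i)^2}},
#' the standard deviation of the energy of a random sequence with
#' independent per-position base probabilities \code{background}.  After
#' rescaling, that standard deviation is exactly 1.
#'
#' @param matrix an \code{energy_matrix}.
#' @param background per-base probabilities b(A..T), summing to 1.
#' @return list with elements \code{matrix} (rescaled \code{energy_matrix})
#'   and \code{lambda} (the positive scale factor removed).
#' @export
rescale_to_unit_sd <- function(matrix, background = rep(0.25, 4)) {
  stopifnot(length(background) == 4L, all(background >= 0))
  if (abs(sum(background) - 1) > 1e-8)
    stop("background probabilities must sum to 1")
  m <- unclass(matrix)
  ebar <- colSums(m * background)
  v <- sum(colSums((m - rep(ebar, each = 4L))^2 * background))
  lambda <- sqrt(v)
  if (lambda <= .Machine$double.eps^0.5)
    stop("degenerate matrix: background energy variance is zero")
  out <- energy_matrix(m / lambda, tf_name = attr(matrix, "tf_name"),
                       units = attr(matrix, "units"))
  list(matrix = out, lambda = lambda)
}

#' Random unit-SD energy matrix
#'
#' Entries are drawn i.i.d. uniform on (0, 1) and the matrix is then rescaled
#' with [rescale_to_unit_sd()] so the background energy distribution (which is
#' approximately Gaussian for moderate L) has standard deviation 1.
#'
#' @param L site length (positions), L >= 1.
#' @param seed optional integer seed (deterministic output when given).
#' @param background per-base probabilities used for the rescaling.
#' @param tf_name label.
#' @return an \code{energy_matrix} with attribute \code{lambda} (the factor
#'   removed by rescaling).
#' @export
random_energy_matrix <- function(L, seed = NULL, background = rep(0.25, 4),
                                 tf_name = "synthTF") {
  if (L < 1L) stop("L must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  raw <- energy_matrix(matrix(runif(4L * L), nrow = 4L), tf_name = tf_name)
  r <- rescale_to_unit_sd(raw, background)
  out <- r$matrix
  attr(out, "lambda") <- r$lambda
  out
}

#' Reverse complement of DNA strings
#' @param seq character vector of DNA strings (ACGT only).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGT", "TGCA", toupper(seq))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Align a collection of sites to an energy matrix
#'
#' Chooses a single offset and strand orientation for the whole collection
#' (all sites are trimmed the same way) minimizing the mean binding energy.
#' Ties are broken toward the smallest offset, forward strand first.  A
#' per-site mode (each site gets its own best offset/strand) is available but
#' off by default.
#'
#' @param matrix an \code{energy_matrix} of length L.
#' @param raw_sites character vector of sequences, each of length >= L; the
#'   usable offsets are limited by the shortest site.
#' @param per_site if TRUE, choose offset/strand independently per site.
#' @return an \code{aligned_site_set}: list with \code{tf_name},
#'   \code{sites} (length-L strings), \code{energies}, \code{offset}
#'   (1-based, per collection or per site), and \code{strand} ("+"/"-").
#' @export
align_sites_to_matrix <- function(matrix, raw_sites, per_site = FALSE) {
  L <- em_length(matrix)
  raw_sites <- toupper(as.character(raw_sites))
  lens <- nchar(raw_sites)
  if (any(lens < L)) stop("all sites must be at least as long as the matrix")
  n_off <- min(lens) - L + 1L
  window <- function(seqs, off) substr(seqs, off, off + L - 1L)

  if (!per_site) {
    best <- NULL
    for (strand in c("+", "-")) {
      seqs <- if (strand == "+") raw_sites else revcomp(raw_sites)
      for (off in seq_len(n_off)) {
        e <- site_energy(matrix, window(seqs, off))
        me <- mean(e)
        if (is.null(best) || me < best$mean - 1e-12) {
          best <- list(mean = me, off = off, strand = strand,
                       sites = window(seqs, off), energies = e)
        }
      }
    }
    out <- list(tf_name = attr(matrix, "tf_name"), sites = best$sites,
                energies = best$energies, offset = best$off,
                strand = best$strand)
  } else {
    n <- length(raw_sites)
    bm <- rep(Inf, n); bo <- integer(n); bs <- character(n)
    bw <- character(n)
    for (strand in c("+", "-")) {
      seqs <- if (strand == "+") raw_sites else revcomp(raw_sites)
      for (off in seq_len(n_off)) {
        w <- window(seqs, off)
        e <- site_energy(matrix, w)
        upd <- e < bm - 1e-12
        bm[upd] <- e[upd]; bo[upd] <- off; bs[upd] <- strand; bw[upd] <- w[upd]
      }
    }
    out <- list(tf_name = attr(matrix, "tf_name"), sites = bw, energies = bm,
                offset = bo, strand = bs)
  }
  class(out) <- "aligned_site_set"
  out
}

#' @export
print.aligned_site_set <- function(x, ...) {
  cat(sprintf("aligned site set '%s': %d sites of length %d; offset %s strand %s\n",
              x$tf_name, length(x$sites), nchar(x$sites[1]),
              paste(unique(x$offset), collapse = ","),
              paste(unique(x$strand), collapse = ",")))
  invisible(x)
}

#' Per-position Boltzmann base frequencies ("energy logo")
#'
#' Assuming a Boltzmann distribution at inverse temperature beta at each
#' position independently, \eqn{p_i(a) \propto e^{-\beta \epsilon_{ia}}}.
#' beta = 0 gives uniform frequencies at every position.
#'
#' @param matrix an \code{energy_matrix}.
#' @param beta inverse temperature >= 0, (kcal/mol)^-1; default room
#'   temperature.
#' @return 4 x L matrix of frequencies; columns sum to 1.
#' @export
boltzmann_logo <- function(matrix, beta = 1.686) {
  if (beta < 0) stop("beta must be >= 0")
  m <- -beta * unclass(matrix)
  m <- sweep(m, 2L, apply(m, 2L, max))
  w <- exp(m)
  sweep(w, 2L, colSums(w), "/")
}
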
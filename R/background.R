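# Neutral background model: mono-/dinucleotide Markov chain over intergenic
# sequence, neutral sequence probabilities pi0, and the projection of pi0
# into energy space (the neutral energy spectrum Q0) by transfer-matrix DP.

#' Construct a Markov background model
#'
#' @param mono per-base probabilities (A,C,G,T), summing to 1.
#' @param di 4 x 4 joint dinucleotide probabilities (rows: first base), or
#'   NULL for the factorized background \code{di = mono \%o\% mono}.
#' @return object of class \code{markov_background} with elements
#'   \code{mono}, \code{di} and \code{trans} (row-normalized transitions,
#'   the first-order chain actually used for \eqn{\pi_0}).
#' @export
markov_background <- function(mono, di = NULL) {
  mono <- setNames(as.numeric(mono), DNA_BASES)
  if (any(mono < 0) || abs(sum(mono) - 1) > 1e-8)
    stop("mono probabilities must be nonnegative and sum to 1")
  if (is.null(di)) di <- outer(mono, mono)
  di <- as.matrix(di)
  if (!all(dim(di) == c(4L, 4L)) || any(di < 0) || abs(sum(di) - 1) > 1e-8)
    stop("di must be a 4x4 nonnegative matrix summing to 1")
  dimnames(di) <- list(DNA_BASES, DNA_BASES)
  rs <- rowSums(di)
  trans <- di / ifelse(rs > 0, rs, 1)
  trans[rs == 0, ] <- 0.25  # unreachable states: any stochastic row works
  structure(list(mono = mono, di = di, trans = trans),
            class = "markov_background")
}

#' @export
print.markov_background <- function(x, ...) {
  cat("Markov background; mono:\n"); print(round(x$mono, 4))
  cat("dinucleotide joint:\n"); print(round(x$di, 4))
  invisible(x)
}

#' Estimate the background model from sequences
#'
#' Mononucleotide frequencies are counted over every base; dinucleotide
#' frequencies over overlapping pairs within each record (no wrap across
#' records).  Characters outside ACGT are skipped (and break dinucleotide
#' adjacency).
#'
#' @param sequences character vector of DNA sequences (e.g. from
#'   [read_fasta()]).
#' @param pseudocount count added to every mono and dinucleotide cell
#'   before normalization (default 0).
#' @return a \code{markov_background}.
#' @export
fit_background <- function(sequences, pseudocount = 0) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) == 0L || sum(nchar(sequences)) < 2L)
    stop("need at least two bases of background sequence")
  mono_ct <- rep(pseudocount, 4L)
  di_ct <- matrix(pseudocount, 4L, 4L)
  for (s in sequences) {
    code <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
    ok <- !is.na(code)
    mono_ct <- mono_ct + tabulate(code[ok], nbins = 4L)
    if (length(code) >= 2L) {
      a <- code[-length(code)]; b <- code[-1L]
      keep <- !is.na(a) & !is.na(b)
      if (any(keep))
        di_ct <- di_ct + table(factor(a[keep], levels = 1:4),
                               factor(b[keep], levels = 1:4))
    }
  }
  if (sum(mono_ct) == 0) stop("no ACGT bases found")
  di <- if (sum(di_ct) > 0) di_ct / sum(di_ct) else outer(mono_ct, mono_ct) / sum(mono_ct)^2
  markov_background(mono_ct / sum(mono_ct), as.matrix(di))
}

#' Neutral log-probability of sequences under the background chain
#'
#' First-order Markov chain built from the dinucleotide frequencies:
#' \eqn{\pi_0(\sigma) = b(\sigma_1) \prod_{i \ge 2} T(\sigma_{i-1}, \sigma_i)}
#' with T the row-normalized dinucleotide matrix, so that \eqn{\pi_0} sums
#' to exactly 1 over all sequences of a given length.
#'
#' @param bg a \code{markov_background}.
#' @param seq character vector of DNA strings (equal lengths).
#' @return numeric vector of log-probabilities (-Inf where a transition has
#'   zero probability).
#' @export
neutral_seq_logprob <- function(bg, seq) {
  code <- encode_sites(seq)
  L <- ncol(code)
  lp <- unname(log(bg$mono)[code[, 1L]])
  if (L >= 2L) {
    lt <- log(bg$trans)
    for (i in 2:L) lp <- lp + lt[cbind(code[, i - 1L], code[, i])]
  }
  lp
}

#' Neutral probability of sequences (see [neutral_seq_logprob()])
#' @inheritParams neutral_seq_logprob
#' @return numeric vector of probabilities; 0 (not an error) where a
#'   transition has zero probability.
#' @export
neutral_seq_prob <- function(bg, seq) exp(neutral_seq_logprob(bg, seq))

# ---- energy discretization ---------------------------------------------

# All spectra live on the grid of integer multiples of `width`; bin k has
# center k*width and covers ((k-0.5)*width, (k+0.5)*width].
energy_bin <- function(E, width) as.integer(round(E / width))

#' Round energy-matrix entries to the spectrum bin grid
#'
#' The transfer-matrix projection quantizes each per-position contribution
#' to the nearest multiple of \code{width}; applying the same quantization
#' to the matrix makes sequence energies land exactly on bin centers, so
#' binned quantities computed either by enumeration or by the DP agree to
#' machine precision.  Worst-case energy shift is L*width/2.
#'
#' @param matrix an \code{energy_matrix}.
#' @param width bin width, kcal/mol.
#' @return the grid-aligned \code{energy_matrix}.
#' @export
snap_matrix <- function(matrix, width) {
  energy_matrix(round(unclass(matrix) / width) * width,
                tf_name = attr(matrix, "tf_name"),
                units = attr(matrix, "units"))
}

new_spectrum <- function(centers, prob, width) {
  structure(list(centers = centers, prob = prob, width = width,
                 edges = c(centers - width / 2, centers[length(centers)] + width / 2)),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("energy spectrum: %d bins of width %g on [%g, %g], total mass %g\n",
              length(x$centers), x$width, min(x$centers), max(x$centers),
              sum(x$prob)))
  invisible(x)
}

#' Neutral energy spectrum Q0(E) by transfer-matrix dynamic programming
#'
#' Projects the neutral sequence distribution \eqn{\pi_0} through the
#' sequence-energy map into an energy histogram, propagating joint
#' (last base, discretized energy) states across positions.  Per-position
#' energy increments are rounded to the bin grid (see [snap_matrix()]);
#' probability mass is conserved exactly.
#'
#' @param bg a \code{markov_background}.
#' @param matrix an \code{energy_matrix}.
#' @param bin_width energy bin width in kcal/mol (default 0.02).
#' @return an \code{energy_spectrum} whose bins span the full energy range
#'   realizable under the (grid-aligned) matrix.
#' @export
neutral_energy_spectrum <- function(bg, matrix, bin_width = 0.02) {
  if (bin_width <= 0) stop("bin_width must be positive")
  L <- em_length(matrix)
  k <- matrix(as.integer(round(unclass(matrix) / bin_width)), nrow = 4L)
  lo <- sum(apply(k, 2L, min)); hi <- sum(apply(k, 2L, max))
  nK <- hi - lo + 1L
  # mass[a, j]: prob of (last base a, partial energy offset) after i cols;
  # partial sums after col i live in [cum_min_i, cum_max_i]
  cum_min <- cumsum(apply(k, 2L, min)); cum_max <- cumsum(apply(k, 2L, max))
  span_lo <- min(cum_min); span_hi <- max(cum_max)
  nW <- span_hi - span_lo + 1L
  mass <- matrix(0, 4L, nW)
  for (a in 1:4) {
    j <- k[a, 1L] - span_lo + 1L
    mass[a, j] <- mass[a, j] + bg$mono[a]
  }
  if (L >= 2L) {
    for (i in 2:L) {
      new <- matrix(0, 4L, nW)
      for (ap in 1:4) {
        sh <- k[ap, i]
        for (a in 1:4) {
          t <- bg$trans[a, ap]
          if (t == 0) next
          src <- which(mass[a, ] > 0)
          if (!length(src)) next
          dst <- src + sh
          new[ap, dst] <- new[ap, dst] + t * mass[a, src]
        }
      }
      mass <- new
    }
  }
  prob_full <- colSums(mass)
  idx <- (lo:hi) - span_lo + 1L
  prob <- numeric(nK)
  keep <- idx >= 1L & idx <= nW
  prob[keep] <- prob_full[idx[keep]]
  new_spectrum(centers = (lo:hi) * bin_width, prob = prob, width = bin_width)
}

# ---- exhaustive enumeration (oracle + exact sampling machinery) ---------

#' Enumerate the energies of all 4^L sequences
#'
#' Sequence index order: position L varies fastest (index 1 = AAA..A,
#' index 2 = AAA..C, ...).  Intended for small L (L <= 10).
#'
#' @param matrix an \code{energy_matrix}.
#' @return numeric vector of length 4^L.
#' @export
enumerate_energies <- function(matrix) {
  m <- unclass(matrix)
  L <- ncol(m)
  if (L > 12L) stop("enumeration limited to L <= 12")
  e <- m[, 1L]
  if (L >= 2L) for (i in 2:L) e <- rep(e, each = 4L) + m[, i]
  e
}

#' Enumerate neutral log-probabilities of all 4^L sequences
#' @param bg a \code{markov_background}.
#' @param L sequence length.
#' @return numeric vector of length 4^L (same index order as
#'   [enumerate_energies()]).
#' @export
enumerate_log_pi0 <- function(bg, L) {
  if (L > 12L) stop("enumeration limited to L <= 12")
  lp <- unname(log(bg$mono))
  last <- 1:4
  lt <- log(bg$trans)
  if (L >= 2L) {
    for (i in 2:L) {
      n <- length(lp)
      lp <- rep(lp, each = 4L) + lt[cbind(rep(last, each = 4L), rep_len(1:4, 4L * n))]
      last <- rep_len(1:4, 4L * n)
    }
  }
  lp
}

#' Decode enumeration indices into sequences
#' @param idx integer vector of 1-based indices into the 4^L enumeration.
#' @param L sequence length.
#' @return character vector of sequences.
#' @export
index_to_seq <- function(idx, L) {
  idx <- as.integer(idx) - 1L
  out <- matrix("", length(idx), L)
  for (i in L:1) {
    out[, i] <- DNA_BASES[idx %% 4L + 1L]
    idx <- idx %/% 4L
  }
  apply(out, 1L, paste, collapse = "")
}

#' Scan background sequences for window energies and compare to Q0
#'
#' Slides an L-bp window over every record (and its reverse complement if
#' \code{both_strands}), computes window energies under the grid-aligned
#' matrix, and bins them on the same grid as the neutral spectrum.  Windows
#' containing non-ACGT characters are skipped and counted.
#'
#' @param matrix an \code{energy_matrix}.
#' @param sequences character vector of records, each of length >= L.
#' @param both_strands scan the reverse complement too (default TRUE).
#' @param bin_width bin width (kcal/mol), default 0.02.
#' @param bg optional \code{markov_background}; if given, the neutral
#'   spectrum and per-bin percent deviation are included in the output.
#' @return list with \code{empirical} (energy_spectrum), \code{n_windows},
#'   \code{n_skipped}, and (if \code{bg} given) \code{neutral} and
#'   \code{deviation} (data.frame center/empirical/neutral/percent_dev,
#'   percent deviation defined where neutral mass > 0).
#' @export
scan_background_energies <- function(matrix, sequences, both_strands = TRUE,
                                     bin_width = 0.02, bg = NULL) {
  L <- em_length(matrix)
  mq <- snap_matrix(matrix, bin_width)
  m <- unclass(mq)
  lo <- sum(apply(round(m / bin_width), 2L, min))
  hi <- sum(apply(round(m / bin_width), 2L, max))
  counts <- numeric(hi - lo + 1L)
  n_win <- 0L; n_skip <- 0L
  todo <- toupper(as.character(sequences))
  if (both_strands) todo <- c(todo, revcomp(todo))
  for (s in todo) {
    code <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
    n <- length(code) - L + 1L
    if (n < 1L) next
    e <- numeric(n)
    for (i in seq_len(L)) e <- e + m[code[seq.int(i, i + n - 1L)], i]
    bad <- is.na(e)
    n_skip <- n_skip + sum(bad)
    e <- e[!bad]
    n_win <- n_win + length(e)
    if (length(e)) {
      kk <- energy_bin(e, bin_width) - lo + 1L
      tb <- tabulate(kk, nbins = length(counts))
      counts <- counts + tb
    }
  }
  if (n_win == 0L) stop("no scannable windows")
  emp <- new_spectrum((lo:hi) * bin_width, counts / n_win, bin_width)
  out <- list(empirical = emp, n_windows = n_win, n_skipped = n_skip)
  if (!is.null(bg)) {
    neu <- neutral_energy_spectrum(bg, matrix, bin_width)
    stopifnot(length(neu$prob) == length(emp$prob))
    pd <- ifelse(neu$prob > 0,
                 100 * (emp$prob - neu$prob) / neu$prob, NA_real_)
    out$neutral <- neu
    out$deviation <- data.frame(center = emp$centers, empirical = emp$prob,
                                neutral = neu$prob, percent_dev = pd)
  }
  out
}
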
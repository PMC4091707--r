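# Tests for site-specific selection: do binding energies correlate with
# biological attributes of the sites or the genes they regulate?
# Permutation nulls for group differences, Spearman rank screens for
# continuous attributes, ortholog divergence comparisons, site-set entropy.

#' Assign binding sites to the genes they regulate
#'
#' A site regulates a gene when its midpoint lies within \code{window} bp
#' upstream of the gene's transcription start site on the gene's strand
#' (upstream means lower coordinates for "+" genes, higher for "-"). A
#' site may regulate several genes; the distance to the nearest assigned
#' TSS is recorded.
#'
#' @param sites data.frame with columns chrom, start, end (0-based
#'   half-open), and any per-site payload columns (e.g. energy, site_id).
#' @param gene_table data.frame with gene_id, tss, strand ("+"/"-"),
#'   chrom optional (matched when present in both).
#' @param window upstream window in bp (default 700).
#' @return data.frame with one row per (site, gene) assignment: all site
#'   columns, gene_id, tss_distance.
#' @export
assign_sites_to_genes <- function(sites, gene_table, window = 700) {
  stopifnot(all(c("start", "end") %in% names(sites)),
            all(c("gene_id", "tss", "strand") %in% names(gene_table)))
  if (!all(gene_table$strand %in% c("+", "-"))) stop("malformed gene strand")
  mid <- (sites$start + sites$end) / 2
  both_chrom <- "chrom" %in% names(sites) && "chrom" %in% names(gene_table)
  out <- list()
  for (g in seq_len(nrow(gene_table))) {
    d <- if (gene_table$strand[g] == "+") gene_table$tss[g] - mid
         else mid - gene_table$tss[g]
    hit <- d > 0 & d < window
    if (both_chrom) hit <- hit & sites$chrom == gene_table$chrom[g]
    if (any(hit)) {
      rows <- sites[hit, , drop = FALSE]
      rows$gene_id <- gene_table$gene_id[g]
      rows$tss_distance <- d[hit]
      out[[length(out) + 1L]] <- rows
    }
  }
  if (!length(out)) {
    warning("no sites fall in any gene's upstream window")
    res <- sites[0, , drop = FALSE]
    res$gene_id <- character(0); res$tss_distance <- numeric(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation test for a two-group difference
#'
#' Null model: group labels were assigned at random, preserving group
#' sizes.  Two-sided p-value with the add-one estimator
#' \eqn{p = (\#\{|stat_{perm}| \ge |stat_{obs}|\} + 1)/(n_{perm} + 1)}, so
#' p is never exactly zero.
#'
#' @param values numeric vector.
#' @param group_labels vector with exactly two distinct values; both
#'   groups must be nonempty.
#' @param statistic "mean_diff" (difference of group means) or "var_diff"
#'   (difference of group sample variances).
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @return list with \code{statistic} (observed, first group minus
#'   second) and \code{p_value}.
#' @export
permutation_group_test <- function(values, group_labels,
                                   statistic = c("mean_diff", "var_diff"),
                                   n_perm = 10000L, seed = NULL) {
  statistic <- match.arg(statistic)
  keep <- !is.na(values) & !is.na(group_labels)
  values <- as.numeric(values[keep])
  g <- factor(group_labels[keep])
  if (nlevels(g) != 2L) stop("need exactly two groups")
  if (any(table(g) == 0L)) stop("both groups must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  res <- perm_group_test_cpp(values, as.integer(g == levels(g)[1L]),
                             if (statistic == "mean_diff") 0L else 1L,
                             as.integer(n_perm))
  list(statistic = res$statistic, p_value = res$p_value,
       groups = levels(g), n = as.vector(table(g)))
}

#' Spearman rank-correlation screen of energy against a gene attribute
#'
#' For each TF with at least \code{min_n} paired observations, the
#' Spearman correlation between site energy and the attribute, with a
#' two-sided p-value (ties mid-ranked).  The cross-TF summary is the
#' unweighted mean p-value.  Benjamini-Hochberg adjusted p-values are
#' appended as an extension beyond the raw-p reporting convention.
#'
#' @param annotated data.frame with columns \code{tf}, \code{energy}, and
#'   the attribute column.
#' @param attribute name of the attribute column.
#' @param min_n minimum pairs per TF (default 5; smaller TFs are skipped
#'   with a note).
#' @return list with \code{per_tf} (tf, n, rho, p, p_bh, note) and
#'   \code{mean_p}.
#' @export
rank_correlation_screen <- function(annotated, attribute, min_n = 5L) {
  stopifnot(all(c("tf", "energy", attribute) %in% names(annotated)))
  tfs <- unique(annotated$tf)
  rows <- lapply(tfs, function(tf) {
    d <- annotated[annotated$tf == tf, ]
    x <- d$energy; y <- d[[attribute]]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < min_n)
      return(data.frame(tf = tf, n = length(x), rho = NA_real_,
                        p = NA_real_, note = "skipped: too few pairs"))
    if (length(unique(y)) < 2L || length(unique(x)) < 2L)
      return(data.frame(tf = tf, n = length(x), rho = NA_real_,
                        p = NA_real_, note = "constant values"))
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    data.frame(tf = tf, n = length(x), rho = unname(ct$estimate),
               p = ct$p.value, note = "")
  })
  per_tf <- do.call(rbind, rows)
  per_tf$p_bh <- stats::p.adjust(per_tf$p, method = "BH")
  list(per_tf = per_tf, mean_p = mean(per_tf$p, na.rm = TRUE))
}

#' Divergence between orthologous site pairs
#'
#' Per-pair Hamming distance and squared binding-energy difference; if a
#' two-level \code{group} is supplied (e.g. essential vs nonessential),
#' group means are compared with [permutation_group_test()].
#'
#' @param pairs data.frame with columns seq1, seq2 (aligned, equal
#'   length) and optionally group.
#' @param matrix an \code{energy_matrix} matching the site length.
#' @param n_perm,seed passed to the permutation test.
#' @return list with \code{per_pair} (hamming, dE2), overall means, and
#'   (when grouped) per-group means and permutation p-values.
#' @export
ortholog_divergence <- function(pairs, matrix, n_perm = 10000L,
                                seed = NULL) {
  c1 <- encode_sites(pairs$seq1)
  c2 <- encode_sites(pairs$seq2)
  if (ncol(c1) != ncol(c2)) stop("pair sequences must have equal length")
  ham <- rowSums(c1 != c2)
  dE2 <- (site_energy(matrix, pairs$seq1) -
            site_energy(matrix, pairs$seq2))^2
  out <- list(per_pair = data.frame(hamming = ham, dE2 = dE2),
              mean_hamming = mean(ham), mean_dE2 = mean(dE2))
  if (!is.null(pairs$group) && length(unique(pairs$group)) == 2L) {
    out$group_means <- aggregate(cbind(hamming = ham, dE2 = dE2),
                                 list(group = pairs$group), mean)
    out$p_hamming <- permutation_group_test(ham, pairs$group, "mean_diff",
                                            n_perm, seed)$p_value
    out$p_dE2 <- permutation_group_test(dE2, pairs$group, "mean_diff",
                                        n_perm, seed)$p_value
  }
  out
}

#' Sequence entropy of a set of aligned sites (bits)
#'
#' Sum over positions of the column entropy
#' \eqn{H_i = -\sum_a f_i(a) \log_2 f_i(a)} of the observed base
#' frequencies (no pseudocount by default).
#'
#' @param sites character vector of equal-length DNA strings.
#' @param pseudocount count added to every cell before normalization.
#' @return entropy in bits (0 for a single sequence; 2L for uniform
#'   columns).
#' @export
tf_site_entropy <- function(sites, pseudocount = 0) {
  code <- encode_sites(sites)
  H <- 0
  for (i in seq_len(ncol(code))) {
    ct <- tabulate(code[, i], nbins = 4L) + pseudocount
    f <- ct / sum(ct)
    f <- f[f > 0]
    H <- H - sum(f * log2(f))
  }
  H
}

#' Full site-specific selection battery
#'
#' For each TF: permutation tests of mean and variance of binding energy
#' between sites regulating essential vs nonessential genes, and Spearman
#' screens of energy against growth rate, expression, dN/dS and TSS
#' distance.  Cross-TF summaries are unweighted mean p-values.
#'
#' @param annotated data.frame with columns tf, energy, essential
#'   ("essential"/"nonessential"), and optionally growth_min, expression,
#'   dnds, tss_distance.
#' @param n_perm permutations per group test.
#' @param seed integer seed.
#' @param min_group minimum sites per group for the permutation tests.
#' @return list with \code{group_tests} (per TF: mean/variance
#'   difference + p), \code{screens} (one [rank_correlation_screen()]
#'   result per available attribute), and \code{mean_p} (named vector of
#'   cross-TF mean p-values).
#' @export
site_specific_battery <- function(annotated, n_perm = 10000L, seed = 1L,
                                  min_group = 2L) {
  stopifnot(all(c("tf", "energy", "essential") %in% names(annotated)))
  tfs <- unique(annotated$tf)
  gt <- lapply(tfs, function(tf) {
    d <- annotated[annotated$tf == tf &
                     annotated$essential %in% c("essential", "nonessential"), ]
    tab <- table(d$essential)
    if (length(tab) < 2L || any(tab < min_group))
      return(data.frame(tf = tf, n_ess = sum(d$essential == "essential"),
                        n_non = sum(d$essential == "nonessential"),
                        mean_diff = NA_real_, p_mean = NA_real_,
                        var_diff = NA_real_, p_var = NA_real_))
    m <- permutation_group_test(d$energy, d$essential, "mean_diff",
                                n_perm, seed)
    v <- permutation_group_test(d$energy, d$essential, "var_diff",
                                n_perm, seed)
    data.frame(tf = tf, n_ess = sum(d$essential == "essential"),
               n_non = sum(d$essential == "nonessential"),
               mean_diff = m$statistic, p_mean = m$p_value,
               var_diff = v$statistic, p_var = v$p_value)
  })
  group_tests <- do.call(rbind, gt)
  attrs <- intersect(c("growth_min", "expression", "dnds", "tss_distance"),
                     names(annotated))
  screens <- lapply(setNames(attrs, attrs), function(a)
    rank_correlation_screen(annotated, a))
  mean_p <- c(essential_mean = mean(group_tests$p_mean, na.rm = TRUE),
              essential_var = mean(group_tests$p_var, na.rm = TRUE),
              vapply(screens, `[[`, numeric(1), "mean_p"))
  list(group_tests = group_tests, screens = screens, mean_p = mean_p)
}
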
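# Worked-example inputs: reported fit summaries for 12 yeast TFs.

#' Reported yeast Fermi-Dirac fit summary table
#'
#' Published summary of unconstrained Fermi-Dirac landscape fits to
#' genomic binding-site collections for 12 yeast TFs: maximum-likelihood
#' f0, gamma = nu (1 - f0), effective beta, the qualitative regime of the
#' site energies relative to mu, the AIC differences of the constrained
#' (f0 = 0.99) and exponential fits relative to the unconstrained fit,
#' and the reported Akaike weights.  Shipped as a worked-example input:
#' the weights can be recomputed from the AIC-difference columns with
#' [akaike_weights()].
#'
#' @return data.frame with one row per TF.
#' @export
published_fit_summary <- function() {
  path <- system.file("extdata", "yeast_fd_fit_summary.tsv",
                      package = "tfscape", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Recompute three-model Akaike weights from AIC differences
#'
#' Given the AIC differences of the CFD and EXP models relative to UFD,
#' returns the weights (w_UFD, w_CFD, w_EXP) via [akaike_weights()].
#'
#' @param daic_cfd_ufd AIC(CFD) - AIC(UFD).
#' @param daic_exp_ufd AIC(EXP) - AIC(UFD).
#' @return named numeric vector of three weights summing to 1.
#' @export
weights_from_daic <- function(daic_cfd_ufd, daic_exp_ufd) {
  w <- akaike_weights(c(UFD = 0, CFD = daic_cfd_ufd, EXP = daic_exp_ufd))
  setNames(w, c("w_ufd", "w_cfd", "w_exp"))
}
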
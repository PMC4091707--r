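# Readers/writers for the plain-text formats used by the pipeline:
# energy-matrix text files, FASTA, BED-like site tables, gene tables,
# spectra and fit reports.

#' Write an energy matrix (or PSAM) to a text file
#'
#' Format: `#` header lines carrying tf_name, units and type
#' (`energy` or `psam`), then L whitespace-delimited rows of 4 columns in
#' A C G T order.
#'
#' @param matrix an \code{energy_matrix}, or a positive 4 x L matrix when
#'   \code{type = "psam"}.
#' @param path output file.
#' @param type "energy" or "psam".
#' @export
write_energy_matrix <- function(matrix, path, type = c("energy", "psam")) {
  type <- match.arg(type)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# tf_name=%s", attr(matrix, "tf_name") %||% "TF"),
               sprintf("# units=%s", attr(matrix, "units") %||% "kcal/mol"),
               sprintf("# type=%s", type),
               "# columns=A C G T"), con)
  write.table(t(unclass(matrix)), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an energy matrix (or PSAM) text file
#'
#' Parses the format written by [write_energy_matrix()].  PSAM files
#' (header `type=psam`) are converted to energies with
#' [psam_to_energy_matrix()] using \code{beta_room}.
#'
#' @param path input file.
#' @param beta_room inverse temperature used for PSAM conversion.
#' @return an \code{energy_matrix}.
#' @export
read_energy_matrix <- function(path, beta_room = 1.686) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key, default) {
    m <- regmatches(hdr, regexpr(sprintf("%s=\\S+", key), hdr))
    if (length(m)) sub(sprintf("%s=", key), "", m[1]) else default
  }
  tf_name <- get("tf_name", "TF")
  type <- get("type", "energy")
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  vals <- t(vapply(strsplit(trimws(body), "\\s+"),
                   function(x) as.numeric(x), numeric(4)))
  if (type == "psam")
    psam_to_energy_matrix(t(vals), beta_room = beta_room, tf_name = tf_name)
  else
    energy_matrix(t(vals), tf_name = tf_name, units = get("units", "kcal/mol"))
}

#' Read DNA sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences (uppercase).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write DNA sequences to a FASTA file
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a BED-like table of genomic site locations
#'
#' Tab-separated with header; required columns chrom, start, end (0-based
#' half-open), strand (+/-); optional columns posterior and site_id.  Rows
#' with posterior <= \code{min_posterior} are dropped (curated site
#' collections ship a posterior probability per site; the conventional
#' cutoff retains only confident sites).
#'
#' @param path TSV file.
#' @param min_posterior posterior filter threshold (default 0.9); ignored if
#'   the file has no posterior column.
#' @return data.frame of retained sites.
#' @export
read_sites_bed <- function(path, min_posterior = 0.9) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(d)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  if (!all(d$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if ("posterior" %in% names(d)) d <- d[d$posterior > min_posterior, ]
  d
}

#' Extract site sequences from chromosome sequences given a BED-like table
#'
#' Coordinates are 0-based half-open; minus-strand sites are
#' reverse-complemented.
#'
#' @param sites data.frame as returned by [read_sites_bed()].
#' @param genome named character vector of chromosome sequences.
#' @return character vector of site sequences.
#' @export
extract_site_seqs <- function(sites, genome) {
  if (!all(sites$chrom %in% names(genome)))
    stop("site table references chromosomes absent from the genome")
  s <- substr(genome[sites$chrom], sites$start + 1L, sites$end)
  s <- unname(s)
  neg <- sites$strand == "-"
  if (any(neg)) s[neg] <- revcomp(s[neg])
  s
}

#' Read a gene attribute table
#'
#' Tab-separated with header.  Required: gene_id, tss, strand.  Optional:
#' essential ("essential"/"nonessential"/"unavailable"), growth-rate columns
#' (any columns named growth_*, relative to wild type), expression, dnds.
#' A summary column \code{growth_min} (the minimum of the available
#' growth-rate conditions, the conventional fitness proxy for a knockout)
#' is added when growth columns are present.
#'
#' @param path TSV file.
#' @return data.frame (class \code{gene_table}).
#' @export
read_gene_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "tss", "strand")
  if (!all(need %in% names(d)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (!all(d$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  gcols <- grep("^growth_", names(d), value = TRUE)
  gcols <- setdiff(gcols, "growth_min")
  if (length(gcols))
    d$growth_min <- do.call(pmin, c(unname(d[gcols]), list(na.rm = TRUE)))
  class(d) <- c("gene_table", "data.frame")
  d
}

#' Write an energy spectrum as a 3-column TSV (bin_lo, bin_hi, prob)
#' @param spectrum an \code{energy_spectrum}.
#' @param path output file.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  half <- spectrum$width / 2
  write.table(data.frame(bin_lo = spectrum$centers - half,
                         bin_hi = spectrum$centers + half,
                         prob = spectrum$prob),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fit result to JSON
#' @param fit a \code{fit_result} from [fit_gridsearch()].
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  x <- list(model = fit$model, params = unclass(fit$params),
            log_likelihood = fit$lnL,
            aicc = fit$aicc, k = fit$k, n = fit$n, regime = fit$regime,
            flags = fit$flags)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
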
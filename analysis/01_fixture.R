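#!/usr/bin/env Rscript
# Build the standing synthetic study: a threshold-regime binding-site
# collection with its energy matrix, intergenic background, gene table
# and ortholog pairs, written as plain-text inputs under results/fixture/.
# Everything downstream (02-04) reads nothing else.

library(tfscape)

out <- file.path("results", "fixture")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- fixture_config(L = 8, regime = "threshold", n_sites = 500, seed = 1)
fx <- make_fixture(cfg)

write_energy_matrix(fx$matrix, file.path(out, "energy_matrix.txt"))
write_fasta(c(intergenic = fx$intergenic),
            file.path(out, "intergenic.fasta"))
write_fasta(setNames(fx$sites$sites,
                     sprintf("site%03d", seq_along(fx$sites$sites))),
            file.path(out, "sites.fasta"))
write.table(fx$annotated, file.path(out, "annotated_sites.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(fx$gene_table, file.path(out, "gene_table.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(fx$ortholog_pairs, file.path(out, "ortholog_pairs.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write_spectrum_tsv(fx$spectrum, file.path(out, "neutral_spectrum.tsv"))
jsonlite::write_json(list(seed = cfg$seed, L = cfg$L, regime = cfg$regime,
                          n_sites = cfg$n_sites,
                          params = unclass(fx$truth$params),
                          gamma = fx$truth$gamma),
                     file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

message(sprintf("fixture: %d sites, L = %d, regime %s (gamma = %.3g, mu = %.3f)",
                cfg$n_sites, cfg$L, cfg$regime, fx$truth$gamma,
                fx$truth$params$mu))
message("energies span [", paste(round(range(fx$sites$energies), 2),
                                 collapse = ", "), "] kcal/mol")
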
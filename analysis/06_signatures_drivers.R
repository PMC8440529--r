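#!/usr/bin/env Rscript
# 96-context spectra per patient (plus trunk/branch scopes), non-negative
# signature refitting against the packaged catalog, and driver gene
# occurrence / dominant scores across the cohort.

suppressMessages(library(mrith))

calls <- read_mutation_table("results/filtered_mutations.tsv", "maf_tsv")
catalog <- read_signature_catalog()

rows <- list()
for (pid in unique(calls$patient_id)) {
  d <- calls[calls$patient_id == pid, ]
  spec <- trinucleotide_spectrum(d)
  if (sum(spec) == 0) next
  fit <- fit_signatures(spec, catalog)
  top <- sort(fit$weights, decreasing = TRUE)[1:3]
  rows[[pid]] <- data.frame(
    patient_id = pid, n_snv = attr(spec, "n_snv"),
    top_signature = names(top)[1], top_weight = top[[1]],
    residual = fit$residual_norm)
}
sig <- do.call(rbind, rows)
write.table(sig, "results/signature_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

gene_sets <- lapply(split(calls, calls$patient_id),
                    function(d) unique(d$gene))
dr <- driver_score_table(gene_sets, drivers = driver_genes())
write.table(dr, "results/driver_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("dominant signature across patients: %s (median weight %.2f)\n",
            names(which.max(table(sig$top_signature))),
            median(sig$top_weight)))
cat(sprintf("top drivers: %s\n",
            paste(sprintf("%s %.0f%%", dr$gene[1:5],
                          100 * dr$occurrence[1:5]), collapse = ", ")))
cat("tables in results/signature_summary.tsv and results/driver_scores.tsv\n")
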
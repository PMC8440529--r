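#!/usr/bin/env Rscript
# Post-calling somatic filters (>= 5 mutant reads, normal depth >= 10,
# tumor depth >= 30, VAF >= 3%, population AF <= 1%) followed by
# cross-region rescue (VAF > 1%, normal mutant reads < 5) for variants
# seen in some but not all regions of a patient.

suppressMessages(library(mrith))

calls <- read_mutation_table("results/cohort/mutations.tsv", "maf_tsv")
pileups <- read.delim("results/cohort/pileups.tsv")
profiles <- read_region_profiles("results/cohort/profiles.tsv")

params <- filter_params()
out <- list()
n_rescued <- 0
for (pid in unique(profiles$patient_id)) {
  f <- apply_somatic_filters(calls[calls$patient_id == pid, ], params)
  f <- rescue_cross_region(f, pileups[pileups$patient_id == pid, ], params,
                           regions = profiles$region_id[
                             profiles$patient_id == pid])
  n_rescued <- n_rescued + sum(f$rescued)
  out[[pid]] <- as.data.frame(f)
}
filtered <- mutation_calls(do.call(rbind, out))
write_mutation_table(filtered, "results/filtered_mutations.tsv")

cat(sprintf("%d raw records -> %d retained (%d rescued across regions)\n",
            nrow(calls), nrow(filtered), n_rescued))
cat("filtered calls in results/filtered_mutations.tsv\n")
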
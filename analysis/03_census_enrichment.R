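#!/usr/bin/env Rscript

# Step 3: species-by-family census of the authentic P450s and the
# fractional enrichment cutoff (2% of the grand total, rounded half-up).
# A family whose summed count reaches the cutoff is enriched; an enriched
# family present in at most two species is additionally species-specific.
#
# Writes results/census.tsv, results/enrichment.tsv and the
# enrichment-matrix view results/enrichment_matrix.tsv.

suppressMessages(library(cypfam))

auth <- read_protein_fasta(file.path("results", "authentic.fasta"))
cen <- build_census(auth)
e <- enrich(cen, fraction = 0.02, k_species_specific = 2)

write_census(cen, file.path("results", "census.tsv"))
write_enrichment(e, file.path("results", "enrichment.tsv"))
em <- cen$counts[, e$enriched, drop = FALSE]
write.table(data.frame(species = rownames(em), em, check.names = FALSE),
            file.path("results", "enrichment_matrix.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

print(cen)
print(e)
cat("\nenriched-family counts by species:\n")
print(em)
cat("wrote results/census.tsv, results/enrichment.tsv, results/enrichment_matrix.tsv\n")
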
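#!/usr/bin/env Rscript

# Step 2: authenticate candidate P450s by the two signature motifs (the
# FXXGXXXCXG heme-binding decapeptide downstream of a K-helix EXXR).
# Proteins lacking either motif, or carrying them out of order, are
# rejected with a machine-readable reason.
#
# Reads results/synthetic/; writes results/authentic.fasta and
# results/rejected.tsv.

suppressMessages(library(cypfam))

records <- read_protein_fasta(file.path("results", "synthetic", "proteins.fasta"))
out <- filter_authentic(records)

write_protein_fasta(out$authentic, file.path("results", "authentic.fasta"))
write.table(out$rejected, file.path("results", "rejected.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("candidates:", nrow(records), "\n")
cat("authentic P450s:", nrow(out$authentic), "\n")
cat("rejected:", nrow(out$rejected), "\n")
print(table(out$rejected$reason))
cat("wrote results/authentic.fasta, results/rejected.tsv\n")
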
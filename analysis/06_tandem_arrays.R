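#!/usr/bin/env Rscript

# Step 6: tandem arrays — two or more same-family genes co-located on one
# scaffold, the signature of local gene duplication — and the per-family
# scaffold distributions of the enriched families.
#
# Writes results/tandem_arrays.tsv and results/scaffold_distribution.tsv.

suppressMessages(library(cypfam))

auth <- read_protein_fasta(file.path("results", "authentic.fasta"))
meta <- read.delim(file.path("results", "synthetic", "names.tsv"))
models <- load_gene_models(file.path("results", "synthetic", "genes.gff3"), meta)
models <- models[names(models) %in% auth$id]

arrays <- detect_tandem(models)
write.table(arrays, file.path("results", "tandem_arrays.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

enr <- read.delim(file.path("results", "enrichment.tsv"))
mf <- cypfam:::.model_frame(models)
rows <- list()
for (fam in enr$family[enr$enriched]) {
  for (sp in sort(unique(mf$species))) {
    d <- scaffold_distribution(models, fam, sp)
    if (!nrow(d)) next
    rows[[paste(fam, sp)]] <- data.frame(
      family = fam, species = sp,
      scaffolds = paste(d$scaffold, collapse = ","),
      counts = paste(d$count, collapse = ","))
  }
}
dist_tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
write.table(dist_tab, file.path("results", "scaffold_distribution.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("tandem arrays:", nrow(arrays), "\n")
cat("genes in arrays:", sum(arrays$size), "of", length(models), "authentic genes",
    sprintf("(%.0f%%)\n", 100 * sum(arrays$size) / length(models)))
cat("largest array:", max(arrays$size), "genes (",
    arrays$family[which.max(arrays$size)], "on",
    arrays$scaffold[which.max(arrays$size)], ")\n")
cat("wrote results/tandem_arrays.tsv, results/scaffold_distribution.tsv\n")
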
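# Shared fixtures: records, tiny distance matrices, GFF3 writers, and the
# paralog-partition helper used by recovery tests.

make_record <- function(id, sequence, species = "SpA", cyp_name = "CYP63A1") {
  data.frame(id = id, species = species, cyp_name = cyp_name,
             sequence = sequence, stringsAsFactors = FALSE)
}

# random standard-alphabet protein without either signature motif
random_nonmotif_protein <- function(n) {
  repeat {
    s <- paste(sample(strsplit("ACDGHIKLMNPQSTVWY", "")[[1]], n, replace = TRUE),
               collapse = "")   # alphabet without E/F/R: no motif can form
    return(s)
  }
}

# plant the two motifs in order into a sequence (1-based positions)
plant_motifs <- function(s, e_pos, h_pos) {
  ch <- strsplit(s, "")[[1]]
  ch[e_pos] <- "E"; ch[e_pos + 3] <- "R"
  ch[h_pos] <- "F"; ch[h_pos + 3] <- "G"; ch[h_pos + 7] <- "C"; ch[h_pos + 9] <- "G"
  paste(ch, collapse = "")
}

named_dist <- function(v, labels) {
  n <- length(labels)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  D[upper.tri(D)] <- v
  D + t(D)
}

# the additive 4-leaf example: split AB|CD, branches A=1 B=2 C=1 D=3 internal=4
additive4 <- function() {
  named_dist(c(3, 6, 7, 8, 9, 4), LETTERS[1:4])
}

# symmetric noise perturbation of an additive matrix
perturb <- function(D, sd = 0.05) {
  n <- nrow(D)
  E <- matrix(stats::rnorm(n * n, 0, sd), n)
  E <- (E + t(E)) / 2
  diag(E) <- 0
  P <- pmax(D + E, 0)
  P <- (P + t(P)) / 2
  diag(P) <- 0
  dimnames(P) <- dimnames(D)
  P
}

write_test_gff3 <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff3_gene <- function(id, scaffold, strand, exons, type = "CDS") {
  gstart <- min(exons[, 1]); gend <- max(exons[, 2])
  c(sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s.gene", scaffold, gstart, gend, strand, id),
    sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s.gene",
            scaffold, gstart, gend, strand, id, id),
    sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tID=%s.x;Parent=%s",
            scaffold, type, exons[, 1], exons[, 2], strand, id, id))
}

# simple in-memory gene model builder (0-based half-open coordinates)
gm <- function(id, exons, strand = "+", scaffold = "s1", species = "SpA",
               family = "CYP63", protein_length = NA) {
  gene_model(id, species = species, scaffold = scaffold, strand = strand,
             exons = exons, protein_length = protein_length, family = family)
}

# predicted paralog partition over authentic models, cluster ids unique
# across (species, family) groups
predict_paralog_partition <- function(models, tol_nt = 3, theta = 0.8) {
  mf <- cypfam:::.model_frame(models)
  pred <- rep(NA_character_, nrow(mf))
  names(pred) <- mf$gene_id
  for (k in unique(paste(mf$species, mf$family))) {
    sub <- models[paste(mf$species, mf$family) == k]
    cl <- cluster_paralogs(sub, tol_nt, theta)
    for (i in seq_along(cl$clusters)) pred[cl$clusters[[i]]] <- paste(k, i)
    for (s in cl$singletons) pred[s] <- paste(k, "singleton", s)
  }
  pred
}

# enrichment detected on the authentic records of a synthetic bundle
detect_enriched <- function(bundle) {
  fa <- suppressWarnings(filter_authentic(bundle$proteins))
  enrich(build_census(fa$authentic), bundle$config$enrich_fraction)$enriched
}
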
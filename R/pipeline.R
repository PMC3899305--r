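# End-to-end analysis: authenticate -> census/enrichment -> per-family
# minimum evolution tree -> structure/paralog/ortholog -> tandem and
# intron summaries, with a reproducibility manifest.

.input_error <- function(...) {
  stop(structure(class = c("cyp_input_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
.compute_error <- function(stage, e) {
  stop(structure(class = c("cyp_compute_error", "error", "condition"),
                 list(message = paste0("stage ", stage, ": ", conditionMessage(e)),
                      call = NULL)))
}

#' Run the genome-wide P450 family analysis
#'
#' Executes the full pipeline on a protein FASTA, a GFF3 of gene models and
#' a name table: signature-motif authentication, species-by-family census
#' with the fractional enrichment cutoff, a minimum evolution tree per
#' enriched family (Poisson distances, NJ start, OLS lengths, CNI search),
#' exon-intron structure profiles with paralog clusters and cross-species
#' ortholog candidates, tandem arrays, and intron summaries. All outputs
#' are tab-separated tables (plus Newick trees and a JSON manifest) under
#' `out_dir`; nothing is written until every stage has succeeded, so a
#' failing run leaves no partial outputs.
#'
#' @param fasta Protein FASTA (headers `id|species|cyp_name` or plain ids
#'   resolved through `names_tsv`).
#' @param gff3 GFF3 gene models (mRNA ids matching protein ids).
#' @param names_tsv Tab-separated table `id`, `species`, `cyp_name` and
#'   optionally `protein_length`.
#' @param out_dir Output directory.
#' @param alignments_dir Optional directory of per-family aligned FASTA
#'   files (`<FAMILY>.fasta`); without it, families whose authentic
#'   members are equal-length are treated as ungapped alignments and
#'   others are skipped with a note.
#' @param fraction Enrichment fraction, default 0.02.
#' @param k_species_specific Species-specific cutoff, default 2.
#' @param tol_nt,theta Structure-matching parameters.
#' @param deletion Gap handling for distances.
#' @param min_len Intron-summary protein-length filter (residues).
#' @param cni_max_taxa CNI refinement ceiling; larger families are
#'   reported from NJ + OLS.
#' @param max_intervening Tandem rule, default `Inf` (scaffold
#'   co-location).
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(fasta, gff3, names_tsv, out_dir,
                         alignments_dir = NULL, fraction = 0.02,
                         k_species_specific = 2, tol_nt = 3, theta = 0.8,
                         deletion = "complete", min_len = 400,
                         cni_max_taxa = 50, max_intervening = Inf,
                         seed = NA_integer_) {
  for (p in c(fasta, gff3, names_tsv))
    if (!file.exists(p)) .input_error("input file not found: ", p)
  if (fraction <= 0 || fraction >= 1) .input_error("fraction must be in (0,1)")

  records <- tryCatch(read_protein_fasta(fasta, names_tsv),
                      error = function(e) .input_error("reading FASTA: ", conditionMessage(e)))
  if (nrow(records) == 0L) .input_error("empty FASTA: ", fasta)

  auth <- tryCatch(filter_authentic(records), error = function(e) .compute_error("authenticate", e))
  if (nrow(auth$authentic) == 0L) .input_error("no authentic P450s in input")

  census <- tryCatch(build_census(auth$authentic), error = function(e) .compute_error("census", e))
  enr <- tryCatch(enrich(census, fraction, k_species_specific),
                  error = function(e) .compute_error("enrich", e))

  meta <- utils::read.delim(names_tsv, stringsAsFactors = FALSE)
  models <- tryCatch(load_gene_models(gff3, meta),
                     error = function(e) .input_error("reading GFF3: ", conditionMessage(e)))
  models <- models[names(models) %in% auth$authentic$id]

  fam_of <- parse_cyp_name(auth$authentic$cyp_name)$family
  trees <- list(); tree_log <- list(); skipped <- character(0)
  for (fam in enr$enriched) {
    members <- auth$authentic[fam_of == fam, , drop = FALSE]
    if (nrow(members) < 2L) { skipped <- c(skipped, fam); next }
    aln <- NULL
    if (!is.null(alignments_dir)) {
      f <- file.path(alignments_dir, paste0(fam, ".fasta"))
      if (file.exists(f)) {
        aa <- Biostrings::readAAStringSet(f)
        aln <- stats::setNames(as.character(aa), sub("\\|.*$", "", names(aa)))
      }
    }
    if (is.null(aln)) {
      if (length(unique(nchar(members$sequence))) != 1L) {
        skipped <- c(skipped, fam); next
      }
      aln <- make_alignment(members)
    }
    ft <- tryCatch(family_tree(aln, deletion = deletion, cni_max_taxa = cni_max_taxa),
                   error = function(e) .compute_error(paste0("tree:", fam), e))
    trees[[fam]] <- ft
    tree_log[[fam]] <- data.frame(family = fam, n_taxa = length(aln),
                                  step = seq_along(ft$trajectory) - 1L,
                                  me_score = ft$trajectory, stringsAsFactors = FALSE)
  }

  profs <- lapply(models, structure_profile)
  mf <- .model_frame(models)
  clusters <- list(); cluster_rows <- list()
  for (key in unique(paste(mf$species, mf$family, sep = "\r"))) {
    sub <- models[which(paste(mf$species, mf$family, sep = "\r") == key)]
    cl <- cluster_paralogs(sub, tol_nt, theta)
    clusters[[key]] <- cl
    if (length(cl$clusters)) {
      cluster_rows[[key]] <- data.frame(
        species = sub[[1L]]$species, family = sub[[1L]]$family,
        cluster = seq_along(cl$clusters),
        size = lengths(cl$clusters),
        members = vapply(cl$clusters, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  paralog_tab <- if (length(cluster_rows)) do.call(rbind, c(cluster_rows, list(make.row.names = FALSE)))
    else data.frame(species = character(0), family = character(0),
                    cluster = integer(0), size = integer(0),
                    members = character(0), stringsAsFactors = FALSE)

  ortho_rows <- lapply(unique(mf$family[!is.na(mf$family)]), function(fam) {
    sub <- models[which(mf$family == fam)]
    o <- ortholog_candidates(sub, tol_nt, theta)
    if (nrow(o)) cbind(family = fam, o, stringsAsFactors = FALSE) else NULL
  })
  ortho_tab <- do.call(rbind, ortho_rows)
  if (is.null(ortho_tab))
    ortho_tab <- data.frame(family = character(0), gene_a = character(0),
                            species_a = character(0), gene_b = character(0),
                            species_b = character(0), score = numeric(0))

  arrays <- detect_tandem(models, max_intervening)
  introns <- intron_summary_table(models, min_len)
  profile_tab <- data.frame(
    gene_id = vapply(profs, `[[`, character(1), "gene_id"),
    species = mf$species, family = mf$family, scaffold = mf$scaffold,
    strand = mf$strand, n_introns = mf$n_introns,
    protein_length = mf$protein_length,
    exon_lengths = vapply(profs, function(p) paste(p$exon_lengths, collapse = ","),
                          character(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  # all stages succeeded: write outputs
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    tsv(auth$rejected, "rejected.tsv"),
    { p <- file.path(out_dir, "census.tsv"); write_census(census, p); p },
    { p <- file.path(out_dir, "enrichment.tsv"); write_enrichment(enr, p); p })
  enr_counts <- census$counts[, enr$enriched, drop = FALSE]
  paths <- c(paths, tsv(data.frame(species = rownames(enr_counts), enr_counts,
                                   check.names = FALSE), "enrichment_matrix.tsv"))
  if (length(trees)) {
    tree_dir <- file.path(out_dir, "trees")
    dir.create(tree_dir, showWarnings = FALSE)
    for (fam in names(trees)) {
      writeLines(trees[[fam]]$newick, file.path(tree_dir, paste0(fam, ".nwk")))
    }
    paths <- c(paths, tsv(do.call(rbind, tree_log), "me_score_log.tsv"))
  }
  paths <- c(paths,
             tsv(profile_tab, "structure_profiles.tsv"),
             tsv(paralog_tab, "paralog_clusters.tsv"),
             tsv(ortho_tab, "ortholog_candidates.tsv"),
             tsv(arrays, "tandem_arrays.tsv"),
             tsv(introns, "intron_summary.tsv"))
  manifest <- list(
    package = "cypfam",
    version = as.character(utils::packageVersion("cypfam")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    parameters = list(fraction = fraction, k_species_specific = k_species_specific,
                      tol_nt = tol_nt, theta = theta, deletion = deletion,
                      min_len = min_len, cni_max_taxa = cni_max_taxa,
                      max_intervening = if (is.infinite(max_intervening)) "Inf" else max_intervening),
    inputs = list(fasta = fasta, gff3 = gff3, names_tsv = names_tsv,
                  md5 = as.list(tools::md5sum(c(fasta, gff3, names_tsv)))),
    skipped_families = skipped,
    outputs = basename(paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(records = records, authentic = auth$authentic,
                 rejected = auth$rejected, census = census, enrichment = enr,
                 trees = trees, models = models, paralogs = paralog_tab,
                 orthologs = ortho_tab, tandem = arrays, introns = introns,
                 skipped_families = skipped, out_dir = out_dir))
}
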
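# Synthetic multi-species P450 complements with planted truth labels.
#
# The generator emulates the statistical structure the analysis assumes:
# per-family member counts across species, tandem duplicate copies with
# conserved exon-intron structure, Poisson-process sequence divergence,
# cross-species orthologs, and pseudogenes lacking signature motifs.
# Substitution-only divergence (no indels) keeps family members the same
# length, so the ungapped sequences are a valid alignment for the
# phylogenetic stage.

.AA20_CHARS <- strsplit(.AA20, "")[[1]]

#' Default planted species-by-family count matrix
#'
#' Six species and twelve families mirroring the shape of a multi-genome
#' P450 complement: five expanded families (one of them restricted to a
#' single species) whose totals clear the 2% enrichment cutoff by at least
#' five counts, and eight rare single-member families at least five counts
#' below it, so rounding can never flip an enrichment call.
#'
#' @param species Species labels (first six are used).
#' @return Integer matrix, species x families.
#' @export
default_family_counts <- function(species = c("Pchr", "Pcar", "Abis", "Gsp", "Ppla", "Slac")) {
  stopifnot(length(species) == 6L)
  m <- rbind(
    CYP5144 = c(18, 22, 12, 14, 11, 11),
    CYP512  = c(14, 16, 10, 12, 10, 10),
    CYP5150 = c(10, 12,  9, 11,  9,  9),
    CYP5035 = c( 8, 12,  5,  6,  5,  4),
    CYP5359 = c( 0,  0,  0, 36,  0,  0),
    CYP63   = c( 0,  0,  0,  1,  0,  0),
    CYP5037 = c( 0,  0,  1,  0,  0,  0),
    CYP5136 = c( 1,  0,  0,  0,  0,  0),
    CYP5141 = c( 0,  1,  0,  0,  0,  0),
    CYP5146 = c( 0,  0,  0,  0,  0,  1),
    CYP5348 = c( 0,  0,  0,  0,  1,  0),
    CYP501  = c( 0,  1,  0,  0,  0,  0))
  m <- t(m)
  dimnames(m) <- list(species, c("CYP5144", "CYP512", "CYP5150", "CYP5035",
                                 "CYP5359", "CYP63", "CYP5037", "CYP5136",
                                 "CYP5141", "CYP5146", "CYP5348", "CYP501"))
  storage.mode(m) <- "integer"
  m
}

#' Configuration for the synthetic genome-annotation generator
#'
#' @param species Species labels.
#' @param family_counts Integer species x family matrix of planted gene
#'   counts (pseudogenes are drawn from these genes afterwards).
#' @param mu Expected substitutions per site per copy/speciation event.
#' @param p_tandem Probability that a duplicate lands on its parent's
#'   scaffold (downstream, fixed intergenic spacing).
#' @param ortholog_fraction Fraction of multi-species families seeded
#'   before the species split (shared ancestor; exon structure copied
#'   across species).
#' @param pseudo_fraction Fraction of genes whose signature motifs are
#'   ablated (`round(fraction * total)` genes, apportioned across families
#'   by largest remainder).
#' @param enrich_fraction Enrichment fraction used for planted truth
#'   labels, default 0.02.
#' @param exon_model Integer range `c(min, max)` of exons per gene.
#' @param protein_length_range Residue-length range for family proteins.
#' @param jitter_nt Maximum exon-boundary jitter (nt) applied to duplicate
#'   copies; 0 copies structure exactly.
#' @param jitter_prob Probability that any one exon of a duplicate is
#'   jittered (annotation wobble is occasional, not systematic).
#' @param intron_length Fixed intron length (nt).
#' @param intergenic Fixed intergenic spacing on a scaffold (nt).
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(species = c("Pchr", "Pcar", "Abis", "Gsp", "Ppla", "Slac"),
                             family_counts = default_family_counts(species),
                             mu = 0.05, p_tandem = 0.8,
                             ortholog_fraction = 0.5, pseudo_fraction = 0.1,
                             enrich_fraction = 0.02,
                             exon_model = c(2L, 14L),
                             protein_length_range = c(360L, 550L),
                             jitter_nt = 0L, jitter_prob = 0.2,
                             intron_length = 60L, intergenic = 2000L,
                             seed = 1L) {
  stopifnot(is.matrix(family_counts), nrow(family_counts) == length(species),
            all(family_counts >= 0L), sum(family_counts) >= 1L,
            mu >= 0, p_tandem >= 0, p_tandem <= 1,
            ortholog_fraction >= 0, ortholog_fraction <= 1,
            pseudo_fraction >= 0, pseudo_fraction < 1,
            exon_model[1L] >= 1L, exon_model[2L] >= exon_model[1L],
            protein_length_range[1L] >= 50L, jitter_nt >= 0, seed == as.integer(seed))
  if (3L * protein_length_range[1L] + 3L <= exon_model[2L] * 3L)
    stop("infeasible exon model: more exons than codons", call. = FALSE)
  rownames(family_counts) <- species
  structure(list(species = species, family_counts = family_counts, mu = mu,
                 p_tandem = p_tandem, ortholog_fraction = ortholog_fraction,
                 pseudo_fraction = pseudo_fraction,
                 enrich_fraction = enrich_fraction,
                 exon_model = as.integer(exon_model),
                 protein_length_range = as.integer(protein_length_range),
                 jitter_nt = as.integer(jitter_nt), jitter_prob = jitter_prob,
                 intron_length = as.integer(intron_length),
                 intergenic = as.integer(intergenic), seed = as.integer(seed)),
            class = "synthetic_config")
}

.mutate_protein <- function(chars, mu, protect = integer(0)) {
  if (mu <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < 1 - exp(-mu))
  hit <- setdiff(hit, protect)
  for (i in hit) chars[i] <- sample(setdiff(.AA20_CHARS, chars[i]), 1L)
  chars
}

# Random protein of length L with the two signature motifs planted in
# order: EXXR near 70% of the length, heme decapeptide near 90%, each
# jittered +/- 5 residues (real P450 architecture). Returns chars and the
# six anchor positions, which mutation must not touch.
.random_p450 <- function(L) {
  chars <- sample(.AA20_CHARS, L, replace = TRUE)
  e <- round(0.70 * L) + sample(-5:5, 1L)
  h <- round(0.90 * L) + sample(-5:5, 1L)
  h <- min(h, L - 9L)
  e <- max(2L, min(e, h - 5L))
  chars[e] <- "E"; chars[e + 3L] <- "R"
  chars[h] <- "F"; chars[h + 3L] <- "G"; chars[h + 7L] <- "C"; chars[h + 9L] <- "G"
  list(chars = chars, anchors = c(e, e + 3L, h, h + 3L, h + 7L, h + 9L))
}

.random_exon_lengths <- function(n_ex, cds_len) {
  if (n_ex == 1L) return(cds_len)
  cuts <- sort(sample.int(cds_len - 1L, n_ex - 1L))
  diff(c(0L, cuts, cds_len))
}

.jitter_lengths <- function(lens, jitter_nt, jitter_prob) {
  if (jitter_nt == 0L) return(lens)
  amounts <- c(-(jitter_nt:1L), 1L:jitter_nt)
  hit <- stats::runif(length(lens)) < jitter_prob
  lens[hit] <- pmax(3L, lens[hit] + sample(amounts, sum(hit), replace = TRUE))
  lens
}

# Ablate signature motifs until the sequence is no longer authentic.
.ablate_motifs <- function(chars, mode) {
  seq1 <- function() paste(chars, collapse = "")
  if (mode %in% c("heme", "both")) {
    repeat {
      hits <- .regex_starts(seq1(), .HEME_REGEX)
      if (!length(hits)) break
      chars[hits + 7L] <- "A"      # destroy the axial cysteine
    }
  }
  if (mode %in% c("exxr", "both")) {
    repeat {
      s <- scan_motifs(seq1())
      if (!s$authentic) break
      bad <- s$exxr_positions[s$exxr_positions < max(s$heme_positions)]
      chars[bad[1L]] <- "D"        # glutamate -> aspartate kills the motif
    }
  }
  # heme-only ablation can still leave the pair non-authentic already;
  # guarantee the contract either way
  if (scan_motifs(seq1())$authentic) chars <- .ablate_motifs(chars, "both")
  chars
}

#' Generate a synthetic multi-species P450 complement
#'
#' For each family, an ancestral protein with planted signature motifs and
#' a random exon structure is drawn. Families seeded before the species
#' split (`ortholog_fraction`) copy the ancestral structure into every
#' species; otherwise each species founds the family independently (same
#' protein length, own structure). Planted counts are then reached by
#' iterated duplication: a copy preserves its founder's exon structure
#' (optionally jittered), diverges by per-site substitution with
#' probability `1 - exp(-mu)` (motif anchors protected), and lands on its
#' parent's scaffold with probability `p_tandem`, else on a fresh
#' scaffold. Finally `round(pseudo_fraction * total)` genes have their
#' motifs ablated and are recorded as pseudogenes. CYP names are assigned
#' per family with subfamily letters cycling A-Z and sequential member
#' numbers.
#'
#' @param config A [synthetic_config()].
#' @return List of class `cyp_synthetic` with `config`, `proteins` (data
#'   frame id/species/cyp_name/sequence, pseudogenes included), `models`
#'   (named list of [gene_model()]s), and `truth`: per-gene label frame
#'   (`genes`), authentic census matrix (`census`), planted count matrix,
#'   planted `enriched_families` and `species_specific` labels, founder
#'   `ortholog_pairs`, authentic `tandem_arrays`, and the paralog cluster
#'   id per gene.
#' @export
synthetic_genomes <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  species <- config$species
  counts <- config$family_counts
  families <- colnames(counts)

  scaffold_n <- stats::setNames(integer(length(species)), species)
  cursor <- list()                       # per-scaffold end coordinate
  gene_n <- stats::setNames(integer(length(species)), species)
  seqs <- list()                         # gene_id -> chars
  rows <- list()
  models <- list()

  new_scaffold <- function(s) {
    scaffold_n[s] <<- scaffold_n[s] + 1L
    sc <- sprintf("%s_scf%02d", s, scaffold_n[s])
    cursor[[sc]] <<- 0L
    sc
  }
  place_gene <- function(s, sc, lens_genomic) {
    start <- cursor[[sc]] + config$intergenic
    widths <- lens_genomic
    starts <- start + cumsum(c(0L, utils::head(widths, -1L) + config$intron_length))
    ex <- cbind(starts, starts + widths)
    cursor[[sc]] <<- ex[nrow(ex), 2L]
    ex
  }

  for (fam in families) {
    anc <- NULL
    L <- sample(config$protein_length_range[1L]:config$protein_length_range[2L], 1L)
    n_ex_base <- sample(config$exon_model[1L]:config$exon_model[2L], 1L)
    base_lens <- .random_exon_lengths(n_ex_base, 3L * L + 3L)
    present <- species[counts[, fam] > 0L]
    shared <- length(present) > 1L && stats::runif(1L) < config$ortholog_fraction
    if (shared) anc <- .random_p450(L)
    founders <- character(0)
    for (s in present) {
      c_fs <- counts[s, fam]
      if (shared) {
        founder_chars <- .mutate_protein(anc$chars, config$mu, anc$anchors)
        anchors <- anc$anchors
        lens <- base_lens
      } else {
        f <- .random_p450(L)
        founder_chars <- f$chars
        anchors <- f$anchors
        lens <- .random_exon_lengths(sample(config$exon_model[1L]:config$exon_model[2L], 1L),
                                     3L * L + 3L)
      }
      member_ids <- character(c_fs)
      for (k in seq_len(c_fs)) {
        gene_n[s] <- gene_n[s] + 1L
        gid <- sprintf("%s_g%04d", s, gene_n[s])
        member_ids[k] <- gid
        if (k == 1L) {
          chars <- founder_chars
          sc <- new_scaffold(s)
          glens <- lens
          parent <- NA_character_
          tandem <- FALSE
        } else {
          parent <- member_ids[sample.int(k - 1L, 1L)]
          chars <- .mutate_protein(seqs[[parent]], config$mu, anchors)
          glens <- .jitter_lengths(lens, config$jitter_nt, config$jitter_prob)
          tandem <- stats::runif(1L) < config$p_tandem
          sc <- if (tandem) models[[parent]]$scaffold else new_scaffold(s)
        }
        seqs[[gid]] <- chars
        strand <- sample(c("+", "-"), 1L)
        lens_genomic <- if (strand == "-") rev(glens) else glens
        ex <- place_gene(s, sc, lens_genomic)
        models[[gid]] <- gene_model(gid, species = s, scaffold = sc,
                                    strand = strand, exons = ex,
                                    protein_length = L, family = fam)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, species = s, family = fam, scaffold = sc,
          start = ex[1L, 1L], strand = strand, parent = parent,
          ancestor = member_ids[1L], tandem_with_parent = tandem,
          protein_length = L, n_exons = length(glens),
          shared_origin = shared, stringsAsFactors = FALSE)
      }
      founders <- c(founders, member_ids[1L])
    }
    if (shared && length(founders) > 1L) {
      prs <- t(utils::combn(founders, 2L))
      op <- data.frame(gene_a = prs[, 1L], gene_b = prs[, 2L], family = fam,
                       stringsAsFactors = FALSE)
      attr(rows, "ortho") <- rbind(attr(rows, "ortho"), op)
    }
  }
  genes <- do.call(rbind, rows)
  ortholog_pairs <- attr(rows, "ortho")
  if (is.null(ortholog_pairs))
    ortholog_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                                 family = character(0), stringsAsFactors = FALSE)

  # pseudogene quota: round(fraction * total), apportioned across families
  # by largest remainder so the loss is proportional and cannot flip
  # enrichment calls within the planted +/-5 margins
  n_total <- nrow(genes)
  n_pseudo <- round(config$pseudo_fraction * n_total)
  genes$pseudo <- FALSE
  if (n_pseudo > 0L) {
    fam_tot <- table(factor(genes$family, levels = families))
    exact <- n_pseudo * as.numeric(fam_tot) / n_total
    quota <- floor(exact)
    rem <- n_pseudo - sum(quota)
    if (rem > 0L) {
      extra <- order(exact - quota, decreasing = TRUE)[seq_len(rem)]
      quota[extra] <- quota[extra] + 1L
    }
    quota <- pmin(quota, as.numeric(fam_tot))
    deficit <- n_pseudo - sum(quota)
    if (deficit > 0L) {  # spill over to families with room
      room <- as.numeric(fam_tot) - quota
      for (i in order(room, decreasing = TRUE)) {
        take <- min(deficit, room[i]); quota[i] <- quota[i] + take
        deficit <- deficit - take
        if (deficit == 0L) break
      }
    }
    for (i in seq_along(families)) {
      if (quota[i] == 0L) next
      pool <- which(genes$family == families[i])
      hit <- pool[sample.int(length(pool), quota[i])]
      genes$pseudo[hit] <- TRUE
      for (g in genes$gene_id[hit]) {
        seqs[[g]] <- .ablate_motifs(seqs[[g]], sample(c("heme", "exxr", "both"), 1L))
      }
    }
  }

  # CYP names: per family, subfamily letters cycling, members sequential
  genes$cyp_name <- NA_character_
  for (fam in families) {
    idx <- which(genes$family == fam)
    i <- seq_along(idx)
    genes$cyp_name[idx] <- paste0(fam, LETTERS[(i - 1L) %% 26L + 1L], (i - 1L) %/% 26L + 1L)
  }

  proteins <- data.frame(id = genes$gene_id, species = genes$species,
                         cyp_name = genes$cyp_name,
                         sequence = vapply(genes$gene_id, function(g)
                           paste(seqs[[g]], collapse = ""), character(1)),
                         stringsAsFactors = FALSE, row.names = NULL)

  auth <- genes[!genes$pseudo, , drop = FALSE]
  census_truth <- table(factor(auth$species, levels = sort(species)),
                        factor(auth$family, levels = .family_order(families)))
  census_truth <- matrix(as.integer(census_truth), nrow = length(species),
                         dimnames = list(sort(species), .family_order(families)))

  planted_tot <- colSums(counts)
  cutoff <- census_cutoff(sum(counts), config$enrich_fraction)
  enriched <- names(planted_tot)[planted_tot >= cutoff]
  n_sp <- colSums(counts[, enriched, drop = FALSE] >= 1L)
  arrays <- detect_tandem(models[auth$gene_id])

  truth <- list(genes = genes, census = census_truth,
                planted_counts = counts, planted_cutoff = cutoff,
                enriched_families = enriched,
                species_specific = enriched[n_sp <= 2L],
                ortholog_pairs = ortholog_pairs,
                tandem_arrays = arrays,
                paralog_cluster = stats::setNames(paste(genes$species, genes$family, sep = ":"),
                                                  genes$gene_id))
  structure(list(config = config, proteins = proteins, models = models,
                 truth = truth),
            class = "cyp_synthetic")
}

#' @export
print.cyp_synthetic <- function(x, ...) {
  cat("synthetic P450 complement:", nrow(x$proteins), "genes,",
      ncol(x$config$family_counts), "families,",
      length(x$config$species), "species (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Ungapped alignment of a generated family
#'
#' Generated family members are equal length (substitution-only
#' divergence), so the sequences themselves form a valid alignment for the
#' phylogenetic stage.
#'
#' @param proteins Protein data frame (e.g. `bundle$proteins` subset).
#' @return Named character vector (id -> sequence).
#' @export
make_alignment <- function(proteins) {
  stopifnot(is.data.frame(proteins), nrow(proteins) >= 1L)
  if (length(unique(nchar(proteins$sequence))) != 1L)
    stop("family sequences differ in length; supply an external alignment",
         call. = FALSE)
  stats::setNames(proteins$sequence, proteins$id)
}

#' Write a synthetic bundle to disk
#'
#' Emits `proteins.fasta` (headers `id|species|cyp_name`), `genes.gff3`
#' (gene/mRNA/CDS features), `names.tsv` (id, species, cyp_name,
#' protein_length) and `truth.json`.
#'
#' @param bundle A `cyp_synthetic`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cyp_synthetic"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_protein_fasta(bundle$proteins, file.path(dir, "proteins.fasta"))
  g <- bundle$truth$genes
  utils::write.table(data.frame(id = g$gene_id, species = g$species,
                                cyp_name = g$cyp_name,
                                protein_length = g$protein_length),
                     file.path(dir, "names.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gff3(bundle$models, file.path(dir, "genes.gff3"))
  truth <- bundle$truth
  truth$paralog_cluster <- as.list(truth$paralog_cluster)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", matrix = "rowmajor", auto_unbox = TRUE)
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' @param models Named list of `gene_model` objects.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  ord <- order(vapply(models, function(g) as.character(g$scaffold), character(1)),
               vapply(models, function(g) g$exons[1L, 1L], numeric(1)))
  for (g in models[ord]) {
    gstart <- g$exons[1L, 1L] + 1L
    gend <- g$exons[nrow(g$exons), 2L]
    lines <- c(lines,
      sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s.gene", g$scaffold,
              gstart, gend, g$strand, g$gene_id),
      sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s.gene",
              g$scaffold, gstart, gend, g$strand, g$gene_id, g$gene_id),
      sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              g$scaffold, g$exons[, 1L] + 1L, g$exons[, 2L], g$strand,
              g$gene_id, g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}
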
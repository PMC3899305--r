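# Exon-intron gene structure: loading GFF3 gene models, strand-normalized
# structure profiles, structural similarity, paralog clusters, ortholog
# candidates, and Table-2-style intron summaries.

#' Construct a gene model
#'
#' Coordinates are stored 0-based half-open; [load_gene_models()] converts
#' from the 1-based inclusive GFF3 convention.
#'
#' @param gene_id Identifier linking to the protein record.
#' @param species Species label (may be `NA`).
#' @param scaffold Scaffold / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of (start, end), 0-based half-open,
#'   sorted by genomic start, non-overlapping.
#' @param protein_length Protein length in residues; when `NA` it is
#'   derived as `sum(exon lengths) / 3 - 1` (coding exons including stop).
#' @param family CYP family label (may be `NA`).
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, species = NA_character_, scaffold,
                       strand, exons, protein_length = NA_real_,
                       family = NA_character_) {
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("gene ", gene_id, ": no exons", call. = FALSE)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("gene ", gene_id, ": empty or inverted exon", call. = FALSE)
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("gene ", gene_id, ": overlapping exons", call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop("gene ", gene_id, ": missing or invalid strand", call. = FALSE)
  if (is.na(protein_length))
    protein_length <- sum(exons[, 2L] - exons[, 1L]) / 3 - 1
  structure(list(gene_id = gene_id, species = species, scaffold = scaffold,
                 strand = strand, exons = exons,
                 protein_length = protein_length, family = family),
            class = "gene_model")
}

#' Load gene models from a GFF3 file
#'
#' One model per mRNA; coding structure is taken from CDS features when the
#' mRNA has any, else from exon features (never mixing, which removes UTR
#' ambiguity). Metadata (species, CYP name, protein length) come from an
#' optional sidecar table keyed by mRNA id. When a protein length is
#' supplied, the internal consistency check `sum(CDS lengths) ==
#' 3 * protein_length + 3` (stop codon included) issues a warning on
#' mismatch; imperfect gene models are common and are not rejected.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @param meta Optional data frame with columns `id`, and any of `species`,
#'   `cyp_name`, `protein_length`.
#' @return Named list of `gene_model` objects (names = gene ids).
#' @export
load_gene_models <- function(path, meta = NULL) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
                      character(1))
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  if (nrow(mrna) == 0L) stop("no mRNA/transcript features in ", path, call. = FALSE)
  cds <- df[df$type == "CDS", , drop = FALSE]
  exon <- df[df$type == "exon", , drop = FALSE]
  if (!is.null(meta)) stopifnot("id" %in% names(meta))
  errors <- character(0)
  mismatches <- character(0)
  models <- list()
  for (r in seq_len(nrow(mrna))) {
    mid <- mrna$ID[r]
    feats <- cds[!is.na(cds$Parent) & cds$Parent == mid, , drop = FALSE]
    if (nrow(feats) == 0L)
      feats <- exon[!is.na(exon$Parent) & exon$Parent == mid, , drop = FALSE]
    if (nrow(feats) == 0L) {
      errors <- c(errors, paste0(mid, ": no CDS or exon features"))
      next
    }
    species <- NA_character_; fam <- NA_character_; plen <- NA_real_
    if (!is.null(meta)) {
      hit <- match(mid, meta$id)
      if (!is.na(hit)) {
        if ("species" %in% names(meta)) species <- meta$species[hit]
        if ("protein_length" %in% names(meta)) plen <- meta$protein_length[hit]
        if ("cyp_name" %in% names(meta) && !is.na(meta$cyp_name[hit]))
          fam <- parse_cyp_name(meta$cyp_name[hit])$family
      }
    }
    g <- tryCatch(
      gene_model(gene_id = mid, species = species,
                 scaffold = as.character(mrna$seqnames[r]),
                 strand = as.character(mrna$strand[r]),
                 exons = cbind(feats$start - 1L, feats$end),  # GFF3 -> 0-based half-open
                 protein_length = plen, family = fam),
      error = function(e) conditionMessage(e))
    if (is.character(g)) { errors <- c(errors, g); next }
    if (!is.na(plen)) {
      clen <- sum(g$exons[, 2L] - g$exons[, 1L])
      if (clen != 3 * plen + 3) mismatches <- c(mismatches, mid)
    }
    models[[mid]] <- g
  }
  if (length(errors))
    stop("invalid gene model(s):\n  ", paste(errors, collapse = "\n  "), call. = FALSE)
  if (length(mismatches))
    warning(length(mismatches), " gene model(s) where CDS length != 3*protein_length+3: ",
            paste(utils::head(mismatches, 5), collapse = ", "),
            if (length(mismatches) > 5) ", ..." else "", call. = FALSE)
  models
}

#' Strand-normalized exon-intron structure profile
#'
#' Exon lengths ordered 5' to 3' in transcript orientation (minus-strand
#' genes have their genomic exon order reversed), with intron insertion
#' offsets as cumulative coding positions. The profile is invariant to the
#' strand a gene is annotated on.
#'
#' @param g A `gene_model`.
#' @return Object of class `structure_profile`: list with `gene_id`,
#'   `exon_lengths`, `n_introns`, `intron_offsets`.
#' @export
structure_profile <- function(g) {
  stopifnot(inherits(g, "gene_model"))
  len <- g$exons[, 2L] - g$exons[, 1L]
  if (g$strand == "-") len <- rev(len)
  structure(list(gene_id = g$gene_id,
                 exon_lengths = as.numeric(len),
                 n_introns = length(len) - 1L,
                 intron_offsets = if (length(len) > 1L) cumsum(len[-length(len)]) else numeric(0)),
            class = "structure_profile")
}

#' Score structural similarity of two genes
#'
#' Genes with different intron counts score 0. With equal intron counts the
#' score is the fraction of positionally paired exons whose lengths differ
#' by at most `tol_nt` nucleotides (default 3, one codon, the smallest
#' tolerance that survives codon-boundary annotation wobble). Two genes
#' share a structure when the score reaches `theta` (default 0.8).
#'
#' @param a,b `structure_profile` objects.
#' @param tol_nt Per-exon length tolerance in nucleotides.
#' @param theta Same-structure score threshold.
#' @return List with `gene_a`, `gene_b`, `score` in `[0, 1]`,
#'   `same_structure`.
#' @export
structure_similarity <- function(a, b, tol_nt = 3, theta = 0.8) {
  stopifnot(inherits(a, "structure_profile"), inherits(b, "structure_profile"))
  if (a$n_introns != b$n_introns) {
    score <- 0
  } else {
    score <- mean(abs(a$exon_lengths - b$exon_lengths) <= tol_nt)
  }
  list(gene_a = a$gene_id, gene_b = b$gene_id, score = score,
       same_structure = a$n_introns == b$n_introns && score >= theta)
}

.profiles <- function(models) lapply(models, structure_profile)

#' Cluster same-structure genes into paralog groups
#'
#' Single-linkage clustering on same-structure edges among genes of one
#' species and family: connected components of size >= 2 are duplicate
#' groups, the rest singletons.
#'
#' @param models List of `gene_model` objects (one species and family).
#' @param tol_nt,theta Passed to [structure_similarity()].
#' @return List with `clusters` (list of gene-id vectors, size >= 2) and
#'   `singletons` (gene ids).
#' @export
cluster_paralogs <- function(models, tol_nt = 3, theta = 0.8) {
  ids <- vapply(models, `[[`, character(1), "gene_id")
  k <- length(ids)
  if (k == 0L) return(list(clusters = list(), singletons = character(0)))
  profs <- .profiles(models)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (k > 1L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (structure_similarity(profs[[i]], profs[[j]], tol_nt, theta)$same_structure) {
      parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(k), find, integer(1))
  groups <- split(ids, comp)
  sizes <- lengths(groups)
  list(clusters = unname(groups[sizes >= 2L]),
       singletons = unname(unlist(groups[sizes == 1L], use.names = FALSE)) %||% character(0))
}

#' Cross-species ortholog candidates by shared gene structure
#'
#' All cross-species gene pairs (same family) with `same_structure` true.
#' Many-to-one mappings are permitted: a single gene in one species may
#' match every member of a duplicate cluster in another.
#'
#' @param models List of `gene_model` objects of one family, >= 2 species.
#' @param tol_nt,theta Passed to [structure_similarity()].
#' @return Data frame `gene_a`, `species_a`, `gene_b`, `species_b`,
#'   `score`.
#' @export
ortholog_candidates <- function(models, tol_nt = 3, theta = 0.8) {
  ids <- vapply(models, `[[`, character(1), "gene_id")
  spc <- vapply(models, `[[`, character(1), "species")
  empty <- data.frame(gene_a = character(0), species_a = character(0),
                      gene_b = character(0), species_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (length(unique(spc)) < 2L) return(empty)
  profs <- .profiles(models)
  rows <- list()
  k <- length(ids)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (spc[i] == spc[j]) next
    s <- structure_similarity(profs[[i]], profs[[j]], tol_nt, theta)
    if (s$same_structure) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = ids[i], species_a = spc[i], gene_b = ids[j],
        species_b = spc[j], score = s$score, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Intron-count summary for one family and species
#'
#' Computed over genes whose protein is at least `min_len` residues
#' (default 400, the published filter); reports the min-max intron range
#' and the P/I statistic: P genes sharing the modal intron count I. Ties
#' on the mode list all tied counts, with P/I reported for the smallest.
#'
#' @param models List of `gene_model` objects (one family and species).
#' @param min_len Minimum protein length in residues.
#' @return List of class `intron_summary`: `n_qualifying`, `min_introns`,
#'   `max_introns`, `modal_counts`, `P`, `I`, `na` (no qualifying gene).
#' @export
intron_summary <- function(models, min_len = 400) {
  plen <- vapply(models, `[[`, numeric(1), "protein_length")
  keep <- !is.na(plen) & plen >= min_len
  counts <- vapply(models[keep], function(g) nrow(g$exons) - 1L, integer(1))
  if (length(counts) == 0L) {
    return(structure(list(n_qualifying = 0L, min_introns = NA_integer_,
                          max_introns = NA_integer_, modal_counts = integer(0),
                          P = NA_integer_, I = NA_integer_, na = TRUE),
                     class = "intron_summary"))
  }
  tab <- table(counts)
  P <- max(tab)
  modes <- sort(as.integer(names(tab)[tab == P]))
  structure(list(n_qualifying = length(counts),
                 min_introns = min(counts), max_introns = max(counts),
                 modal_counts = modes, P = as.integer(P), I = modes[1L],
                 na = FALSE),
            class = "intron_summary")
}

#' @export
print.intron_summary <- function(x, ...) {
  if (x$na) cat("intron summary: NA (no qualifying gene)\n")
  else cat(sprintf("intron summary: min-max %d-%d, P/I %d/%d (%d genes)\n",
                   x$min_introns, x$max_introns, x$P, x$I, x$n_qualifying))
  invisible(x)
}

#' Table of intron summaries per family and species
#'
#' @param models List of `gene_model` objects with family and species set.
#' @param min_len Minimum protein length, default 400.
#' @return Data frame with `family`, `species`, `n_qualifying`, `min_max`
#'   (e.g. `"9-14"` or `"NA"`), `p_over_i` (e.g. `"2/13"`, tied modes
#'   separated by `;`).
#' @export
intron_summary_table <- function(models, min_len = 400) {
  fam <- vapply(models, `[[`, character(1), "family")
  spc <- vapply(models, `[[`, character(1), "species")
  key <- paste(fam, spc, sep = "\r")
  rows <- lapply(unique(key), function(k) {
    sub <- models[key == k]
    s <- intron_summary(sub, min_len)
    data.frame(family = sub[[1L]]$family, species = sub[[1L]]$species,
               n_qualifying = s$n_qualifying,
               min_max = if (s$na) "NA" else paste0(s$min_introns, "-", s$max_introns),
               p_over_i = if (s$na) "NA" else
                 paste(sprintf("%d/%d", s$P, s$modal_counts), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$family, out$species), , drop = FALSE]
}
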
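# Tandem gene arrays: same-family genes co-located on a scaffold.

.model_frame <- function(models) {
  data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    species = vapply(models, `[[`, character(1), "species"),
    family = vapply(models, `[[`, character(1), "family"),
    scaffold = vapply(models, function(g) as.character(g$scaffold), character(1)),
    start = vapply(models, function(g) g$exons[1L, 1L], numeric(1)),
    end = vapply(models, function(g) g$exons[nrow(g$exons), 2L], numeric(1)),
    strand = vapply(models, `[[`, character(1), "strand"),
    n_introns = vapply(models, function(g) nrow(g$exons) - 1L, integer(1)),
    protein_length = vapply(models, `[[`, numeric(1), "protein_length"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect tandem arrays of same-family P450 genes
#'
#' The default criterion follows the published scaffold-level rule: two or
#' more genes of the same family and species on one scaffold form an
#' array, regardless of how many unrelated genes intervene. A finite
#' `max_intervening` applies a stricter adjacency rule: runs are broken
#' wherever more than that many non-family genes sit between consecutive
#' members (gene order taken over *all* models on the scaffold). Strand is
#' ignored.
#'
#' @param models List of `gene_model` objects with species and family set;
#'   include all genes (any family) when using a finite `max_intervening`.
#' @param max_intervening Maximum intervening non-family genes, default
#'   `Inf` (scaffold co-location only).
#' @return Data frame with one row per array: `family`, `species`,
#'   `scaffold`, `size`, `members` (comma-separated ids ordered by start
#'   coordinate). Genes lacking a scaffold or family are skipped.
#' @export
detect_tandem <- function(models, max_intervening = Inf) {
  df <- .model_frame(models)
  df <- df[!is.na(df$scaffold) & !is.na(df$family), , drop = FALSE]
  empty <- data.frame(family = character(0), species = character(0),
                      scaffold = character(0), size = integer(0),
                      members = character(0), stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(empty)
  rows <- list()
  if (is.infinite(max_intervening)) {
    key <- paste(df$species, df$family, df$scaffold, sep = "\r")
    for (k in unique(key)) {
      sub <- df[key == k, , drop = FALSE]
      if (nrow(sub) < 2L) next
      sub <- sub[order(sub$start), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        family = sub$family[1L], species = sub$species[1L],
        scaffold = sub$scaffold[1L], size = nrow(sub),
        members = paste(sub$gene_id, collapse = ","), stringsAsFactors = FALSE)
    }
  } else {
    skey <- paste(df$species, df$scaffold, sep = "\r")
    for (k in unique(skey)) {
      scaf <- df[skey == k, , drop = FALSE]
      scaf <- scaf[order(scaf$start), , drop = FALSE]
      for (fam in unique(scaf$family)) {
        pos <- which(scaf$family == fam)
        if (length(pos) < 2L) next
        run_break <- c(FALSE, diff(pos) - 1L > max_intervening)
        run_id <- cumsum(run_break)
        for (g in split(pos, run_id)) {
          if (length(g) < 2L) next
          rows[[length(rows) + 1L]] <- data.frame(
            family = fam, species = scaf$species[1L],
            scaffold = scaf$scaffold[1L], size = length(g),
            members = paste(scaf$gene_id[g], collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$family, out$species, out$scaffold), , drop = FALSE]
}

#' Scaffold distribution of a family's genes
#'
#' Per-scaffold gene counts including singleton scaffolds, ordered by
#' descending count then scaffold name — the presentation used in the
#' published duplication table.
#'
#' @param models List of `gene_model` objects.
#' @param family Family to tabulate.
#' @param species Optional species restriction.
#' @return Data frame `scaffold`, `count`.
#' @export
scaffold_distribution <- function(models, family, species = NULL) {
  df <- .model_frame(models)
  df <- df[!is.na(df$family) & df$family == family, , drop = FALSE]
  if (!is.null(species)) df <- df[df$species %in% species, , drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(scaffold = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(df$scaffold)
  out <- data.frame(scaffold = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$scaffold), , drop = FALSE]
  rownames(out) <- NULL
  out
}
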
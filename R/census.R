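# CYP nomenclature and the species-by-family census with the fractional
# enrichment cutoff.

#' Parse CYP-style names into family, subfamily and member
#'
#' A CYP name is `CYP<family number><subfamily letter><member number>`,
#' e.g. `CYP5035C1`; subfamily and member may be absent (`CYP63B`,
#' `CYP63`). The `CYP` prefix is case-insensitive.
#'
#' @param name Character vector of names.
#' @return Data frame with columns `name`, `family` (e.g. `"CYP5035"`),
#'   `subfamily` (single uppercase letter or `NA`), `member` (integer or
#'   `NA`).
#' @examples
#' parse_cyp_name(c("CYP5035C1", "CYP63B", "CYP63"))
#' @export
parse_cyp_name <- function(name) {
  m <- regmatches(name, regexec("^[Cc][Yy][Pp]([0-9]+)([A-Za-z]?)([0-9]*)$", name))
  ok <- lengths(m) == 4L
  if (any(!ok))
    stop("unparseable CYP name(s): ", paste(unique(name[!ok]), collapse = ", "),
         call. = FALSE)
  fam <- vapply(m, `[`, character(1), 2L)
  sub <- toupper(vapply(m, `[`, character(1), 3L))
  mem <- vapply(m, `[`, character(1), 4L)
  bad <- nzchar(mem) & !nzchar(sub)   # digits after family with no subfamily letter
  if (any(bad))
    stop("unparseable CYP name(s): ", paste(unique(name[bad]), collapse = ", "),
         call. = FALSE)
  data.frame(name = name,
             family = paste0("CYP", fam),
             subfamily = ifelse(nzchar(sub), sub, NA_character_),
             member = ifelse(nzchar(mem), suppressWarnings(as.integer(mem)), NA_integer_),
             stringsAsFactors = FALSE)
}

.family_order <- function(families) {
  families[order(as.integer(sub("^CYP", "", families)))]
}

#' Build the species-by-family P450 census
#'
#' Counts authentic P450 records per species and CYP family. Families are
#' ordered by their numeric family identifier, species lexicographically;
#' ordering is deterministic and independent of input order.
#'
#' @param records Data frame of authentic records with columns `species`
#'   and `cyp_name` (every `cyp_name` must parse).
#' @return An object of class `cyp_census`: list with `species`,
#'   `families`, integer `counts` matrix (species x families) and `total`.
#' @export
build_census <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    out <- list(species = character(0), families = character(0),
                counts = matrix(0L, 0, 0), total = 0L)
    class(out) <- "cyp_census"
    return(out)
  }
  if (anyNA(records$species) || anyNA(records$cyp_name))
    stop("records with missing species or cyp_name: ",
         paste(utils::head(records$id[is.na(records$species) | is.na(records$cyp_name)], 10),
               collapse = ", "), call. = FALSE)
  fam <- parse_cyp_name(records$cyp_name)$family
  species <- sort(unique(records$species))
  families <- .family_order(unique(fam))
  counts <- table(factor(records$species, levels = species),
                  factor(fam, levels = families))
  counts <- matrix(as.integer(counts), nrow = length(species),
                   dimnames = list(species, families))
  out <- list(species = species, families = families, counts = counts,
              total = sum(counts))
  class(out) <- "cyp_census"
  out
}

#' @export
print.cyp_census <- function(x, ...) {
  cat("P450 census:", x$total, "proteins,", length(x$families), "families,",
      length(x$species), "species\n")
  invisible(x)
}

# Round half away from zero (round-half-up for positive x); base round()
# rounds half to even, which would be direction-unstable here.
round_half_up <- function(x) floor(x + 0.5)

#' Enrichment cutoff from a census total
#'
#' The cutoff is `fraction * total` rounded half-up, floored at 1. With the
#' published six-genome total of 1061 proteins and the 2% fraction this
#' gives 21.
#'
#' @param total Total P450 count across all species.
#' @param fraction Fraction of the total, default 0.02.
#' @return Positive integer cutoff.
#' @export
census_cutoff <- function(total, fraction = 0.02) {
  stopifnot(total >= 1, fraction > 0, fraction < 1)
  max(1L, as.integer(round_half_up(fraction * total)))
}

#' Flag enriched and species-specific P450 families
#'
#' A family is enriched when its summed count over all species reaches the
#' fractional cutoff (see [census_cutoff()]); an enriched family present in
#' at most `k_species_specific` species is additionally flagged
#' species-specific.
#'
#' @param census A `cyp_census`.
#' @param fraction Enrichment fraction of the census total, default 0.02.
#' @param k_species_specific Maximum number of species for the
#'   species-specific flag, default 2.
#' @return An object of class `cyp_enrichment`: list with `fraction`,
#'   `cutoff`, `families` (data frame of family, total, enriched,
#'   n_species, species_specific; enriched families first, by descending
#'   total), `enriched` (character vector), `species_specific`, and
#'   `presence` (logical species x enriched-family matrix).
#' @export
enrich <- function(census, fraction = 0.02, k_species_specific = 2) {
  stopifnot(inherits(census, "cyp_census"))
  if (census$total == 0L) stop("census total is zero", call. = FALSE)
  stopifnot(fraction > 0, fraction < 1)
  cutoff <- census_cutoff(census$total, fraction)
  totals <- colSums(census$counts)
  n_species <- colSums(census$counts >= 1L)
  fam <- data.frame(family = census$families,
                    total = as.integer(totals),
                    n_species = as.integer(n_species),
                    stringsAsFactors = FALSE)
  fam$enriched <- fam$total >= cutoff
  fam$species_specific <- fam$enriched & fam$n_species <= k_species_specific
  # enriched first by descending total; ties and the remainder keep numeric
  # family order
  fam <- fam[order(-fam$enriched, -fam$total * fam$enriched), , drop = FALSE]
  rownames(fam) <- NULL
  enriched <- fam$family[fam$enriched]
  presence <- census$counts[, enriched, drop = FALSE] >= 1L
  out <- list(fraction = fraction, cutoff = cutoff, families = fam,
              enriched = enriched,
              species_specific = fam$family[fam$species_specific],
              presence = presence)
  class(out) <- "cyp_enrichment"
  out
}

#' @export
print.cyp_enrichment <- function(x, ...) {
  cat("Enrichment cutoff", x$cutoff, sprintf("(%.1f%% of total)\n", 100 * x$fraction))
  cat(length(x$enriched), "enriched families:",
      paste(x$enriched, collapse = ", "), "\n")
  if (length(x$species_specific))
    cat("species-specific:", paste(x$species_specific, collapse = ", "), "\n")
  invisible(x)
}

#' Write census and enrichment tables
#'
#' `write_census` writes the species x family count matrix as TSV;
#' `write_enrichment` writes the per-family enrichment table (family,
#' total, enriched flag, n_species, species-specific flag).
#'
#' @param census A `cyp_census`.
#' @param enrichment A `cyp_enrichment`.
#' @param path Output TSV path.
#' @export
write_census <- function(census, path) {
  df <- data.frame(species = census$species, census$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_census
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(enrichment$families, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
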
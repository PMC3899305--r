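# P450 authentication by signature motifs.
#
# An authentic P450 carries the heme-binding decapeptide FXXGXXXCXG (the
# axial cysteine ligand of the heme iron) and, upstream of it, the EXXR
# salt-bridge motif of the K-helix.

.AA20 <- "ACDEFGHIKLMNPQRSTVWY"
.AA_CLASS <- paste0("[", .AA20, "]")

# X positions of the patterns accept any of the 20 standard residues but not
# the ambiguity code X: an unknown residue cannot positively evidence a motif.
.HEME_REGEX <- paste0("(?=F", .AA_CLASS, "{2}G", .AA_CLASS, "{3}C", .AA_CLASS, "G)")
.EXXR_REGEX <- paste0("(?=E", .AA_CLASS, "{2}R)")

.regex_starts <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Clean a protein sequence for motif scanning
#'
#' Uppercases the sequence and strips terminal stop characters (`*`).
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return Cleaned character vector.
#' @export
clean_sequence <- function(sequence) {
  sub("\\*+$", "", toupper(sequence))
}

.validate_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    return("empty sequence")
  bad <- gsub(paste0("[", .AA20, "X]"), "", sequence)
  if (nzchar(bad))
    return(paste0("non-amino-acid characters: ", paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
  NULL
}

#' Scan a protein for the two P450 signature motifs
#'
#' Finds all (possibly overlapping) matches of the heme-binding decapeptide
#' (F at offset 1, G at 4, C at 8, G at 10 of a 10-residue window, any
#' standard residue elsewhere) and of the K-helix EXXR tetrapeptide. A
#' protein is called authentic when both motifs occur and at least one EXXR
#' start lies strictly upstream of at least one heme-motif start, matching
#' the K-helix-before-heme-ligand order of the P450 fold.
#'
#' Positions are 1-based. The ambiguity code X matches nothing.
#'
#' @param sequence A single amino-acid sequence (uppercase one-letter codes;
#'   lowercase input and terminal `*` are tolerated and cleaned).
#' @return A list with integer vectors `heme_positions` and
#'   `exxr_positions` (ascending 1-based match starts) and logical
#'   `authentic`.
#' @examples
#' scan_motifs("MAEVLRAAAAFGRGRHRCLG")
#' @export
scan_motifs <- function(sequence) {
  sequence <- clean_sequence(sequence)
  err <- .validate_sequence(sequence)
  if (!is.null(err)) stop("invalid sequence: ", err, call. = FALSE)
  heme <- .regex_starts(sequence, .HEME_REGEX)
  exxr <- .regex_starts(sequence, .EXXR_REGEX)
  authentic <- length(heme) > 0L && length(exxr) > 0L && min(exxr) < max(heme)
  list(heme_positions = heme, exxr_positions = exxr, authentic = authentic)
}

.rejection_reason <- function(sequence) {
  sequence <- clean_sequence(sequence)
  err <- .validate_sequence(sequence)
  if (!is.null(err)) return("bad-sequence")
  heme <- .regex_starts(sequence, .HEME_REGEX)
  exxr <- .regex_starts(sequence, .EXXR_REGEX)
  if (length(heme) == 0L) return("missing-heme")
  if (length(exxr) == 0L) return("missing-exxr")
  if (!(min(exxr) < max(heme))) return("wrong-order")
  NA_character_
}

#' Partition candidate proteins into authentic P450s and rejects
#'
#' @param records A data frame of protein records with at least columns
#'   `id` and `sequence`; columns `species` and `cyp_name` are carried
#'   through untouched.
#' @return A list with `authentic` (the subset of `records` passing both
#'   motif checks, input order preserved) and `rejected`, a data frame of
#'   `id` and machine-readable `reason` (`bad-sequence`, `missing-heme`,
#'   `missing-exxr`, `wrong-order`).
#' @export
filter_authentic <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (nrow(records) == 0L) {
    return(list(authentic = records,
                rejected = data.frame(id = character(0), reason = character(0),
                                      stringsAsFactors = FALSE)))
  }
  dup <- unique(records$id[duplicated(records$id)])
  if (length(dup) > 0L)
    stop("duplicate record ids: ", paste(dup, collapse = ", "), call. = FALSE)
  reason <- vapply(records$sequence, .rejection_reason, character(1), USE.NAMES = FALSE)
  keep <- is.na(reason)
  list(authentic = records[keep, , drop = FALSE],
       rejected = data.frame(id = records$id[!keep], reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Read protein records from FASTA
#'
#' Headers follow the convention `id|species|cyp_name`; if headers carry no
#' `|`, a sidecar table (`id`, `species`, `cyp_name`) supplies the labels.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param names_tsv Optional path to a tab-separated sidecar with columns
#'   `id`, `species`, `cyp_name` (additional columns are kept).
#' @return Data frame with columns `id`, `species`, `cyp_name`, `sequence`
#'   (plus any extra sidecar columns).
#' @export
read_protein_fasta <- function(path, names_tsv = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- sub("\\s.*$", "", names(aa))
  seqs <- as.character(aa)
  if (any(grepl("\\|", headers))) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    rec <- data.frame(
      id = vapply(parts, `[`, character(1), 1L),
      species = vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, character(1)),
      cyp_name = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else NA_character_, character(1)),
      sequence = unname(seqs), stringsAsFactors = FALSE)
  } else {
    rec <- data.frame(id = headers, species = NA_character_,
                      cyp_name = NA_character_, sequence = unname(seqs),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(names_tsv)) {
    side <- utils::read.delim(names_tsv, stringsAsFactors = FALSE)
    stopifnot("id" %in% names(side))
    ids0 <- rec$id
    rec$species <- NULL; rec$cyp_name <- NULL
    rec <- merge(rec, side, by = "id", all.x = TRUE, sort = FALSE)
    rec <- rec[match(ids0, rec$id), , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}

#' Write protein records to FASTA with `id|species|cyp_name` headers
#'
#' @param records Data frame with `id`, `species`, `cyp_name`, `sequence`.
#' @param path Output file.
#' @export
write_protein_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- paste(records$id, records$species, records$cyp_name, sep = "|")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
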
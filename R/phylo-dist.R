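# Poisson-corrected protein distances.

.aln_matrix <- function(aln) {
  if (inherits(aln, "AAStringSet")) aln <- as.character(aln)
  if (is.matrix(aln)) {
    stopifnot(!is.null(rownames(aln)))
    return(aln)
  }
  stopifnot(is.character(aln), !is.null(names(aln)))
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows differ in length", call. = FALSE)
  if (anyDuplicated(names(aln)))
    stop("duplicate taxon labels", call. = FALSE)
  do.call(rbind, strsplit(aln, ""))
}

#' Proportion of differing residues between two aligned sequences
#'
#' Columns where either sequence has a gap (`-`) are excluded. For a pair
#' of sequences complete and pairwise deletion coincide; the alignment-wide
#' complete-deletion rule (drop columns gapped in *any* taxon) is applied
#' by [p_distance_matrix()].
#'
#' @param a,b Equal-length (gapped) amino-acid strings.
#' @return p-distance in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  if (length(x) != length(y)) stop("sequences differ in length", call. = FALSE)
  keep <- x != "-" & y != "-"
  if (!any(keep)) stop("no comparable (ungapped) columns", call. = FALSE)
  mean(x[keep] != y[keep])
}

#' Pairwise p-distance matrix from an alignment
#'
#' Under complete deletion, columns containing a gap in any taxon are
#' removed globally before any pair is compared; under pairwise deletion
#' each pair uses its own ungapped columns.
#'
#' @param aln Named character vector of equal-length gapped sequences, a
#'   character matrix with rownames, or an `AAStringSet`.
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return Symmetric matrix of p-distances with taxa as dimnames.
#' @export
p_distance_matrix <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- .aln_matrix(aln)
  n <- nrow(m)
  if (deletion == "complete") {
    keep <- colSums(m == "-") == 0L
    if (!any(keep)) stop("no comparable columns after complete deletion", call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    keep <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(keep))
      stop("no comparable columns for pair ", rownames(m)[i], " / ",
           rownames(m)[j], call. = FALSE)
    d[i, j] <- d[j, i] <- mean(m[i, keep] != m[j, keep])
  }
  d
}

#' Poisson correction of a p-distance
#'
#' `d = -ln(1 - p)`, the expected number of amino-acid substitutions per
#' site under a Poisson model of equal rates across sites. Near-saturated
#' pairs (`p > max_p`, default 0.95) are capped at `-ln(1 - max_p)` with a
#' warning so matrices stay finite; `p >= 1` is an error.
#'
#' @param p Numeric vector of p-distances in `[0, 1)`.
#' @param max_p Saturation cap, default 0.95.
#' @return Distances in substitutions per site.
#' @export
poisson_distance <- function(p, max_p = 0.95) {
  if (any(p < 0)) stop("negative p-distance", call. = FALSE)
  if (any(p >= 1)) stop("saturated p-distance (p >= 1)", call. = FALSE)
  sat <- p > max_p
  if (any(sat)) {
    warning(sum(sat), " pair(s) with p > ", max_p, " capped at -ln(1-",
            max_p, ")", call. = FALSE)
    p[sat] <- max_p
  }
  -log(1 - p)
}

#' Poisson-corrected distance matrix from an alignment
#'
#' @inheritParams p_distance_matrix
#' @inheritParams poisson_distance
#' @return Symmetric matrix of Poisson-corrected distances.
#' @export
poisson_distance_matrix <- function(aln, deletion = c("complete", "pairwise"),
                                    max_p = 0.95) {
  p <- p_distance_matrix(aln, deletion)
  d <- p
  d[] <- 0
  off <- row(p) != col(p)
  d[off] <- poisson_distance(p[off], max_p = max_p)
  d
}

.check_dist <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(!is.finite(D))) stop("non-finite distances", call. = FALSE)
  if (any(D < -1e-12)) stop("negative distances", call. = FALSE)
  D
}
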
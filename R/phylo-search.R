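# Minimum evolution tree search: nearest-neighbor-interchange (NNI)
# neighborhoods, close-neighbor-interchange (CNI) local search, and an
# exhaustive enumeration oracle for small taxon sets.

#' All topologies one nearest-neighbor interchange away
#'
#' Each internal edge of an unrooted binary tree admits two NNI
#' rearrangements, giving `2 * (n - 3)` neighbor topologies.
#'
#' @param tree An `me_tree`.
#' @return List of `me_tree` topologies (no branch lengths).
#' @export
nni_neighbors <- function(tree) {
  stopifnot(inherits(tree, "me_tree"))
  n <- length(tree$tip.label)
  if (n < 4L) return(list())
  edge <- tree$edge
  adj <- .adjacency(edge, 2L * n - 2L)
  out <- list()
  find_row <- function(E, a, b) {
    which((E[, 1L] == a & E[, 2L] == b) | (E[, 1L] == b & E[, 2L] == a))[1L]
  }
  internal <- which(edge[, 1L] > n & edge[, 2L] > n)
  for (k in internal) {
    u <- edge[k, 1L]; v <- edge[k, 2L]
    a <- setdiff(adj[[u]], v)   # two subtrees attached at u
    b <- setdiff(adj[[v]], u)   # two subtrees attached at v
    for (swap in list(c(a[2L], b[1L]), c(a[2L], b[2L]))) {
      E2 <- edge
      r1 <- find_row(E2, u, swap[1L])
      r2 <- find_row(E2, v, swap[2L])
      E2[r1, ] <- c(u, swap[2L])
      E2[r2, ] <- c(v, swap[1L])
      out[[length(out) + 1L]] <- new_me_tree(tree$tip.label, E2)
    }
  }
  out
}

# Distinct topologies within `level` NNI moves of `tree` (excluding itself).
.nni_neighborhood <- function(tree, level = 1L) {
  seen <- canonical_topology(tree)
  frontier <- list(tree)
  out <- list()
  for (step in seq_len(level)) {
    nxt <- list()
    for (t0 in frontier) for (nb in nni_neighbors(t0)) {
      key <- canonical_topology(nb)
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- nb
        nxt[[length(nxt) + 1L]] <- nb
      }
    }
    frontier <- nxt
    if (!length(frontier)) break
  }
  out
}

#' Close-neighbor-interchange search for the minimum evolution tree
#'
#' Iterated best-improvement local search: at each step every topology
#' within `level` NNI moves of the current tree is evaluated by OLS branch
#' lengths, and the neighbor with the smallest ME score (sum of branch
#' lengths) replaces the current tree if it improves it by more than
#' `tol`. Terminates at a local optimum; the returned score never exceeds
#' the starting score. `level = 1` is the plain NNI neighborhood.
#'
#' @param start An `me_tree`; OLS lengths are fitted if absent.
#' @param D Distance matrix over the tree's taxa.
#' @param level Search radius in NNI moves, default 1.
#' @param tol Strict-improvement tolerance, default 1e-12.
#' @return The locally optimal `me_tree` (OLS lengths, `me_score`, `ssq`),
#'   with the accepted ME-score trajectory in attribute `"trajectory"`.
#' @export
cni_search <- function(start, D, level = 1L, tol = 1e-12) {
  stopifnot(inherits(start, "me_tree"))
  D <- .check_dist(D)
  cur <- if (is.null(start$ssq)) ols_branch_lengths(start, D) else start
  trajectory <- cur$me_score
  repeat {
    nbs <- .nni_neighborhood(cur, level)
    if (!length(nbs)) break
    fits <- lapply(nbs, ols_branch_lengths, D = D)
    scores <- vapply(fits, `[[`, numeric(1), "me_score")
    best <- which.min(scores)
    if (scores[best] < cur$me_score - tol) {
      cur <- fits[[best]]
      trajectory <- c(trajectory, cur$me_score)
    } else break
  }
  attr(cur, "trajectory") <- trajectory
  cur
}

# Enumerate all unrooted binary topologies over the given labels by
# sequential leaf insertion ((2k-5)!! topologies).
.enumerate_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3L)
  res <- list()
  grow <- function(edge, k) {
    if (k > n) {
      res[[length(res) + 1L]] <<- new_me_tree(labels, edge)
      return(invisible())
    }
    w <- n + k - 2L
    for (e in seq_len(nrow(edge))) {
      old <- edge[e, ]
      E2 <- edge
      E2[e, ] <- c(old[1L], w)
      E2 <- rbind(E2, c(w, old[2L]), c(w, k))
      grow(E2, k + 1L)
    }
  }
  grow(rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L)), 4L)
  res
}

#' Exhaustive minimum evolution search (oracle)
#'
#' Evaluates every unrooted binary topology by OLS and returns the ME-score
#' minimizer. Ties (within 1e-12) are broken by the lexicographically
#' smallest canonical topology string. Feasible for `n <= max_n` only
#' (10395 topologies at n = 8).
#'
#' @param D Distance matrix.
#' @param max_n Refuse larger problems, default 8.
#' @return The optimal `me_tree` with OLS lengths.
#' @export
exhaustive_me <- function(D, max_n = 8L) {
  D <- .check_dist(D)
  n <- nrow(D)
  if (n > max_n) stop("n = ", n, " exceeds max_n = ", max_n, call. = FALSE)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  topos <- .enumerate_topologies(rownames(D))
  best <- NULL; best_key <- NULL
  for (tp in topos) {
    fit <- ols_branch_lengths(tp, D)
    if (is.null(best) || fit$me_score < best$me_score - 1e-12) {
      best <- fit; best_key <- canonical_topology(fit)
    } else if (abs(fit$me_score - best$me_score) <= 1e-12) {
      key <- canonical_topology(fit)
      if (key < best_key) { best <- fit; best_key <- key }
    }
  }
  best
}

#' Minimum evolution tree for one P450 family
#'
#' The full inference pipeline: p-distances (complete deletion by default)
#' -> Poisson correction -> neighbor-joining initial tree -> OLS branch
#' lengths -> CNI search. CNI refinement can be restricted to smaller
#' families via `cni_max_taxa` (NJ + OLS is reported beyond it).
#'
#' @param aln Named character vector (or `AAStringSet`/matrix) of aligned,
#'   equal-length family member sequences; >= 2 members.
#' @param deletion Gap handling for p-distances, `"complete"` (default) or
#'   `"pairwise"`.
#' @param level CNI search level (NNI radius), default 1.
#' @param cni Run the CNI search (default `TRUE`).
#' @param cni_max_taxa Skip CNI above this many taxa, default `Inf`.
#' @param max_p Saturation cap passed to [poisson_distance()].
#' @return List with `tree` (`me_tree`), `newick` (branch lengths clamped
#'   at zero), `me_score`, `trajectory`, and the distance matrix `D`.
#' @export
family_tree <- function(aln, deletion = c("complete", "pairwise"),
                        level = 1L, cni = TRUE, cni_max_taxa = Inf,
                        max_p = 0.95) {
  deletion <- match.arg(deletion)
  m <- .aln_matrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 family members", call. = FALSE)
  D <- poisson_distance_matrix(m, deletion = deletion, max_p = max_p)
  tr <- nj_tree(D)
  if (nrow(m) >= 3L) {
    tr <- ols_branch_lengths(tr, D)
    if (cni && nrow(m) <= cni_max_taxa) tr <- cni_search(tr, D, level = level)
  }
  list(tree = tr, newick = write_newick(tr), me_score = tr$me_score,
       trajectory = attr(tr, "trajectory") %||% tr$me_score, D = D)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
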
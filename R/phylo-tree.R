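# Unrooted binary trees, neighbor joining, and ordinary least-squares (OLS)
# branch lengths for the minimum evolution criterion.
#
# Internal representation (class "me_tree"): tips are nodes 1..n, internal
# nodes n+1..2n-2, and `edge` is an undirected m x 2 integer matrix with
# m = 2n-3 (n >= 2; a two-taxon tree is the single tip-tip edge).

#' Construct an unrooted binary tree
#'
#' Low-level constructor for the `me_tree` representation: tips are nodes
#' `1..n`, internal nodes `n+1..2n-2`, `edge` is an undirected
#' `(2n-3) x 2` integer matrix (a two-taxon tree is the single tip-tip
#' edge). `me_score` defaults to the sum of the branch lengths.
#'
#' @param tip.label Character vector of tip labels.
#' @param edge Undirected edge matrix.
#' @param edge.length Optional branch lengths, one per edge row.
#' @param me_score,ssq Optional fit statistics (see
#'   [ols_branch_lengths()]).
#' @return An object of class `me_tree`.
#' @export
new_me_tree <- function(tip.label, edge, edge.length = NULL,
                        me_score = NULL, ssq = NULL) {
  n <- length(tip.label)
  stopifnot(n >= 2L, is.matrix(edge), ncol(edge) == 2L)
  if (nrow(edge) != 2L * n - 3L)
    stop("expected ", 2L * n - 3L, " edges for ", n, " tips", call. = FALSE)
  if (!is.null(edge.length)) stopifnot(length(edge.length) == nrow(edge))
  structure(list(tip.label = tip.label, edge = edge,
                 edge.length = edge.length,
                 me_score = if (!is.null(edge.length) && is.null(me_score))
                   sum(edge.length) else me_score,
                 ssq = ssq),
            class = "me_tree")
}

#' @export
print.me_tree <- function(x, ...) {
  cat("unrooted binary tree:", length(x$tip.label), "tips")
  if (!is.null(x$me_score)) cat(sprintf(", ME score %.6g", x$me_score))
  cat("\n")
  invisible(x)
}

.adjacency <- function(edge, n_nodes) {
  adj <- vector("list", n_nodes)
  for (k in seq_len(nrow(edge))) {
    a <- edge[k, 1L]; b <- edge[k, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Logical m x n matrix: tips lying on the far-from-root side of each edge.
.edge_splits <- function(tree) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  m <- nrow(edge)
  if (n == 2L) return(matrix(c(TRUE, FALSE), 1L, 2L))
  n_nodes <- 2L * n - 2L
  adj <- .adjacency(edge, n_nodes)
  root <- n + 1L
  parent <- integer(n_nodes)
  order_ <- integer(n_nodes)
  stack <- root; parent[root] <- 0L; cnt <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    cnt <- cnt + 1L; order_[cnt] <- v
    for (w in adj[[v]]) if (w != parent[v]) {
      parent[w] <- v
      stack <- c(stack, w)
    }
  }
  below <- matrix(FALSE, n_nodes, n)
  for (v in rev(order_[seq_len(cnt)])) {
    if (v <= n) below[v, v] <- TRUE
    else for (w in adj[[v]]) if (w != parent[v]) below[v, ] <- below[v, ] | below[w, ]
  }
  splits <- matrix(FALSE, m, n)
  for (k in seq_len(m)) {
    a <- edge[k, 1L]; b <- edge[k, 2L]
    child <- if (parent[a] == b) a else b
    splits[k, ] <- below[child, ]
  }
  splits
}

#' Fit OLS branch lengths to a fixed topology
#'
#' Branch lengths minimize the sum of squared differences between the input
#' distances and the tree path lengths. The ME score is the raw sum of the
#' fitted lengths; negative lengths are kept in the score (they are clamped
#' to zero only when a Newick string is emitted).
#'
#' @param tree An `me_tree` topology (lengths, if present, are ignored).
#' @param D Symmetric distance matrix over `tree$tip.label`.
#' @return The tree with fitted `edge.length`, `me_score` (sum of lengths)
#'   and `ssq` (residual sum of squares).
#' @export
ols_branch_lengths <- function(tree, D) {
  stopifnot(inherits(tree, "me_tree"))
  D <- .check_dist(D)
  lab <- tree$tip.label
  stopifnot(setequal(lab, rownames(D)))
  D <- D[lab, lab]
  n <- length(lab)
  splits <- .edge_splits(tree)
  ut <- upper.tri(D)
  ii <- row(D)[ut]; jj <- col(D)[ut]
  dvec <- D[ut]
  M <- (splits[, ii, drop = FALSE] != splits[, jj, drop = FALSE]) * 1
  G <- tcrossprod(M)
  rhs <- as.vector(M %*% dvec)
  b <- tryCatch(solve(G, rhs), error = function(e) as.vector(MASS::ginv(G) %*% rhs))
  resid <- dvec - as.vector(crossprod(M, b))
  new_me_tree(lab, tree$edge, edge.length = as.numeric(b),
              me_score = sum(b), ssq = sum(resid^2))
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on the Q-criterion. Ties in Q are
#' broken by the smallest (i, j) index pair in the current node ordering
#' (original taxa first, joined nodes appended), so the result is fully
#' deterministic. For two taxa the tree is the single edge of length
#' `d`; for three taxa the star with closed-form branch lengths.
#'
#' @param D Symmetric distance matrix with taxon dimnames.
#' @return An `me_tree` with NJ branch lengths (`me_score` = their sum).
#' @export
nj_tree <- function(D) {
  D <- .check_dist(D)
  n <- nrow(D)
  lab <- rownames(D)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (n == 2L)
    return(new_me_tree(lab, matrix(c(1L, 2L), 1L), edge.length = D[1L, 2L]))
  active <- seq_len(n)
  cur <- unname(D)
  next_id <- n + 1L
  E <- matrix(0L, 2L * n - 3L, 2L); L <- numeric(2L * n - 3L); ne <- 0L
  push <- function(a, b, len) {
    ne <<- ne + 1L; E[ne, ] <<- c(a, b); L[ne] <<- len
  }
  while (length(active) > 3L) {
    k <- length(active)
    r <- rowSums(cur)
    Q <- (k - 2) * cur - outer(r, r, "+")
    diag(Q) <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    dij <- cur[i, j]
    li <- 0.5 * dij + (r[i] - r[j]) / (2 * (k - 2))
    lj <- dij - li
    push(next_id, active[i], li)
    push(next_id, active[j], lj)
    dnew <- 0.5 * (cur[i, ] + cur[j, ] - dij)
    keep <- setdiff(seq_len(k), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    active <- c(active[keep], next_id)
    next_id <- next_id + 1L
  }
  a <- active
  b1 <- (cur[1, 2] + cur[1, 3] - cur[2, 3]) / 2
  b2 <- (cur[1, 2] + cur[2, 3] - cur[1, 3]) / 2
  b3 <- (cur[1, 3] + cur[2, 3] - cur[1, 2]) / 2
  push(next_id, a[1L], b1); push(next_id, a[2L], b2); push(next_id, a[3L], b3)
  new_me_tree(lab, E, edge.length = L)
}

#' Canonical topology string of an unrooted tree
#'
#' A branch-length-free Newick-like string, rooted at the internal node
#' adjacent to the lexicographically smallest tip with subtrees sorted
#' recursively: two `me_tree`s describe the same unrooted topology exactly
#' when their canonical strings are equal. Used for topology comparison
#' and for tie-breaking in [exhaustive_me()].
#'
#' @param tree An `me_tree`.
#' @return A character string.
#' @export
canonical_topology <- function(tree) {
  n <- length(tree$tip.label)
  if (n == 2L) return(paste0("(", paste(sort(tree$tip.label), collapse = ","), ")"))
  adj <- .adjacency(tree$edge, 2L * n - 2L)
  first_tip <- which.min(rank(tree$tip.label))  # index of smallest label
  root <- adj[[first_tip]][1L]
  rec <- function(v, from) {
    if (v <= n) return(tree$tip.label[v])
    kids <- setdiff(adj[[v]], from)
    paste0("(", paste(sort(vapply(kids, rec, character(1), from = v)),
                      collapse = ","), ")")
  }
  kids <- adj[[root]]
  paste0("(", paste(sort(vapply(kids, rec, character(1), from = root)),
                    collapse = ","), ")")
}

#' Convert an `me_tree` to an ape `phylo` object
#'
#' Internal nodes are renumbered in preorder as ape requires. Negative OLS
#' branch lengths are preserved here; use `clamp = TRUE` (the default of
#' [write_newick()]) to floor them at zero for presentation.
#'
#' @param x An `me_tree`.
#' @param clamp Floor negative branch lengths at zero.
#' @param ... Unused.
#' @return An object of class `phylo`.
#' @export
as.phylo.me_tree <- function(x, clamp = FALSE, ...) {
  n <- length(x$tip.label)
  len <- x$edge.length
  if (!is.null(len) && clamp) len <- pmax(len, 0)
  if (n == 2L) {
    phy <- list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                tip.label = x$tip.label, Nnode = 1L)
    if (!is.null(len)) phy$edge.length <- c(len / 2, len / 2)
    class(phy) <- "phylo"
    attr(phy, "order") <- "cladewise"
    return(phy)
  }
  n_nodes <- 2L * n - 2L
  adj_idx <- vector("list", n_nodes)   # adjacency carrying edge row indices
  for (k in seq_len(nrow(x$edge))) {
    a <- x$edge[k, 1L]; b <- x$edge[k, 2L]
    adj_idx[[a]] <- rbind(adj_idx[[a]], c(b, k))
    adj_idx[[b]] <- rbind(adj_idx[[b]], c(a, k))
  }
  root <- n + 1L
  newid <- integer(n_nodes)
  newid[seq_len(n)] <- seq_len(n)
  next_int <- n + 1L
  E <- matrix(0L, nrow(x$edge), 2L); LL <- numeric(nrow(x$edge)); ne <- 0L
  # preorder DFS assigning ape-style internal ids
  visit <- function(v, from) {
    if (v > n) { newid[v] <<- next_int; next_int <<- next_int + 1L }
    for (r in seq_len(nrow(adj_idx[[v]]))) {
      w <- adj_idx[[v]][r, 1L]; k <- adj_idx[[v]][r, 2L]
      if (w == from) next
      ne <<- ne + 1L
      E[ne, ] <<- c(v, w)       # old ids; remapped after traversal
      LL[ne] <<- if (is.null(len)) NA_real_ else len[k]
      visit(w, v)
    }
  }
  visit(root, 0L)
  E[] <- newid[E]
  # unrooted binary tree: root is the basal trifurcation, Nnode = n - 2
  phy <- list(edge = E, tip.label = x$tip.label, Nnode = n - 2L)
  if (!is.null(len)) phy$edge.length <- LL
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

#' Write an `me_tree` as a Newick string
#'
#' @param tree An `me_tree` with branch lengths.
#' @param file Optional path; when `NULL` the string is returned.
#' @param clamp Floor negative OLS branch lengths at zero (default), as in
#'   the emitted trees; the ME score itself always uses raw lengths.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, clamp = TRUE) {
  phy <- as.phylo.me_tree(tree, clamp = clamp)
  s <- ape::write.tree(phy)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Simulate an additive distance matrix from a random tree
#'
#' Draws a random unrooted binary topology by sequential leaf insertion,
#' assigns branch lengths uniformly from `branch_range`, and returns the
#' matrix of exact path-length distances together with the generating tree.
#' Additive matrices are the standard oracle for distance-method tests:
#' NJ must reconstruct them exactly.
#'
#' @param n Number of taxa (>= 3).
#' @param branch_range Length-2 numeric range for branch lengths.
#' @param labels Optional tip labels, default `t1..tn`.
#' @return List with `tree` (`me_tree` with lengths) and `D`.
#' @export
simulate_additive_distances <- function(n, branch_range = c(0.1, 1),
                                        labels = paste0("t", seq_len(n))) {
  stopifnot(n >= 3L)
  edge <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
  if (n > 3L) for (k in 4L:n) {
    e <- sample.int(nrow(edge), 1L)
    w <- n + k - 2L
    old <- edge[e, ]
    edge[e, ] <- c(old[1L], w)
    edge <- rbind(edge, c(w, old[2L]), c(w, k))
  }
  len <- stats::runif(nrow(edge), branch_range[1L], branch_range[2L])
  tree <- new_me_tree(labels, edge, edge.length = len)
  splits <- .edge_splits(tree)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- sum(len[splits[, i] != splits[, j]])
  }
  list(tree = tree, D = D)
}
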
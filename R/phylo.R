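#' Euclidean distance matrix between PCNVs
#'
#' Plain Euclidean distance over the 18 components, with no scaling or
#' weighting of components.
#'
#' @param vectors Numeric matrix from [compute_pcnv_matrix()]: one row per
#'   sequence, 18 columns, unique rownames.
#' @return Symmetric numeric matrix with zero diagonal, labeled by the
#'   sequence ids.
#' @export
pcnv_dist <- function(vectors) {
  if (is.null(dim(vectors)) || ncol(vectors) != 18L)
    abort_input("expected a matrix with 18 PCNV columns")
  if (nrow(vectors) < 2L)
    abort_input("need at least 2 vectors to compute distances")
  ids <- rownames(vectors)
  if (is.null(ids) || anyDuplicated(ids))
    abort_input("vector rownames (ids) must be present and unique")
  as.matrix(stats::dist(vectors, method = "euclidean"))
}

validate_distmat <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort_input("distance matrix must be square")
  if (!isSymmetric(unname(d), tol = 1e-12))
    abort_input("distance matrix must be symmetric")
  if (any(d < 0)) abort_input("distance matrix must be nonnegative")
  if (is.null(rownames(d))) rownames(d) <- colnames(d)
  if (is.null(rownames(d))) rownames(d) <- paste0("t", seq_len(nrow(d)))
  if (anyDuplicated(rownames(d))) abort_input("duplicate taxon labels")
  colnames(d) <- rownames(d)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou–Nei neighbor joining: repeatedly join the pair (i, j)
#' minimizing the Q-criterion Q(i,j) = (m-2) d(i,j) - r_i - r_j (with r the
#' row sums of the current matrix), assign branch lengths, and reduce the
#' matrix, closing with the standard three-taxon formula. The result is the
#' unrooted tree (an `ape` \code{phylo} with a basal trifurcation).
#'
#' Determinism: Q ties are broken by the lowest (i, j) index pair in current
#' matrix order. Negative branch lengths are clamped to 0 unless
#' `allow_negative`; pre-clamp values are kept in the `clamped` attribute of
#' the result.
#'
#' @param d Symmetric nonnegative distance matrix with unique labels,
#'   at least 3 taxa.
#' @param allow_negative Keep negative branch lengths instead of clamping.
#' @return An object of class \code{phylo}.
#' @export
nj_tree <- function(d, allow_negative = FALSE) {
  d <- validate_distmat(d)
  n <- nrow(d)
  if (n < 3L) abort_input("neighbor joining needs at least 3 taxa")
  labels <- rownames(d)

  # active[k] is the tree-node id of the k-th row of the working matrix;
  # tips are 1..n, internal nodes are created from n+1 upward.
  active <- seq_len(n)
  D <- unname(d)
  next_node <- n + 1L
  # children[[as.character(node)]] = list of c(child_node, branch_length)
  children <- list()
  clamped <- list()

  add_child <- function(parent, child, len) {
    key <- as.character(parent)
    if (!allow_negative && len < 0) {
      clamped[[length(clamped) + 1L]] <<- c(node = child, length = len)
      len <- 0
    }
    children[[key]] <<- c(children[[key]], list(c(child, len)))
  }

  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    f <- cand[1L, 1L]; g <- cand[1L, 2L]

    bf <- 0.5 * D[f, g] + (r[f] - r[g]) / (2 * (m - 2))
    bg <- D[f, g] - bf
    u <- next_node; next_node <- next_node + 1L
    add_child(u, active[f], bf)
    add_child(u, active[g], bg)

    keep <- setdiff(seq_len(m), c(f, g))
    du <- 0.5 * (D[f, keep] + D[g, keep] - D[f, g])
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du), c(du, 0))
    active <- c(active[keep], u)
  }

  # close with the standard three-taxon star formulas
  root <- next_node
  b1 <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  b2 <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  b3 <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  add_child(root, active[1L], b1)
  add_child(root, active[2L], b2)
  add_child(root, active[3L], b3)

  # assemble the ape phylo: renumber internal nodes in preorder from n+1
  n_internal <- root - n
  new_id <- integer(root)
  new_id[seq_len(n)] <- seq_len(n)
  edges <- matrix(0L, nrow = n + n_internal - 1L, ncol = 2L)
  lens <- numeric(nrow(edges))
  counter_node <- n
  counter_edge <- 0L
  recurse <- function(old_node) {
    counter_node <<- counter_node + 1L
    new_id[old_node] <<- counter_node
    me <- counter_node
    for (ch in children[[as.character(old_node)]]) {
      counter_edge <<- counter_edge + 1L
      e <- counter_edge
      edges[e, 1L] <<- me
      lens[e] <<- ch[2L]
      if (ch[1L] <= n) {
        edges[e, 2L] <<- as.integer(ch[1L])
      } else {
        edges[e, 2L] <<- 0L  # patched after recursion
        child_slot <- e
        recurse(as.integer(ch[1L]))
        edges[child_slot, 2L] <<- new_id[ch[1L]]
      }
    }
  }
  recurse(root)

  tree <- structure(list(edge = edges, edge.length = lens,
                         tip.label = labels, Nnode = n_internal),
                    class = "phylo", order = "cladewise")
  if (length(clamped) > 0L)
    attr(tree, "clamped") <- do.call(rbind, clamped)
  tree
}

# Quote a label for Newick output when it contains characters that would
# otherwise be structural; internal single quotes are doubled.
newick_label <- function(x) {
  needs <- grepl("[][ \t(),:;']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs], fixed = TRUE), "'")
  x
}

#' Serialize a tree to Newick text
#'
#' Writes branch lengths and quotes labels containing Newick-special
#' characters. The output is readable by `ape::read.tree` and any standard
#' Newick consumer.
#'
#' @param tree A \code{phylo} object.
#' @param file Optional path; when given the Newick string is also written
#'   there.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when `file` is given).
#' @export
to_newick <- function(tree, file = NULL, digits = 10L) {
  if (!inherits(tree, "phylo")) abort_input("expected a phylo object")
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt <- function(x) sprintf("%.*g", digits, x)
  labels <- newick_label(tree$tip.label)
  serialize <- function(node) {
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(e) {
      child <- tree$edge[e, 2L]
      sub <- if (child <= n) labels[child] else serialize(child)
      if (is.null(tree$edge.length)) sub
      else paste0(sub, ":", fmt(tree$edge.length[e]))
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(serialize(n + 1L), ";")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
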
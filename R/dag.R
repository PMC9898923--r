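# Directed acyclic graphs over named binary variables.
#
# Internal representation: logical adjacency matrix A with A[parent, child].
# Acyclicity is enforced on construction and on every edge addition.

#' Construct a DAG
#'
#' @param nodes character vector of unique node names; their order is the
#'   canonical order used for deterministic tie-breaking everywhere.
#' @param edges optional 2-column matrix or data frame of (parent, child)
#'   pairs. Self-loops, duplicate edges and cycles are errors.
#' @return a `bn_dag`.
#' @export
#' @examples
#' bn_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
bn_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) < 1 || anyDuplicated(nodes)) {
    stop("'nodes' must be a non-empty vector of unique names")
  }
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  dag <- structure(list(nodes = nodes, A = A), class = "bn_dag")
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    for (i in seq_len(nrow(edges))) {
      dag <- add_edge(dag, edges[i, 1], edges[i, 2])
    }
  }
  dag
}

# Directed path from -> to? (BFS over children; integer node indices.)
has_path_idx <- function(A, from, to) {
  seen <- logical(nrow(A))
  frontier <- from
  seen[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen[to]
}

#' Add a directed edge
#'
#' @param dag a `bn_dag`.
#' @param parent,child node names.
#' @return the extended `bn_dag`; cycle, self-loop or duplicate -> error.
#' @export
add_edge <- function(dag, parent, child) {
  i <- match(parent, dag$nodes)
  j <- match(child, dag$nodes)
  if (is.na(i) || is.na(j)) stop("unknown node in edge ", parent, " -> ", child)
  if (i == j) stop("self-loop on node ", parent)
  if (dag$A[i, j]) stop("duplicate edge ", parent, " -> ", child)
  if (has_path_idx(dag$A, j, i)) {
    stop("edge ", parent, " -> ", child, " would create a cycle")
  }
  dag$A[i, j] <- TRUE
  dag
}

#' Edges of a DAG
#'
#' @param dag a `bn_dag`.
#' @return 2-column character matrix (`parent`, `child`), rows ordered by
#'   canonical (parent, child) node order.
#' @export
dag_edges <- function(dag) {
  w <- which(dag$A, arr.ind = TRUE)
  w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
  out <- cbind(parent = dag$nodes[w[, 1]], child = dag$nodes[w[, 2]])
  rownames(out) <- NULL
  out
}

#' Parents of a node
#' @param dag a `bn_dag`.
#' @param node node name.
#' @return character vector of parent names in canonical order.
#' @export
parents_of <- function(dag, node) {
  j <- match(node, dag$nodes)
  if (is.na(j)) stop("unknown node: ", node)
  dag$nodes[dag$A[, j]]
}

#' Children of a node
#' @inheritParams parents_of
#' @return character vector of child names in canonical order.
#' @export
children_of <- function(dag, node) {
  i <- match(node, dag$nodes)
  if (is.na(i)) stop("unknown node: ", node)
  dag$nodes[dag$A[i, ]]
}

# Kahn topological sort, preferring the smallest canonical index; errors on a
# cycle (cannot happen for a bn_dag built through the constructors).
topo_sort <- function(dag) {
  A <- dag$A
  n <- nrow(A)
  indeg <- colSums(A)
  out <- integer(0)
  avail <- which(indeg == 0)
  done <- logical(n)
  while (length(avail)) {
    v <- min(avail)
    out <- c(out, v)
    done[v] <- TRUE
    ch <- which(A[v, ])
    indeg[ch] <- indeg[ch] - 1L
    avail <- which(indeg == 0 & !done)
  }
  if (length(out) != n) stop("graph contains a cycle")
  dag$nodes[out]
}

#' @export
print.bn_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat("<bn_dag> ", length(x$nodes), " node(s), ", nrow(e), " edge(s)\n", sep = "")
  if (nrow(e)) {
    cat(paste0("  ", e[, 1], " -> ", e[, 2], collapse = "\n"), "\n", sep = "")
  }
  invisible(x)
}

#' Classify three-node patterns of a DAG
#'
#' Enumerates every unordered node triple whose induced subgraph has exactly
#' two edges and reports it once as one of the three canonical patterns:
#' chain (`x -> y -> z`), fork (`x <- y -> z`, a common cause) or collider
#' (`x -> y <- z`, a common effect). `y` is always the middle node; `x`/`z`
#' are ordered canonically for forks and colliders. Triples with any other
#' induced edge count are omitted. Terminology follows standard usage: the
#' fork is the common-cause pattern and the collider the common-effect
#' pattern.
#'
#' @param dag a `bn_dag`.
#' @return data frame with columns `x`, `y`, `z`, `kind`.
#' @export
classify_triples <- function(dag) {
  n <- length(dag$nodes)
  empty <- data.frame(x = character(0), y = character(0), z = character(0),
                      kind = character(0), stringsAsFactors = FALSE)
  if (n < 3) return(empty)
  trip <- combn(n, 3)
  rows <- vector("list", ncol(trip))
  for (c in seq_len(ncol(trip))) {
    t3 <- trip[, c]
    sub <- dag$A[t3, t3, drop = FALSE]
    if (sum(sub) != 2L) next
    e <- which(sub, arr.ind = TRUE)
    p <- t3[e[, 1]]
    ch <- t3[e[, 2]]
    if (ch[1] == ch[2]) {
      pa <- sort(p)
      rows[[c]] <- c(dag$nodes[pa[1]], dag$nodes[ch[1]], dag$nodes[pa[2]],
                     "collider")
    } else if (p[1] == p[2]) {
      cc <- sort(ch)
      rows[[c]] <- c(dag$nodes[cc[1]], dag$nodes[p[1]], dag$nodes[cc[2]],
                     "fork")
    } else if (ch[1] == p[2]) {
      rows[[c]] <- c(dag$nodes[p[1]], dag$nodes[ch[1]], dag$nodes[ch[2]],
                     "chain")
    } else if (ch[2] == p[1]) {
      rows[[c]] <- c(dag$nodes[p[2]], dag$nodes[ch[2]], dag$nodes[ch[1]],
                     "chain")
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("x", "y", "z", "kind")
  out
}
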
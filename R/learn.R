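# Structure learning: BIC-scored greedy hill climbing and the Chow-Liu tree.

#' Learn a DAG by BIC hill climbing
#'
#' Greedy search over single-edge moves (add, delete, reverse) maximizing
#' [bic_score()], starting from the empty graph and stopping at a local
#' optimum. When `root` is given, edges into the root are forbidden, so the
#' root can only ever be an ancestor. The search is deterministic: candidate
#' moves are enumerated in a fixed canonical order (adds, then deletes, then
#' reverses, each by (parent, child) node index) and only a strict score
#' improvement is accepted, so exact ties keep the earlier move and an
#' all-tie neighbourhood keeps the current graph. Constant data columns are
#' left isolated with a warning. With `restarts > 0` the search is repeated
#' from randomly perturbed versions of the current optimum (seeded), keeping
#' the best-scoring result.
#'
#' @param data a `sens_matrix` or binary matrix with named columns
#'   (>= 2 columns, >= 10 rows).
#' @param root optional node name that may not receive incoming edges.
#' @param max_parents maximum in-degree (default 4).
#' @param restarts number of random restarts (default 0, fully deterministic).
#' @param seed RNG seed for the restarts (unused when `restarts = 0`).
#' @return a `bn_dag`.
#' @export
learn_structure_hc <- function(data, root = NULL, max_parents = 4,
                               restarts = 0, seed = NULL) {
  d <- as_binary_matrix(data)
  nodes <- colnames(d)
  p <- length(nodes)
  n <- nrow(d)
  if (p < 2) stop("need at least two columns")
  if (n < 10) stop("need at least 10 rows")
  if (!is.null(root) && !root %in% nodes) stop("unknown root node: ", root)
  root_j <- if (is.null(root)) 0L else match(root, nodes)
  const <- apply(d, 2, function(x) all(x == x[1]))
  if (any(const)) {
    warning("constant column(s) left isolated: ",
            paste(nodes[const], collapse = ", "))
  }

  cache <- new.env(parent = emptyenv())
  fam <- function(j, pa_idx) {
    key <- paste(j, paste(sort(pa_idx), collapse = ","), sep = "|")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- family_loglik(d[, j], d[, pa_idx, drop = FALSE]) -
        log(n) / 2 * 2^length(pa_idx)
      cache[[key]] <- val
    }
    val
  }

  climb <- function(A) {
    f <- vapply(seq_len(p), function(j) fam(j, which(A[, j])), 0)
    eps <- 1e-10
    repeat {
      best <- 0
      bm <- NULL
      for (u in seq_len(p)) {
        for (v in seq_len(p)) {
          if (u == v || const[u] || const[v] || A[u, v] || v == root_j) next
          if (sum(A[, v]) >= max_parents) next
          if (has_path_idx(A, v, u)) next
          delta <- fam(v, c(which(A[, v]), u)) - f[v]
          if (delta > best + eps) {
            best <- delta
            bm <- c(1L, u, v)
          }
        }
      }
      for (u in seq_len(p)) {
        for (v in seq_len(p)) {
          if (!A[u, v]) next
          delta <- fam(v, setdiff(which(A[, v]), u)) - f[v]
          if (delta > best + eps) {
            best <- delta
            bm <- c(2L, u, v)
          }
        }
      }
      for (u in seq_len(p)) {
        for (v in seq_len(p)) {
          if (!A[u, v] || u == root_j) next
          if (sum(A[, u]) >= max_parents) next
          A2 <- A
          A2[u, v] <- FALSE
          if (has_path_idx(A2, u, v)) next
          delta <- (fam(v, which(A2[, v])) - f[v]) +
            (fam(u, c(which(A[, u]), v)) - f[u])
          if (delta > best + eps) {
            best <- delta
            bm <- c(3L, u, v)
          }
        }
      }
      if (is.null(bm)) break
      u <- bm[2]
      v <- bm[3]
      if (bm[1] == 1L) {
        A[u, v] <- TRUE
      } else if (bm[1] == 2L) {
        A[u, v] <- FALSE
      } else {
        A[u, v] <- FALSE
        A[v, u] <- TRUE
        f[u] <- fam(u, which(A[, u]))
      }
      f[v] <- fam(v, which(A[, v]))
    }
    list(A = A, score = sum(f))
  }

  empty <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  best <- climb(empty)
  if (restarts > 0) {
    best <- run_seeded(seed, function() {
      cur <- best
      for (r in seq_len(restarts)) {
        A <- perturb_dag(cur$A, root_j, const, max_parents, n_moves = 2L)
        cand <- climb(A)
        if (cand$score > cur$score + 1e-10) cur <- cand
      }
      cur
    })
  }
  structure(list(nodes = nodes, A = best$A), class = "bn_dag")
}

# Random legal edge toggles used between hill-climbing restarts.
perturb_dag <- function(A, root_j, const, max_parents, n_moves = 2L) {
  p <- nrow(A)
  for (m in seq_len(n_moves)) {
    cand <- which(upper.tri(A) | lower.tri(A))
    for (pick in sample(cand)) {
      u <- (pick - 1L) %% p + 1L
      v <- (pick - 1L) %/% p + 1L
      if (const[u] || const[v]) next
      if (A[u, v]) {
        A[u, v] <- FALSE
        break
      }
      if (v == root_j || sum(A[, v]) >= max_parents) next
      if (has_path_idx(A, v, u)) next
      A[u, v] <- TRUE
      break
    }
  }
  A
}

# Mutual information of two binary vectors from the 2x2 contingency table,
# natural log, with 0*log(0) = 0.
mutual_info <- function(x, y) {
  n <- length(x)
  tab <- c(sum(x == 0L & y == 0L), sum(x == 1L & y == 0L),
           sum(x == 0L & y == 1L), sum(x == 1L & y == 1L)) / n
  px <- c(tab[1] + tab[3], tab[2] + tab[4])
  py <- c(tab[1] + tab[2], tab[3] + tab[4])
  prod_marg <- c(px[1] * py[1], px[2] * py[1], px[1] * py[2], px[2] * py[2])
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / prod_marg[nz]))
}

#' Learn a Chow-Liu tree
#'
#' Maximum-weight spanning tree on pairwise mutual information (natural log),
#' oriented away from `root`, so every non-root node has exactly one parent.
#' Fully deterministic: Kruskal's algorithm with ties broken by canonical
#' (smaller, larger) node-index order. A constant column has zero mutual
#' information with everything; it is kept in the tree (attached through a
#' zero-weight edge) with a warning.
#'
#' @param data a `sens_matrix` or binary matrix with named columns.
#' @param root node name used as the orientation root.
#' @return a `bn_dag` with `ncol(data) - 1` edges.
#' @export
learn_structure_chowliu <- function(data, root) {
  d <- as_binary_matrix(data)
  nodes <- colnames(d)
  p <- length(nodes)
  if (p < 2) stop("need at least two columns")
  if (!root %in% nodes) stop("unknown root node: ", root)
  const <- apply(d, 2, function(x) all(x == x[1]))
  if (any(const)) {
    warning("constant column(s) carry zero mutual information: ",
            paste(nodes[const], collapse = ", "))
  }

  pairs <- t(combn(p, 2))
  mi <- apply(pairs, 1, function(ij) mutual_info(d[, ij[1]], d[, ij[2]]))
  ord <- order(-mi, pairs[, 1], pairs[, 2])

  parent <- seq_len(p) # union-find
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  chosen <- matrix(0L, 0, 2)
  for (k in ord) {
    i <- pairs[k, 1]
    j <- pairs[k, 2]
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      chosen <- rbind(chosen, c(i, j))
      if (nrow(chosen) == p - 1) break
    }
  }

  und <- matrix(FALSE, p, p)
  und[chosen] <- TRUE
  und <- und | t(und)
  A <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  r <- match(root, nodes)
  visited <- logical(p)
  visited[r] <- TRUE
  frontier <- r
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      nb <- which(und[u, ] & !visited)
      A[u, nb] <- TRUE
      visited[nb] <- TRUE
      nxt <- c(nxt, nb)
    }
    frontier <- sort(nxt)
  }
  structure(list(nodes = nodes, A = A), class = "bn_dag")
}
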
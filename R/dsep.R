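# d-separation via the moralized ancestral graph criterion: X and Y are
# d-separated by Z iff they are disconnected in the moralized subgraph
# induced by the ancestors of X, Y and Z once Z is removed.

#' Test d-separation
#'
#' Returns `TRUE` when every path between `x` and `y` is blocked by `given`
#' under the standard rules (a chain or fork node blocks when conditioned on;
#' a collider blocks unless it — or a descendant — is conditioned on).
#' Every d-separation entailed by the DAG corresponds to a conditional
#' independence in any distribution that factorizes over it.
#'
#' @param dag a `bn_dag`.
#' @param x,y disjoint sets of node names.
#' @param given conditioning set, disjoint from `x` and `y` (may be empty).
#' @return logical.
#' @export
#' @examples
#' chain <- bn_dag(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
#' d_separated(chain, "X", "Z")              # FALSE
#' d_separated(chain, "X", "Z", given = "Y") # TRUE
d_separated <- function(dag, x, y, given = character(0)) {
  all_named <- c(x, y, given)
  if (!all(all_named %in% dag$nodes)) {
    stop("unknown node(s): ",
         paste(setdiff(all_named, dag$nodes), collapse = ", "))
  }
  if (length(intersect(x, y)) || length(intersect(x, given)) ||
      length(intersect(y, given))) {
    stop("'x', 'y' and 'given' must be disjoint")
  }

  # ancestral closure of x, y and given
  idx <- match(unique(all_named), dag$nodes)
  seen <- logical(length(dag$nodes))
  seen[idx] <- TRUE
  frontier <- idx
  while (length(frontier)) {
    pa <- which(rowSums(dag$A[, frontier, drop = FALSE]) > 0 & !seen)
    seen[pa] <- TRUE
    frontier <- pa
  }
  anc <- which(seen)

  A <- dag$A[anc, anc, drop = FALSE]
  U <- A | t(A)
  # moralize: marry parents sharing a child
  for (j in seq_len(ncol(A))) {
    pa <- which(A[, j])
    if (length(pa) > 1) {
      U[pa, pa] <- TRUE
    }
  }
  diag(U) <- FALSE
  keep <- !rownames(U) %in% given
  U <- U[keep, keep, drop = FALSE]

  start <- match(intersect(x, rownames(U)), rownames(U))
  targets <- match(intersect(y, rownames(U)), rownames(U))
  if (!length(start) || !length(targets)) {
    return(TRUE)
  }
  reach <- logical(nrow(U))
  reach[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- which(colSums(U[frontier, , drop = FALSE]) > 0 & !reach)
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  !any(reach[targets])
}
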
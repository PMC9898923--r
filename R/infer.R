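# Exact inference: joint probabilities, full-joint enumeration (the testing
# oracle), variable elimination, and ancestral sampling.

#' Joint probability of a full assignment
#'
#' Product over nodes of the relevant CPT entries, following the DAG
#' factorization. Touching an undefined (`NA`) CPT entry is an error.
#'
#' @param net a `bn_fit`.
#' @param assignment named 0/1 vector covering every node.
#' @return the joint probability.
#' @export
joint_probability <- function(net, assignment) {
  assignment <- check_assignment(assignment)
  nodes <- net$dag$nodes
  if (!setequal(names(assignment), nodes)) {
    stop("assignment must cover all nodes exactly")
  }
  a <- assignment[nodes]
  prob <- 1
  for (v in nodes) {
    cpt <- net$cpts[[v]]
    pv <- cpt_prob(cpt, a[[v]],
                   matrix(a[cpt$parents], nrow = 1))
    if (is.na(pv)) {
      stop("undefined CPT entry touched for node ", v)
    }
    prob <- prob * pv
  }
  unname(prob)
}

# Full joint table: all 2^n assignments (columns in node order) and their
# probabilities. The enumeration oracle behind brute_force_query() and the
# fixture validity checks; refuses more than `max_nodes` nodes.
enumerate_joint <- function(net, max_nodes = 16L) {
  nodes <- net$dag$nodes
  n <- length(nodes)
  if (n > max_nodes) {
    stop("refusing to enumerate more than ", max_nodes, " nodes")
  }
  B <- bitgrid(n)
  colnames(B) <- nodes
  p <- rep(1, nrow(B))
  for (v in nodes) {
    cpt <- net$cpts[[v]]
    if (anyNA(cpt$p1)) stop("undefined CPT entry in node ", v)
    p <- p * cpt_prob(cpt, B[, v], B[, cpt$parents, drop = FALSE])
  }
  list(assignments = B, p = p)
}

# Exact marginal P(node = 1) for every node, by enumeration.
bn_marginals <- function(net) {
  j <- enumerate_joint(net)
  setNames(as.vector(crossprod(j$assignments, j$p)), net$dag$nodes)
}

new_query_result <- function(probability, target, evidence, support_count,
                             undefined = FALSE) {
  structure(list(probability = probability, target = target,
                 evidence = evidence, support_count = support_count,
                 undefined = undefined),
            class = "bn_query")
}

#' @export
print.bn_query <- function(x, ...) {
  fmt <- function(a) {
    if (!length(a)) return("-")
    paste(names(a), "=", a, collapse = ", ")
  }
  cat("P(", fmt(x$target), " | ", fmt(x$evidence), ") = ",
      if (x$undefined) "undefined (evidence has probability 0)"
      else sprintf("%.6f", x$probability),
      "  [", x$support_count, " joint states]\n", sep = "")
  invisible(x)
}

check_query_args <- function(net, target, evidence) {
  target <- parse_assignment(target)
  evidence <- parse_assignment(evidence)
  if (!length(target)) stop("'target' must assign at least one variable")
  if (length(intersect(names(target), names(evidence)))) {
    stop("target and evidence overlap: ",
         paste(intersect(names(target), names(evidence)), collapse = ", "))
  }
  unknown <- setdiff(c(names(target), names(evidence)), net$dag$nodes)
  if (length(unknown)) stop("unknown node(s): ", paste(unknown, collapse = ", "))
  list(target = target, evidence = evidence)
}

#' Conditional probability query by brute-force enumeration
#'
#' Reference implementation of [query()]: sums the explicitly enumerated
#' joint table (at most 16 nodes, 2^16 states). `support_count` is the number
#' of joint states compatible with the evidence.
#'
#' @param net a `bn_fit` with at most 16 nodes.
#' @param target named 0/1 vector (or `"A=1,B=0"` string), disjoint from
#'   `evidence`.
#' @param evidence named 0/1 vector or string; may be empty.
#' @return a `bn_query`; if the evidence has probability zero the result is
#'   flagged `undefined` with probability `NA`, never silently 0.
#' @export
brute_force_query <- function(net, target, evidence = integer(0)) {
  qa <- check_query_args(net, target, evidence)
  target <- qa$target
  evidence <- qa$evidence
  j <- enumerate_joint(net)
  B <- j$assignments
  match_rows <- function(a) {
    ok <- rep(TRUE, nrow(B))
    for (v in names(a)) ok <- ok & B[, v] == a[[v]]
    ok
  }
  ev_ok <- match_rows(evidence)
  p_e <- sum(j$p[ev_ok])
  support <- 2L^(length(net$dag$nodes) - length(evidence))
  if (p_e == 0) {
    return(new_query_result(NA_real_, target, evidence, support,
                            undefined = TRUE))
  }
  p_te <- sum(j$p[ev_ok & match_rows(target)])
  new_query_result(p_te / p_e, target, evidence, support)
}

## ---- factor algebra for variable elimination ----------------------------
# A factor is a list(vars, p): vars in canonical node order, p of length
# 2^|vars| indexed by 1 + sum(value_i * 2^(i-1)). bitgrid() row order makes
# reduction and marginalization simple subsetting.

cpt_to_factor <- function(cpt, node_order) {
  vars <- sort_canonical(c(cpt$node, cpt$parents), node_order)
  B <- bitgrid(length(vars))
  colnames(B) <- vars
  p <- cpt_prob(cpt, B[, cpt$node], B[, cpt$parents, drop = FALSE])
  list(vars = vars, p = p)
}

factor_reduce <- function(f, var, val) {
  i <- match(var, f$vars)
  if (is.na(i)) return(f)
  B <- bitgrid(length(f$vars))
  list(vars = f$vars[-i], p = f$p[B[, i] == val])
}

factor_marginalize <- function(f, var) {
  i <- match(var, f$vars)
  B <- bitgrid(length(f$vars))
  list(vars = f$vars[-i], p = f$p[B[, i] == 0] + f$p[B[, i] == 1])
}

factor_product <- function(f1, f2, node_order) {
  vars <- sort_canonical(union(f1$vars, f2$vars), node_order)
  B <- bitgrid(length(vars))
  colnames(B) <- vars
  idx_of <- function(f) {
    k <- length(f$vars)
    if (k == 0) return(rep(1L, nrow(B)))
    as.integer(B[, f$vars, drop = FALSE] %*% 2^(seq_len(k) - 1)) + 1L
  }
  list(vars = vars, p = f1$p[idx_of(f1)] * f2$p[idx_of(f2)])
}

#' Conditional probability query by variable elimination
#'
#' Computes `P(target | evidence)` exactly. Evidence is absorbed by factor
#' reduction; the remaining non-query variables are summed out one at a time
#' in min-degree order (the variable appearing with the fewest distinct
#' neighbours across current factors first, ties broken by canonical node
#' order), which keeps intermediate factors small. Agrees with
#' [brute_force_query()] to machine precision on any network both can handle.
#'
#' @inheritParams brute_force_query
#' @param net a `bn_fit`.
#' @return a `bn_query`; zero-probability evidence yields an `undefined` flag.
#' @export
query <- function(net, target, evidence = integer(0)) {
  qa <- check_query_args(net, target, evidence)
  target <- qa$target
  evidence <- qa$evidence
  nodes <- net$dag$nodes
  factors <- lapply(net$cpts, cpt_to_factor, node_order = nodes)
  for (v in names(evidence)) {
    factors <- lapply(factors, factor_reduce, var = v, val = evidence[[v]])
  }
  elim <- setdiff(nodes, c(names(target), names(evidence)))
  while (length(elim)) {
    deg <- vapply(elim, function(v) {
      nb <- unique(unlist(lapply(factors, function(f) {
        if (v %in% f$vars) f$vars else character(0)
      })))
      length(setdiff(nb, v))
    }, 0L)
    v <- elim[order(deg, match(elim, nodes))][1]
    has_v <- vapply(factors, function(f) v %in% f$vars, TRUE)
    prod_f <- Reduce(function(a, b) factor_product(a, b, nodes),
                     factors[has_v])
    factors <- c(factors[!has_v], list(factor_marginalize(prod_f, v)))
    elim <- setdiff(elim, v)
  }
  final <- Reduce(function(a, b) factor_product(a, b, nodes), factors)
  support <- 2L^(length(nodes) - length(evidence))
  z <- sum(final$p)
  if (z == 0) {
    return(new_query_result(NA_real_, target, evidence, support,
                            undefined = TRUE))
  }
  tvals <- target[final$vars]
  idx <- if (length(final$vars)) {
    as.integer(sum(tvals * 2^(seq_along(final$vars) - 1))) + 1L
  } else {
    1L
  }
  new_query_result(final$p[idx] / z, target, evidence, support)
}

#' Ancestral sampling from a Bayesian network
#'
#' Draws `n` joint binary profiles by sampling each node given its parents in
#' topological order. Reproducible for a fixed `seed`; the caller's RNG state
#' is preserved.
#'
#' @param net a `bn_fit` with fully defined CPTs.
#' @param n number of samples (>= 1).
#' @param seed optional RNG seed.
#' @return a `sens_matrix` (ids `S000001`, ..., no ages).
#' @export
sample_net <- function(net, n, seed = NULL) {
  if (n < 1) stop("'n' must be >= 1")
  run_seeded(seed, function() {
    nodes <- net$dag$nodes
    x <- matrix(0L, n, length(nodes), dimnames = list(NULL, nodes))
    for (v in topo_sort(net$dag)) {
      cpt <- net$cpts[[v]]
      if (anyNA(cpt$p1)) stop("undefined CPT entry in node ", v)
      p1 <- cpt_prob(cpt, rep(1L, n), x[, cpt$parents, drop = FALSE])
      x[, v] <- (runif(n) < p1) * 1L
    }
    new_sens_matrix(x, ids = sprintf("S%06d", seq_len(n)))
  })
}
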